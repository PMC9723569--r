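# Cross-plant summaries: shared-species membership, cohort-intersection
# tables (the upset-plot logic, emitted as tables), cumulative group series
# with harmonic fits, and alpha-diversity seasonality.

#' Shared-species membership across plants
#'
#' @param sets Named list of per-plant retained-species id vectors.
#' @return List: `membership` (logical species x plants matrix) and `counts`
#'   (data frame of intersection pattern, e.g. "PlantA+PlantC", with the
#'   number of species in each cell).
#' @export
shared_species <- function(sets) {
  stopifnot(length(sets) >= 2, !is.null(names(sets)))
  all_sp <- sort(unique(unlist(sets)))
  m <- vapply(sets, function(s) all_sp %in% s, logical(length(all_sp)))
  rownames(m) <- all_sp
  pattern <- apply(m, 1, function(r) paste(colnames(m)[r], collapse = "+"))
  tab <- table(pattern)
  counts <- data.frame(pattern = names(tab), n_species = as.integer(tab),
                       stringsAsFactors = FALSE)
  counts <- counts[order(-counts$n_species), , drop = FALSE]
  rownames(counts) <- NULL
  list(membership = m, counts = counts)
}

# cyclically adjacent season pairs; winter-summer and spring-autumn are
# opposite and can never be identical/concomitant
season_adjacent <- function(a, b) {
  adj <- list(winter = c("spring", "autumn"), spring = c("winter", "summer"),
              summer = c("spring", "autumn"), autumn = c("summer", "winter"))
  b %in% adj[[a]]
}

#' Cohort agreement of shared species across plants
#'
#' For each species with a cohort label in every plant it is shared across,
#' classifies the agreement of its labels: `identical` (one distinct
#' seasonal cohort), `concomitant` (exactly two distinct seasonal cohorts
#' that are cyclically adjacent seasons), `all-non-significant` (no seasonal
#' label anywhere), otherwise `mixed`. Non-significant labels are ignored
#' when testing adjacency but recorded in the intersection key.
#'
#' @param cohorts Character matrix, species x plants, of labels in
#'   winter/spring/summer/autumn/non-significant; `NA` where a species is
#'   not present in a plant.
#' @return Data frame: species_id, intersection (sorted distinct labels
#'   joined by "+"), n_plants, agreement.
#' @export
cohort_intersections <- function(cohorts) {
  cohorts <- as.matrix(cohorts)
  stopifnot(!is.null(rownames(cohorts)))
  rows <- lapply(rownames(cohorts), function(sp) {
    lab <- cohorts[sp, ]
    lab <- lab[!is.na(lab)]
    seas <- unique(lab[lab != "non-significant"])
    agreement <-
      if (length(seas) == 0) "all-non-significant"
      else if (length(seas) == 1) "identical"
      else if (length(seas) == 2 && season_adjacent(seas[1], seas[2]))
        "concomitant"
      else "mixed"
    data.frame(species_id = sp,
               intersection = paste(sort(unique(lab)), collapse = "+"),
               n_plants = length(lab), agreement = agreement,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise cohort intersections
#'
#' Counts species per intersection key, optionally broken down by a
#' per-species annotation such as the seasonal strength category.
#'
#' @param intersections Output of [cohort_intersections()].
#' @param annotation Optional named character vector (by species_id).
#' @return Data frame of intersection, agreement, (annotation,) n_species.
#' @export
summarise_intersections <- function(intersections, annotation = NULL) {
  key <- intersections[c("intersection", "agreement")]
  if (!is.null(annotation))
    key$annotation <- unname(annotation[intersections$species_id])
  agg <- stats::aggregate(list(n_species = seq_len(nrow(key))), key, length)
  agg[order(-agg$n_species), , drop = FALSE]
}

#' Cumulative abundance series per species group, with harmonic fits
#'
#' Sums relative abundances over each label's species per sample, regularizes
#' the per-label series to a weekly grid, and fits the annual harmonic. The
#' labels partition the assigned species, so the label sums per sample add up
#' to those species' total abundance.
#'
#' @param x A proportion-valued [sample_table()] from one plant.
#' @param assignment Named character vector: species id -> group label.
#' @param alpha Significance threshold; fits above it are reported with
#'   `significant = FALSE`.
#' @param frequency Weeks per cycle.
#' @return List per label: `series` (weekly_series), `fit` (harmonic_fit),
#'   `significant`.
#' @export
group_series <- function(x, assignment, alpha = 0.01, frequency = 52L) {
  stopifnot(inherits(x, "sample_table"))
  sp <- names(assignment)
  stopifnot(all(sp %in% colnames(x$counts)))
  props <- if (x$proportions) x$counts else relative_abundance(x$counts)
  o <- order(x$meta$date)
  dates <- x$meta$date[o]
  out <- lapply(split(sp, unname(assignment)), function(ids) {
    v <- rowSums(props[o, ids, drop = FALSE])
    ws <- regularize_weekly(v, dates)
    fit <- fit_harmonic(ws, frequency = frequency)
    list(series = ws, fit = fit, significant = fit$p_value <= alpha)
  })
  out
}

#' Alpha-diversity series and their seasonality
#'
#' Rarefies each sample to a common depth, computes observed richness and
#' Simpson diversity (1 - D), regularizes both to weekly grids per plant,
#' and fits the annual harmonic to each.
#'
#' @param x A count-valued [sample_table()] (samples passing the read
#'   filter; below-depth samples are dropped by rarefaction).
#' @param depth Rarefaction depth (default 10000).
#' @param seed Integer seed for rarefaction.
#' @param alpha Significance threshold for reporting.
#' @return Data frame: plant, metric, m, amplitude, p_value, peak_week,
#'   cohort-window season of the peak, significant; with the per-plant
#'   weekly series attached as attribute "series".
#' @export
diversity_series <- function(x, depth = 10000, seed = 1, alpha = 0.01) {
  stopifnot(inherits(x, "sample_table"))
  rar <- rarefy_counts(x, depth = depth, seed = seed)
  meta <- x$meta[match(rownames(rar), x$meta$sample_id), , drop = FALSE]
  div <- data.frame(richness = richness(rar),
                    simpson = simpson_1_minus_d(rar))
  rows <- list(); series <- list()
  for (pl in unique(meta$plant)) {
    i <- which(meta$plant == pl)
    i <- i[order(meta$date[i])]
    i <- i[!duplicated(meta$date[i])]  # replicates: keep first per date
    for (metric in names(div)) {
      ws <- regularize_weekly(div[[metric]][i], meta$date[i])
      fit <- fit_harmonic(ws)
      rows[[length(rows) + 1]] <- data.frame(
        plant = pl, metric = metric, m = fit$m, amplitude = fit$amplitude,
        p_value = fit$p_value, peak_week = fit$peak_week,
        season = season_of_day(fit$peak_doy),
        significant = fit$p_value <= alpha, stringsAsFactors = FALSE)
      series[[paste(pl, metric, sep = ".")]] <- ws
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "series") <- series
  out
}
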