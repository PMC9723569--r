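#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis in one place; the
#' defaults are the study thresholds (10000-read sample filter, 0.05 percent
#' species retention, 1 percent significance, 52-week annual cycle, Fs cut
#' points 0.75/0.55/0.35/0.15, 0.005 per-day surviving band, rarefaction at
#' 10000 reads).
#'
#' @param plants List of [plant_spec()] objects to simulate, or `NULL` when
#'   `input` supplies tables read from disk.
#' @param input Optional list of pre-built per-plant inputs (each a list with
#'   `table`, `taxonomy`, `species`), bypassing simulation.
#' @param shared_species Optional shared-core [species_specs()] rows passed
#'   to every simulated plant.
#' @param min_reads,abundance_threshold,alpha,frequency,fs_cutpoints,
#'   epsilon_k,rarefaction_depth,n_boot Analysis thresholds (see Details).
#' @param fit_on Passed to [species_seasonality()].
#' @param n_influent_pairs Paired influent/reactor dates per plant.
#' @param influent_noise_sd Multiplicative noise SD of the paired tables.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param out_dir Output directory for tables and the manifest; `NULL`
#'   disables writing.
#' @return A `run_config` list.
#' @export
run_config <- function(plants = NULL, input = NULL, shared_species = NULL,
                       min_reads = 10000, abundance_threshold = 0.0005,
                       alpha = 0.01, frequency = 52L,
                       fs_cutpoints = c(0.75, 0.55, 0.35, 0.15),
                       epsilon_k = 0.005, rarefaction_depth = 10000,
                       n_boot = 1000, fit_on = "seasonal",
                       n_influent_pairs = 26, influent_noise_sd = 0.2,
                       seed = 1, out_dir = NULL) {
  stopifnot(alpha > 0, alpha <= 1, all(diff(fs_cutpoints) < 0),
            all(fs_cutpoints > 0), all(fs_cutpoints < 1))
  structure(list(plants = plants, input = input,
                 shared_species = shared_species,
                 min_reads = min_reads,
                 abundance_threshold = abundance_threshold,
                 alpha = alpha, frequency = frequency,
                 fs_cutpoints = fs_cutpoints, epsilon_k = epsilon_k,
                 rarefaction_depth = rarefaction_depth, n_boot = n_boot,
                 fit_on = fit_on, n_influent_pairs = n_influent_pairs,
                 influent_noise_sd = influent_noise_sd,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full seasonality pipeline
#'
#' Executes simulate/load, sample QC (read filter, replicate merge, species
#' aggregation, abundance retention), rarefied alpha diversity, per-species
#' decomposition + harmonic seasonality per plant, growth-group
#' classification from paired influent/reactor tables, and cross-plant
#' cohort comparison. All intermediate tables are written to
#' `config$out_dir` (when set) together with a JSON manifest echoing the
#' configuration, seeds, and per-stage row counts. Reruns with the same
#' config are identical.
#'
#' @param config A [run_config()].
#' @return Invisibly, a result bundle: per-plant inputs, QC'd tables,
#'   seasonality tables, diversity fits, growth classification, shared
#'   species and cohort intersections, and the manifest.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  log_stage <- function(...) message(sprintf("[%s] ", format(Sys.time(), "%H:%M:%S")), ...)

  # -- stage: simulate or load -------------------------------------------
  plants_in <- if (!is.null(config$input)) config$input else {
    if (is.null(config$plants)) stop("run_all: neither input nor plants given")
    log_stage("simulate: ", length(config$plants), " plant(s)")
    lapply(config$plants, simulate_plant,
           shared_species = config$shared_species)
  }
  names(plants_in) <- vapply(plants_in, function(p) p$table$meta$plant[1], "")

  # -- stage: QC + seasonality per plant ---------------------------------
  seasonality <- list(); retained <- list(); tables <- list()
  diversity <- list()
  for (pl in names(plants_in)) {
    log_stage("qc+seasonality: ", pl)
    raw <- plants_in[[pl]]$table
    filt <- filter_min_reads(raw, config$min_reads)
    diversity[[pl]] <- diversity_series(filt, depth = config$rarefaction_depth,
                                        seed = config$seed + 11L,
                                        alpha = config$alpha)
    merged <- merge_replicates(filt)
    agg <- aggregate_to_species(merged, plants_in[[pl]]$taxonomy)
    keep <- retain_abundant_species(agg, config$abundance_threshold)
    retained[[pl]] <- keep
    tables[[pl]] <- agg
    seasonality[[pl]] <- species_seasonality(
      agg, species = keep, frequency = config$frequency,
      alpha = config$alpha, fit_on = config$fit_on,
      n_boot = config$n_boot, seed = config$seed + 23L)
  }

  # -- stage: growth groups ----------------------------------------------
  growth <- NULL
  if (!is.null(plants_in[[1]]$species)) {
    log_stage("growth groups")
    k_cols <- list()
    for (pl in names(plants_in)) {
      spec_pl <- Find(function(p) p$plant_id == pl, config$plants %||% list())
      if (is.null(spec_pl))
        spec_pl <- plant_spec(pl, n_species = 0,
                              srt_days = 20, hrt_days = 1, seed = config$seed)
      pairs <- simulate_influent_pairs(
        plants_in[[pl]]$species, spec_pl,
        n_dates = config$n_influent_pairs,
        noise_sd = config$influent_noise_sd,
        seed = config$seed + 31L + match(pl, names(plants_in)))
      k_cols[[pl]] <- growth_rate_table(pairs)
    }
    all_ids <- sort(unique(unlist(lapply(k_cols, `[[`, "species_id"))))
    k_mat <- vapply(k_cols, function(d) d$k[match(all_ids, d$species_id)],
                    numeric(length(all_ids)))
    k_mat <- matrix(k_mat, nrow = length(all_ids),
                    dimnames = list(all_ids, names(k_cols)))
    max_ab <- vapply(all_ids, function(id) {
      max(vapply(tables, function(tb) {
        if (id %in% colnames(tb$counts)) max(tb$counts[, id]) else 0
      }, numeric(1)))
    }, numeric(1))
    growth <- classify_growth(k_mat, max_ab, epsilon = config$epsilon_k,
                              min_abundance = config$abundance_threshold)
  }

  # -- stage: cross-plant -------------------------------------------------
  log_stage("cross-plant summaries")
  shared <- if (length(retained) >= 2) shared_species(retained) else NULL
  intersections <- NULL
  if (!is.null(shared)) {
    in_all <- rownames(shared$membership)[rowSums(shared$membership) ==
                                            ncol(shared$membership)]
    if (length(in_all) > 0) {
      cmat <- vapply(names(seasonality), function(pl) {
        s <- seasonality[[pl]]
        s$cohort[match(in_all, s$species)]
      }, character(length(in_all)))
      cmat <- matrix(cmat, nrow = length(in_all),
                     dimnames = list(in_all, names(seasonality)))
      intersections <- cohort_intersections(cmat)
    }
  }

  manifest <- list(
    config = config[setdiff(names(config), c("plants", "input", "shared_species"))],
    r_version = R.version.string,
    n_plants = length(plants_in),
    retained_per_plant = lapply(retained, length),
    seasonality_rows = lapply(seasonality, nrow),
    growth_rows = if (is.null(growth)) 0L else nrow(growth),
    shared_in_all = if (is.null(intersections)) 0L else nrow(intersections),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  bundle <- list(inputs = plants_in, tables = tables, retained = retained,
                 seasonality = seasonality, diversity = diversity,
                 growth = growth, shared = shared,
                 intersections = intersections, manifest = manifest)

  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  invisible(bundle)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (pl in names(bundle$seasonality)) {
    utils::write.table(bundle$seasonality[[pl]],
                       file.path(out_dir, paste0("seasonality_", pl, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(bundle$diversity[[pl]],
                       file.path(out_dir, paste0("diversity_", pl, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bundle$growth))
    utils::write.table(bundle$growth, file.path(out_dir, "growth_groups.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$shared))
    utils::write.table(bundle$shared$counts,
                       file.path(out_dir, "shared_species.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$intersections))
    utils::write.table(bundle$intersections,
                       file.path(out_dir, "cohort_intersections.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
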