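# Apparent net growth rates from paired influent/reactor abundances under a
# steady-state first-order immigration mass balance. With C_in the influent
# biomass concentration of a species (cells/L), X its reactor concentration,
# Q the influent flow and V the reactor volume, steady state of
#   V dX/dt = Q C_in + k V X - (V/SRT) X
# gives k = 1/SRT - C_in/(X * HRT), HRT = V/Q. Outputs are labelled
# "apparent net growth rate (simplified steady-state)".

#' Apparent net growth rate from one influent/reactor pair
#'
#' @param influent_abundance Relative abundance in the influent (proportion).
#' @param influent_total_cells Influent total cell concentration (cells/L).
#' @param reactor_abundance Relative abundance in the reactor (> 0).
#' @param reactor_total_cells Reactor total cell concentration (cells/L).
#' @param srt_days Solids retention time (days).
#' @param hrt_days Hydraulic retention time (days).
#' @return k in per day. Vectorized over abundances.
#' @export
estimate_net_growth <- function(influent_abundance, influent_total_cells,
                                reactor_abundance, reactor_total_cells,
                                srt_days, hrt_days) {
  stopifnot(srt_days > 0, hrt_days > 0)
  if (any(reactor_abundance <= 0))
    stop("species absent from the reactor: k undefined")
  c_in <- influent_abundance * influent_total_cells
  x <- reactor_abundance * reactor_total_cells
  1 / srt_days - c_in / (x * hrt_days)
}

#' Per-species growth rates from a paired abundance table
#'
#' Applies [estimate_net_growth()] to every date x species cell of a paired
#' influent/reactor table and aggregates each species' per-date estimates by
#' the median (robust to outlier pairs). Species absent from the reactor on
#' a date are excluded from that date with a message.
#'
#' @param pairs List with `influent` and `reactor` (dates x species relative
#'   abundance matrices) and `params` (srt_days, hrt_days,
#'   influent_total_cells, reactor_total_cells), as produced by
#'   [simulate_influent_pairs()] or read from disk.
#' @return Data frame: species_id, k (median per-day rate), n_pairs.
#' @export
growth_rate_table <- function(pairs) {
  inf <- pairs$influent; reac <- pairs$reactor; p <- pairs$params
  stopifnot(identical(dim(inf), dim(reac)))
  ok <- reac > 0
  if (!all(ok))
    message("growth_rate_table: ", sum(!ok),
            " pair(s) with the species absent from the reactor excluded")
  k <- matrix(NA_real_, nrow(inf), ncol(inf), dimnames = dimnames(inf))
  k[ok] <- 1 / p$srt_days -
    (inf[ok] * p$influent_total_cells) /
    (reac[ok] * p$reactor_total_cells * p$hrt_days)
  data.frame(species_id = colnames(inf),
             k = apply(k, 2, stats::median, na.rm = TRUE),
             n_pairs = colSums(ok),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify species into growth groups
#'
#' Sign-consistency rule across plants: growing when every per-plant rate
#' exceeds +epsilon, disappearing when every rate is below -epsilon,
#' surviving when all rates are within epsilon of zero; any disagreement, or
#' a maximum relative abundance below `min_abundance`, yields ambiguous.
#'
#' @param k_by_plant Numeric matrix, species x plants, of per-plant median
#'   rates (per day); or a data frame with a `species_id` column plus one
#'   column per plant.
#' @param max_abundance Named vector of each species' maximum relative
#'   abundance across all samples and plants.
#' @param epsilon Half-width of the "close to zero" band (per day).
#' @param min_abundance Abundance floor below which species are ambiguous.
#' @return Data frame: species_id, median_k, group.
#' @export
classify_growth <- function(k_by_plant, max_abundance, epsilon = 0.005,
                            min_abundance = 0.0005) {
  if (is.data.frame(k_by_plant)) {
    ids <- k_by_plant$species_id
    k_by_plant <- as.matrix(k_by_plant[setdiff(names(k_by_plant), "species_id")])
    rownames(k_by_plant) <- ids
  }
  ids <- rownames(k_by_plant)
  stopifnot(!is.null(ids), all(ids %in% names(max_abundance)))
  grp <- vapply(seq_along(ids), function(i) {
    k <- k_by_plant[i, ]
    k <- k[!is.na(k)]
    if (length(k) == 0) return("ambiguous")
    if (max_abundance[[ids[i]]] < min_abundance) return("ambiguous")
    if (all(k > epsilon)) "growing"
    else if (all(k < -epsilon)) "disappearing"
    else if (all(abs(k) <= epsilon)) "surviving"
    else "ambiguous"
  }, character(1))
  data.frame(species_id = ids,
             median_k = apply(k_by_plant, 1, stats::median, na.rm = TRUE),
             group = grp, row.names = NULL, stringsAsFactors = FALSE)
}
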