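# Synthetic multi-plant longitudinal communities with known seasonal and
# growth-rate ground truth. The latent model is log-linear: for species i at
# calendar time t (days),
#   lambda_i(t) = baseline_i + slope_i * t/365.25
#                 + A_i * cos(2*pi*(t - tau_i)/365.25) + N(0, sigma_i^2)
# and reads are drawn multinomially with probabilities proportional to
# exp(lambda_i(t)) at a per-sample depth. The rclr of a log-linear signal is
# approximately sinusoidal, so the generator matches the assumptions of the
# downstream harmonic analysis by construction.

#' Ground-truth species specifications
#'
#' Draws a table of per-species latent parameters. A `seasonal_fraction` of
#' species receive an annual cosine of amplitude in `amplitude_range` (natural
#' log scale) with peak day-of-year uniform over the year; the rest have
#' amplitude 0 and true cohort "none". The true cohort is derived from
#' `peak_day` with [season_of_day()], the same calendar windows the analysis
#' side uses.
#'
#' @param n Number of species.
#' @param seasonal_fraction Fraction of species with a seasonal signal.
#' @param amplitude_range Range of latent annual amplitudes (log scale).
#' @param baseline_sd SD of baseline log abundances (mean 0).
#' @param noise_sd_range Range of per-species observation noise SDs.
#' @param trend_slope Per-year latent drift applied to every species.
#' @param growth_fractions Named fractions for growing / disappearing /
#'   surviving species (used by [simulate_influent_pairs()]).
#' @param seed Integer seed.
#' @param prefix Species id prefix.
#' @return Data frame with one row per species: `species_id`,
#'   `baseline_log_abundance`, `amplitude`, `peak_day`, `trend_slope`,
#'   `noise_sd`, `true_growth_rate`, `true_cohort`.
#' @export
species_specs <- function(n, seasonal_fraction = 0.8,
                          amplitude_range = c(0.5, 2.5),
                          baseline_sd = 1.5,
                          noise_sd_range = c(0.2, 0.6),
                          trend_slope = 0,
                          growth_fractions = c(growing = 0.5,
                                               disappearing = 0.3,
                                               surviving = 0.2),
                          seed = 1, prefix = "midas_s_") {
  stopifnot(n >= 1, seasonal_fraction >= 0, seasonal_fraction <= 1)
  withr_seed(seed, {
    seasonal <- runif(n) < seasonal_fraction
    amp <- ifelse(seasonal, runif(n, amplitude_range[1], amplitude_range[2]), 0)
    peak <- sample.int(365, n, replace = TRUE)
    grp <- sample(names(growth_fractions), n, replace = TRUE,
                  prob = growth_fractions)
    k <- numeric(n)
    k[grp == "growing"] <- runif(sum(grp == "growing"), 0.01, 0.045)
    k[grp == "disappearing"] <- runif(sum(grp == "disappearing"), -0.30, -0.05)
    k[grp == "surviving"] <- runif(sum(grp == "surviving"), -0.003, 0.003)
    data.frame(
      species_id = sprintf("%s%04d", prefix, seq_len(n)),
      baseline_log_abundance = rnorm(n, 0, baseline_sd),
      amplitude = amp,
      peak_day = peak,
      trend_slope = trend_slope,
      noise_sd = runif(n, noise_sd_range[1], noise_sd_range[2]),
      true_growth_rate = k,
      true_cohort = ifelse(amp == 0, "none",
                           vapply(peak, season_of_day, character(1))),
      stringsAsFactors = FALSE
    )
  })
}

#' Plant-level simulation settings
#'
#' @param plant_id Plant label.
#' @param n_species Number of plant-specific species to generate (in addition
#'   to any shared core passed to [simulate_plant()]).
#' @param years Number of sampled years.
#' @param sampling_interval_days Days between consecutive sampling dates
#'   (7 to 10).
#' @param depth_range Integer (min, max) read depth per sample.
#' @param srt_days Solids retention time, days.
#' @param hrt_days Hydraulic retention time, days.
#' @param seed Integer seed.
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(plant_id, n_species = 200, years = 3,
                       sampling_interval_days = 7,
                       depth_range = c(10893L, 170639L),
                       srt_days = 20, hrt_days = 1, seed = 1) {
  stopifnot(years >= 1, n_species >= 0,
            sampling_interval_days >= 7, sampling_interval_days <= 10,
            depth_range[1] >= 1, depth_range[2] >= depth_range[1],
            srt_days > 0, hrt_days > 0)
  structure(list(plant_id = plant_id, n_species = n_species, years = years,
                 sampling_interval_days = sampling_interval_days,
                 depth_range = as.integer(depth_range),
                 srt_days = srt_days, hrt_days = hrt_days, seed = seed),
            class = "plant_spec")
}

#' Simulate one plant's longitudinal count table
#'
#' Samples the latent log-linear community model at a regular interval over
#' `spec$years` years, draws multinomial reads at a per-sample depth uniform
#' over `spec$depth_range`, emits a fraction of dates twice as technical
#' replicates (same latent composition, independent read draw), and gives a
#' fraction of samples sub-threshold depth to exercise QC. Identical seeds
#' yield identical output.
#'
#' @param spec A [plant_spec()].
#' @param shared_species Optional [species_specs()] rows forming a cross-plant
#'   core; these keep their peak days (and hence phases) identical in every
#'   plant that receives them.
#' @param replicate_fraction Fraction of sampling dates duplicated.
#' @param low_depth_fraction Fraction of samples drawn below 10000 reads.
#' @param start_date First sampling date (ISO-8601).
#' @return List with `table` (a count-valued [sample_table()]), `taxonomy`
#'   (taxon_id + 7 ranks), and `species` (ground-truth spec rows used).
#' @export
simulate_plant <- function(spec, shared_species = NULL,
                           replicate_fraction = 0.05,
                           low_depth_fraction = 0.02,
                           start_date = "2015-01-05") {
  stopifnot(inherits(spec, "plant_spec"))
  withr_seed(spec$seed, {
    own <- if (spec$n_species > 0)
      species_specs(spec$n_species, seed = spec$seed + 1000L,
                    prefix = sprintf("%s_s_", spec$plant_id))
    else NULL
    sp <- rbind(shared_species, own)
    if (is.null(sp) || nrow(sp) == 0) stop("no species to simulate")
    n_dates <- floor(spec$years * 365.25 / spec$sampling_interval_days) + 1
    start <- as.Date(start_date)
    dates <- start + spec$sampling_interval_days * (0:(n_dates - 1))
    t_abs <- as.numeric(dates - as.Date("2000-01-01"))  # common phase epoch
    t_loc <- as.numeric(dates - start)
    is_rep <- runif(n_dates) < replicate_fraction
    idx <- rep(seq_len(n_dates), times = 1L + is_rep)   # replicate rows follow
    n_samp <- length(idx)
    low <- runif(n_samp) < low_depth_fraction
    depth <- ifelse(low,
                    sample(1000:9999, n_samp, replace = TRUE),
                    sample(spec$depth_range[1]:spec$depth_range[2],
                           n_samp, replace = TRUE))
    n_sp <- nrow(sp)
    lam_det <- outer(rep(1, n_dates), sp$baseline_log_abundance) +
      outer(t_loc / 365.25, sp$trend_slope) +
      t(sp$amplitude *
          cos(2 * pi * outer(sp$peak_day - 1, t_abs, function(p, t) t - p) / 365.25))
    eps <- matrix(rnorm(n_dates * n_sp, 0, rep(sp$noise_sd, each = n_dates)),
                  n_dates, n_sp)
    lam <- lam_det + eps  # replicates share the date's latent state
    counts <- matrix(0L, n_samp, n_sp, dimnames = list(NULL, sp$species_id))
    for (s in seq_len(n_samp)) {
      p <- exp(lam[idx[s], ] - max(lam[idx[s], ]))
      counts[s, ] <- as.integer(rmultinom(1, depth[s], p))
    }
    sid <- sprintf("%s_%s%s", spec$plant_id, format(dates[idx], "%Y%m%d"),
                   ifelse(duplicated(idx), "_r2", ""))
    rownames(counts) <- sid
    rep_of <- ifelse(duplicated(idx),
                     sprintf("%s_%s", spec$plant_id, format(dates[idx], "%Y%m%d")),
                     NA_character_)
    meta <- data.frame(sample_id = sid, plant = spec$plant_id,
                       date = dates[idx], replicate_of = rep_of,
                       stringsAsFactors = FALSE)
    tax <- data.frame(
      taxon_id = sp$species_id,
      Kingdom = "Bacteria", Phylum = "midas_p_1", Class = "midas_c_1",
      Order = "midas_o_1", Family = "midas_f_1", Genus = "midas_g_1",
      Species = sp$species_id, stringsAsFactors = FALSE)
    list(table = sample_table(counts, meta), taxonomy = tax, species = sp)
  })
}

#' Simulate paired influent/reactor abundances at steady state
#'
#' For each species with true net growth rate k (per day), the reactor
#' abundance is set so the steady-state immigration mass balance
#' k = 1/SRT - C_in/(X * HRT) holds exactly (C_in, X in cells/L), then
#' perturbed by multiplicative lognormal noise. Influent relative abundances
#' are lognormal around a per-species mean.
#'
#' @param specs [species_specs()] rows with `true_growth_rate`.
#' @param plant A [plant_spec()] supplying SRT and HRT.
#' @param n_dates Number of paired sampling dates.
#' @param noise_sd SD of the multiplicative (log-scale) noise on both tables.
#' @param influent_total_cells,reactor_total_cells Total cell concentrations
#'   (cells/L) used to convert relative abundances to biomass.
#' @param seed Integer seed.
#' @return List: `influent` and `reactor` (dates x species relative-abundance
#'   matrices), `truth` (species_id, true_k), and `params` (SRT, HRT, totals).
#' @export
simulate_influent_pairs <- function(specs, plant, n_dates = 26,
                                    noise_sd = 0,
                                    influent_total_cells = 1e11,
                                    reactor_total_cells = 1e12,
                                    seed = 1) {
  stopifnot(inherits(plant, "plant_spec"), n_dates >= 1)
  k <- specs$true_growth_rate
  if (any(k >= 1 / plant$srt_days))
    stop("species with k >= 1/SRT need no immigration; the balance degenerates")
  withr_seed(seed, {
    n <- nrow(specs)
    mean_rel <- exp(rnorm(n, log(2e-4), 0.8))
    inf_rel <- outer(rep(1, n_dates), mean_rel) *
      exp(matrix(rnorm(n_dates * n, 0, noise_sd), n_dates, n))
    c_in <- inf_rel * influent_total_cells
    x_cells <- c_in / (plant$hrt_days * (1 / plant$srt_days - rep(k, each = n_dates)))
    reac_rel <- x_cells / reactor_total_cells *
      exp(matrix(rnorm(n_dates * n, 0, noise_sd), n_dates, n))
    dimnames(inf_rel) <- dimnames(reac_rel) <-
      list(sprintf("pair_%02d", seq_len(n_dates)), specs$species_id)
    list(influent = inf_rel, reactor = reac_rel,
         truth = data.frame(species_id = specs$species_id, true_k = k,
                            stringsAsFactors = FALSE),
         params = list(srt_days = plant$srt_days, hrt_days = plant$hrt_days,
                       influent_total_cells = influent_total_cells,
                       reactor_total_cells = reactor_total_cells))
  })
}
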