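# Harmonic (cosinor) inference on weekly series: fit y = m + A*cos(2*pi*t/52
# - phi) by OLS on the {1, cos, sin} basis, test the two trigonometric terms
# jointly by an F-test, locate the peak week, and translate it to a calendar
# season.

harmonic_design <- function(n, frequency) {
  t <- seq_len(n)
  cbind(`(Intercept)` = 1,
        c = cos(2 * pi * t / frequency),
        s = sin(2 * pi * t / frequency))
}

#' Fit the annual harmonic model to a weekly series
#'
#' Ordinary least squares of the series on an intercept plus one annual
#' cosine/sine pair (period `frequency` weeks). The amplitude is the norm of
#' the two trigonometric coefficients, the phase their `atan2`, and the
#' p-value comes from the F-test of the pair against the intercept-only
#' model. The fitted curve peaks where the cosine argument vanishes; that
#' week (real-valued, in (0, 52]) is reported together with its day-of-year
#' when the series carries a start date.
#'
#' @param s A `weekly_series` or numeric vector.
#' @param frequency Weeks per annual cycle (default 52).
#' @return A `harmonic_fit`: `m`, `amplitude`, `phase` (radians in [0, 2pi)),
#'   `p_value`, `peak_week`, `peak_doy`, `n`, `frequency`, `fitted`,
#'   `residuals`, `start_date`.
#' @export
fit_harmonic <- function(s, frequency = 52L) {
  ws <- as_weekly_series(s, frequency)
  y <- ws$values
  n <- length(y)
  if (n < frequency + 3) stop("series too short for the harmonic fit")
  X <- harmonic_design(n, frequency)
  fit <- stats::lm.fit(X, y)
  b <- fit$coefficients
  A <- sqrt(b["c"]^2 + b["s"]^2)
  phi <- atan2(b["s"], b["c"]) %% (2 * pi)
  rss1 <- sum(fit$residuals^2)
  rss0 <- sum((y - mean(y))^2)
  df2 <- n - 3
  if (rss0 == 0) {
    p <- 1  # constant series: no seasonal signal to test
  } else if (rss1 <= 0) {
    p <- 0
  } else {
    f <- ((rss0 - rss1) / 2) / (rss1 / df2)
    p <- stats::pf(f, 2, df2, lower.tail = FALSE)
  }
  if (A == 0) p <- 1
  peak_week <- ((phi / (2 * pi) * frequency - 1) %% frequency) + 1
  structure(list(m = unname(b[1]), amplitude = unname(A), phase = unname(phi),
                 p_value = unname(p), peak_week = unname(peak_week),
                 peak_doy = peak_doy(peak_week, ws$start_date),
                 n = n, frequency = as.integer(frequency),
                 fitted = fit$fitted.values, residuals = fit$residuals,
                 start_date = ws$start_date),
            class = "harmonic_fit")
}

#' @export
print.harmonic_fit <- function(x, ...) {
  cat(sprintf("<harmonic_fit> m=%.3g A=%.3g peak week %.1f (p=%.3g)\n",
              x$m, x$amplitude, x$peak_week, x$p_value))
  invisible(x)
}

# Day-of-year (365-day calendar) of the fitted peak. Week 1 starts at the
# series start date; without a start date, week 1 is anchored at Jan 1.
peak_doy <- function(peak_week, start_date) {
  if (is.na(start_date)) {
    (round((peak_week - 1) * 7) %% 365) + 1
  } else {
    doy_365(start_date + round((peak_week - 1) * 7))
  }
}

# day-of-year on a fixed 365-day (non-leap) calendar; Feb 29 folds onto Feb 28
doy_365 <- function(date) {
  p <- as.POSIXlt(date)
  cum <- c(0, 31, 59, 90, 120, 151, 181, 212, 243, 273, 304, 334)
  cum[p$mon + 1] + min(p$mday, if (p$mon == 1) 28 else 31)
}

#' Astronomical season of a day of the year
#'
#' Northern-hemisphere astronomical seasons on a 365-day calendar:
#' winter Dec 21 - Mar 20, spring Mar 21 - Jun 21, summer Jun 22 - Sep 22,
#' autumn Sep 23 - Dec 22, all endpoints inclusive; winter wraps the year
#' boundary and takes precedence on the overlapping Dec 21-22 days. This is
#' the single source of truth for cohort windows, used both by the analysis
#' and by the synthetic ground truth.
#'
#' @param doy Integer day of year (1-365).
#' @return One of "winter", "spring", "summer", "autumn".
#' @export
season_of_day <- function(doy) {
  stopifnot(doy >= 1, doy <= 365)
  if (doy >= 355 || doy <= 79) "winter"        # Dec 21 - Mar 20
  else if (doy <= 172) "spring"                # Mar 21 - Jun 21
  else if (doy <= 265) "summer"                # Jun 22 - Sep 22
  else "autumn"                                # Sep 23 - Dec 22 (non-winter)
}

#' Bootstrap confidence interval for the peak week
#'
#' Residual bootstrap: residuals of the harmonic fit are resampled with
#' replacement, added back to the fitted curve, and the model refit; the
#' 2.5/97.5 percentiles of the bootstrap peak weeks are taken circularly
#' (deviations measured along the shortest arc around the point estimate).
#' Deterministic given `seed`.
#'
#' @param fit A [fit_harmonic()] result.
#' @param s The series the fit came from.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return List `ci_low`, `ci_high` (weeks in (0, 52], possibly wrapping the
#'   year boundary), and `full_year` flag set when the amplitude is
#'   numerically zero and the interval is the whole year.
#' @export
peak_confidence_interval <- function(fit, s, n_boot = 1000, seed = 1) {
  stopifnot(inherits(fit, "harmonic_fit"))
  ws <- as_weekly_series(s, fit$frequency)
  n <- fit$n
  f <- fit$frequency
  if (fit$amplitude < .Machine$double.eps^0.5 * max(1, abs(fit$m)))
    return(list(ci_low = 0, ci_high = f, full_year = TRUE))
  X <- harmonic_design(n, f)
  P <- solve(crossprod(X), t(X))  # 3 x n projection onto coefficients
  peaks <- withr_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
    Y <- fit$fitted + matrix(fit$residuals[idx], n, n_boot)
    B <- P %*% Y
    phi <- atan2(B[3, ], B[2, ]) %% (2 * pi)
    ((phi / (2 * pi) * f - 1) %% f) + 1
  })
  d <- ((peaks - fit$peak_week + f / 2) %% f) - f / 2
  q <- stats::quantile(d, c(0.025, 0.975), names = FALSE)
  list(ci_low = ((fit$peak_week + q[1] - 1) %% f) + 1,
       ci_high = ((fit$peak_week + q[2] - 1) %% f) + 1,
       full_year = FALSE)
}

#' Is a week inside a (possibly wrapping) cyclic interval?
#' @param week Week value(s) in (0, 52].
#' @param ci_low,ci_high Interval endpoints from [peak_confidence_interval()].
#' @param frequency Weeks per cycle.
#' @export
week_in_interval <- function(week, ci_low, ci_high, frequency = 52) {
  if (ci_low <= ci_high) week >= ci_low & week <= ci_high
  else week >= ci_low | week <= ci_high
}

#' Seasonal strength of a decomposition
#'
#' Fs = 1 - var(remainder) / (var(remainder) + var(seasonal)), with
#' population variances; 1 means the deseasonalized series is noise-free,
#' 0 means no seasonal variation. Clipped to [0, 1].
#'
#' @param d An `stl_decomposition`.
#' @return Fs in [0, 1].
#' @export
seasonal_strength <- function(d) {
  stopifnot(inherits(d, "stl_decomposition"))
  pvar <- function(x) mean((x - mean(x))^2)
  vs <- pvar(d$seasonal); vr <- pvar(d$remainder)
  if (vs + vr == 0) stop("degenerate series: seasonal and remainder both constant")
  min(1, max(0, 1 - vr / (vr + vs)))
}

#' Seasonal strength category
#'
#' Five categories on Fs for species with a significant harmonic fit, using
#' left-closed cut points (Fs >= 0.75 very strong, 0.55-0.75 strong,
#' 0.35-0.55 moderate, 0.15-0.35 weak, below 0.15 very weak); fits with
#' p above `alpha` are "non-significant" regardless of Fs.
#'
#' @param fs Seasonal strength in [0, 1].
#' @param p_value Harmonic-fit p-value.
#' @param alpha Significance threshold (default 0.01); ties significant.
#' @param cutpoints Strictly decreasing cut points.
#' @return Category string.
#' @export
strength_category <- function(fs, p_value, alpha = 0.01,
                              cutpoints = c(0.75, 0.55, 0.35, 0.15)) {
  stopifnot(fs >= 0, fs <= 1, all(diff(cutpoints) < 0))
  if (p_value > alpha) return("non-significant")
  if (fs >= cutpoints[1]) "very strong"
  else if (fs >= cutpoints[2]) "strong"
  else if (fs >= cutpoints[3]) "moderate"
  else if (fs >= cutpoints[4]) "weak"
  else "very weak"
}

#' Assign a species to a seasonal cohort
#'
#' Species with a significant harmonic fit are assigned to the astronomical
#' season containing their fitted peak day ([season_of_day()]); others go to
#' the non-significant cohort.
#'
#' @param fit A [fit_harmonic()] result.
#' @param alpha Significance threshold (default 0.01); ties significant.
#' @return One of "winter", "spring", "summer", "autumn", "non-significant".
#' @export
assign_cohort <- function(fit, alpha = 0.01) {
  stopifnot(inherits(fit, "harmonic_fit"))
  if (fit$p_value > alpha) "non-significant" else season_of_day(fit$peak_doy)
}

#' Per-species seasonality analysis for one plant
#'
#' Runs the full per-species chain on a proportion- or count-valued
#' species-aggregated table from a single plant: rclr transform of the whole
#' composition, weekly regularization of each retained species' series,
#' periodic seasonal-trend decomposition, harmonic fit (on the seasonal
#' component by default), seasonal strength, strength category, cohort, and
#' a bootstrap peak-week confidence interval.
#'
#' @param x A [sample_table()] from one plant (dates unique).
#' @param species Species ids to analyse; default [retain_abundant_species()].
#' @param frequency Weeks per cycle.
#' @param alpha Significance threshold.
#' @param fit_on "seasonal" fits the harmonic to the decomposed seasonal
#'   component (the default analysis); "raw" fits the regularized rclr series
#'   directly, which carries ordinary independent-error p-values.
#' @param rclr_zero Zero handling before decomposition: "zero" places absent
#'   taxa at the sample geometric mean (rclr 0); "interpolate" fills missing
#'   values linearly along time.
#' @param n_boot Bootstrap replicates for the peak CI; 0 skips the CI.
#' @param seed Integer seed for the bootstrap.
#' @return Data frame: species, m, amplitude, phase, p_value, peak_week,
#'   ci_low, ci_high, fs, strength, cohort.
#' @export
species_seasonality <- function(x, species = NULL, frequency = 52L,
                                alpha = 0.01,
                                fit_on = c("seasonal", "raw"),
                                rclr_zero = c("zero", "interpolate"),
                                n_boot = 1000, seed = 1) {
  stopifnot(inherits(x, "sample_table"))
  fit_on <- match.arg(fit_on)
  rclr_zero <- match.arg(rclr_zero)
  if (length(unique(x$meta$plant)) > 1)
    stop("species_seasonality analyses one plant at a time")
  if (is.null(species)) species <- retain_abundant_species(x)
  o <- order(x$meta$date)
  dates <- x$meta$date[o]
  r <- rclr(x$counts[o, , drop = FALSE])
  rows <- lapply(seq_along(species), function(j) {
    sp <- species[j]
    v <- r[, sp]
    if (rclr_zero == "zero") {
      v[is.na(v)] <- 0
    } else {
      v <- stats::approx(seq_along(v)[!is.na(v)], v[!is.na(v)],
                         xout = seq_along(v), rule = 2)$y
    }
    ws <- regularize_weekly(v, dates)
    dec <- stl_periodic(ws, frequency = frequency)
    fs <- seasonal_strength(dec)
    target <- if (fit_on == "seasonal")
      structure(list(values = dec$seasonal, start_date = ws$start_date,
                     frequency = ws$frequency), class = "weekly_series")
    else ws
    fit <- fit_harmonic(target, frequency = frequency)
    ci <- if (n_boot > 0)
      peak_confidence_interval(fit, target, n_boot = n_boot,
                               seed = seed + j)
    else list(ci_low = NA_real_, ci_high = NA_real_)
    data.frame(species = sp, m = fit$m, amplitude = fit$amplitude,
               phase = fit$phase, p_value = fit$p_value,
               peak_week = fit$peak_week, peak_doy = fit$peak_doy,
               ci_low = ci$ci_low, ci_high = ci$ci_high, fs = fs,
               strength = strength_category(fs, fit$p_value, alpha),
               cohort = assign_cohort(fit, alpha),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
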