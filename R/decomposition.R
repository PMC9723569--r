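#' Regularize an irregular series to a weekly grid
#'
#' Builds a grid of 7-day steps starting at the first observation date and
#' fills each grid point by linear interpolation between the bracketing
#' observations. The grid never extends beyond the last observation.
#'
#' @param values Numeric observations.
#' @param dates `Date` (or ISO-8601 string) vector, strictly increasing after
#'   replicate merging; duplicate dates are an error.
#' @return A `weekly_series`: list with `values`, `start_date`, and
#'   `frequency` (52 weeks per annual cycle).
#' @export
regularize_weekly <- function(values, dates) {
  dates <- as.Date(dates)
  if (length(values) != length(dates)) stop("values/dates length mismatch")
  if (length(values) < 2) stop("need at least 2 observations")
  o <- order(dates)
  dates <- dates[o]; values <- values[o]
  if (anyDuplicated(dates)) stop("duplicate dates; merge replicates first")
  day <- as.numeric(dates - dates[1])
  grid <- seq(0, max(day), by = 7)
  v <- stats::approx(day, values, xout = grid, method = "linear")$y
  structure(list(values = v, start_date = dates[1], frequency = 52L),
            class = "weekly_series")
}

#' @export
print.weekly_series <- function(x, ...) {
  cat(sprintf("<weekly_series> %d weeks from %s (frequency %d)\n",
              length(x$values), x$start_date, x$frequency))
  invisible(x)
}

as_weekly_series <- function(x, frequency = 52L) {
  if (inherits(x, "weekly_series")) return(x)
  structure(list(values = as.numeric(x), start_date = as.Date(NA),
                 frequency = as.integer(frequency)),
            class = "weekly_series")
}

next_odd <- function(x) { x <- ceiling(x); x + (x %% 2 == 0) }

#' Seasonal-trend decomposition with a periodic seasonal window
#'
#' Additive decomposition input = trend + seasonal + remainder by the
#' loess-based seasonal-trend procedure, specialised to a periodic seasonal
#' window: each cycle-subseries (all points sharing a week-of-year) is
#' replaced by its mean, so the seasonal component repeats identically every
#' cycle. The low-pass stage reduces to subtracting the grand mean of the
#' weekly means, because a full-period moving average of an exactly periodic
#' series covers each week exactly once and is therefore constant. The trend
#' is a degree-1 loess of the deseasonalized series.
#'
#' @param s A `weekly_series` (from [regularize_weekly()]) or numeric vector
#'   with no missing values.
#' @param frequency Observations per cycle (52 for weekly/annual).
#' @param t_window Trend loess window in observations (odd); default the
#'   classical choice `next odd >= 1.5 * frequency` = 79 for weekly data.
#' @param inner Inner-loop iterations (default 2, the classical default).
#' @param outer Robustness iterations with bisquare weights (default 0).
#' @param tol If given, iterate the inner loop until the seasonal and trend
#'   both change by less than `tol` (max 200 iterations), instead of a fixed
#'   `inner` count. Needed for exactness on inputs like pure ramps, where the
#'   fixed two-pass loop has not yet converged.
#' @return An `stl_decomposition`: `input`, `trend`, `seasonal`, `remainder`
#'   (remainder defined by subtraction, so additivity is exact), plus
#'   `start_date` and `frequency`.
#' @export
stl_periodic <- function(s, frequency = 52L, t_window = NULL,
                         inner = 2L, outer = 0L, tol = NULL) {
  ws <- as_weekly_series(s, frequency)
  y <- ws$values
  n <- length(y)
  if (anyNA(y)) stop("series has missing values; regularize first")
  if (n < 2 * frequency) stop("need at least two full cycles")
  if (is.null(t_window)) t_window <- next_odd(1.5 * frequency)
  span <- min(1, t_window / n)
  tt <- seq_len(n)
  widx <- ((tt - 1) %% frequency) + 1  # week-of-year index
  w <- rep(1, n)
  trend <- numeric(n)
  seasonal <- numeric(n)
  max_it <- if (is.null(tol)) inner else 200L
  for (o in 0:outer) {
    for (it in seq_len(max_it)) {
      old_s <- seasonal; old_t <- trend
      detr <- y - trend
      cs <- vapply(split(seq_len(n), widx), function(i) {
        stats::weighted.mean(detr[i], w[i])
      }, numeric(1))
      # low-pass of the periodically extended cycle-subseries = its grand mean
      seasonal <- unname((cs - mean(cs))[widx])
      fit <- stats::loess(I(y - seasonal) ~ tt, span = span, degree = 1,
                          weights = w, family = "gaussian",
                          surface = "direct")
      trend <- unname(stats::predict(fit, tt))
      if (!is.null(tol) &&
          max(abs(seasonal - old_s)) < tol && max(abs(trend - old_t)) < tol)
        break
    }
    if (o < outer) {
      r <- abs(y - trend - seasonal)
      h <- 6 * stats::median(r)
      w <- if (h > 0) pmax(0, (1 - pmin(1, r / h)^2))^2 else rep(1, n)
    }
  }
  structure(list(input = y, trend = trend, seasonal = seasonal,
                 remainder = y - trend - seasonal,
                 start_date = ws$start_date, frequency = as.integer(frequency)),
            class = "stl_decomposition")
}

#' @export
print.stl_decomposition <- function(x, ...) {
  cat(sprintf("<stl_decomposition> %d weeks; var(seasonal)=%.4g var(remainder)=%.4g\n",
              length(x$input), stats::var(x$seasonal), stats::var(x$remainder)))
  invisible(x)
}
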