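test_that("harmonic fit recovers an exact cosine", {
  y <- make_cosine(156, m = 2, A = 3, peak_week = 26)
  f <- fit_harmonic(y)
  expect_equal(f$m, 2, tolerance = 1e-9)
  expect_equal(f$amplitude, 3, tolerance = 1e-9)
  expect_equal(f$peak_week, 26, tolerance = 1e-9)
  expect_lt(f$p_value, 1e-10)
  # constant series degenerates gracefully
  fc <- fit_harmonic(rep(4, 156))
  expect_equal(fc$amplitude, 0)
  expect_equal(fc$p_value, 1)
})

test_that("amplitude agrees with a brute-force grid search of the SSE", {
  y <- make_cosine(156, m = 0.5, A = 1, peak_week = 18, sigma = 1, seed = 21)
  f <- fit_harmonic(y)
  # independent oracle: direct SSE evaluation over an (m, A, phi) grid at
  # resolution 0.01 (phi 0.005 rad), via the expanded quadratic form
  t <- 1:156
  n <- length(y); Sy <- sum(y); Syy <- sum(y^2)
  best <- c(sse = Inf, m = NA, A = NA)
  for (phi in seq(0, 2 * pi, by = 0.005)) {
    cc <- cos(2 * pi * t / 52 - phi)
    Sc <- sum(cc); Scc <- sum(cc^2); Syc <- sum(y * cc)
    for (A in seq(0, 2, by = 0.01)) {
      mg <- seq(mean(y) - 0.5, mean(y) + 0.5, by = 0.01)
      sse <- Syy - 2 * mg * Sy - 2 * A * Syc + mg^2 * n +
        2 * mg * A * Sc + A^2 * Scc
      i <- which.min(sse)
      if (sse[i] < best["sse"]) best <- c(sse = sse[i], m = mg[i], A = A)
    }
  }
  expect_lt(abs(f$amplitude - best["A"]), 0.02)
  expect_lt(abs(f$m - best["m"]), 0.02)
})

test_that("peak week is equivariant under circular shifts", {
  y <- make_cosine(156, A = 1, peak_week = 10)
  f0 <- fit_harmonic(y)
  for (w in c(5, 17, 40)) {
    ys <- make_cosine(156, A = 1, peak_week = ((10 + w - 1) %% 52) + 1)
    fs <- fit_harmonic(ys)
    expect_equal(((fs$peak_week - f0$peak_week) %% 52), w, tolerance = 1e-6)
  }
})

test_that("bootstrap peak interval collapses without noise and wraps the year", {
  y <- make_cosine(156, A = 1, peak_week = 26)
  f <- fit_harmonic(y)
  ci <- peak_confidence_interval(f, y, n_boot = 200, seed = 5)
  expect_equal(ci$ci_low, f$peak_week, tolerance = 1e-6)
  expect_equal(ci$ci_high, f$peak_week, tolerance = 1e-6)

  # peak near week 1: the interval must wrap across the 52/1 boundary
  yw <- make_cosine(156, A = 1, peak_week = 1, sigma = 0.8, seed = 12)
  fw <- fit_harmonic(yw)
  cw <- peak_confidence_interval(fw, yw, n_boot = 500, seed = 12)
  expect_gt(cw$ci_low, cw$ci_high)  # wrapping interval
  expect_true(week_in_interval(52, cw$ci_low, cw$ci_high))
  expect_true(week_in_interval(2, cw$ci_low, cw$ci_high))
  expect_false(week_in_interval(26, cw$ci_low, cw$ci_high))

  # deterministic under the seed
  cw2 <- peak_confidence_interval(fw, yw, n_boot = 500, seed = 12)
  expect_identical(cw, cw2)

  # no amplitude: interval is the whole year, flagged
  f0 <- fit_harmonic(rep(2, 156))
  c0 <- peak_confidence_interval(f0, rep(2, 156), n_boot = 50, seed = 1)
  expect_true(c0$full_year)
})

test_that("peak interval covers the true peak at nominal rate", {
  hits <- vapply(1:200, function(s) {
    y <- make_cosine(156, A = 1, peak_week = 30, sigma = 0.3, seed = 1000 + s)
    f <- fit_harmonic(y)
    ci <- peak_confidence_interval(f, y, n_boot = 300, seed = s)
    week_in_interval(30, ci$ci_low, ci$ci_high)
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("seasonal strength follows its defining ratio", {
  mk <- function(seasonal, remainder) {
    structure(list(input = seasonal + remainder, trend = 0 * seasonal,
                   seasonal = seasonal, remainder = remainder,
                   start_date = as.Date(NA), frequency = 52L),
              class = "stl_decomposition")
  }
  s <- rep(sin(2 * pi * (1:52) / 52), 2)
  expect_equal(seasonal_strength(mk(s, 0 * s)), 1)
  expect_equal(seasonal_strength(mk(0 * s, rnorm(104))), 0)
  # var(seasonal) = 3, var(remainder) = 1 -> Fs = 0.75 (population variances)
  pvar <- function(x) mean((x - mean(x))^2)
  s3 <- s * sqrt(3 / pvar(s))
  r1 <- rep(c(1, -1), 52)          # population variance exactly 1
  expect_equal(seasonal_strength(mk(s3, r1)), 0.75, tolerance = 1e-12)
  expect_error(seasonal_strength(mk(0 * s, 0 * s)), "degenerate")
  # invariant to adding a constant, unchanged under common scaling
  d <- stl_periodic(make_cosine(156, A = 1, sigma = 0.5, seed = 3))
  d2 <- stl_periodic(make_cosine(156, A = 1, sigma = 0.5, seed = 3) * 4 + 10)
  expect_equal(seasonal_strength(d), seasonal_strength(d2), tolerance = 1e-9)
})

test_that("strength categories use the stated cut points, gated on p", {
  expect_equal(strength_category(0.8, 0.001), "very strong")
  expect_equal(strength_category(0.5, 0.001), "moderate")
  expect_equal(strength_category(0.9, 0.02), "non-significant")
  expect_equal(strength_category(0.2, 0.005), "weak")
  expect_equal(strength_category(0.05, 0.005), "very weak")
  # left-closed boundaries; exact threshold p = 0.01 counts as significant
  expect_equal(strength_category(0.75, 0.01), "very strong")
  expect_equal(strength_category(0.55, 0.01), "strong")
  expect_equal(strength_category(0.35, 0.01), "moderate")
  expect_equal(strength_category(0.15, 0.01), "weak")
})

test_that("cohorts follow the astronomical season windows", {
  expect_equal(season_of_day(32), "winter")    # Feb 1
  expect_equal(season_of_day(79), "winter")    # Mar 20
  expect_equal(season_of_day(80), "spring")    # Mar 21
  expect_equal(season_of_day(172), "spring")   # Jun 21
  expect_equal(season_of_day(173), "summer")   # Jun 22
  expect_equal(season_of_day(265), "summer")   # Sep 22
  expect_equal(season_of_day(266), "autumn")   # Sep 23
  expect_equal(season_of_day(354), "autumn")   # Dec 20
  expect_equal(season_of_day(355), "winter")   # Dec 21 (winter precedence)
  expect_equal(season_of_day(365), "winter")   # Dec 31 wraps

  # assign_cohort gates on the significance threshold
  dc <- make_dated_cosine(peak_day = 32, years = 3, A = 1)
  ws <- regularize_weekly(dc$values, dc$dates)
  f <- fit_harmonic(ws)
  expect_equal(assign_cohort(f), "winter")
  f$p_value <- 0.02
  expect_equal(assign_cohort(f), "non-significant")
  f$p_value <- 0.01                         # tie -> significant
  expect_equal(assign_cohort(f), "winter")
})

test_that("per-species analysis returns one coherent row per retained species", {
  ps <- plant_spec("T", n_species = 30, years = 3, seed = 3)
  sim <- simulate_plant(ps)
  suppressMessages({
    agg <- aggregate_to_species(merge_replicates(filter_min_reads(sim$table)),
                                sim$taxonomy)
  })
  keep <- retain_abundant_species(agg)
  res <- species_seasonality(agg, species = keep, n_boot = 100, seed = 2)
  expect_identical(res$species, keep)
  expect_true(all(res$fs >= 0 & res$fs <= 1))
  expect_true(all((res$cohort == "non-significant") == (res$p_value > 0.01)))
  ok_cat <- vapply(seq_len(nrow(res)), function(i)
    identical(res$strength[i], strength_category(res$fs[i], res$p_value[i])),
    logical(1))
  expect_true(all(ok_cat))
})
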