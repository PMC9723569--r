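# Shared fixture builders: all synthetic, built in code at test time.

# weekly cosine series on an integer week grid (period 52)
make_cosine <- function(n = 156, m = 0, A = 1, peak_week = 26, sigma = 0,
                        seed = NULL) {
  gen <- function() {
    t <- seq_len(n)
    m + A * cos(2 * pi * (t - peak_week) / 52) +
      if (sigma > 0) rnorm(n, 0, sigma) else 0
  }
  if (is.null(seed)) gen() else seasonflow:::withr_seed(seed, gen())
}

# calendar-dated weekly series whose latent peak falls on a given day-of-year
# (same 365.25-day annual cosine the generator uses)
make_dated_cosine <- function(peak_day, years = 3, A = 1, sigma = 0,
                              start = as.Date("2015-01-05"), seed = 1) {
  dates <- start + 7 * (0:(floor(years * 365.25 / 7)))
  t_abs <- as.numeric(dates - as.Date("2000-01-01"))
  y <- A * cos(2 * pi * (t_abs - (peak_day - 1)) / 365.25)
  if (sigma > 0) y <- y + seasonflow:::withr_seed(seed, rnorm(length(y), 0, sigma))
  list(values = y, dates = dates)
}

# minimal sample_table: counts matrix built from a list of rows
make_table <- function(rows, dates, plant = "P1", replicate_of = NA,
                       taxa = NULL) {
  m <- do.call(rbind, rows)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(ncol(m)))
  dimnames(m) <- list(paste0("s", seq_along(rows)), taxa)
  meta <- data.frame(sample_id = rownames(m), plant = plant,
                     date = as.Date(dates),
                     replicate_of = replicate_of, stringsAsFactors = FALSE)
  sample_table(m, meta)
}
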