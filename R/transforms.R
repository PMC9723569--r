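#' Relative abundance per sample
#'
#' Row-normalizes a counts matrix (or a single count vector) to proportions.
#'
#' @param x Non-negative matrix (samples x taxa) or vector.
#' @return Same shape, rows summing to 1.
#' @export
relative_abundance <- function(x) {
  if (is.matrix(x)) {
    rs <- rowSums(x)
    if (any(rs <= 0)) stop("zero-sum sample row")
    x / rs
  } else {
    s <- sum(x)
    if (s <= 0) stop("zero-sum sample")
    x / s
  }
}

#' Robust centred log-ratio transform
#'
#' For each sample, positive counts x_i map to log(x_i) minus the mean log
#' over that sample's positive counts — i.e. the log-ratio to the geometric
#' mean computed over taxa with reads > 0 only. Zero counts stay missing
#' (`NA`) rather than being imputed, which is what makes the transform
#' robust to compositional sparsity. Non-missing values per sample sum to 0.
#'
#' @param x Non-negative matrix (samples x taxa) or vector; counts or
#'   proportions (the transform is scale-invariant per sample).
#' @return Same shape; `NA` where the input was 0.
#' @export
rclr <- function(x) {
  one <- function(v) {
    pos <- v > 0
    if (!any(pos)) stop("all-zero sample row")
    out <- rep(NA_real_, length(v))
    lv <- log(v[pos])
    out[pos] <- lv - mean(lv)
    out
  }
  if (is.matrix(x)) {
    out <- t(apply(x, 1, one))
    dimnames(out) <- dimnames(x)
    out
  } else one(x)
}

#' Hellinger transform
#'
#' Square root of relative abundances; squared values sum to 1 per sample.
#' Standard pre-treatment before Euclidean ordination of count compositions.
#'
#' @param x Non-negative matrix (samples x taxa) or vector.
#' @return Same shape.
#' @export
hellinger <- function(x) sqrt(relative_abundance(x))

#' Rarefy samples to a common depth
#'
#' Subsamples each sample's reads without replacement (hypergeometric) to
#' `depth` reads. Samples with fewer than `depth` reads are excluded with a
#' message. Deterministic given `seed`.
#'
#' @param x Integer matrix (samples x taxa) or a [sample_table()].
#' @param depth Target depth. Default 10000.
#' @param seed Integer seed.
#' @return Integer matrix of rarefied counts (possibly fewer rows).
#' @export
rarefy_counts <- function(x, depth = 10000, seed = 1) {
  if (inherits(x, "sample_table")) {
    if (x$proportions) stop("rarefaction requires read counts")
    x <- x$counts
  }
  keep <- rowSums(x) >= depth
  if (any(!keep))
    message("rarefy_counts: excluded below-depth samples: ",
            paste(rownames(x)[!keep], collapse = ", "))
  x <- x[keep, , drop = FALSE]
  # vegan advises whenever the smallest positive count exceeds 1, which is
  # true of essentially every amplicon table; muffle that advisory only
  out <- withCallingHandlers(
    withr_seed(seed, vegan::rrarefy(x, depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  storage.mode(out) <- "integer"
  out
}

# evaluate expr under a local RNG seed without touching the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Observed richness per sample
#' @param x Counts matrix or vector.
#' @return Number of taxa with reads > 0 (per row for matrices).
#' @export
richness <- function(x) {
  if (is.matrix(x)) rowSums(x > 0) else sum(x > 0)
}

#' Simpson diversity, reported as 1 - D
#'
#' 1 - sum(p_i^2) over each sample's relative abundances; 0 for a
#' single-taxon sample, approaching 1 for many evenly abundant taxa.
#'
#' @param x Counts matrix or vector.
#' @export
simpson_1_minus_d <- function(x) {
  one <- function(v) { p <- relative_abundance(v); 1 - sum(p^2) }
  if (is.matrix(x)) apply(x, 1, one) else one(x)
}
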