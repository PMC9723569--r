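#' Longitudinal sample-by-taxon abundance table
#'
#' The central container of the package: a samples x taxa abundance matrix
#' together with per-sample metadata (plant, sampling date, optional replicate
#' link). Values are integer read counts when `proportions = FALSE`, or
#' row-normalized relative abundances after [merge_replicates()].
#'
#' @param counts Numeric matrix, samples as rows, taxa as columns. Row and
#'   column names are the sample and taxon identifiers.
#' @param meta Data frame with columns `sample_id`, `plant`, `date`
#'   (ISO-8601 string or `Date`), and optionally `replicate_of` (the
#'   `sample_id` of the primary sample of a replicate group, `NA` otherwise).
#' @param proportions Logical; `TRUE` when rows hold relative abundances
#'   rather than read counts.
#'
#' @return An object of class `sample_table`.
#' @export
sample_table <- function(counts, meta, proportions = FALSE) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have sample ids as rownames")
  if (is.null(colnames(counts))) stop("counts must have taxon ids as colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids")
  if (any(counts < 0)) stop("negative abundances")
  if (!proportions && any(counts != round(counts)))
    stop("count table must hold integers; use proportions = TRUE otherwise")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  req <- c("sample_id", "plant", "date")
  if (!all(req %in% names(meta)))
    stop("metadata must have columns: ", paste(req, collapse = ", "))
  if (!"replicate_of" %in% names(meta)) meta$replicate_of <- NA_character_
  meta$replicate_of <- as.character(meta$replicate_of)
  meta$date <- as.Date(meta$date)  # ISO-8601 only; NA signals a parse failure
  if (anyNA(meta$date)) stop("unparseable dates (ISO-8601 required)")
  if (!setequal(meta$sample_id, rownames(counts)))
    stop("metadata sample_id set must match count rownames")
  meta <- meta[match(rownames(counts), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(counts = counts, meta = meta, proportions = proportions),
            class = "sample_table")
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("<sample_table> %d samples x %d taxa (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (x$proportions) "proportions" else "read counts"))
  cat(sprintf("  plants: %s\n", paste(unique(x$meta$plant), collapse = ", ")))
  cat(sprintf("  dates:  %s .. %s\n", min(x$meta$date), max(x$meta$date)))
  invisible(x)
}

#' @export
dim.sample_table <- function(x) dim(x$counts)

subset_samples <- function(x, keep) {
  meta <- x$meta[keep, , drop = FALSE]
  # repair replicate groups whose primary sample was dropped: promote the
  # first surviving member to primary and re-point the rest at it
  orphan <- !is.na(meta$replicate_of) & !(meta$replicate_of %in% meta$sample_id)
  for (gid in unique(meta$replicate_of[orphan])) {
    members <- which(!is.na(meta$replicate_of) & meta$replicate_of == gid)
    meta$replicate_of[members[1]] <- NA_character_
    if (length(members) > 1)
      meta$replicate_of[members[-1]] <- meta$sample_id[members[1]]
  }
  sample_table(x$counts[keep, , drop = FALSE], meta,
               proportions = x$proportions)
}

#' Discard samples with too few reads
#'
#' Removes samples whose total read count falls below `min_reads`
#' (strictly less than; a sample at exactly the threshold is retained).
#' Dropped sample ids are reported via `message()`.
#'
#' @param x A count-valued [sample_table()].
#' @param min_reads Minimum total reads per sample. Default 10000.
#' @return A `sample_table` with low-depth samples removed.
#' @export
filter_min_reads <- function(x, min_reads = 10000) {
  stopifnot(inherits(x, "sample_table"))
  if (x$proportions) stop("filter_min_reads requires a count-valued table")
  depth <- rowSums(x$counts)
  keep <- depth >= min_reads
  if (!any(keep)) stop("all samples fall below the read threshold")
  if (any(!keep))
    message("filter_min_reads: dropped ",
            paste(rownames(x$counts)[!keep], collapse = ", "))
  subset_samples(x, keep)
}

#' Merge replicate samples by averaging relative abundances
#'
#' Replicate groups (a primary sample plus samples pointing at it through
#' `replicate_of`) are collapsed to one pseudo-sample whose per-taxon value is
#' the arithmetic mean of the replicates' relative abundances. The result is
#' proportion-valued: count-based operations such as rarefaction must run
#' before merging.
#'
#' @param x A count-valued [sample_table()].
#' @return A proportion-valued `sample_table`, one row per sampling point.
#' @export
merge_replicates <- function(x) {
  stopifnot(inherits(x, "sample_table"))
  props <- relative_abundance(x$counts)
  group <- ifelse(is.na(x$meta$replicate_of), x$meta$sample_id, x$meta$replicate_of)
  if (!all(group %in% x$meta$sample_id))
    stop("replicate_of references unknown samples")
  prim <- match(group, x$meta$sample_id)
  if (any(x$meta$plant != x$meta$plant[prim]) ||
      any(x$meta$date != x$meta$date[prim]))
    stop("replicate group spans plants or dates")
  keys <- unique(group)
  merged <- t(vapply(keys, function(k) {
    colMeans(props[group == k, , drop = FALSE])
  }, numeric(ncol(props))))
  rownames(merged) <- keys
  meta <- x$meta[match(keys, x$meta$sample_id), , drop = FALSE]
  meta$replicate_of <- NA_character_
  sample_table(merged, meta, proportions = TRUE)
}

#' Aggregate ASV columns to species
#'
#' Columns sharing a species label in the taxonomy are summed per sample.
#' Taxa without a species-level classification stay as their own columns,
#' keyed by their original (ASV) id — they are treated as separate species.
#' Per-sample totals are conserved exactly.
#'
#' @param x A [sample_table()] (counts or proportions).
#' @param tax Taxonomy data frame with a `taxon_id` column and rank columns
#'   `Kingdom` .. `Species`; `Species` may be `NA` or `""` for unclassified.
#' @return A `sample_table` with one column per species / unclassified ASV.
#' @export
aggregate_to_species <- function(x, tax) {
  stopifnot(inherits(x, "sample_table"))
  tax <- as.data.frame(tax, stringsAsFactors = FALSE)
  i <- match(colnames(x$counts), tax$taxon_id)
  if (anyNA(i)) stop("taxa missing from taxonomy: ",
                     paste(colnames(x$counts)[is.na(i)], collapse = ", "))
  sp <- tax$Species[i]
  key <- ifelse(is.na(sp) | sp == "", colnames(x$counts), sp)
  keys <- unique(key)
  agg <- vapply(keys, function(k) {
    rowSums(x$counts[, key == k, drop = FALSE])
  }, numeric(nrow(x$counts)))
  agg <- matrix(agg, nrow = nrow(x$counts),
                dimnames = list(rownames(x$counts), keys))
  sample_table(agg, x$meta, proportions = x$proportions)
}

#' Species retained for seasonality analysis
#'
#' Returns the ids of species whose relative abundance strictly exceeds
#' `threshold` in at least one sample.
#'
#' @param x A species-aggregated [sample_table()].
#' @param threshold Relative-abundance cut-off as a proportion.
#'   Default 0.0005 (0.05 percent).
#' @return Character vector of retained species ids.
#' @export
retain_abundant_species <- function(x, threshold = 0.0005) {
  stopifnot(inherits(x, "sample_table"))
  props <- if (x$proportions) x$counts else relative_abundance(x$counts)
  colnames(props)[apply(props, 2, max) > threshold]
}
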