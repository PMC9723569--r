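# Plain-text readers/writers for the package's table formats. TSV for count,
# taxonomy and ground-truth tables; CSV for sample metadata. Dates ISO-8601.

#' Read a count table
#'
#' @param path TSV file, samples as rows and taxa as columns (header row of
#'   taxon ids, first column of sample ids) unless `taxa_as_rows = TRUE`.
#' @param taxa_as_rows Logical; set when the file stores taxa as rows.
#' @return Integer matrix with sample rownames and taxon colnames.
#' @export
read_count_table <- function(path, taxa_as_rows = FALSE) {
  d <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(d)
  if (taxa_as_rows) m <- t(m)
  storage.mode(m) <- if (all(m == round(m))) "integer" else "double"
  m
}

#' Write a count table
#' @param counts Matrix with sample rownames and taxon colnames.
#' @param path Output TSV path.
#' @export
write_count_table <- function(counts, path) {
  d <- data.frame(sample_id = rownames(counts), counts,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read sample metadata (CSV: sample_id, plant, date, replicate_of)
#' @param path CSV path.
#' @export
read_metadata <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  if ("replicate_of" %in% names(m))
    m$replicate_of[m$replicate_of == ""] <- NA_character_
  m
}

#' Write sample metadata
#' @param meta Metadata data frame.
#' @param path Output CSV path.
#' @export
write_metadata <- function(meta, path) {
  meta$date <- as.character(meta$date)
  utils::write.csv(meta, path, row.names = FALSE, quote = FALSE, na = "")
}

#' Read a taxonomy table (TSV: taxon_id, Kingdom .. Species)
#' @param path TSV path.
#' @export
read_taxonomy <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
}

#' Write a taxonomy table
#' @param tax Taxonomy data frame.
#' @param path Output TSV path.
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.table(tax, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
}
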