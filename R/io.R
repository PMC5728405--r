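# Shared readers and writers.  Images and label masks travel as multi-page
# 16-bit grayscale TIFF (one channel per page), tables as CSV, sequences as
# FASTA, configuration as YAML and reports as JSON; all text is UTF-8.
# Pixel coordinates in output tables are 0-based (row, col); CDS coordinates
# are 1-based.

#' Write image channels to a multi-page 16-bit TIFF
#'
#' @param channels named list of numeric matrices on a 16-bit intensity
#'   scale (values clipped to `[0, 65535]`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(channels, path) {
  if (is.matrix(channels)) channels <- list(channels)
  pages <- lapply(channels, function(ch) {
    ch <- pmin(pmax(ch, 0), 65535)
    round(ch) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page 16-bit TIFF written by [write_image_tiff()]
#'
#' @param path TIFF file.
#' @return list of numeric matrices on the 16-bit scale.
#' @export
read_image_tiff <- function(path) {
  if (!file.exists(path)) stop("missing input: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) round(p * 65535))
}

#' Write an integer label mask as a 16-bit TIFF
#' @param labels integer matrix (0 = background, labels < 65536).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_label_tiff <- function(labels, path) {
  stopifnot(max(labels) < 65536)
  write_image_tiff(list(labels = labels), path)
}

#' Read a label mask written by [write_label_tiff()]
#' @param path TIFF file.
#' @return integer matrix.
#' @export
read_label_tiff <- function(path) {
  m <- read_image_tiff(path)[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write sequences to FASTA
#' @param seqs named character vector of ACGT sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA file.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("missing input: ", path, call. = FALSE)
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write a data.frame as CSV (UTF-8, no row names)
#' @param df data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a CSV written by [write_table_csv()]
#' @param path CSV file.
#' @return data.frame.
#' @export
read_table_csv <- function(path) {
  if (!file.exists(path)) stop("missing input: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Write a gene set as one identifier per line
#' @param set `gene_set` or character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(set, path) {
  writeLines(as_gene_vector(set), path, useBytes = TRUE)
  invisible(path)
}

#' Read a one-identifier-per-line gene set
#' @param path text file.
#' @param label condition label to attach.
#' @return a `gene_set`.
#' @export
read_gene_set <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("missing input: ", path, call. = FALSE)
  structure(list(label = label, genes = sort(readLines(path))),
            class = "gene_set")
}

#' Write a report object as JSON
#' @param x list/data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
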