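#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @param width Line wrap width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' Sequence names are truncated at the first whitespace, following common
#' aligner behaviour.
#'
#' @param path FASTA file.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write intervals to BED (0-based half-open)
#'
#' @param x Data frame with columns `scaffold`, `start`, `end` and optionally
#'   `name`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(all(c("scaffold", "start", "end") %in% names(x)))
  cols <- c("scaffold", "start", "end", if ("name" %in% names(x)) "name")
  write.table(x[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file (0-based half-open)
#'
#' @param path BED file.
#' @return Data frame with columns `scaffold`, `start`, `end` and, when
#'   present in the file, `name`.
#' @export
read_bed <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  names(x)[1:3] <- c("scaffold", "start", "end")
  if (ncol(x) >= 4L) names(x)[4] <- "name"
  x[, 1:min(ncol(x), 4L), drop = FALSE]
}
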