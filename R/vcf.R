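# Light VCF interface for SNV calls carrying DP4 in INFO.  Deliberately a
# purpose-built text writer/reader: the only payload is the four DP4 counts
# and the call coordinates, and round-trip identity of BAF values is part of
# the contract (tested against an independent VCF parser).

#' Write SNV calls to VCF
#'
#' Positions are converted to the 1-based VCF convention; DP4 is written as
#' an INFO field (`ref_fwd,ref_rev,alt_fwd,alt_rev`).
#'
#' @param calls A `variant_calls` data frame.
#' @param path Output VCF path.
#' @param contigs Optional named scaffold lengths for `##contig` header
#'   lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, contigs = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=haplodepth",
    paste0("##INFO=<ID=DP4,Number=4,Type=Integer,Description=",
           "\"Strand-resolved ref/alt depths: ref-fwd,ref-rev,alt-fwd,",
           "alt-rev\">"),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Ref+alt depth\">"),
    con)
  if (!is.null(contigs)) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                       as.integer(contigs)), con)
  }
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  if (nrow(calls)) {
    dp <- calls$ref_fwd + calls$ref_rev + calls$alt_fwd + calls$alt_rev
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;DP4=%d,%d,%d,%d",
                       calls$scaffold, calls$pos + 1L, calls$ref, calls$alt,
                       dp, calls$ref_fwd, calls$ref_rev, calls$alt_fwd,
                       calls$alt_rev), con)
  }
  invisible(path)
}

#' Read SNV calls from a VCF with DP4 INFO
#'
#' Reads SNV records (1 bp REF and ALT) and reconstructs DP4 counts and BAF;
#' indel records are skipped, matching the SNV-only scope of the
#' heterozygosity diagnostics.
#'
#' @param path VCF file.
#' @return A `variant_calls` data frame (0-based positions).
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  empty <- data.frame(scaffold = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      ref_fwd = integer(0), ref_rev = integer(0),
                      alt_fwd = integer(0), alt_rev = integer(0),
                      baf = numeric(0), stringsAsFactors = FALSE)
  if (length(lines) == 0L) {
    class(empty) <- c("variant_calls", "data.frame")
    return(empty)
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  f <- do.call(rbind, f)
  snv <- nchar(f[, 4]) == 1L & nchar(f[, 5]) == 1L & f[, 5] != "."
  f <- f[snv, , drop = FALSE]
  if (nrow(f) == 0L) {
    class(empty) <- c("variant_calls", "data.frame")
    return(empty)
  }
  dp4 <- regmatches(f[, 8], regexpr("DP4=[0-9,]+", f[, 8]))
  if (length(dp4) != nrow(f)) {
    stop("VCF records missing DP4 INFO", call. = FALSE)
  }
  cnt <- do.call(rbind, lapply(strsplit(sub("^DP4=", "", dp4), ","),
                               as.integer))
  out <- data.frame(scaffold = f[, 1], pos = as.integer(f[, 2]) - 1L,
                    ref = f[, 4], alt = f[, 5],
                    ref_fwd = cnt[, 1], ref_rev = cnt[, 2],
                    alt_fwd = cnt[, 3], alt_rev = cnt[, 4],
                    stringsAsFactors = FALSE)
  out$baf <- compute_baf(out)
  class(out) <- c("variant_calls", "data.frame")
  out
}
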