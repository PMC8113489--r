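#' Place reads on an assembly with the built-in exact-seed placer
#'
#' Indexes every `k`-mer of the assembly, seeds each read at five offsets on
#' both strands and extends by ungapped full-length comparison, keeping the
#' placement(s) with the fewest mismatches within the budget.  A unique best
#' placement gets MAPQ 60; if two or more placements tie on the best score,
#' one is chosen uniformly at random and MAPQ is set to 0 - the conventional
#' multi-mapper flag the depth filters act on.  Reads spanning an indel
#' between haplotypes may exceed the mismatch budget and go unplaced; at the
#' simulator's default indel rate this loses a small, locus-independent
#' fraction of reads.
#'
#' The default mismatch budget tolerates both sequencing error and haplotype
#' divergence (well under 0.4% per bp), so reads drawn from haplotype 2 still
#' place on a haplotype-1 (collapsed) assembly across heterozygous sites -
#' exactly the behaviour of a practical aligner that the B-allele-frequency
#' diagnostics rely on.
#'
#' @param reads A `read_set`, or a character vector of read sequences.
#' @param assembly An `assembly_rendering` or named character vector of
#'   scaffold sequences.
#' @param k Seed length (default 31); every read must be at least `k` bp.
#' @param max_mismatch Mismatch budget; default
#'   `max(ceil(0.04 * read_length), ceil(3 * error_rate * read_length))`.
#' @param seed Optional seed for tie-breaking reproducibility.
#' @return Object of class `alignments`: data frame with `read`, `scaffold`,
#'   `pos` (0-based), `width`, `strand`, `mapq` (0 or 60), `nm`, `seq`
#'   (reference-oriented), plus a `scaffold_lengths` attribute.
#' @export
place_reads <- function(reads, assembly, k = 31L, max_mismatch = NULL,
                        seed = NULL) {
  seqs <- if (inherits(assembly, "assembly_rendering")) assembly$sequences
          else assembly
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  if (inherits(reads, "read_set")) {
    rv <- c(rbind(reads$r1, reads$r2))
    ids <- c(rbind(paste0(reads$id, "/1"), paste0(reads$id, "/2")))
    err <- reads$config$error_rate
  } else {
    rv <- reads
    ids <- if (!is.null(names(reads))) names(reads) else
      sprintf("read%07d", seq_along(reads))
    err <- 0
  }
  if (any(nchar(rv) < k)) stop("read shorter than seed length k",
                               call. = FALSE)
  if (is.null(max_mismatch)) {
    max_mismatch <- max(ceiling(0.04 * max(nchar(rv))),
                        ceiling(3 * err * max(nchar(rv))))
  }
  res <- if (is.null(seed)) {
    .place_reads_cpp(unname(seqs), rv, as.integer(k),
                     as.integer(max_mismatch))
  } else {
    with_seed(seed, .place_reads_cpp(unname(seqs), rv, as.integer(k),
                                     as.integer(max_mismatch)))
  }
  out <- data.frame(
    read = ids[res$read],
    scaffold = names(seqs)[res$ref],
    pos = res$pos,
    width = nchar(res$seq),
    strand = ifelse(res$fwd == 1L, "+", "-"),
    mapq = res$mapq,
    nm = res$nm,
    seq = res$seq,
    stringsAsFactors = FALSE
  )
  attr(out, "scaffold_lengths") <- stats::setNames(nchar(seqs), names(seqs))
  attr(out, "n_input_reads") <- length(rv)
  class(out) <- c("alignments", "data.frame")
  out
}

# reference-consumed width of a simple CIGAR (M/D/N/=/X)
.cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    op <- sub("^[0-9]+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Load alignments from a BAM file
#'
#' Reads primary, non-supplementary, mapped records with MAPQ >=
#' `min_mapq` - the standard route for real data, where reads were aligned
#' with a general aligner (e.g. BWA-MEM) and sorted with SAMtools.
#'
#' @param path Coordinate-sorted BAM file.
#' @param min_mapq Minimum MAPQ to retain (0 keeps everything).
#' @return An `alignments` object (see [place_reads()]); `width` is the
#'   reference-consumed length from the CIGAR.
#' @export
load_alignments <- function(path, min_mapq = 0L) {
  hdr <- Rsamtools::scanBamHeader(path)[[1]]$targets
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "strand", "pos", "mapq", "cigar", "seq"),
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE))
  b <- Rsamtools::scanBam(path, param = param)[[1]]
  out <- data.frame(
    read = b$qname,
    scaffold = as.character(b$rname),
    pos = b$pos - 1L,
    width = .cigar_ref_width(b$cigar),
    strand = as.character(b$strand),
    mapq = as.integer(b$mapq),
    nm = NA_integer_,
    seq = as.character(b$seq),
    stringsAsFactors = FALSE
  )
  keep <- !is.na(out$mapq) & out$mapq >= min_mapq
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "scaffold_lengths") <- hdr
  class(out) <- c("alignments", "data.frame")
  out
}

#' Write alignments as SAM
#'
#' Minimal SAM writer for the synthetic placer's ungapped alignments
#' (full-length match CIGAR); convert with `Rsamtools::asBam()` for a
#' BAM round trip.
#'
#' @param aln An `alignments` object.
#' @param path Output SAM path.
#' @param scaffold_lengths Named lengths for the header; defaults to the
#'   object's attribute.
#' @return `path`, invisibly.
#' @export
write_alignments_sam <- function(aln, path, scaffold_lengths = NULL) {
  sl <- scaffold_lengths %||% attr(aln, "scaffold_lengths")
  stopifnot(!is.null(sl))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(sl), as.integer(sl)), con)
  flag <- ifelse(aln$strand == "-", 16L, 0L)
  writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
                     aln$read, flag, aln$scaffold, aln$pos + 1L, aln$mapq,
                     aln$width, aln$seq), con)
  invisible(path)
}

#' @export
print.alignments <- function(x, ...) {
  cat(sprintf("Alignments: %s records on %d scaffolds (%.1f%% MAPQ 0)\n",
              format(nrow(x), big.mark = ","), length(unique(x$scaffold)),
              if (nrow(x)) 100 * mean(x$mapq == 0) else 0))
  print.data.frame(utils::head(as.data.frame(x)[, setdiff(names(x), "seq")],
                               8L))
  if (nrow(x) > 8L) cat(sprintf("  ... %d more records\n", nrow(x) - 8L))
  invisible(x)
}
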