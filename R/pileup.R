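#' Strand-resolved pileup counts
#'
#' Accumulates per-site base counts, separated by read strand, over every
#' position of the assembly - the raw material for DP4-style
#' (ref-forward, ref-reverse, alt-forward, alt-reverse) tallies, SNV calling
#' and B-allele frequencies.
#'
#' @param aln An `alignments` object whose records carry reference-oriented
#'   read sequences (the built-in placer and [load_alignments()] both
#'   provide them).
#' @param assembly Named character vector of scaffold sequences, or an
#'   `assembly_rendering`.
#' @param min_mapq Minimum MAPQ of alignments to include.
#' @return Object of class `pileup_counts`: per-scaffold 8 x L integer
#'   matrices (rows A,C,G,T forward then A,C,G,T reverse) plus the reference
#'   sequences.
#' @export
pileup_counts <- function(aln, assembly, min_mapq = 0L) {
  seqs <- if (inherits(assembly, "assembly_rendering")) assembly$sequences
          else assembly
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  keep <- aln$mapq >= min_mapq & aln$scaffold %in% names(seqs)
  a <- aln[keep, , drop = FALSE]
  counts <- .pileup_counts_cpp(unname(seqs),
                               match(a$scaffold, names(seqs)),
                               a$pos, a$strand == "+", a$seq)
  names(counts) <- names(seqs)
  out <- list(counts = counts, ref = seqs,
              filters = list(min_mapq = min_mapq))
  class(out) <- "pileup_counts"
  out
}

#' @export
print.pileup_counts <- function(x, ...) {
  cat(sprintf("Pileup counts: %d scaffolds, %s sites (MAPQ >= %d)\n",
              length(x$counts),
              format(sum(vapply(x$counts, ncol, integer(1))),
                     big.mark = ","),
              x$filters$min_mapq))
  invisible(x)
}

#' DP4 tallies at specific sites
#'
#' For each requested site, reports the reference base, the most frequent
#' non-reference base (the alternate), and the strand-resolved DP4 counts.
#'
#' @param pileup A `pileup_counts`.
#' @param sites Data frame with `scaffold` and `pos` (0-based).
#' @return Data frame with `scaffold`, `pos`, `ref`, `alt`, `ref_fwd`,
#'   `ref_rev`, `alt_fwd`, `alt_rev`.
#' @export
dp4_sites <- function(pileup, sites) {
  stopifnot(inherits(pileup, "pileup_counts"))
  out <- lapply(unique(sites$scaffold), function(sc) {
    if (!sc %in% names(pileup$counts)) {
      stop("site outside assembly scaffolds", call. = FALSE)
    }
    p <- sites$pos[sites$scaffold == sc]
    m <- pileup$counts[[sc]]
    if (any(p < 0L | p >= ncol(m))) {
      stop("site outside scaffold", call. = FALSE)
    }
    rc <- .seq_codes(pileup$ref[[sc]])[p + 1L]
    fwd <- m[1:4, p + 1L, drop = FALSE]
    rev <- m[5:8, p + 1L, drop = FALSE]
    tot <- fwd + rev
    n <- length(p)
    ref_fwd <- fwd[cbind(rc, seq_len(n))]
    ref_rev <- rev[cbind(rc, seq_len(n))]
    masked <- tot
    masked[cbind(rc, seq_len(n))] <- -1L
    alt_code <- max.col(t(masked), ties.method = "first")
    data.frame(scaffold = sc, pos = p,
               ref = names(.base_int)[rc],
               alt = names(.base_int)[alt_code],
               ref_fwd = ref_fwd, ref_rev = ref_rev,
               alt_fwd = fwd[cbind(alt_code, seq_len(n))],
               alt_rev = rev[cbind(alt_code, seq_len(n))],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Call SNVs from pileup counts
#'
#' Threshold caller standing in for a genotype-likelihood caller on
#' synthetic data: a site is emitted when total (ref + alt) depth reaches
#' `min_depth` and the alternate fraction reaches `min_alt_fraction`.
#' Indel evidence is invisible to the pileup (substitutions only), so calls
#' are SNVs by construction.  Defaults keep false calls below 1% of the
#' truth count at 30x with percent-scale sequencing error.
#'
#' @param pileup A `pileup_counts`.
#' @param min_depth Minimum ref+alt depth (default 10).
#' @param min_alt_fraction Minimum alternate fraction (default 0.2).
#' @return Object of class `variant_calls`: data frame with `scaffold`,
#'   `pos` (0-based), `ref`, `alt`, DP4 columns and `baf`.
#' @export
call_snvs <- function(pileup, min_depth = 10L, min_alt_fraction = 0.2) {
  stopifnot(inherits(pileup, "pileup_counts"))
  if (min_depth <= 0 || min_alt_fraction <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  out <- lapply(names(pileup$counts), function(sc) {
    m <- pileup$counts[[sc]]
    L <- ncol(m)
    if (L == 0L) return(NULL)
    rc <- .seq_codes(pileup$ref[[sc]])
    bad_ref <- is.na(rc)
    rc[bad_ref] <- 1L
    fwd <- m[1:4, , drop = FALSE]
    rev <- m[5:8, , drop = FALSE]
    tot <- fwd + rev
    idx <- cbind(rc, seq_len(L))
    ref_tot <- tot[idx]
    masked <- tot
    masked[idx] <- -1L
    alt_code <- max.col(t(masked), ties.method = "first")
    aidx <- cbind(alt_code, seq_len(L))
    alt_tot <- tot[aidx]
    dp <- ref_tot + alt_tot
    baf <- ifelse(dp > 0, alt_tot / dp, 0)
    keep <- which(!bad_ref & dp >= min_depth & alt_tot > 0L &
                    baf >= min_alt_fraction)
    if (length(keep) == 0L) return(NULL)
    data.frame(scaffold = sc, pos = keep - 1L,
               ref = names(.base_int)[rc[keep]],
               alt = names(.base_int)[alt_code[keep]],
               ref_fwd = fwd[idx[keep, , drop = FALSE]],
               ref_rev = rev[idx[keep, , drop = FALSE]],
               alt_fwd = fwd[aidx[keep, , drop = FALSE]],
               alt_rev = rev[aidx[keep, , drop = FALSE]],
               baf = baf[keep],
               stringsAsFactors = FALSE)
  })
  out <- .rbind_df(out, data.frame(scaffold = character(0),
                                   pos = integer(0), ref = character(0),
                                   alt = character(0), ref_fwd = integer(0),
                                   ref_rev = integer(0),
                                   alt_fwd = integer(0),
                                   alt_rev = integer(0), baf = numeric(0),
                                   stringsAsFactors = FALSE))
  class(out) <- c("variant_calls", "data.frame")
  out
}

#' B-allele frequency from DP4 counts
#'
#' `BAF = (alt_fwd + alt_rev) / (ref_fwd + ref_rev + alt_fwd + alt_rev)`;
#' heterozygous diploid sites are expected near 0.5.
#'
#' @param x A `variant_calls` data frame (or any data frame with the four
#'   DP4 columns), or a numeric vector of length 4
#'   (`ref_fwd, ref_rev, alt_fwd, alt_rev`).
#' @return Numeric vector of BAF values in `[0, 1]`.
#' @examples
#' compute_baf(c(5, 5, 5, 5))   # 0.5
#' compute_baf(c(2, 3, 7, 8))   # 0.75
#' @export
compute_baf <- function(x) {
  if (is.numeric(x) && is.null(dim(x))) {
    stopifnot(length(x) == 4L)
    x <- data.frame(ref_fwd = x[1], ref_rev = x[2], alt_fwd = x[3],
                    alt_rev = x[4])
  }
  tot <- x$ref_fwd + x$ref_rev + x$alt_fwd + x$alt_rev
  if (any(tot <= 0)) stop("zero total DP4 depth", call. = FALSE)
  (x$alt_fwd + x$alt_rev) / tot
}

#' @export
print.variant_calls <- function(x, ...) {
  cat(sprintf("SNV calls: %s sites on %d scaffolds, mean BAF %.3f\n",
              format(nrow(x), big.mark = ","), length(unique(x$scaffold)),
              if (nrow(x)) mean(x$baf) else NA_real_))
  print.data.frame(utils::head(as.data.frame(x), 8L))
  if (nrow(x) > 8L) cat(sprintf("  ... %d more sites\n", nrow(x) - 8L))
  invisible(x)
}
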