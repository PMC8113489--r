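#' Per-base mapped read depth
#'
#' Builds a per-base depth vector for every scaffold from filtered
#' alignments, reproducing the filtering used for the depth diagnostics:
#' records below `min_mapq` are removed (MAPQ 0 marks ambiguous multi-mapped
#' placements), and alignments *fully contained* within a repeat-mask
#' interval are dropped - containment, not mere overlap, the strictest
#' reading of masking out repeat-dominated alignments.  Filtering happens
#' before depth is accumulated.
#'
#' @param aln An `alignments` object.
#' @param min_mapq Minimum MAPQ (default 0 = keep all).
#' @param mask Optional data frame of mask intervals (`scaffold`, `start`,
#'   `end`, 0-based half-open), e.g. from [read_bed()].
#' @param scaffold_lengths Named scaffold lengths; defaults to the
#'   alignments' attribute.
#' @return Object of class `depth_track`: list with `depth` (named list of
#'   integer vectors) and `filters`.
#' @export
depth_track <- function(aln, min_mapq = 0L, mask = NULL,
                        scaffold_lengths = NULL) {
  sl <- scaffold_lengths %||% attr(aln, "scaffold_lengths")
  stopifnot(!is.null(sl))
  keep <- aln$mapq >= min_mapq
  s <- aln$pos[keep]
  e <- aln$pos[keep] + aln$width[keep]
  sc <- aln$scaffold[keep]
  if (!is.null(mask)) {
    if (!all(mask$scaffold %in% names(sl))) {
      stop("mask references unknown scaffold", call. = FALSE)
    }
    contained <- rep(FALSE, length(s))
    for (msc in unique(mask$scaffold)) {
      m <- mask[mask$scaffold == msc, , drop = FALSE]
      m <- .merge_intervals(m$start, m$end)
      i <- sc == msc
      if (!any(i)) next
      j <- findInterval(s[i], m$start)
      ok <- j >= 1L
      ok[ok] <- e[i][ok] <= m$end[j[ok]]
      contained[i] <- ok
    }
    s <- s[!contained]
    e <- e[!contained]
    sc <- sc[!contained]
  }
  depth <- lapply(stats::setNames(names(sl), names(sl)), function(nm) {
    i <- sc == nm
    .depth_from_intervals(s[i], e[i], as.integer(sl[[nm]]))
  })
  out <- list(depth = depth,
              filters = list(min_mapq = min_mapq, masked = !is.null(mask)),
              scaffold_lengths = sl)
  class(out) <- "depth_track"
  out
}

#' Depth track from simulator truth placements
#'
#' Computes the depth the reads would produce on the collapsed assembly if
#' every read were placed at its true origin: haplotype-2 placements are
#' lifted through the indel coordinate map to haplotype-1 coordinates, and
#' tandem-duplication insertions (from [apply_true_duplication()]) are folded
#' back onto the single pre-duplication copy.  For error-free reads this
#' agrees with the built-in placer at >= 99% of unmasked bases and is the
#' fast path used by the replicate calibration drivers.
#'
#' @param placements A `read_placements` (or `read_set`).
#' @param genome The `diploid_genome` the placements were drawn from.
#' @return A `depth_track` on the collapsed-assembly scaffolds.
#' @export
truth_depth_track <- function(placements, genome) {
  if (inherits(placements, "read_set")) placements <- placements$placements
  stopifnot(inherits(genome, "diploid_genome"))
  L <- attr(placements, "read_length")
  starts <- c(placements$r1_start, placements$r2_start)
  scf <- rep(placements$scaffold, 2L)
  hap <- rep(placements$hap, 2L)

  # collapsed-assembly scaffold lengths are the pre-duplication ones
  dup <- genome$dup_loci
  sl <- genome$hap1_length
  if (!is.null(dup) && nrow(dup)) {
    dl <- tapply(dup$end - dup$start, dup$scaffold, sum)
    sl[names(dl)] <- sl[names(dl)] - as.integer(dl)
  }

  depth <- stats::setNames(vector("list", length(genome$scaffolds)),
                           genome$scaffolds)
  for (sc in genome$scaffolds) {
    i <- scf == sc
    st <- starts[i]
    h2 <- hap[i] == 2L
    if (any(h2)) {
      st[h2] <- .lift_hap2_to_hap1(st[h2], genome$offsets[[sc]])
    }
    if (!is.null(dup) && nrow(dup)) {
      tab <- .dup_lift_table(dup, sc)
      st <- .lift_dup_to_collapsed(st, tab)
    }
    depth[[sc]] <- .depth_from_intervals(st, st + L, as.integer(sl[[sc]]))
  }
  out <- list(depth = depth,
              filters = list(min_mapq = NA_integer_, masked = FALSE,
                             source = "truth_placements"),
              scaffold_lengths = sl)
  class(out) <- "depth_track"
  out
}

#' @export
print.depth_track <- function(x, ...) {
  means <- vapply(x$depth, mean, numeric(1))
  cat(sprintf("Depth track: %d scaffolds, %s bp", length(x$depth),
              format(sum(lengths(x$depth)), big.mark = ",")))
  if (!is.na(x$filters$min_mapq)) {
    cat(sprintf(" (MAPQ >= %d%s)", x$filters$min_mapq,
                if (x$filters$masked) ", masked" else ""))
  }
  cat("\n  mean depth per scaffold:",
      paste(sprintf("%s=%.1f", names(means), means), collapse = ", "), "\n")
  invisible(x)
}

#' Mean mapped depth over each marker gene
#'
#' Mean of the per-base depth across the complete genomic range of each
#' gene, zero-depth bases included.
#'
#' @param track A `depth_track`.
#' @param genes Marker genes: data frame with `gene_id`, `scaffold`, `start`,
#'   `end` (0-based half-open) and optionally `status`/`linkage`.
#' @return The `genes` data frame with a `mean_depth` column appended.
#' @export
mean_depth_per_gene <- function(track, genes) {
  stopifnot(inherits(track, "depth_track"))
  if (any(genes$end <= genes$start)) {
    stop("zero-length gene interval", call. = FALSE)
  }
  if (!all(genes$scaffold %in% names(track$depth))) {
    stop("gene scaffold not in depth track", call. = FALSE)
  }
  md <- numeric(nrow(genes))
  for (sc in unique(genes$scaffold)) {
    d <- track$depth[[sc]]
    if (any(genes$end[genes$scaffold == sc] > length(d))) {
      stop("gene interval outside depth track", call. = FALSE)
    }
    cs <- c(0, cumsum(as.numeric(d)))
    i <- genes$scaffold == sc
    md[i] <- (cs[genes$end[i] + 1L] - cs[genes$start[i] + 1L]) /
      (genes$end[i] - genes$start[i])
  }
  genes$mean_depth <- md
  genes
}

#' Window means of a depth track
#'
#' Non-overlapping windows of exactly `window` bp per scaffold.  The
#' trailing partial window is always dropped; with `drop_terminal` the first
#' and last *full* windows are dropped as well (scaffold-terminal windows
#' carry assembly-edge depth artifacts).  Scaffolds shorter than three full
#' windows yield no retained window under `drop_terminal` and are reported
#' empty.
#'
#' @param track A `depth_track`.
#' @param window Window width, bp (> 0); 100 kb is the conventional scale
#'   for scaffold-level copy-number scans.
#' @param drop_terminal Drop first/last full window (default `TRUE`).
#' @return Data frame with `scaffold`, `window`, `start`, `end`,
#'   `mean_depth`.
#' @export
windowed_depth <- function(track, window = 1e5, drop_terminal = TRUE) {
  stopifnot(inherits(track, "depth_track"))
  if (window <= 0) stop("`window` must be positive", call. = FALSE)
  window <- as.integer(window)
  out <- lapply(names(track$depth), function(sc) {
    d <- track$depth[[sc]]
    nf <- length(d) %/% window
    if (nf == 0L) return(NULL)
    idx <- seq_len(nf)
    cs <- c(0, cumsum(as.numeric(d)))
    st <- (idx - 1L) * window
    en <- idx * window
    m <- (cs[en + 1L] - cs[st + 1L]) / window
    keep <- if (drop_terminal) idx > 1L & idx < nf else rep(TRUE, nf)
    if (!any(keep)) return(NULL)
    data.frame(scaffold = sc, window = idx[keep], start = st[keep],
               end = en[keep], mean_depth = m[keep],
               stringsAsFactors = FALSE)
  })
  .rbind_df(out, data.frame(scaffold = character(0), window = integer(0),
                            start = integer(0), end = integer(0),
                            mean_depth = numeric(0)))
}
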