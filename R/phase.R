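#' Phase-block concordance of SNV calls
#'
#' Profiles heterozygosity against a phase-block layout: per-scaffold SNV
#' counts and densities, the fraction of SNVs falling inside phased blocks,
#' maximal runs of consecutive SNVs outside any phase block (reported as
#' heterozygous-but-unphased intervals, the signature of incomplete
#' phasing), and a low-heterozygosity flag for scaffolds whose SNV density
#' falls below `density_threshold` (candidate runs of homozygosity, or
#' hemizygous sex scaffolds in a male sample).
#'
#' @param calls A `variant_calls` data frame.
#' @param phase_blocks Data frame of phased intervals (`scaffold`, `start`,
#'   `end`, 0-based half-open), sorted and non-overlapping per scaffold,
#'   e.g. from [phased_blocks()] or [read_bed()].
#' @param scaffold_lengths Named scaffold lengths.
#' @param density_threshold Low-heterozygosity flag threshold, SNVs per kb
#'   (default 0.1).
#' @param min_run Minimum number of consecutive outside-block SNVs for an
#'   unphased-heterozygous interval (default 5).
#' @param min_span Minimum genomic span of such a run, bp (default 10 kb).
#' @return Object of class `phase_report`: list with `summary` (per-scaffold
#'   data frame) and `unphased_het` (interval data frame).
#' @export
phase_concordance <- function(calls, phase_blocks, scaffold_lengths,
                              density_threshold = 0.1, min_run = 5L,
                              min_span = 1e4) {
  stopifnot(!is.null(names(scaffold_lengths)))
  if (nrow(phase_blocks) &&
      !all(phase_blocks$scaffold %in% names(scaffold_lengths))) {
    stop("phase blocks on unknown scaffolds", call. = FALSE)
  }
  summaries <- list()
  runs <- list()
  for (sc in names(scaffold_lengths)) {
    len <- as.numeric(scaffold_lengths[[sc]])
    pb <- phase_blocks[phase_blocks$scaffold == sc, , drop = FALSE]
    pb <- pb[order(pb$start), , drop = FALSE]
    pos <- sort(calls$pos[calls$scaffold == sc])
    inside <- .in_intervals(pos, pb$start, pb$end)
    n <- length(pos)
    phased_bp <- sum(pb$end - pb$start)
    density <- n / (len / 1000)
    summaries[[sc]] <- data.frame(
      scaffold = sc, length = len, n_snv = n,
      snv_per_kb = density, phased_bp = phased_bp,
      frac_snv_phased = if (n > 0) mean(inside) else NA_real_,
      low_heterozygosity = density < density_threshold,
      stringsAsFactors = FALSE)
    if (n == 0L) next
    r <- rle(!inside)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_run)) {
      span_s <- pos[starts[k]]
      span_e <- pos[ends[k]] + 1L
      if (span_e - span_s >= min_span) {
        runs[[length(runs) + 1L]] <- data.frame(
          scaffold = sc, start = span_s, end = span_e,
          n_snv = r$lengths[k], stringsAsFactors = FALSE)
      }
    }
  }
  out <- list(
    summary = do.call(rbind, c(summaries, list(make.row.names = FALSE))),
    unphased_het = if (length(runs)) {
      do.call(rbind, c(runs, list(make.row.names = FALSE)))
    } else {
      data.frame(scaffold = character(0), start = integer(0),
                 end = integer(0), n_snv = integer(0))
    },
    params = list(density_threshold = density_threshold, min_run = min_run,
                  min_span = min_span))
  class(out) <- "phase_report"
  out
}

#' @export
print.phase_report <- function(x, ...) {
  cat("Phase-block concordance report\n")
  print.data.frame(x$summary, digits = 3)
  n <- nrow(x$unphased_het)
  cat(sprintf("%d heterozygous-but-unphased interval%s (>= %d SNVs over >= %s bp)\n",
              n, if (n == 1) "" else "s", x$params$min_run,
              format(x$params$min_span, big.mark = ",")))
  invisible(x)
}

#' Karyotype-style BAF plot
#'
#' Plots per-SNV B-allele frequencies along one scaffold with phased blocks
#' as shaded rectangles - the visual check that phased regions coincide with
#' heterozygosity at BAF ~ 0.5.
#'
#' @param calls A `variant_calls` data frame.
#' @param phase_blocks Phased intervals (`scaffold`, `start`, `end`).
#' @param scaffold Scaffold to plot.
#' @param ... Passed to [plot()].
#' @return Invisibly, `NULL`.
#' @export
plot_baf <- function(calls, phase_blocks, scaffold, ...) {
  v <- calls[calls$scaffold == scaffold, , drop = FALSE]
  pb <- phase_blocks[phase_blocks$scaffold == scaffold, , drop = FALSE]
  plot(NA, xlim = c(0, max(c(v$pos, pb$end, 1))), ylim = c(0, 1),
       xlab = sprintf("%s position (bp)", scaffold),
       ylab = "B-allele frequency", ...)
  if (nrow(pb)) {
    rect(pb$start, 0, pb$end, 1, col = adjustcolor("grey70", 0.4),
         border = NA)
  }
  points(v$pos, v$baf, pch = 16, cex = 0.3)
  abline(h = 0.5, lty = 2)
  invisible(NULL)
}
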