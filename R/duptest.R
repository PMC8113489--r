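#' Duplication-artifact depth test
#'
#' The central diagnostic: do marker genes labelled *duplicated* (by a BUSCO
#' run on a suspect assembly) show elevated mapped read depth on the
#' collapsed assembly, as true-but-collapsed duplications would, or the same
#' depth as single-copy genes, as haplotype-induced duplication artifacts
#' would?  Per-gene mean depths are partitioned by status and compared with
#' [ks_one_sided()], duplicated as the putatively greater sample.  A
#' significant result (p below `alpha`) supports genuine duplication; a
#' non-significant one supports the artifact interpretation.
#'
#' Passing a named list of tracks (e.g. all reads and MAPQ >= 1) runs the
#' test once per filtering, the conventional robustness check against
#' low-quality mappings.
#'
#' @param track A `depth_track`, or a named list of them.
#' @param genes A `marker_genes` data frame with `status` labels; only
#'   `single_copy` and `duplicated` genes enter the test.
#' @param alpha Significance level (default 0.05).
#' @param method,n_perm Passed to [ks_one_sided()].
#' @param binwidth Histogram bin width for the report; default one tenth of
#'   the median single-copy depth (i.e. coverage/10 when depth is at
#'   coverage).
#' @return Object of class `dup_artifact_test`; one result per track with
#'   per-class depth samples, medians, histogram bin counts and the
#'   `ks_onesided` result, or an `untestable` flag when a class is empty.
#' @export
duplication_artifact_test <- function(track, genes, alpha = 0.05,
                                      method = "asymptotic", n_perm = 2000L,
                                      binwidth = NULL) {
  tracks <- if (inherits(track, "depth_track")) list(depth = track) else track
  stopifnot(is.list(tracks), length(tracks) >= 1L)
  results <- lapply(tracks, function(tr) {
    g <- genes[genes$status %in% c("single_copy", "duplicated"), ,
               drop = FALSE]
    md <- mean_depth_per_gene(tr, g)
    dup <- md$mean_depth[md$status == "duplicated"]
    sing <- md$mean_depth[md$status == "single_copy"]
    if (length(dup) == 0L || length(sing) == 0L) {
      return(list(untestable = TRUE,
                  n_duplicated = length(dup), n_single = length(sing)))
    }
    bw <- binwidth %||% max(stats::median(sing) / 10, 0.5)
    lim <- max(md$mean_depth) + bw
    breaks <- seq(0, lim, by = bw)
    if (breaks[length(breaks)] < lim) breaks <- c(breaks, lim)
    list(
      untestable = FALSE,
      depths = md,
      median_duplicated = stats::median(dup),
      median_single = stats::median(sing),
      ks = ks_one_sided(dup, sing, method = method, n_perm = n_perm),
      breaks = breaks,
      hist_duplicated = hist(dup, breaks = breaks, plot = FALSE)$counts,
      hist_single = hist(sing, breaks = breaks, plot = FALSE)$counts
    )
  })
  out <- list(results = results, alpha = alpha)
  class(out) <- "dup_artifact_test"
  out
}

#' @export
print.dup_artifact_test <- function(x, ...) {
  cat("Duplication-artifact depth test",
      sprintf("(alpha = %g)\n", x$alpha))
  for (nm in names(x$results)) {
    r <- x$results[[nm]]
    cat(sprintf("-- track '%s':\n", nm))
    if (isTRUE(r$untestable)) {
      cat(sprintf("   untestable: %d duplicated / %d single-copy genes\n",
                  r$n_duplicated, r$n_single))
      next
    }
    cat(sprintf("   median depth: duplicated %.2f, single-copy %.2f (ratio %.2f)\n",
                r$median_duplicated, r$median_single,
                r$median_duplicated / r$median_single))
    cat(sprintf("   KS one-sided: D+ = %.3f, p = %.4g -> %s\n",
                r$ks$D_plus, r$ks$p_value,
                if (r$ks$p_value < x$alpha) {
                  "depth supports true duplication"
                } else {
                  "no depth excess: consistent with haplotype artifacts"
                }))
  }
  invisible(x)
}

#' @export
summary.dup_artifact_test <- function(object, ...) {
  rows <- lapply(names(object$results), function(nm) {
    r <- object$results[[nm]]
    if (isTRUE(r$untestable)) {
      return(data.frame(track = nm, untestable = TRUE,
                        n_duplicated = r$n_duplicated,
                        n_single = r$n_single, median_duplicated = NA_real_,
                        median_single = NA_real_, D_plus = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    }
    data.frame(track = nm, untestable = FALSE,
               n_duplicated = r$ks$n1, n_single = r$ks$n2,
               median_duplicated = r$median_duplicated,
               median_single = r$median_single,
               D_plus = r$ks$D_plus, p_value = r$ks$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' @export
plot.dup_artifact_test <- function(x, track = 1L, ...) {
  r <- x$results[[track]]
  if (isTRUE(r$untestable)) {
    stop("result is untestable; nothing to plot", call. = FALSE)
  }
  mids <- (utils::head(r$breaks, -1) + r$breaks[-1]) / 2
  ylim <- c(0, max(r$hist_single, r$hist_duplicated))
  plot(mids, r$hist_single, type = "s", col = "grey40",
       xlab = "mean mapped depth per gene", ylab = "genes", ylim = ylim,
       ...)
  lines(mids, r$hist_duplicated, type = "s", col = "firebrick")
  abline(v = r$median_single, col = "grey40", lty = 2)
  abline(v = r$median_duplicated, col = "firebrick", lty = 2)
  legend("topright", legend = c("single-copy", "duplicated"),
         col = c("grey40", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}

#' X-vs-autosome depth positive control
#'
#' Power control for the duplication test: compares per-gene mean depths of
#' autosomal versus X-linked marker genes with the same one-sided KS test
#' (autosomal as the putatively greater sample).  In a male sample the X is
#' hemizygous, so depth on X genes is half the autosomal depth and the null
#' should be rejected; in a female sample the two classes have equal copy
#' number and it should not - demonstrating the test can detect a two-fold
#' copy-number shift.
#'
#' @param track A `depth_track`.
#' @param genes A `marker_genes` data frame with `linkage` labels
#'   (`"autosome"`/`"X"`).
#' @param sex `"male"` or `"female"` (the expectation reported alongside).
#' @param method,n_perm Passed to [ks_one_sided()].
#' @return Object of class `xa_control` with the `ks_onesided` result,
#'   per-class medians and the sex-specific expectation.
#' @export
x_autosome_control <- function(track, genes, sex, method = "asymptotic",
                               n_perm = 2000L) {
  sex <- match.arg(sex, c("male", "female"))
  if (!all(genes$linkage %in% c("autosome", "X"))) {
    stop("genes must carry autosome/X linkage labels", call. = FALSE)
  }
  md <- mean_depth_per_gene(track, genes)
  auto <- md$mean_depth[md$linkage == "autosome"]
  xs <- md$mean_depth[md$linkage == "X"]
  if (length(auto) == 0L || length(xs) == 0L) {
    stop("both autosomal and X gene classes must be non-empty",
         call. = FALSE)
  }
  out <- list(
    ks = ks_one_sided(auto, xs, method = method, n_perm = n_perm),
    sex = sex,
    median_autosome = stats::median(auto),
    median_x = stats::median(xs),
    expectation = if (sex == "male") "reject (X at half depth)" else
      "no rejection (equal copy number)")
  class(out) <- "xa_control"
  out
}

#' @export
print.xa_control <- function(x, ...) {
  cat(sprintf("X-vs-autosome depth control (%s sample)\n", x$sex))
  cat(sprintf("  median depth: autosome %.2f, X %.2f\n", x$median_autosome,
              x$median_x))
  cat(sprintf("  KS one-sided (autosome greater): D+ = %.3f, p = %.4g\n",
              x$ks$D_plus, x$ks$p_value))
  cat(sprintf("  expectation: %s\n", x$expectation))
  invisible(x)
}
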