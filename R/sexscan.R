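#' Normalized male/female depth ratio per scaffold
#'
#' Computes windowed depth means for a male and a female track on the same
#' assembly, normalizes each sample, and reports the per-scaffold ratio
#' `R = (male mean / male normalizer) / (female mean / female normalizer)`.
#' X-linked scaffolds, hemizygous in males, are expected at R ~ 0.5;
#' autosomes at R ~ 1.
#'
#' Normalization modes:
#' * `"autosomal_median"` (default): each sample is scaled by the median of
#'   its retained window means; with autosomes dominating the assembly this
#'   is the autosomal depth level, and it is robust to unequal sequencing
#'   input.
#' * `"total_bases"`: each sample is scaled by its genome-wide mean depth,
#'   reproducing the logic of subsampling both read sets to equal input
#'   bases before mapping.
#'
#' @param male,female `depth_track` objects on the same assembly.
#' @param window Window width, bp (default 100 kb); terminal windows are
#'   dropped (see [windowed_depth()]).
#' @param normalization `"autosomal_median"` or `"total_bases"`.
#' @param min_windows Minimum retained windows for a scaffold to be
#'   classifiable (default 3; shorter scaffolds are reported but left
#'   unclassified by [classify_scaffolds()]).
#' @return Object of class `scaffold_ratio_set`: data frame with `scaffold`,
#'   `n_windows`, `male_mean`, `female_mean`, `ratio`.
#' @export
scaffold_ratio <- function(male, female, window = 1e5,
                           normalization = c("autosomal_median",
                                             "total_bases"),
                           min_windows = 3L) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(male, "depth_track"), inherits(female, "depth_track"))
  if (!identical(sort(names(male$depth)), sort(names(female$depth)))) {
    stop("male and female tracks must cover the same assembly",
         call. = FALSE)
  }
  wm <- windowed_depth(male, window, drop_terminal = TRUE)
  wf <- windowed_depth(female, window, drop_terminal = TRUE)
  norm_of <- function(track, w) {
    if (normalization == "autosomal_median") {
      stats::median(w$mean_depth)
    } else {
      sum(vapply(track$depth, function(d) sum(as.numeric(d)), numeric(1))) /
        sum(lengths(track$depth))
    }
  }
  nm <- norm_of(male, wm)
  nf <- norm_of(female, wf)
  out <- lapply(names(male$depth), function(sc) {
    m <- wm$mean_depth[wm$scaffold == sc]
    f <- wf$mean_depth[wf$scaffold == sc]
    mmean <- if (length(m)) mean(m) else NA_real_
    fmean <- if (length(f)) mean(f) else NA_real_
    ratio <- if (!is.na(mmean) && !is.na(fmean) && fmean > 0 && nf > 0) {
      (mmean / nm) / (fmean / nf)
    } else {
      NA_real_
    }
    data.frame(scaffold = sc, n_windows = min(length(m), length(f)),
               male_mean = mmean, female_mean = fmean, ratio = ratio,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(out, "normalization") <- normalization
  attr(out, "window") <- window
  attr(out, "min_windows") <- min_windows
  class(out) <- c("scaffold_ratio_set", "data.frame")
  out
}

#' Classify scaffolds from male/female depth ratios
#'
#' Scaffolds whose ratio falls inside `x_band` are called `X_linked`, inside
#' `autosome_band` `autosomal`, otherwise (or with too few windows, or an
#' undefined ratio) `unclassified`.  Default bands put "~0.5" at
#' `[0.35, 0.65]` and "~1" at `[0.8, 1.2]`.
#'
#' @param ratios A `scaffold_ratio_set`.
#' @param x_band,autosome_band Numeric `c(lo, hi)` intervals; must be
#'   disjoint.
#' @return The input with a `call` column
#'   (`X_linked`/`autosomal`/`unclassified`).
#' @export
classify_scaffolds <- function(ratios, x_band = c(0.35, 0.65),
                               autosome_band = c(0.8, 1.2)) {
  stopifnot(length(x_band) == 2L, length(autosome_band) == 2L)
  if (max(min(x_band[2], autosome_band[2]) -
          max(x_band[1], autosome_band[1]), 0) > 0) {
    stop("classification bands must be disjoint", call. = FALSE)
  }
  min_windows <- attr(ratios, "min_windows") %||% 3L
  r <- ratios$ratio
  call <- rep("unclassified", nrow(ratios))
  ok <- !is.na(r) & ratios$n_windows >= min_windows
  call[ok & r >= x_band[1] & r <= x_band[2]] <- "X_linked"
  call[ok & r >= autosome_band[1] & r <= autosome_band[2]] <- "autosomal"
  ratios$call <- call
  ratios
}

#' @export
print.scaffold_ratio_set <- function(x, ...) {
  cat(sprintf("Male/female depth ratios (%s normalization, %s bp windows)\n",
              attr(x, "normalization") %||% "?",
              format(attr(x, "window") %||% NA, big.mark = ",")))
  print.data.frame(as.data.frame(x), digits = 3)
  invisible(x)
}

#' @export
plot.scaffold_ratio_set <- function(x, ...) {
  plot(seq_len(nrow(x)), x$ratio, pch = 16, xaxt = "n",
       xlab = "", ylab = "male/female depth ratio",
       ylim = range(c(0, 1.3, x$ratio), na.rm = TRUE), ...)
  axis(1, at = seq_len(nrow(x)), labels = x$scaffold, las = 2,
       cex.axis = 0.7)
  abline(h = c(0.5, 1), lty = 2, col = c("firebrick", "grey40"))
  invisible(x)
}
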