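# Internal helpers shared across modules.  Coordinates are 0-based half-open
# everywhere inside the package; conversion to 1-based happens only at I/O
# boundaries (FASTA/FASTQ are coordinate-free, BED is already 0-based,
# VCF/GTF/BUSCO tables are 1-based).

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded operations are reproducible without disturbing an
#' enclosing simulation.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# TRUE for each pos (0-based) lying inside one of the sorted, non-overlapping
# intervals [starts, ends).
.in_intervals <- function(pos, starts, ends) {
  if (length(starts) == 0L) return(rep(FALSE, length(pos)))
  i <- findInterval(pos, starts)
  ok <- i >= 1L
  ok[ok] <- pos[ok] < ends[i[ok]]
  ok
}

# Merge possibly-overlapping intervals (0-based half-open) into a sorted
# disjoint set.
.merge_intervals <- function(start, end) {
  if (length(start) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  o <- order(start, end)
  start <- start[o]
  end <- end[o]
  ms <- start[1]
  me <- end[1]
  out_s <- integer(0)
  out_e <- integer(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms)
      out_e <- c(out_e, me)
      ms <- start[i]
      me <- end[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

# Complement of sorted disjoint intervals within [0, len).
.complement_intervals <- function(start, end, len) {
  if (length(start) == 0L) return(data.frame(start = 0L, end = len))
  s <- c(0L, end)
  e <- c(start, len)
  keep <- s < e
  data.frame(start = s[keep], end = e[keep])
}

# Depth vector over [0, len) from read intervals [starts, ends) (0-based).
.depth_from_intervals <- function(starts, ends, len) {
  if (length(starts) == 0L) return(integer(len))
  starts <- pmax(starts, 0L)
  ends <- pmin(ends, len)
  keep <- ends > starts
  starts <- starts[keep]
  ends <- ends[keep]
  if (length(starts) == 0L) return(integer(len))
  inc <- tabulate(starts + 1L, nbins = len)
  dec <- tabulate(ends[ends < len] + 1L, nbins = len)
  cumsum(inc - dec)
}

# rbind a list of data frames, tolerating NULL elements; returns `empty`
# when nothing is left
.rbind_df <- function(lst, empty) {
  lst <- lst[!vapply(lst, is.null, logical(1))]
  if (length(lst) == 0L) return(empty)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}

.base_int <- c(A = 65L, C = 67L, G = 71L, T = 84L)

# Map an A/C/G/T string to integer codes 1..4 (NA otherwise).
.seq_codes <- function(seq) {
  lut <- rep(NA_integer_, 128L)
  lut[.base_int + 1L] <- 1:4
  lut[utf8ToInt(seq) + 1L]
}

.stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
}
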