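# Read simulation.  Fragments are drawn uniformly from the haplotype copies
# present in the individual: autosomes contribute both haplotypes in both
# sexes, X scaffolds contribute both haplotypes in females but only
# haplotype 1 in males (hemizygosity).  The pair count is chosen so that the
# expected mapped depth on autosomes equals `coverage`; X depth in males is
# then coverage/2 by construction.

# table of haplotype copies present in one individual
.haplotype_copies <- function(genome, sex) {
  sex <- match.arg(sex, c("male", "female"))
  sc <- genome$scaffolds
  cp <- rbind(
    data.frame(scaffold = sc, hap = 1L,
               len = unname(genome$hap1_length[sc]),
               stringsAsFactors = FALSE),
    data.frame(scaffold = sc, hap = 2L,
               len = unname(genome$hap2_length[sc]),
               stringsAsFactors = FALSE)
  )
  if (sex == "male") {
    cp <- cp[!(cp$hap == 2L & genome$sex_linkage[cp$scaffold] == "X"), ,
             drop = FALSE]
  }
  rownames(cp) <- NULL
  cp
}

#' Sample paired-end fragment placements
#'
#' The sequence-free core of [simulate_reads()]: samples fragment positions
#' (and therefore the truth placements of both mates) without rendering read
#' sequences.  Depth-only analyses (the replicate calibration drivers) use
#' these placements directly via [truth_depth_track()].
#'
#' @param genome A `diploid_genome`.
#' @param sex `"male"` or `"female"`; males carry a single X copy.
#' @param config A [sim_config()].
#' @param seed Seed; defaults to `config$seed`.
#' @return Object of class `read_placements`: data frame with one row per
#'   pair (`scaffold`, `hap`, `r1_start`, `r2_start`, `insert`; starts are
#'   0-based on the source haplotype, mate 1 forward, mate 2 reverse), with
#'   attributes `sex`, `read_length`.
#' @export
simulate_placements <- function(genome, sex, config = genome$config,
                                seed = config$seed) {
  stopifnot(inherits(genome, "diploid_genome"))
  sex <- match.arg(sex, c("male", "female"))
  L <- config$read_length
  if (config$insert_mean < L) {
    stop("insert_mean must be >= read_length", call. = FALSE)
  }
  cp <- .haplotype_copies(genome, sex)
  if (any(cp$len < L)) stop("scaffold shorter than one read", call. = FALSE)
  D <- sum(as.numeric(cp$len))
  n_pairs <- round(config$coverage * D / (4 * L))
  with_seed(seed, {
    ci <- sample.int(nrow(cp), n_pairs, replace = TRUE, prob = cp$len)
    ins <- round(rnorm(n_pairs, config$insert_mean, config$insert_sd))
    ins <- pmax(ins, L)
    ins <- pmin(ins, cp$len[ci])
    start <- floor(runif(n_pairs) * (cp$len[ci] - ins + 1))
    out <- data.frame(scaffold = cp$scaffold[ci], hap = cp$hap[ci],
                      r1_start = as.integer(start),
                      r2_start = as.integer(start + ins - L),
                      insert = as.integer(ins), stringsAsFactors = FALSE)
    attr(out, "sex") <- sex
    attr(out, "read_length") <- L
    class(out) <- c("read_placements", "data.frame")
    out
  })
}

#' Simulate a sexed paired-end read set
#'
#' Renders read sequences for sampled fragment placements: mate 1 is the
#' forward strand at the fragment start, mate 2 the reverse complement at the
#' fragment end, each `read_length` bp, with per-base substitution errors at
#' `error_rate`.  Base qualities are constant Q30 (the diagnostics never use
#' them).
#'
#' @inheritParams simulate_placements
#' @return Object of class `read_set`: list with `id`, `r1`, `r2` (character
#'   vectors), `placements` (the truth table), `sex`, `config`.
#' @examples
#' g <- simulate_genome(sim_config(n_autosomes = 1, n_x_scaffolds = 0,
#'                                 scaffold_length = 2e4, coverage = 5))
#' rs <- simulate_reads(g, "female")
#' length(rs$r1)
#' @export
simulate_reads <- function(genome, sex, config = genome$config,
                           seed = config$seed) {
  stopifnot(inherits(genome, "diploid_genome"))
  if (is.null(genome$hap2)) {
    stop("read simulation requires haplotype 2 sequences", call. = FALSE)
  }
  pl <- simulate_placements(genome, sex, config, seed = seed)
  L <- config$read_length
  pool_idx <- ifelse(pl$hap == 1L, match(pl$scaffold, genome$scaffolds),
                     length(genome$scaffolds) +
                       match(pl$scaffold, genome$scaffolds))
  pool <- c(unname(genome$hap1), unname(genome$hap2))
  src <- pool[pool_idx]
  r1 <- substring(src, pl$r1_start + 1L, pl$r1_start + L)
  r2 <- .revcomp_cpp(substring(src, pl$r2_start + 1L, pl$r2_start + L))
  if (config$error_rate > 0) {
    with_seed(seed + 7L, {
      r1 <- .add_errors_cpp(r1, config$error_rate)
      r2 <- .add_errors_cpp(r2, config$error_rate)
    })
  }
  out <- list(id = sprintf("read%07d", seq_len(nrow(pl))), r1 = r1, r2 = r2,
              placements = pl, sex = attr(pl, "sex"), config = config)
  class(out) <- "read_set"
  out
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("Read set (%s): %s pairs x %d bp\n", x$sex,
              format(length(x$r1), big.mark = ","), x$config$read_length))
  invisible(x)
}

#' Truth placements in long (per-mate) form
#'
#' @param reads A `read_set` or `read_placements`.
#' @return Data frame with one row per mate: `read` (id with `/1`,`/2`
#'   suffix), `scaffold`, `hap`, `start` (0-based on the source haplotype),
#'   `strand`.
#' @export
truth_placements <- function(reads) {
  pl <- if (inherits(reads, "read_set")) reads$placements else reads
  ids <- if (inherits(reads, "read_set")) reads$id else
    sprintf("read%07d", seq_len(nrow(pl)))
  data.frame(
    read = c(paste0(ids, "/1"), paste0(ids, "/2")),
    scaffold = rep(pl$scaffold, 2L),
    hap = rep(pl$hap, 2L),
    start = c(pl$r1_start, pl$r2_start),
    strand = rep(c("+", "-"), each = nrow(pl)),
    stringsAsFactors = FALSE
  )
}

#' Write a read set as paired FASTQ
#'
#' @param reads A `read_set`.
#' @param prefix Output prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` with `/1`,`/2` read-name suffixes and constant Q30
#'   qualities.
#' @return The two paths, invisibly.
#' @export
write_fastq <- function(reads, prefix) {
  stopifnot(inherits(reads, "read_set"))
  qual <- strrep("?", reads$config$read_length)
  p1 <- paste0(prefix, "_1.fastq")
  p2 <- paste0(prefix, "_2.fastq")
  writeLines(rbind(paste0("@", reads$id, "/1"), reads$r1, "+", qual), p1)
  writeLines(rbind(paste0("@", reads$id, "/2"), reads$r2, "+", qual), p2)
  invisible(c(p1, p2))
}
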