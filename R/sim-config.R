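#' Simulation configuration
#'
#' Parameters of the bundled diploid genome / read simulator.  Defaults
#' emulate the sequencing design the depth diagnostics assume: an inbred
#' diploid insect genome whose two haplotypes differ by well under 0.4% per
#' base (mostly SNVs, with a minority of short indels), 150 bp paired-end
#' reads at 30x genome-wide coverage, and hemizygous X scaffolds in males.
#'
#' @param n_autosomes Number of autosomal scaffolds.
#' @param n_x_scaffolds Number of X-linked scaffolds (hemizygous in males).
#' @param scaffold_length Length of every scaffold, bp.
#' @param snv_rate Heterozygous SNVs per bp outside homozygous blocks.
#' @param indel_rate Short heterozygous indels (1-10 bp) per bp outside
#'   homozygous blocks.
#' @param homozygous_block_fraction Fraction of each scaffold rendered
#'   identical between haplotypes (one contiguous block per scaffold),
#'   emulating runs of homozygosity from inbreeding.
#' @param unphased_fraction Fraction of heterozygous segments left
#'   heterozygous-but-unphased in the phase-block layout.
#' @param artifact_fraction Fraction of marker loci duplicated as haplotype
#'   artifacts in the artifact assembly rendering.
#' @param true_dup_fraction Fraction of marker loci truly duplicated in both
#'   haplotypes.
#' @param coverage Mean mapped depth on autosomes (per diploid individual).
#' @param read_length Read length, bp (>= 31 so the default placer seed fits).
#' @param insert_mean,insert_sd Fragment-size distribution, bp.
#' @param error_rate Per-base substitution error probability.
#' @param gc_content GC fraction of the simulated ancestor sequence.
#' @param seed Integer seed; all simulator operations are reproducible given
#'   the configuration.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_autosomes = 1, scaffold_length = 5e4, coverage = 10)
#' cfg
#' @export
sim_config <- function(n_autosomes = 5L,
                       n_x_scaffolds = 2L,
                       scaffold_length = 1e6,
                       snv_rate = 0.004,
                       indel_rate = 4e-4,
                       homozygous_block_fraction = 0,
                       unphased_fraction = 0.2,
                       artifact_fraction = 0.3,
                       true_dup_fraction = 0,
                       coverage = 30,
                       read_length = 150L,
                       insert_mean = 350,
                       insert_sd = 50,
                       error_rate = 0.001,
                       gc_content = 0.3221,
                       seed = 1L) {
  cfg <- list(
    n_autosomes = as.integer(n_autosomes),
    n_x_scaffolds = as.integer(n_x_scaffolds),
    scaffold_length = as.integer(scaffold_length),
    snv_rate = snv_rate,
    indel_rate = indel_rate,
    homozygous_block_fraction = homozygous_block_fraction,
    unphased_fraction = unphased_fraction,
    artifact_fraction = artifact_fraction,
    true_dup_fraction = true_dup_fraction,
    coverage = coverage,
    read_length = as.integer(read_length),
    insert_mean = insert_mean,
    insert_sd = insert_sd,
    error_rate = error_rate,
    gc_content = gc_content,
    seed = as.integer(seed)
  )
  for (nm in c("snv_rate", "indel_rate", "homozygous_block_fraction",
               "unphased_fraction", "artifact_fraction", "true_dup_fraction",
               "error_rate")) {
    v <- cfg[[nm]]
    .stopifnot_scalar_number(v, nm)
    if (v < 0 || v > 1) {
      stop(sprintf("`%s` must be in [0, 1]", nm), call. = FALSE)
    }
  }
  if (cfg$artifact_fraction + cfg$true_dup_fraction > 1) {
    stop("artifact_fraction + true_dup_fraction must be <= 1", call. = FALSE)
  }
  if (cfg$n_autosomes < 1L) stop("need at least one autosome", call. = FALSE)
  if (cfg$n_x_scaffolds < 0L) stop("n_x_scaffolds must be >= 0", call. = FALSE)
  if (cfg$scaffold_length <= 0L) {
    stop("scaffold_length must be positive", call. = FALSE)
  }
  if (cfg$coverage <= 0) stop("coverage must be > 0", call. = FALSE)
  if (cfg$read_length < 31L) stop("read_length must be >= 31", call. = FALSE)
  if (cfg$insert_mean < cfg$read_length) {
    stop("insert_mean must be >= read_length", call. = FALSE)
  }
  if (cfg$gc_content <= 0 || cfg$gc_content >= 1) {
    stop("gc_content must be in (0, 1)", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Diploid simulation configuration\n")
  cat(sprintf("  scaffolds: %d autosomes + %d X, %s bp each\n",
              x$n_autosomes, x$n_x_scaffolds,
              format(x$scaffold_length, big.mark = ",")))
  cat(sprintf("  heterozygosity: %.4g SNV/bp, %.4g indel/bp, %.0f%% homozygous block\n",
              x$snv_rate, x$indel_rate, 100 * x$homozygous_block_fraction))
  cat(sprintf("  reads: %dx coverage, %d bp pairs, insert %.0f+/-%.0f, error %.4g\n",
              round(x$coverage), x$read_length, x$insert_mean, x$insert_sd,
              x$error_rate))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
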