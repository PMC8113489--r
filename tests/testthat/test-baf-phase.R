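# SNV calling thresholds, B-allele frequencies, VCF round trips and
# phase-block concordance.

# pileup over one short scaffold with chosen per-site ref/alt counts
pileup_from_counts <- function(ref, site_counts) {
  L <- nchar(ref)
  m <- matrix(0L, 8L, L)
  codes <- haplodepth:::.seq_codes(ref)
  for (i in seq_len(nrow(site_counts))) {
    p <- site_counts$pos[i] + 1L
    rc <- codes[p]
    ac <- match(site_counts$alt[i], c("A", "C", "G", "T"))
    m[rc, p] <- site_counts$ref_fwd[i]
    m[rc + 4L, p] <- site_counts$ref_rev[i]
    m[ac, p] <- site_counts$alt_fwd[i]
    m[ac + 4L, p] <- site_counts$alt_rev[i]
  }
  manual_pileup(list(s1 = m), c(s1 = ref))
}

test_that("the threshold caller applies depth and fraction cutoffs", {
  ref <- strrep("A", 50L)
  sites <- data.frame(
    pos = c(5L, 10L, 15L, 20L),
    alt = c("C", "G", "T", "C"),
    ref_fwd = c(5L, 10L, 4L, 20L),
    ref_rev = c(5L, 10L, 4L, 20L),
    alt_fwd = c(5L, 0L, 1L, 4L),
    alt_rev = c(5L, 0L, 0L, 4L))
  pu <- pileup_from_counts(ref, sites)
  calls <- call_snvs(pu, min_depth = 10L, min_alt_fraction = 0.2)
  # pos 5: DP4 = (5,5,5,5) -> called with BAF 0.5
  # pos 10: zero alt -> not called; pos 15: depth 9 -> not called
  # pos 20: alt fraction 8/48 = 0.167 -> not called
  expect_equal(calls$pos, 5L)
  expect_equal(calls$baf, 0.5)
  expect_equal(c(calls$ref_fwd, calls$ref_rev, calls$alt_fwd,
                 calls$alt_rev), c(5L, 5L, 5L, 5L))
  expect_error(call_snvs(pu, min_depth = 0), "positive")
})

test_that("BAF arithmetic matches the DP4 definition", {
  expect_equal(compute_baf(c(5, 5, 5, 5)), 0.5)
  expect_equal(compute_baf(c(2, 3, 7, 8)), 0.75)
  expect_error(compute_baf(c(0, 0, 0, 0)), "zero")
})

test_that("VCF round trip preserves calls and BAF exactly", {
  set.seed(8)
  calls <- data.frame(
    scaffold = rep(c("s1", "s2"), c(6L, 4L)),
    pos = c(sort(sample.int(1000L, 6L)), sort(sample.int(1000L, 4L))),
    ref = sample(c("A", "C", "G", "T"), 10L, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), 10L, replace = TRUE),
    ref_fwd = rpois(10L, 8L), ref_rev = rpois(10L, 8L),
    alt_fwd = rpois(10L, 8L), alt_rev = 1L + rpois(10L, 7L),
    stringsAsFactors = FALSE)
  calls$baf <- compute_baf(calls)
  class(calls) <- c("variant_calls", "data.frame")
  path <- tempfile(fileext = ".vcf")
  write_vcf(calls, path, contigs = c(s1 = 2000L, s2 = 2000L))
  back <- read_vcf(path)
  expect_equal(back$pos, calls$pos)
  expect_equal(back$baf, calls$baf)
  expect_equal(back$ref_fwd, calls$ref_fwd)

  skip_if_not_installed("vcfR")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  expect_equal(as.integer(v@fix[, "POS"]), calls$pos + 1L)
  dp4 <- vcfR::extract.info(v, "DP4")
  cnt <- do.call(rbind, lapply(strsplit(dp4, ","), as.integer))
  expect_equal((cnt[, 3] + cnt[, 4]) / rowSums(cnt), calls$baf)
})

test_that("phase concordance reports densities, runs and flags", {
  sl <- c(s1 = 1e5, s2 = 1e5)
  blocks <- data.frame(scaffold = "s1",
                       start = c(0L, 60000L), end = c(40000L, 100000L))
  mk_calls <- function(scaffold, pos) {
    data.frame(scaffold = scaffold, pos = pos, ref = "A", alt = "C",
               ref_fwd = 10L, ref_rev = 10L, alt_fwd = 10L, alt_rev = 10L,
               baf = 0.5, stringsAsFactors = FALSE)
  }

  # an empty scaffold gets density 0 and the low-heterozygosity flag
  rep0 <- phase_concordance(mk_calls("s1", seq(1000L, 39000L, by = 500L)),
                            blocks, sl)
  s2row <- rep0$summary[rep0$summary$scaffold == "s2", ]
  expect_equal(s2row$n_snv, 0L)
  expect_true(s2row$low_heterozygosity)
  expect_false(rep0$summary$low_heterozygosity[1])
  # all variants inside blocks: no unphased-het intervals
  expect_equal(nrow(rep0$unphased_het), 0L)
  expect_equal(rep0$summary$frac_snv_phased[1], 1)

  # a deliberate unphased heterozygous segment is recovered within one SNV
  inside <- seq(1000L, 39000L, by = 1000L)
  gap <- seq(42000L, 58000L, by = 1000L)   # 17 SNVs in the unphased gap
  rep1 <- phase_concordance(mk_calls("s1", c(inside, gap)), blocks, sl)
  expect_equal(nrow(rep1$unphased_het), 1L)
  expect_equal(rep1$unphased_het$start, 42000L)
  expect_equal(rep1$unphased_het$end, 58001L)
  expect_equal(rep1$unphased_het$n_snv, 17L)

  # short or sparse outside-block runs are not reported
  rep2 <- phase_concordance(mk_calls("s1", c(inside, c(45000L, 45100L))),
                            blocks, sl)
  expect_equal(nrow(rep2$unphased_het), 0L)

  expect_error(phase_concordance(mk_calls("s1", 1L),
                                 data.frame(scaffold = "zz", start = 0L,
                                            end = 10L), sl), "unknown")
})

test_that("female X scaffolds are heterozygous while homozygous blocks are flagged", {
  cfg <- sim_config(n_autosomes = 1L, n_x_scaffolds = 1L,
                    scaffold_length = 1e5, seed = 41L)
  g <- simulate_genome(cfg)
  # pretend-calls at the truth heterozygous sites (the female diploid view)
  tv <- truth_variants(g, "SNV")
  calls <- data.frame(scaffold = tv$scaffold, pos = tv$pos, ref = tv$ref,
                      alt = tv$alt, ref_fwd = 8L, ref_rev = 8L,
                      alt_fwd = 8L, alt_rev = 8L, baf = 0.5,
                      stringsAsFactors = FALSE)
  rep <- phase_concordance(calls, phased_blocks(g), g$hap1_length)
  # X scaffolds in a female are as heterozygous as autosomes: not flagged
  expect_false(any(rep$summary$low_heterozygosity))

  # a strongly inbred (homozygous-block) scaffold is flagged
  cfg_hom <- sim_config(n_autosomes = 1L, n_x_scaffolds = 0L,
                        scaffold_length = 1e5,
                        homozygous_block_fraction = 0.995, seed = 42L)
  g_hom <- simulate_genome(cfg_hom)
  tv_h <- truth_variants(g_hom, "SNV")
  calls_h <- calls[0, ]
  if (nrow(tv_h)) {
    calls_h <- data.frame(scaffold = tv_h$scaffold, pos = tv_h$pos,
                          ref = tv_h$ref, alt = tv_h$alt, ref_fwd = 8L,
                          ref_rev = 8L, alt_fwd = 8L, alt_rev = 8L,
                          baf = 0.5, stringsAsFactors = FALSE)
  }
  rep_h <- phase_concordance(calls_h, phased_blocks(g_hom),
                             g_hom$hap1_length)
  expect_true(all(rep_h$summary$low_heterozygosity))
})
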