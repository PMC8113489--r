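# The diploid simulator: ancestor composition, haplotype divergence truth
# tables, assembly renderings and read sets.

test_that("ancestor sequences hit the GC target and are seed-deterministic", {
  s <- generate_ancestor(1e5, gc_content = 0.3221, seed = 1)
  gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / nchar(s)
  expect_lt(abs(gc - 0.3221), 0.01)

  s2 <- generate_ancestor(1e4, gc_content = 0.5, seed = 3)
  gc_count <- sum(strsplit(s2, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc_count - 5000), 3 * sqrt(1e4 * 0.25))

  expect_identical(generate_ancestor(500, 0.5, seed = 7),
                   generate_ancestor(500, 0.5, seed = 7))
  expect_error(generate_ancestor(0, 0.5, 1), "positive")
  expect_error(generate_ancestor(100, 1, 1), "gc_content")
})

test_that("realized SNV density matches the configured rate", {
  for (rate in c(0.001, 0.004, 0.01)) {
    cfg <- sim_config(n_autosomes = 1L, n_x_scaffolds = 0L,
                      scaffold_length = 3e5, snv_rate = rate,
                      indel_rate = 0, seed = 101L)
    g <- simulate_genome(cfg)
    n_elig <- 3e5 - 12  # end margin excluded from edit placement
    expected <- n_elig * rate
    sd3 <- 3 * sqrt(n_elig * rate * (1 - rate))
    expect_lt(abs(nrow(truth_variants(g, "SNV")) - expected), sd3)
  }
})

test_that("zero divergence yields identical haplotypes and empty truth", {
  cfg <- tiny_config(snv_rate = 0, indel_rate = 0)
  g <- simulate_genome(cfg)
  expect_identical(g$hap1, g$hap2)
  expect_equal(nrow(truth_variants(g)), 0L)
})

test_that("homozygous blocks carry no variants and identical sequence", {
  cfg <- sim_config(n_autosomes = 1L, n_x_scaffolds = 0L,
                    scaffold_length = 1e5, homozygous_block_fraction = 0.5,
                    seed = 5L)
  g <- simulate_genome(cfg)
  hb <- g$hom_blocks
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$end - hb$start, 5e4)
  tv <- truth_variants(g)
  expect_false(any(tv$pos >= hb$start & tv$pos < hb$end))
  # block sequence identical between haplotypes (modulo indel offsets)
  tab <- g$offsets[[hb$scaffold]]
  s2 <- haplodepth:::.lift_hap1_to_hap2(hb$start, tab)
  expect_identical(substring(g$hap1[[hb$scaffold]], hb$start + 1, hb$end),
                   substring(g$hap2[[hb$scaffold]], s2 + 1,
                             s2 + (hb$end - hb$start)))
})

test_that("haplotype-2 reconstruction and coordinate lift are consistent", {
  cfg <- sim_config(n_autosomes = 1L, n_x_scaffolds = 0L,
                    scaffold_length = 8e4, snv_rate = 0.004,
                    indel_rate = 0.001, seed = 9L)
  g <- simulate_genome(cfg)
  sc <- g$scaffolds[1]
  tab <- g$offsets[[sc]]
  expect_equal(nchar(g$hap2[[sc]]), unname(g$hap2_length[[sc]]))
  tv <- truth_variants(g)
  # at each truth SNV the lifted hap2 base equals the alt allele
  snv <- tv[tv$type == "SNV", ]
  p2 <- haplodepth:::.lift_hap1_to_hap2(snv$pos, tab)
  expect_identical(substring(g$hap2[[sc]], p2 + 1, p2 + 1), snv$alt)
  # positions far from any edit round-trip through both lifts
  pos <- setdiff(seq(0, 8e4 - 1, by = 997L),
                 unlist(lapply(tv$pos, function(p) (p - 12):(p + 12))))
  fwd <- haplodepth:::.lift_hap1_to_hap2(pos, tab)
  expect_equal(haplodepth:::.lift_hap2_to_hap1(fwd, tab), pos)
})

test_that("phase blocks tile the heterozygous portion of each scaffold", {
  cfg <- sim_config(n_autosomes = 2L, n_x_scaffolds = 0L,
                    scaffold_length = 4e5, homozygous_block_fraction = 0.3,
                    unphased_fraction = 0.3, seed = 21L)
  g <- simulate_genome(cfg)
  pb <- g$phase_blocks
  hb <- g$hom_blocks
  for (sc in g$scaffolds) {
    p <- pb[pb$scaffold == sc, ]
    h <- hb[hb$scaffold == sc, ]
    # phased blocks never intersect the homozygous block
    expect_false(any(p$start[p$phased] < h$end & p$end[p$phased] > h$start))
    # block chunks cover exactly the heterozygous complement
    expect_equal(sum(p$end - p$start), 4e5 - sum(h$end - h$start))
  }
  expect_true(any(!pb$phased))
})

test_that("artifact rendering duplicates the right loci with exact bookkeeping", {
  cfg <- tiny_config(artifact_fraction = 0.3)
  g <- simulate_genome(cfg)
  genes <- place_marker_genes(g, n_autosomal = 20L, gene_length = 1500L)
  rend <- render_assemblies(g, genes)
  expect_identical(rend$collapsed$sequences, g$hap1)
  lab <- rend$artifact$duplication_truth
  expect_equal(sum(lab$label == "haplotype_artifact"), 6L)  # round(0.3*20)
  extra <- setdiff(names(rend$artifact$sequences),
                   names(rend$collapsed$sequences))
  expect_equal(sort(extra),
               sort(paste0(lab$gene_id[lab$label == "haplotype_artifact"],
                           "_hap2")))
  # conservation: added length equals the summed appended copies exactly
  expect_equal(sum(nchar(rend$artifact$sequences)) -
                 sum(nchar(rend$collapsed$sequences)),
               sum(nchar(rend$artifact$sequences[extra])))

  cfg0 <- tiny_config(artifact_fraction = 0)
  g0 <- simulate_genome(cfg0)
  rend0 <- render_assemblies(g0, genes)
  expect_identical(rend0$artifact$sequences, rend0$collapsed$sequences)

  expect_error(render_assemblies(g, genes[0, ], cfg), "marker loci")
})

test_that("true duplication doubles loci in both haplotypes", {
  cfg <- tiny_config(indel_rate = 0.001)
  g <- simulate_genome(cfg)
  expect_identical(apply_true_duplication(g, NULL), g)

  loc <- data.frame(scaffold = g$scaffolds[1], start = 10000L, end = 12000L)
  g2 <- apply_true_duplication(g, loc)
  expect_equal(unname(g2$hap1_length[1] - g$hap1_length[1]), 2000L)
  # the two tandem copies are identical in haplotype 1
  expect_identical(substring(g2$hap1[[1]], 10001, 12000),
                   substring(g2$hap1[[1]], 12001, 14000))
  # haplotype 2 grows by the lifted copy length and stays reconstructable
  expect_equal(nchar(g2$hap2[[1]]), unname(g2$hap2_length[[1]]))
  expect_gt(g2$hap2_length[[1]], g$hap2_length[[1]])

  overlapping <- data.frame(scaffold = g$scaffolds[1],
                            start = c(100L, 500L), end = c(600L, 900L))
  expect_error(apply_true_duplication(g, overlapping), "non-overlapping")
})

test_that("read sets honour coverage, hemizygosity and error-free identity", {
  cfg <- sim_config(n_autosomes = 1L, n_x_scaffolds = 1L,
                    scaffold_length = 6e4, coverage = 25, error_rate = 0,
                    seed = 31L)
  g <- simulate_genome(cfg)
  rs_f <- simulate_reads(g, "female")
  rs_m <- simulate_reads(g, "male", seed = 32L)

  # male read sets never sample the absent X haplotype copy
  pm <- rs_m$placements
  expect_false(any(pm$hap == 2L & g$sex_linkage[pm$scaffold] == "X"))

  # truth-placement depth: autosomes at coverage in both sexes, X at half
  # in the male
  tr_f <- truth_depth_track(rs_f, g)
  tr_m <- truth_depth_track(rs_m, g)
  expect_lt(abs(mean(tr_f$depth$autosome1) - 25), 2.5)
  expect_lt(abs(mean(tr_f$depth$chrX_1) - 25), 2.5)
  expect_lt(abs(mean(tr_m$depth$autosome1) - 25), 2.5)
  expect_lt(abs(mean(tr_m$depth$chrX_1) - 12.5), 2)

  # error-free reads are exact substrings of their source haplotype
  pl <- rs_f$placements
  idx <- sample.int(nrow(pl), 50)
  src <- ifelse(pl$hap == 1L, g$hap1[pl$scaffold], g$hap2[pl$scaffold])
  expect_identical(rs_f$r1[idx],
                   substring(src[idx], pl$r1_start[idx] + 1,
                             pl$r1_start[idx] + cfg$read_length))
  rc <- haplodepth:::.revcomp_cpp(rs_f$r2[idx])
  expect_identical(rc, substring(src[idx], pl$r2_start[idx] + 1,
                                 pl$r2_start[idx] + cfg$read_length))
})

test_that("simulator output is bit-reproducible and writers round-trip", {
  cfg <- tiny_config()
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1$hap2, g2$hap2)
  expect_identical(truth_variants(g1), truth_variants(g2))
  rs1 <- simulate_reads(g1, "female")
  rs2 <- simulate_reads(g2, "female")
  expect_identical(rs1$r1, rs2$r1)

  fa <- tempfile(fileext = ".fa")
  write_fasta(g1$hap1, fa)
  expect_identical(read_fasta(fa), g1$hap1)
  expect_true(all(nchar(readLines(fa)[-1]) <= 60))

  bed <- tempfile(fileext = ".bed")
  write_bed(phased_blocks(g1), bed)
  back <- read_bed(bed)
  expect_equal(back$start, phased_blocks(g1)$start)

  fq <- write_fastq(rs1, tempfile())
  l1 <- readLines(fq[1])
  expect_equal(length(l1), 4 * length(rs1$r1))
  expect_match(l1[1], "^@read0000001/1$")
  expect_identical(l1[2], rs1$r1[1])
})
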