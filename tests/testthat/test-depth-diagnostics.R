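# BUSCO table handling, per-gene depth, the one-sided KS test and the
# duplication-artifact / X-control diagnostics.

busco_fixture <- function() {
  c("# BUSCO version is: 4.0.6",
    "# Busco id\tStatus\tSequence\tGene Start\tGene End\tScore\tLength",
    "busco1\tComplete\tscf1\t100\t900\t99.1\t800",
    "busco2\tComplete\tscf1\t2000\t2500\t88.0\t500",
    "busco3\tDuplicated\tscf1\t3000\t3600\t80.0\t600",
    "busco3\tDuplicated\tscf2\t100\t700\t79.0\t600",
    "busco4\tFragmented\tscf2\t900\t1000\t10.0\t100",
    "busco5\tMissing",
    "busco6\tComplete\tscf2\t1500\t2200\t70.0\t700",
    "busco7\tDuplicated\tscf1\t5000\t5400\t60.0\t400",
    "busco7\tDuplicated\tscf1\t6000\t6400\t59.0\t400",
    "busco8\tComplete\tscf2\t3000\t3300\t50.0\t300")
}

test_that("BUSCO full tables parse with the right conventions", {
  path <- tempfile(fileext = ".tsv")
  writeLines(busco_fixture(), path)
  g <- parse_busco_table(path)
  # coordinate convention: 1-based inclusive -> 0-based half-open
  expect_equal(g$start[g$gene_id == "busco1"], 99L)
  expect_equal(g$end[g$gene_id == "busco1"], 900L)
  # duplicated genes keep one row per placement under a single id
  expect_equal(sum(g$gene_id == "busco3"), 2L)
  expect_equal(sum(g$gene_id == "busco7"), 2L)
  # manual tally by status
  expect_equal(as.integer(table(g$status)[c("single_copy", "duplicated",
                                            "fragmented", "missing")]),
               c(4L, 4L, 1L, 1L))
  expect_true(is.na(g$start[g$status == "missing"]))

  bad <- tempfile()
  writeLines("busco1\tWeird\tscf1\t1\t10", bad)
  expect_error(parse_busco_table(bad), "unknown BUSCO status")

  # write/parse round trip on simulated genes
  cfg <- tiny_config()
  genes <- place_marker_genes(simulate_genome(cfg), 10L)
  out <- tempfile()
  write_busco_table(genes, out)
  back <- parse_busco_table(out)
  expect_equal(back$start, genes$start)
  expect_equal(back$end, genes$end)
  expect_equal(back$status, genes$status)
})

test_that("per-gene mean depth averages every base of the interval", {
  tr <- manual_track(list(s1 = rep(10L, 100L)))
  g1 <- data.frame(gene_id = "g1", scaffold = "s1", start = 10L, end = 60L)
  expect_equal(mean_depth_per_gene(tr, g1)$mean_depth, 10)

  tr2 <- manual_track(list(s1 = c(0L, 0L, 10L, 10L)))
  g2 <- data.frame(gene_id = "g", scaffold = "s1", start = 0L, end = 4L)
  expect_equal(mean_depth_per_gene(tr2, g2)$mean_depth, 5)

  expect_error(mean_depth_per_gene(tr, transform(g1, end = start)),
               "zero-length")

  # brute-force oracle on a random track
  set.seed(7)
  d <- sample.int(50L, 500L, replace = TRUE)
  tr3 <- manual_track(list(s1 = d))
  genes <- data.frame(gene_id = sprintf("g%02d", 1:20), scaffold = "s1",
                      start = sample.int(400L, 20L) - 1L)
  genes$end <- genes$start + sample(10:100, 20L, replace = TRUE)
  md <- mean_depth_per_gene(tr3, genes)
  brute <- mapply(function(s, e) mean(d[(s + 1):e]), genes$start, genes$end)
  expect_equal(md$mean_depth, unname(brute))
})

test_that("one-sided KS statistic and p-value follow the stated form", {
  # identical samples
  k0 <- ks_one_sided(c(1, 2, 3), c(1, 2, 3))
  expect_equal(k0$D_plus, 0)
  expect_equal(k0$p_value, 1)

  # full separation: D+ = 1, p = exp(-2 * 1 * 9/6) = exp(-3)
  k1 <- ks_one_sided(c(4, 5, 6), c(1, 2, 3))
  expect_equal(k1$D_plus, 1)
  expect_equal(k1$p_value, exp(-3))

  expect_error(ks_one_sided(numeric(0), 1), "non-empty")

  # brute-force ECDF supremum oracle, exact, n <= 100
  set.seed(11)
  for (i in 1:5) {
    a <- rnorm(sample(5:100, 1))
    b <- rnorm(sample(5:100, 1), mean = runif(1, -1, 1))
    k <- ks_one_sided(a, b)
    expect_equal(k$D_plus, brute_d_plus(a, b))
    # agreement with R's one-sided asymptotic two-sample test
    r <- stats::ks.test(b, a, alternative = "greater", exact = FALSE)
    expect_equal(k$D_plus, unname(r$statistic))
    expect_equal(k$p_value, r$p.value, tolerance = 1e-12)
  }

  # permutation p agrees with the asymptotic one to first order
  set.seed(3)
  a <- rnorm(40, 0.6)
  b <- rnorm(40)
  kp <- ks_one_sided(a, b, method = "permutation", n_perm = 400,
                     seed = 1)
  ka <- ks_one_sided(a, b)
  expect_lt(abs(kp$p_value - ka$p_value), 0.06)
})

test_that("duplication test separates artifact-like and true-duplication depths", {
  set.seed(19)
  # artifact-like: both classes drawn from the same depth distribution
  d_null <- manual_track(list(s1 = rpois(6000L, 30L)))
  genes <- data.frame(gene_id = sprintf("g%03d", 1:60), scaffold = "s1",
                      start = seq(0L, by = 100L, length.out = 60L))
  genes$end <- genes$start + 100L
  genes$status <- rep(c("duplicated", "single_copy"), c(20L, 40L))
  res_null <- duplication_artifact_test(d_null, genes)
  s <- summary(res_null)
  expect_false(s$untestable)
  expect_gt(s$p_value, 0.05)
  expect_lt(abs(s$median_duplicated / s$median_single - 1), 0.1)

  # true-duplication-like: duplicated class at twice the depth
  depth2 <- c(rpois(2000L, 60L), rpois(4000L, 30L))
  d_dup <- manual_track(list(s1 = depth2))
  res_dup <- duplication_artifact_test(d_dup, genes)
  s2 <- summary(res_dup)
  expect_lt(s2$p_value, 1e-6)
  expect_lt(abs(s2$median_duplicated / s2$median_single - 2), 0.15)

  # histogram bookkeeping: counts cover every gene in the test
  r <- res_dup$results[[1]]
  expect_equal(sum(r$hist_duplicated), 20L)
  expect_equal(sum(r$hist_single), 40L)

  # one class empty -> untestable flag, no p-value
  res_empty <- duplication_artifact_test(
    d_null, transform(genes, status = "single_copy"))
  expect_true(res_empty$results[[1]]$untestable)
  expect_true(is.na(summary(res_empty)$p_value))

  # named list of tracks runs the test per filtering
  both <- duplication_artifact_test(list(all = d_null, hq = d_dup), genes)
  expect_equal(names(both$results), c("all", "hq"))
})

test_that("the X-vs-autosome control detects the male two-fold shift", {
  set.seed(23)
  tr <- manual_track(list(a = rpois(4000L, 30L), x = rpois(2000L, 15L)))
  genes <- rbind(
    data.frame(gene_id = sprintf("a%02d", 1:40), scaffold = "a",
               start = seq(0L, by = 100L, length.out = 40L),
               linkage = "autosome"),
    data.frame(gene_id = sprintf("x%02d", 1:20), scaffold = "x",
               start = seq(0L, by = 100L, length.out = 20L),
               linkage = "X"))
  genes$end <- genes$start + 100L
  male <- x_autosome_control(tr, genes, "male")
  expect_lt(male$ks$p_value, 0.05)
  expect_lt(abs(male$median_x / male$median_autosome - 0.5), 0.1)

  tr_f <- manual_track(list(a = rpois(4000L, 30L), x = rpois(2000L, 30L)))
  female <- x_autosome_control(tr_f, genes, "female")
  expect_gt(female$ks$p_value, 0.05)

  expect_error(x_autosome_control(tr, transform(genes, linkage = "unknown"),
                                  "male"), "linkage")
})
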