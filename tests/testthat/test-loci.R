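# Transcript-to-locus clustering, isoform sampling and locus overlap.

test_that("clustering joins same-strand exonic overlap and splits strands", {
  ex <- data.frame(
    transcript_id = c("t1", "t2", "t3"),
    scaffold = "s1", strand = c("+", "+", "-"),
    start = c(100L, 199L, 150L), end = c(200L, 300L, 260L))
  ls <- cluster_loci(ex)
  # t1 and t2 share exactly one exonic base; t3 overlaps both but on the
  # opposite strand and stays its own locus
  expect_equal(nrow(ls$loci), 2L)
  mem <- split(ls$members$transcript_id, ls$members$locus_id)
  expect_true(any(vapply(mem, function(m) setequal(m, c("t1", "t2")),
                         logical(1))))

  # transitive connection through a bridging transcript
  ex2 <- data.frame(
    transcript_id = rep(c("a", "b", "c"), times = c(1L, 2L, 1L)),
    scaffold = "s1", strand = "+",
    start = c(0L, 80L, 400L, 450L), end = c(100L, 120L, 440L, 600L))
  expect_equal(nrow(cluster_loci(ex2)$loci), 2L)   # {a,b} and {c}
  ex2$end[3] <- 460L   # b's second exon now reaches c: one component
  expect_equal(nrow(cluster_loci(ex2)$loci), 1L)

  # unknown-strand single-exon transcripts are excluded and reported
  ex3 <- rbind(ex, data.frame(transcript_id = "t4", scaffold = "s1",
                              strand = ".", start = 10L, end = 90L))
  ls3 <- cluster_loci(ex3)
  expect_equal(ls3$unstranded, "t4")
  expect_equal(nrow(ls3$loci), 2L)

  expect_error(transcript_set(transform(ex, end = start)), "end <= start")
})

test_that("clustering matches brute-force components and is order-invariant", {
  ex <- random_transcripts(100L, seed = 31L)
  ls <- cluster_loci(ex)
  brute <- brute_components(ex)
  ours <- stats::setNames(ls$members$locus_id, ls$members$transcript_id)
  ours <- ours[names(brute)]
  # identical partitions: equal label co-membership
  expect_equal(outer(ours, ours, "=="), outer(brute, brute, "=="))

  # permutation invariance and idempotence of the locus table
  perm <- ex[withr::with_seed(9L, sample.int(nrow(ex))), ]
  ls_perm <- cluster_loci(perm)
  expect_equal(ls_perm$loci, ls$loci)
  expect_equal(ls_perm$members[order(ls_perm$members$transcript_id), ],
               ls$members[order(ls$members$transcript_id), ],
               ignore_attr = TRUE)
})

test_that("one isoform per locus is uniform, seeded and cardinality-preserving", {
  ex <- random_transcripts(50L, seed = 12L)
  ls <- cluster_loci(ex)
  picks <- one_isoform_per_locus(ls, seed = 4L)
  expect_equal(length(picks), nrow(ls$loci))
  expect_identical(picks, one_isoform_per_locus(ls, seed = 4L))
  # each pick belongs to its locus
  mem <- split(ls$members$transcript_id, ls$members$locus_id)
  expect_true(all(mapply(function(p, l) p %in% mem[[l]], picks,
                         ls$loci$locus_id)))

  # single-isoform loci: the identity
  singles <- data.frame(transcript_id = c("u1", "u2"), scaffold = "s1",
                        strand = "+", start = c(0L, 1000L),
                        end = c(100L, 1100L))
  ls1 <- cluster_loci(singles)
  expect_setequal(one_isoform_per_locus(ls1, seed = 1L), c("u1", "u2"))

  # a three-isoform locus is sampled uniformly: 3000 draws, 3 SD multinomial
  tri <- data.frame(transcript_id = c("i1", "i2", "i3"), scaffold = "s1",
                    strand = "+", start = 0L, end = 100L)
  ls3 <- cluster_loci(tri)
  draws <- vapply(1:3000, function(s) one_isoform_per_locus(ls3, seed = s),
                  character(1))
  counts <- table(factor(draws, levels = c("i1", "i2", "i3")))
  expect_true(all(abs(counts - 1000) < 3 * sqrt(3000 * (1 / 3) * (2 / 3))))
})

test_that("locus overlap counts and opposite-strand flags are correct", {
  ex <- random_transcripts(30L, seed = 21L)
  A <- cluster_loci(ex)
  # identical sets: full reciprocal overlap
  self <- overlap_loci(A, A)
  expect_equal(self$summary$query_overlapped, nrow(A$loci))
  expect_equal(self$summary$reference_overlapped, nrow(A$loci))

  # flipping every strand (on a single-strand set, so no incidental
  # antisense overlap exists): zero same-strand overlap, everything flagged
  ex_plus <- transform(ex, strand = "+")
  C <- cluster_loci(ex_plus)
  Cflip <- cluster_loci(transform(ex, strand = "-"))
  flip <- overlap_loci(C, Cflip)
  expect_equal(flip$summary$query_overlapped, 0L)
  expect_equal(flip$summary$opposite_strand_flagged,
               nrow(overlap_loci(C, C)$pairs))

  # brute-force all-pairs oracle on independent reference/query sets
  exq <- random_transcripts(40L, seed = 22L)
  Q <- cluster_loci(exq)
  rep <- overlap_loci(A, Q)
  lex_r <- haplodepth:::.locus_exons(A)
  lex_q <- haplodepth:::.locus_exons(Q)
  brute_pairs <- 0L
  brute_q <- character(0)
  for (qi in seq_len(nrow(Q$loci))) {
    for (ri in seq_len(nrow(A$loci))) {
      if (Q$loci$scaffold[qi] != A$loci$scaffold[ri]) next
      if (Q$loci$strand[qi] != A$loci$strand[ri]) next
      ov <- haplodepth:::.intervals_overlap_bp(lex_q[[Q$loci$locus_id[qi]]],
                                               lex_r[[A$loci$locus_id[ri]]])
      if (ov >= 1L) {
        brute_pairs <- brute_pairs + 1L
        brute_q <- union(brute_q, Q$loci$locus_id[qi])
      }
    }
  }
  expect_equal(nrow(rep$pairs), brute_pairs)
  expect_equal(rep$summary$query_overlapped, length(brute_q))

  # scaffold disjointness warns and yields zero overlaps
  far <- random_transcripts(5L, seed = 23L, scaffolds = "elsewhere")
  expect_warning(none <- overlap_loci(A, cluster_loci(far)), "only one")
  expect_equal(none$summary$query_overlapped, 0L)
})

test_that("GTF/GFF interfaces round-trip transcript models", {
  skip_if_not_installed("rtracklayer")
  ex <- transcript_set(data.frame(
    transcript_id = c("tx1", "tx1", "tx2"),
    gene_id = c("g1", "g1", "g2"),
    scaffold = "s1", strand = c("+", "+", "-"),
    start = c(100L, 300L, 1000L), end = c(200L, 400L, 1200L)))
  path <- tempfile(fileext = ".gtf")
  write_transcripts(ex, path)
  back <- read_transcripts(path)
  back <- back[order(back$transcript_id, back$start), ]
  expect_equal(back$start, ex$start)
  expect_equal(back$end, ex$end)
  expect_equal(back$strand, ex$strand)
  expect_equal(back$transcript_id, ex$transcript_id)
  # the emitted file is GTF2-dialect (transcript_id "x")
  expect_true(any(grepl('transcript_id "tx1"', readLines(path))))
})
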