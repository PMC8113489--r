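# Shared fixtures: tiny configurations and hand-built objects used across
# test files.  Everything is generated in code; no stored data.

tiny_config <- function(...) {
  sim_config(n_autosomes = 2L, n_x_scaffolds = 0L, scaffold_length = 5e4,
             coverage = 20, seed = 11L, ...)
}

# depth_track built directly from per-scaffold vectors
manual_track <- function(depth_list) {
  out <- list(depth = depth_list,
              filters = list(min_mapq = NA_integer_, masked = FALSE),
              scaffold_lengths = vapply(depth_list, length, integer(1)))
  class(out) <- "depth_track"
  out
}

# pileup_counts built from a named list of 8 x L matrices and reference
# sequences
manual_pileup <- function(counts, ref) {
  out <- list(counts = counts, ref = ref, filters = list(min_mapq = 0L))
  class(out) <- "pileup_counts"
  out
}

# alignments data frame from parallel vectors
manual_alignments <- function(scaffold, pos, width, mapq,
                              scaffold_lengths, strand = "+",
                              seq = strrep("A", width)) {
  out <- data.frame(
    read = sprintf("r%03d", seq_along(pos)), scaffold = scaffold, pos = pos,
    width = width, strand = strand, mapq = mapq, nm = 0L, seq = seq,
    stringsAsFactors = FALSE)
  attr(out, "scaffold_lengths") <- scaffold_lengths
  class(out) <- c("alignments", "data.frame")
  out
}

# brute-force per-base depth by interval stabbing
brute_depth <- function(starts, ends, len) {
  vapply(seq_len(len) - 1L, function(p) sum(starts <= p & p < ends),
         integer(1))
}

# brute-force one-sided KS statistic over a fine grid of pooled points
brute_d_plus <- function(greater, lesser) {
  xs <- sort(unique(c(greater, lesser)))
  max(c(vapply(xs, function(x) mean(lesser <= x) - mean(greater <= x),
               numeric(1)), 0))
}

# brute-force connected components of the same-scaffold/strand exonic
# overlap graph; returns membership labelled by representative transcript
brute_components <- function(exons) {
  tx <- unique(exons$transcript_id)
  n <- length(tx)
  adj <- matrix(FALSE, n, n)
  sp <- split(exons, exons$transcript_id)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      a <- sp[[tx[i]]]
      b <- sp[[tx[j]]]
      if (a$scaffold[1] != b$scaffold[1] || a$strand[1] != b$strand[1]) next
      hit <- FALSE
      for (p in seq_len(nrow(a))) {
        if (any(pmin(a$end[p], b$end) - pmax(a$start[p], b$start) >= 1L)) {
          hit <- TRUE
          break
        }
      }
      adj[i, j] <- adj[j, i] <- hit
    }
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  stats::setNames(comp, tx)
}

# random multi-exon transcript set for property tests
random_transcripts <- function(n, seed, scaffolds = c("s1", "s2"),
                               span = 5000L) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      sc <- sample(scaffolds, 1)
      st <- sample(c("+", "-"), 1)
      n_ex <- sample(1:3, 1)
      s0 <- sample.int(span, 1)
      s <- sort(s0 + cumsum(c(0, sample(250:500, 2 * n_ex - 1,
                                        replace = TRUE)))[seq(1, 2 * n_ex,
                                                              by = 2)])
      w <- sample(30:200, n_ex, replace = TRUE)
      data.frame(transcript_id = sprintf("t%03d", i), scaffold = sc,
                 strand = st, start = s, end = s + w,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
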