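#' Generate a random ancestral sequence
#'
#' I.i.d. nucleotides with a target GC content; the shared ancestor from
#' which the two haplotypes of a simulated diploid are derived.
#'
#' @param length Sequence length, bp (> 0).
#' @param gc_content Target GC fraction, in (0, 1).
#' @param seed Integer seed; identical inputs give identical sequences.
#' @return A single character string over A/C/G/T.
#' @examples
#' s <- generate_ancestor(1000, gc_content = 0.32, seed = 1)
#' @export
generate_ancestor <- function(length, gc_content, seed) {
  .stopifnot_scalar_number(length, "length")
  if (length <= 0) stop("`length` must be positive", call. = FALSE)
  .stopifnot_scalar_number(gc_content, "gc_content")
  if (gc_content <= 0 || gc_content >= 1) {
    stop("`gc_content` must be in (0, 1)", call. = FALSE)
  }
  p <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
         (1 - gc_content) / 2)
  with_seed(seed, {
    codes <- sample.int(4L, size = length, replace = TRUE, prob = p)
    intToUtf8(.base_int[codes])
  })
}

# Piecewise offset table turning indel edits (hap1 coordinates) into the
# hap1 <-> hap2 coordinate maps.  After edit i (pos p, ref length r, alt
# length a), positions x >= p + r satisfy hap2 = x + offset_i with
# offset_i = offset_{i-1} + (a - r).
.offset_table <- function(edits) {
  ind <- edits[edits$type != "SNV", , drop = FALSE]
  if (nrow(ind) == 0L) {
    return(data.frame(hap1_break = integer(0), hap2_break = integer(0),
                      offset = integer(0)))
  }
  ind <- ind[order(ind$pos), , drop = FALSE]
  delta <- nchar(ind$alt) - nchar(ind$ref)
  offset <- cumsum(delta)
  hap1_break <- ind$pos + nchar(ind$ref)
  data.frame(hap1_break = hap1_break, hap2_break = hap1_break + offset,
             offset = offset)
}

.lift_hap1_to_hap2 <- function(pos, tab) {
  if (nrow(tab) == 0L) return(pos)
  i <- findInterval(pos, tab$hap1_break)
  pos + c(0L, tab$offset)[i + 1L]
}

.lift_hap2_to_hap1 <- function(pos, tab) {
  if (nrow(tab) == 0L) return(pos)
  i <- findInterval(pos, tab$hap2_break)
  pos - c(0L, tab$offset)[i + 1L]
}

# Apply sorted non-overlapping edits (pos 0-based, ref/alt strings, possibly
# empty) to a sequence.
.apply_edits <- function(seq, edits) {
  if (nrow(edits) == 0L) return(seq)
  edits <- edits[order(edits$pos), , drop = FALSE]
  ref_len <- nchar(edits$ref)
  seg_start <- c(0L, edits$pos + ref_len)
  seg_end <- c(edits$pos, nchar(seq))
  segs <- substring(seq, seg_start + 1L, seg_end)
  paste0(paste0(c("", edits$alt), segs, collapse = ""))
}

.random_bases <- function(n) {
  vapply(n, function(k) intToUtf8(.base_int[sample.int(4L, k, replace = TRUE)]),
         character(1))
}

# Sample heterozygous edits for one scaffold.  Indels are kept >= 12 bp apart
# (and away from homozygous-block margins) so edits never overlap; SNVs
# falling inside a sampled deletion are dropped (a negligible fraction at the
# rates the package targets).
.sample_scaffold_edits <- function(seq, len, hom_block, snv_rate, indel_rate) {
  margin <- 12L
  if (nrow(hom_block) > 0L) {
    guard <- data.frame(start = pmax(hom_block$start - margin, 0L),
                        end = pmin(hom_block$end + margin, len))
  } else {
    guard <- hom_block
  }
  guard <- rbind(guard, data.frame(start = max(len - margin, 0L), end = len))
  guard <- .merge_intervals(guard$start, guard$end)
  elig <- .complement_intervals(guard$start, guard$end, len)
  elig_pos <- unlist(mapply(function(s, e) seq.int(s, e - 1L), elig$start,
                            elig$end, SIMPLIFY = FALSE), use.names = FALSE)
  n_elig <- length(elig_pos)
  if (n_elig == 0L) {
    return(data.frame(pos = integer(0), ref = character(0),
                      alt = character(0), type = character(0),
                      stringsAsFactors = FALSE))
  }
  n_snv <- rbinom(1L, n_elig, snv_rate)
  n_ind <- rbinom(1L, n_elig, indel_rate)
  snv_pos <- sort(elig_pos[sample.int(n_elig, min(n_snv, n_elig))])
  ind_pos <- sort(elig_pos[sample.int(n_elig, min(n_ind, n_elig))])
  if (length(ind_pos) > 1L) {
    keep <- c(TRUE, diff(ind_pos) >= margin)
    ind_pos <- ind_pos[keep]
  }

  edits <- list()
  if (length(ind_pos) > 0L) {
    is_ins <- runif(length(ind_pos)) < 0.5
    ind_len <- sample.int(10L, length(ind_pos), replace = TRUE)
    ref <- ifelse(is_ins, "",
                  substring(seq, ind_pos + 1L, ind_pos + ind_len))
    alt <- ifelse(is_ins, .random_bases(ind_len), "")
    edits$ind <- data.frame(pos = ind_pos, ref = ref, alt = alt,
                            type = ifelse(is_ins, "INS", "DEL"),
                            stringsAsFactors = FALSE)
    # drop SNVs colliding with an indel footprint
    del <- edits$ind[edits$ind$type == "DEL", , drop = FALSE]
    bad <- .in_intervals(snv_pos, edits$ind$pos,
                         edits$ind$pos + pmax(nchar(edits$ind$ref), 1L))
    snv_pos <- snv_pos[!bad]
  }
  if (length(snv_pos) > 0L) {
    ref <- substring(seq, snv_pos + 1L, snv_pos + 1L)
    shift <- sample.int(3L, length(snv_pos), replace = TRUE)
    code <- match(ref, names(.base_int))
    alt <- names(.base_int)[(code - 1L + shift) %% 4L + 1L]
    edits$snv <- data.frame(pos = snv_pos, ref = ref, alt = alt, type = "SNV",
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, edits)
  if (is.null(out)) {
    out <- data.frame(pos = integer(0), ref = character(0),
                      alt = character(0), type = character(0),
                      stringsAsFactors = FALSE)
  }
  out[order(out$pos), , drop = FALSE]
}

#' Derive two haplotypes from ancestral scaffolds
#'
#' Introduces heterozygous SNVs and short (1-10 bp) indels outside a
#' homozygous block, records the complete truth table, and lays out phase
#' blocks over the heterozygous portion of each scaffold (a configurable
#' fraction of heterozygous segments is left unphased, emulating incomplete
#' phasing from insufficient linked-read data).
#'
#' Haplotype 1 equals the ancestor; haplotype 2 carries the edits.  The
#' collapsed assembly rendering ([render_assemblies()]) exposes haplotype 1.
#'
#' @param ancestors Named character vector of ancestral scaffold sequences.
#' @param config A [sim_config()].
#' @param sex_linkage Optional named character vector (`"autosome"`/`"X"`)
#'   per scaffold; defaults to all autosomes.
#' @param materialize_hap2 If `FALSE`, haplotype 2 sequences are not built
#'   (coordinate maps and truth tables still are); used by the replicate
#'   drivers where only depth, never sequence, is consumed.
#' @return An object of class `diploid_genome`.
#' @seealso [simulate_genome()] for the one-call wrapper.
#' @export
diverge_haplotypes <- function(ancestors, config, sex_linkage = NULL,
                               materialize_hap2 = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  stopifnot(is.character(ancestors), !is.null(names(ancestors)))
  scaffolds <- names(ancestors)
  if (is.null(sex_linkage)) {
    sex_linkage <- stats::setNames(rep("autosome", length(scaffolds)),
                                   scaffolds)
  }
  stopifnot(all(scaffolds %in% names(sex_linkage)))

  with_seed(config$seed + 1L, {
    hom_blocks <- list()
    phase_blocks <- list()
    edits <- list()
    hap2 <- stats::setNames(character(length(scaffolds)), scaffolds)
    hap2_len <- stats::setNames(integer(length(scaffolds)), scaffolds)
    offsets <- list()

    for (sc in scaffolds) {
      seq1 <- ancestors[[sc]]
      len <- nchar(seq1)
      hb <- data.frame(scaffold = character(0), start = integer(0),
                       end = integer(0))
      if (config$homozygous_block_fraction > 0) {
        bl <- round(config$homozygous_block_fraction * len)
        if (bl >= len) {
          bl <- len
          bs <- 0L
        } else {
          bs <- sample.int(len - bl + 1L, 1L) - 1L
        }
        if (bl > 0L) {
          hb <- data.frame(scaffold = sc, start = bs, end = bs + bl)
        }
      }
      ed <- .sample_scaffold_edits(seq1, len,
                                   hb[, c("start", "end"), drop = FALSE],
                                   config$snv_rate, config$indel_rate)
      tab <- .offset_table(ed)
      offsets[[sc]] <- tab
      hap2_len[[sc]] <- len + (if (nrow(tab)) tab$offset[nrow(tab)] else 0L)
      if (materialize_hap2) hap2[[sc]] <- .apply_edits(seq1, ed)
      if (nrow(ed)) ed <- cbind(scaffold = sc, ed)
      edits[[sc]] <- ed
      hom_blocks[[sc]] <- hb

      # phase-block layout: chop heterozygous segments into ~100 kb chunks,
      # each phased with probability 1 - unphased_fraction
      het <- .complement_intervals(hb$start, hb$end, len)
      pb <- list()
      for (i in seq_len(nrow(het))) {
        cuts <- seq.int(het$start[i], het$end[i], by = 1e5L)
        if (cuts[length(cuts)] < het$end[i]) cuts <- c(cuts, het$end[i])
        if (length(cuts) < 2L) next
        st <- cuts[-length(cuts)]
        en <- cuts[-1L]
        phased <- runif(length(st)) >= config$unphased_fraction
        pb[[i]] <- data.frame(scaffold = sc, start = st, end = en,
                              phased = phased)
      }
      phase_blocks[[sc]] <- if (length(pb)) do.call(rbind, pb) else
        data.frame(scaffold = character(0), start = integer(0),
                   end = integer(0), phased = logical(0))
    }

    edits <- do.call(rbind, c(edits, list(make.row.names = FALSE)))
    if (is.null(edits) || nrow(edits) == 0L) {
      edits <- data.frame(scaffold = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          type = character(0), stringsAsFactors = FALSE)
    }
    hom_blocks <- do.call(rbind, c(hom_blocks, list(make.row.names = FALSE)))
    phase_blocks <- do.call(rbind, c(phase_blocks,
                                     list(make.row.names = FALSE)))

    genome <- list(
      scaffolds = scaffolds,
      hap1 = ancestors,
      hap2 = if (materialize_hap2) hap2 else NULL,
      hap1_length = stats::setNames(nchar(ancestors), scaffolds),
      hap2_length = hap2_len,
      edits = edits,
      offsets = offsets,
      hom_blocks = hom_blocks,
      phase_blocks = phase_blocks,
      sex_linkage = sex_linkage[scaffolds],
      dup_loci = NULL,
      config = config
    )
    class(genome) <- "diploid_genome"
    genome
  })
}

#' Simulate a diploid genome
#'
#' Generates ancestral scaffolds (autosomes then X scaffolds, per the
#' configuration) and derives the two haplotypes; see [diverge_haplotypes()].
#'
#' @param config A [sim_config()].
#' @param materialize_hap2 See [diverge_haplotypes()].
#' @return A `diploid_genome`.
#' @examples
#' g <- simulate_genome(sim_config(n_autosomes = 1, n_x_scaffolds = 0,
#'                                 scaffold_length = 2e4))
#' g
#' @export
simulate_genome <- function(config, materialize_hap2 = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_autosomes + config$n_x_scaffolds
  scaffolds <- c(sprintf("autosome%d", seq_len(config$n_autosomes)),
                 if (config$n_x_scaffolds > 0L)
                   sprintf("chrX_%d", seq_len(config$n_x_scaffolds)))
  linkage <- stats::setNames(
    c(rep("autosome", config$n_autosomes), rep("X", config$n_x_scaffolds)),
    scaffolds)
  ancestors <- stats::setNames(vapply(seq_len(n), function(i) {
    generate_ancestor(config$scaffold_length, config$gc_content,
                      seed = config$seed * 131L + i)
  }, character(1)), scaffolds)
  diverge_haplotypes(ancestors, config, sex_linkage = linkage,
                     materialize_hap2 = materialize_hap2)
}

#' Truth table of heterozygous variants
#'
#' @param genome A `diploid_genome`.
#' @param type Optional subset: `"SNV"`, `"INS"`, `"DEL"`.
#' @return Data frame with columns `scaffold`, `pos` (0-based, haplotype-1
#'   coordinates), `ref`, `alt`, `type`.
#' @export
truth_variants <- function(genome, type = NULL) {
  stopifnot(inherits(genome, "diploid_genome"))
  v <- genome$edits
  if (!is.null(type)) v <- v[v$type %in% type, , drop = FALSE]
  v
}

#' Phased blocks of a simulated genome
#'
#' @param genome A `diploid_genome`.
#' @return Data frame of phased intervals (`scaffold`, `start`, `end`),
#'   0-based half-open, suitable for [write_bed()].
#' @export
phased_blocks <- function(genome) {
  stopifnot(inherits(genome, "diploid_genome"))
  pb <- genome$phase_blocks
  pb[pb$phased, c("scaffold", "start", "end"), drop = FALSE]
}

#' @export
print.diploid_genome <- function(x, ...) {
  cat("Simulated diploid genome\n")
  cat(sprintf("  %d scaffolds (%d autosome, %d X), haplotype-1 total %s bp\n",
              length(x$scaffolds), sum(x$sex_linkage == "autosome"),
              sum(x$sex_linkage == "X"),
              format(sum(x$hap1_length), big.mark = ",")))
  tv <- table(factor(x$edits$type, levels = c("SNV", "INS", "DEL")))
  cat(sprintf("  truth variants: %d SNV, %d INS, %d DEL\n",
              tv[["SNV"]], tv[["INS"]], tv[["DEL"]]))
  cat(sprintf("  phased: %s bp of %s bp heterozygous\n",
              format(sum(with(x$phase_blocks, end - start)[x$phase_blocks$phased]),
                     big.mark = ","),
              format(sum(with(x$phase_blocks, end - start)), big.mark = ",")))
  if (!is.null(x$dup_loci) && nrow(x$dup_loci)) {
    cat(sprintf("  %d tandem-duplicated loci (both haplotypes)\n",
                nrow(x$dup_loci)))
  }
  invisible(x)
}
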