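#' Render assemblies from a diploid genome
#'
#' Produces the two haploid representations the diagnostics compare:
#'
#' * `collapsed` - haplotype 1 once per scaffold (the pseudo-haplotype
#'   representation: one copy of every locus).
#' * `artifact` - the collapsed scaffolds plus, for a randomly selected
#'   fraction of the marker loci, the haplotype-2 copy of the locus (with a
#'   1 kb flank) appended as an extra scaffold.  This emulates
#'   megabubbles-style scaffolding injecting both haplotypes of divergent
#'   loci into one "haploid" assembly, creating haplotype-induced duplication
#'   artifacts.
#'
#' @param genome A `diploid_genome` with haplotype 2 materialized.
#' @param genes Marker genes (see [place_marker_genes()]): data frame with
#'   `gene_id`, `scaffold`, `start`, `end` (0-based half-open,
#'   non-overlapping, within scaffold bounds).
#' @param config A [sim_config()]; `artifact_fraction` controls how many loci
#'   are duplicated.
#' @param flank Flank added around the haplotype-2 copy, bp.
#' @return List with elements `collapsed` and `artifact`, each of class
#'   `assembly_rendering` (fields `sequences`, `kind`, `duplication_truth`).
#' @export
render_assemblies <- function(genome, genes, config = genome$config,
                              flank = 1000L) {
  stopifnot(inherits(genome, "diploid_genome"))
  if (config$artifact_fraction > 0 && nrow(genes) == 0L) {
    stop("artifact_fraction > 0 requires marker loci", call. = FALSE)
  }
  n_art <- round(config$artifact_fraction * nrow(genes))
  .check_marker_genes(genes, genome$hap1_length)

  truth <- data.frame(gene_id = genes$gene_id,
                      label = rep("single", nrow(genes)),
                      stringsAsFactors = FALSE)
  collapsed <- list(sequences = genome$hap1, kind = "collapsed",
                    duplication_truth = truth)
  class(collapsed) <- "assembly_rendering"

  art_seqs <- genome$hap1
  if (n_art > 0L) {
    if (is.null(genome$hap2)) {
      stop("artifact rendering requires haplotype 2 sequences", call. = FALSE)
    }
    pick <- with_seed(config$seed + 9001L,
                      sort(sample.int(nrow(genes), n_art)))
    truth$label[pick] <- "haplotype_artifact"
    for (i in pick) {
      sc <- genes$scaffold[i]
      tab <- genome$offsets[[sc]]
      s2 <- .lift_hap1_to_hap2(max(genes$start[i] - flank, 0L), tab)
      e2 <- .lift_hap1_to_hap2(min(genes$end[i] + flank,
                                   genome$hap1_length[[sc]]), tab)
      e2 <- min(e2, genome$hap2_length[[sc]])
      nm <- paste0(genes$gene_id[i], "_hap2")
      art_seqs[[nm]] <- substring(genome$hap2[[sc]], s2 + 1L, e2)
    }
  }
  artifact <- list(sequences = art_seqs, kind = "artifact",
                   duplication_truth = truth)
  class(artifact) <- "assembly_rendering"
  list(collapsed = collapsed, artifact = artifact)
}

.check_marker_genes <- function(genes, scaffold_lengths) {
  stopifnot(all(c("gene_id", "scaffold", "start", "end") %in% names(genes)))
  if (nrow(genes) == 0L) return(invisible(TRUE))
  if (!all(genes$scaffold %in% names(scaffold_lengths))) {
    stop("marker genes reference unknown scaffolds", call. = FALSE)
  }
  bad <- genes$start < 0L | genes$end > scaffold_lengths[genes$scaffold] |
    genes$start >= genes$end
  if (any(bad)) stop("marker loci out of scaffold bounds", call. = FALSE)
  for (sc in unique(genes$scaffold)) {
    g <- genes[genes$scaffold == sc, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    if (nrow(g) > 1L && any(g$start[-1L] < g$end[-nrow(g)])) {
      stop("marker loci must be non-overlapping", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.assembly_rendering <- function(x, ...) {
  cat(sprintf("Assembly rendering (%s): %d scaffolds, %s bp\n", x$kind,
              length(x$sequences),
              format(sum(nchar(x$sequences)), big.mark = ",")))
  if (!is.null(x$duplication_truth)) {
    tab <- table(x$duplication_truth$label)
    cat("  marker locus truth:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tandem-duplicate loci in both haplotypes
#'
#' Turns the listed loci into true segmental duplications: each locus is
#' duplicated in tandem in haplotype 1 and in the corresponding haplotype-2
#' interval, giving copy number 2 per haplotype.  Truth variants, homozygous
#' blocks and phase blocks downstream of each insertion are shifted; variants
#' inside a duplicated locus are duplicated with it.  The genome remembers
#' the insertions so [truth_depth_track()] can map reads back to the
#' pre-duplication (collapsed assembly) coordinates.
#'
#' @param genome A `diploid_genome`.
#' @param loci Data frame with `scaffold`, `start`, `end` (0-based half-open,
#'   non-overlapping); typically a subset of the marker genes.
#' @return The modified `diploid_genome`.
#' @export
apply_true_duplication <- function(genome, loci) {
  stopifnot(inherits(genome, "diploid_genome"))
  if (is.null(loci) || nrow(loci) == 0L) return(genome)
  stopifnot(all(c("scaffold", "start", "end") %in% names(loci)))
  loci <- loci[order(loci$scaffold, loci$start), , drop = FALSE]
  for (sc in unique(loci$scaffold)) {
    l <- loci[loci$scaffold == sc, , drop = FALSE]
    if (nrow(l) > 1L && any(l$start[-1L] < l$end[-nrow(l)])) {
      stop("duplication loci must be non-overlapping", call. = FALSE)
    }
    if (any(l$start < 0L) || any(l$end > genome$hap1_length[[sc]])) {
      stop("duplication loci out of bounds", call. = FALSE)
    }
  }

  edits <- genome$edits
  for (sc in unique(loci$scaffold)) {
    l <- loci[loci$scaffold == sc, , drop = FALSE]
    # process right-to-left so earlier coordinates stay valid
    for (i in rev(seq_len(nrow(l)))) {
      s <- l$start[i]
      e <- l$end[i]
      L <- e - s
      seq1 <- genome$hap1[[sc]]
      genome$hap1[[sc]] <- paste0(substring(seq1, 1L, e),
                                  substring(seq1, s + 1L, e),
                                  substring(seq1, e + 1L, nchar(seq1)))
      sel <- edits$scaffold == sc
      inside <- sel & edits$pos >= s & edits$pos < e
      after <- sel & edits$pos >= e
      dup_edits <- edits[inside, , drop = FALSE]
      if (nrow(dup_edits)) dup_edits$pos <- dup_edits$pos + L
      edits$pos[after] <- edits$pos[after] + L
      edits <- rbind(edits, dup_edits)
      shift_blocks <- function(b) {
        sel <- b$scaffold == sc
        b$start[sel & b$start >= e] <- b$start[sel & b$start >= e] + L
        b$end[sel & b$end >= e] <- b$end[sel & b$end >= e] + L
        b
      }
      genome$hom_blocks <- shift_blocks(genome$hom_blocks)
      genome$phase_blocks <- shift_blocks(genome$phase_blocks)
    }
  }
  edits <- edits[order(edits$scaffold, edits$pos), , drop = FALSE]
  rownames(edits) <- NULL
  genome$edits <- edits
  genome$hap1_length <- stats::setNames(nchar(genome$hap1), genome$scaffolds)

  # rebuild haplotype 2 and the coordinate maps from the updated edits
  for (sc in genome$scaffolds) {
    ed <- edits[edits$scaffold == sc, , drop = FALSE]
    tab <- .offset_table(ed)
    genome$offsets[[sc]] <- tab
    genome$hap2_length[[sc]] <- genome$hap1_length[[sc]] +
      (if (nrow(tab)) tab$offset[nrow(tab)] else 0L)
    if (!is.null(genome$hap2)) {
      genome$hap2[[sc]] <- .apply_edits(genome$hap1[[sc]], ed)
    }
  }

  prev <- genome$dup_loci
  genome$dup_loci <- rbind(prev,
                           loci[, c("scaffold", "start", "end"), drop = FALSE])
  genome
}

# Map post-duplication haplotype-1 coordinates back to the original
# (collapsed assembly) coordinates: each tandem insertion i of length l_i at
# original end e_i occupies [b_i, b_i + l_i) in the new coordinates with
# b_i = e_i + sum of earlier insertion lengths; positions >= b_i (second copy
# included) lift back by the cumulative inserted length.
.dup_lift_table <- function(dup_loci, scaffold) {
  l <- dup_loci[dup_loci$scaffold == scaffold, , drop = FALSE]
  if (nrow(l) == 0L) {
    return(data.frame(brk = integer(0), cum = integer(0)))
  }
  l <- l[order(l$start), , drop = FALSE]
  len <- l$end - l$start
  cum <- cumsum(len)
  brk <- l$end + c(0L, head(cum, -1L))
  data.frame(brk = brk, cum = cum)
}

.lift_dup_to_collapsed <- function(pos, tab) {
  if (nrow(tab) == 0L) return(pos)
  i <- findInterval(pos, tab$brk)
  pos - c(0L, tab$cum)[i + 1L]
}
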