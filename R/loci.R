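#' Construct a transcript set
#'
#' Validates an exon table into the container the locus tools operate on.
#' Exons are 0-based half-open, and must be sorted and disjoint within each
#' transcript.
#'
#' @param exons Data frame with `transcript_id`, `scaffold`, `strand`
#'   (`"+"`, `"-"`, or `"."` for unknown), `start`, `end`, and optionally
#'   `gene_id`.
#' @return Object of class `transcript_set` (the validated exon data frame).
#' @export
transcript_set <- function(exons) {
  need <- c("transcript_id", "scaffold", "strand", "start", "end")
  stopifnot(all(need %in% names(exons)))
  if (!"gene_id" %in% names(exons)) exons$gene_id <- NA_character_
  exons <- exons[order(exons$scaffold, exons$transcript_id, exons$start), ,
                 drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$end <= exons$start)) {
    stop("malformed exon: end <= start", call. = FALSE)
  }
  if (!all(exons$strand %in% c("+", "-", "."))) {
    stop("strand must be '+', '-' or '.'", call. = FALSE)
  }
  sp <- split(seq_len(nrow(exons)), exons$transcript_id)
  for (idx in sp) {
    if (length(unique(exons$scaffold[idx])) > 1L ||
        length(unique(exons$strand[idx])) > 1L) {
      stop("transcript spans multiple scaffolds or strands", call. = FALSE)
    }
    s <- exons$start[idx]
    e <- exons$end[idx]
    if (length(idx) > 1L && any(s[-1L] < e[-length(e)])) {
      stop("exons within a transcript must be disjoint", call. = FALSE)
    }
  }
  class(exons) <- c("transcript_set", "data.frame")
  exons
}

#' Cluster transcripts into loci by same-strand exonic overlap
#'
#' Loci are the connected components of the graph joining transcripts on the
#' same scaffold and strand that share at least `min_overlap` bp of exonic
#' sequence - the strand- and exon-aware clustering used to collapse
#' alternative isoforms into genes.  Single-exon transcripts with unknown
#' strand (`"."`) are excluded from clustering and reported separately (no
#' strand, no orientation-aware overlap).  Locus ids are assigned
#' deterministically by (scaffold, leftmost coordinate).
#'
#' @param transcripts A `transcript_set` (or an exon data frame).
#' @param min_overlap Minimum shared exonic bp to join two transcripts
#'   (default 1).
#' @return Object of class `locus_set`: list with `loci` (data frame:
#'   `locus_id`, `scaffold`, `strand`, `start`, `end`, `n_transcripts`),
#'   `members` (`locus_id`, `transcript_id`), `unstranded` (excluded
#'   transcript ids), and the exon table.
#' @export
cluster_loci <- function(transcripts, min_overlap = 1L) {
  if (!inherits(transcripts, "transcript_set")) {
    transcripts <- transcript_set(transcripts)
  }
  ex <- as.data.frame(transcripts)
  unstranded <- unique(ex$transcript_id[ex$strand == "."])
  ex <- ex[ex$strand != ".", , drop = FALSE]
  tx <- unique(ex$transcript_id)
  if (length(tx) == 0L) {
    out <- list(loci = data.frame(locus_id = character(0),
                                  scaffold = character(0),
                                  strand = character(0), start = integer(0),
                                  end = integer(0),
                                  n_transcripts = integer(0)),
                members = data.frame(locus_id = character(0),
                                     transcript_id = character(0)),
                unstranded = unstranded, exons = ex)
    class(out) <- "locus_set"
    return(out)
  }

  # union-find over transcripts
  parent <- seq_along(tx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(i, j) {
    ri <- find(i)
    rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
  }

  ex$txi <- match(ex$transcript_id, tx)
  for (key in split(seq_len(nrow(ex)),
                    paste(ex$scaffold, ex$strand, sep = "\r"))) {
    e <- ex[key, , drop = FALSE]
    e <- e[order(e$start, e$end), , drop = FALSE]
    # sweep: exons whose overlap with the running merged interval reaches
    # min_overlap share a component
    cur_end <- -Inf
    cur_rep <- NA_integer_
    for (i in seq_len(nrow(e))) {
      if (e$start[i] <= cur_end - min_overlap) {
        union(e$txi[i], cur_rep)
        cur_end <- max(cur_end, e$end[i])
      } else {
        cur_rep <- e$txi[i]
        cur_end <- e$end[i]
      }
    }
  }
  comp <- vapply(seq_along(tx), find, integer(1))

  # locus table ordered by (scaffold, leftmost start)
  tx_start <- tapply(ex$start, ex$txi, min)
  tx_end <- tapply(ex$end, ex$txi, max)
  tx_scaffold <- tapply(ex$scaffold, ex$txi, `[`, 1L)
  tx_strand <- tapply(ex$strand, ex$txi, `[`, 1L)
  comp_ids <- unique(comp)
  locus <- data.frame(
    comp = comp_ids,
    scaffold = vapply(comp_ids, function(cid)
      unname(tx_scaffold[as.character(which(comp == cid)[1])]),
      character(1)),
    strand = vapply(comp_ids, function(cid)
      unname(tx_strand[as.character(which(comp == cid)[1])]), character(1)),
    start = vapply(comp_ids, function(cid)
      min(tx_start[as.character(which(comp == cid))]), numeric(1)),
    end = vapply(comp_ids, function(cid)
      max(tx_end[as.character(which(comp == cid))]), numeric(1)),
    n_transcripts = vapply(comp_ids, function(cid) sum(comp == cid),
                           integer(1)),
    stringsAsFactors = FALSE)
  locus <- locus[order(locus$scaffold, locus$start, locus$end), ,
                 drop = FALSE]
  locus$locus_id <- sprintf("LOC%06d", seq_len(nrow(locus)))
  members <- data.frame(
    locus_id = locus$locus_id[match(comp, locus$comp)],
    transcript_id = tx, stringsAsFactors = FALSE)
  members <- members[order(members$locus_id, members$transcript_id), ,
                     drop = FALSE]
  rownames(members) <- NULL
  locus <- locus[, c("locus_id", "scaffold", "strand", "start", "end",
                     "n_transcripts")]
  rownames(locus) <- NULL
  out <- list(loci = locus, members = members, unstranded = unstranded,
              exons = ex[, setdiff(names(ex), "txi"), drop = FALSE])
  class(out) <- "locus_set"
  out
}

#' @export
print.locus_set <- function(x, ...) {
  cat(sprintf("Locus set: %d loci from %d stranded transcripts",
              nrow(x$loci), nrow(x$members)))
  if (length(x$unstranded)) {
    cat(sprintf(" (+%d unstranded excluded)", length(x$unstranded)))
  }
  cat("\n")
  multi <- sum(x$loci$n_transcripts > 1L)
  cat(sprintf("  %d loci with multiple isoforms\n", multi))
  invisible(x)
}

#' Pick one random isoform per locus
#'
#' The de-biasing step for transcriptome-mode duplication estimates:
#' multiple isoforms of one locus can be falsely counted as gene
#' duplications, so completeness is re-assessed on a single randomly chosen
#' isoform per locus.
#'
#' @param loci A `locus_set`.
#' @param seed Integer seed.
#' @return Character vector of transcript ids, one per locus (length equals
#'   the locus count).
#' @export
one_isoform_per_locus <- function(loci, seed = 1L) {
  stopifnot(inherits(loci, "locus_set"))
  if (nrow(loci$loci) == 0L) stop("no loci to sample from", call. = FALSE)
  sp <- split(loci$members$transcript_id, loci$members$locus_id)
  sp <- sp[loci$loci$locus_id]
  with_seed(seed, vapply(sp, function(m) m[sample.int(length(m), 1L)],
                         character(1), USE.NAMES = FALSE))
}

# merged exonic intervals per locus
.locus_exons <- function(ls) {
  mem <- ls$members
  ex <- ls$exons
  ex$locus_id <- mem$locus_id[match(ex$transcript_id, mem$transcript_id)]
  lapply(split(ex, ex$locus_id), function(e) .merge_intervals(e$start, e$end))
}

.intervals_overlap_bp <- function(a, b) {
  # total overlap between two sorted disjoint interval sets
  tot <- 0L
  for (i in seq_len(nrow(a))) {
    ov <- pmin(a$end[i], b$end) - pmax(a$start[i], b$start)
    tot <- tot + sum(pmax(ov, 0L))
  }
  tot
}

#' Overlap two locus sets
#'
#' Reference/query comparison of clustered loci: counts query loci with
#' same-strand exonic overlap in the reference (and vice versa), tabulates
#' one-to-many multiplicities, and flags exonic overlaps on *opposite*
#' strands - candidate anti-sense artifacts, which are reported but do not
#' contribute to the overlap counts.
#'
#' @param reference,query `locus_set` objects on the same assembly.
#' @param min_overlap Minimum shared exonic bp (default 1).
#' @return Object of class `locus_overlap`: list with `summary` (counts),
#'   `pairs` (same-strand overlapping locus pairs),
#'   `opposite_strand_flags` (flagged pairs), and the query multiplicity
#'   table.
#' @export
overlap_loci <- function(reference, query, min_overlap = 1L) {
  stopifnot(inherits(reference, "locus_set"), inherits(query, "locus_set"))
  shared <- intersect(unique(reference$loci$scaffold),
                      unique(query$loci$scaffold))
  only <- setdiff(union(reference$loci$scaffold, query$loci$scaffold),
                  shared)
  if (length(only)) {
    warning(sprintf("scaffolds present in only one set get zero overlaps: %s",
                    paste(only, collapse = ", ")))
  }
  rex <- .locus_exons(reference)
  qex <- .locus_exons(query)
  rl <- reference$loci
  ql <- query$loci
  pairs <- list()
  flags <- list()
  for (i in seq_len(nrow(ql))) {
    cand <- which(rl$scaffold == ql$scaffold[i] & rl$start < ql$end[i] &
                    rl$end > ql$start[i])
    for (j in cand) {
      ov <- .intervals_overlap_bp(qex[[ql$locus_id[i]]],
                                  rex[[rl$locus_id[j]]])
      if (ov < min_overlap) next
      rec <- data.frame(reference = rl$locus_id[j], query = ql$locus_id[i],
                        overlap_bp = ov, stringsAsFactors = FALSE)
      if (rl$strand[j] == ql$strand[i]) {
        pairs[[length(pairs) + 1L]] <- rec
      } else {
        flags[[length(flags) + 1L]] <- rec
      }
    }
  }
  pairs <- if (length(pairs)) {
    do.call(rbind, c(pairs, list(make.row.names = FALSE)))
  } else {
    data.frame(reference = character(0), query = character(0),
               overlap_bp = integer(0))
  }
  flags <- if (length(flags)) {
    do.call(rbind, c(flags, list(make.row.names = FALSE)))
  } else {
    data.frame(reference = character(0), query = character(0),
               overlap_bp = integer(0))
  }
  mult <- table(pairs$query)
  out <- list(
    summary = data.frame(
      n_reference = nrow(rl), n_query = nrow(ql),
      query_overlapped = length(unique(pairs$query)),
      reference_overlapped = length(unique(pairs$reference)),
      one_to_many_queries = sum(mult > 1L),
      opposite_strand_flagged = nrow(flags)),
    pairs = pairs,
    opposite_strand_flags = flags,
    query_multiplicity = mult)
  class(out) <- "locus_overlap"
  out
}

#' @export
print.locus_overlap <- function(x, ...) {
  s <- x$summary
  cat("Locus overlap report\n")
  cat(sprintf("  query: %d/%d loci with same-strand exonic overlap in reference\n",
              s$query_overlapped, s$n_query))
  cat(sprintf("  reference: %d/%d loci overlapped\n",
              s$reference_overlapped, s$n_reference))
  cat(sprintf("  one-to-many query loci: %d\n", s$one_to_many_queries))
  cat(sprintf("  opposite-strand exonic overlaps flagged: %d\n",
              s$opposite_strand_flagged))
  invisible(x)
}

#' Read transcript models from GTF/GFF
#'
#' Accepts both GTF2 (`transcript_id "x"`) and GFF3 (`ID=`/`Parent=`)
#' attribute dialects via `rtracklayer`; exon records are converted to the
#' package's 0-based half-open exon table.
#'
#' @param path GTF or GFF file.
#' @return A `transcript_set`.
#' @export
read_transcripts <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  meta <- S4Vectors::mcols(gr)
  tid <- if ("transcript_id" %in% names(meta)) meta$transcript_id else
    meta$Parent
  if (is.null(tid)) stop("no transcript_id/Parent attributes", call. = FALSE)
  tid <- as.character(tid)
  gid <- if ("gene_id" %in% names(meta)) as.character(meta$gene_id) else
    NA_character_
  transcript_set(data.frame(
    transcript_id = tid,
    gene_id = gid,
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE))
}

#' Write transcript models as GTF2
#'
#' @param transcripts A `transcript_set`.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(transcripts, path) {
  ex <- as.data.frame(transcripts)
  gr <- GenomicRanges::GRanges(
    seqnames = ex$scaffold,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = sub("\\.", "*", ex$strand))
  gr$type <- "exon"
  gr$source <- "haplodepth"
  gr$transcript_id <- ex$transcript_id
  gr$gene_id <- ifelse(is.na(ex$gene_id), ex$transcript_id, ex$gene_id)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
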