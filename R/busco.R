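#' Parse a BUSCO full-table TSV into marker genes
#'
#' Consumes the `full_table.tsv` a BUSCO genome-mode run writes (comment
#' lines starting with `#`, then tab-separated
#' `Busco id / Status / Sequence / Gene Start / Gene End / ...`).
#' `Complete` rows become `single_copy` marker genes; `Duplicated` rows are
#' kept one row per placement, sharing the gene id; `Fragmented`/`Missing`
#' rows are retained with their status (Missing rows carry no interval).
#' Coordinates are converted from the table's 1-based inclusive convention
#' to 0-based half-open.
#'
#' @param path Path to a BUSCO full table.
#' @return Object of class `marker_genes`: data frame with `gene_id`,
#'   `scaffold`, `start`, `end`, `status`
#'   (`single_copy`/`duplicated`/`fragmented`/`missing`), `linkage`
#'   (`"unknown"`).
#' @export
parse_busco_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    stop("no data rows in BUSCO table", call. = FALSE)
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  status_map <- c(Complete = "single_copy", Duplicated = "duplicated",
                  Fragmented = "fragmented", Missing = "missing")
  out <- lapply(f, function(x) {
    if (length(x) < 2L) stop("malformed BUSCO table row", call. = FALSE)
    st <- status_map[x[2]]
    if (is.na(st)) {
      stop(sprintf("unknown BUSCO status '%s'", x[2]), call. = FALSE)
    }
    if (st == "missing" || length(x) < 5L) {
      return(data.frame(gene_id = x[1], scaffold = NA_character_,
                        start = NA_integer_, end = NA_integer_,
                        status = unname(st), stringsAsFactors = FALSE))
    }
    data.frame(gene_id = x[1], scaffold = x[3],
               start = as.integer(x[4]) - 1L, end = as.integer(x[5]),
               status = unname(st), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  out$linkage <- "unknown"
  class(out) <- c("marker_genes", "data.frame")
  out
}

#' Write marker genes as a BUSCO-style full table
#'
#' Inverse of [parse_busco_table()] (1-based inclusive coordinates), for
#' exercising the real-data path on simulated marker genes.
#'
#' @param genes A `marker_genes` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_busco_table <- function(genes, path) {
  status_map <- c(single_copy = "Complete", duplicated = "Duplicated",
                  fragmented = "Fragmented", missing = "Missing")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# Simulated BUSCO-style full table",
               "# Busco id\tStatus\tSequence\tGene Start\tGene End\tScore\tLength"),
             con)
  st <- status_map[genes$status]
  rows <- ifelse(
    st == "Missing",
    paste(genes$gene_id, st, sep = "\t"),
    sprintf("%s\t%s\t%s\t%d\t%d\t%.1f\t%d", genes$gene_id, st,
            genes$scaffold, genes$start + 1L, genes$end, 0,
            genes$end - genes$start))
  writeLines(rows, con)
  invisible(path)
}

#' Place marker genes on a simulated genome
#'
#' Samples non-overlapping gene intervals (conserved single-copy marker
#' genes, BUSCO-style) on the simulated scaffolds, away from scaffold ends
#' where read depth ramps down.
#'
#' @param genome A `diploid_genome`.
#' @param n_autosomal Number of genes on autosomes.
#' @param n_x Number of genes on X scaffolds.
#' @param gene_length Gene length, bp (default 3 kb, the scale of a typical
#'   conserved insect gene).
#' @param margin Distance kept from scaffold ends, bp.
#' @param seed Seed; defaults to the genome configuration's seed.
#' @return A `marker_genes` data frame (`status` initialized to
#'   `single_copy`, `linkage` from the genome).
#' @export
place_marker_genes <- function(genome, n_autosomal = 100L, n_x = 0L,
                               gene_length = 3000L, margin = 2000L,
                               seed = genome$config$seed) {
  stopifnot(inherits(genome, "diploid_genome"))
  autos <- genome$scaffolds[genome$sex_linkage == "autosome"]
  xs <- genome$scaffolds[genome$sex_linkage == "X"]
  if (n_x > 0L && length(xs) == 0L) {
    stop("no X scaffolds to place genes on", call. = FALSE)
  }
  with_seed(seed + 17L, {
    place_on <- function(scaffolds, n, prefix) {
      if (n == 0L) return(NULL)
      per <- tabulate(sample(rep_len(seq_along(scaffolds), n)),
                      nbins = length(scaffolds))
      out <- list()
      for (i in seq_along(scaffolds)) {
        if (per[i] == 0L) next
        sc <- scaffolds[i]
        len <- genome$hap1_length[[sc]]
        usable <- len - 2L * margin
        if (usable < per[i] * (gene_length + 1L)) {
          stop("scaffold too short for requested marker genes",
               call. = FALSE)
        }
        # sample non-overlapping starts by spacing sorted draws
        gap <- usable - per[i] * gene_length
        cuts <- sort(sample.int(gap + 1L, per[i], replace = TRUE) - 1L)
        starts <- margin + cuts + (seq_len(per[i]) - 1L) * gene_length
        out[[sc]] <- data.frame(scaffold = sc, start = starts,
                                end = starts + gene_length,
                                stringsAsFactors = FALSE)
      }
      out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
      out$gene_id <- sprintf("%s%04d", prefix, seq_len(nrow(out)))
      out
    }
    g <- rbind(place_on(autos, n_autosomal, "simbusco_a"),
               place_on(xs, n_x, "simbusco_x"))
    g <- g[, c("gene_id", "scaffold", "start", "end")]
    g$status <- "single_copy"
    g$linkage <- unname(genome$sex_linkage[g$scaffold])
    class(g) <- c("marker_genes", "data.frame")
    g
  })
}

#' Label marker genes from a rendering's duplication truth
#'
#' Marks genes recorded as `haplotype_artifact` or `true_duplication` in an
#' assembly rendering's truth table with status `duplicated` - the label a
#' BUSCO run on that (artifact-bearing) assembly would assign.
#'
#' @param genes A `marker_genes` data frame.
#' @param rendering An `assembly_rendering`, or a `duplication_truth` data
#'   frame (`gene_id`, `label`).
#' @return The relabelled `marker_genes`.
#' @export
assign_duplication_status <- function(genes, rendering) {
  truth <- if (inherits(rendering, "assembly_rendering")) {
    rendering$duplication_truth
  } else {
    rendering
  }
  i <- match(genes$gene_id, truth$gene_id)
  lab <- truth$label[i]
  genes$status[!is.na(lab) & lab != "single"] <- "duplicated"
  genes
}
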