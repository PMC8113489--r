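# Replicate drivers for calibration and power studies of the depth
# diagnostics.  Each replicate re-simulates variants, marker genes and read
# placements on a fixed set of ancestral scaffolds (regenerating the
# ancestor every replicate would only re-randomize the base composition,
# which none of the depth statistics see) and computes per-gene depths from
# truth placements - the sequence-free fast path that [truth_depth_track()]
# provides and that the placer-equivalence tests justify.

# one scenario replicate -> per-gene mean depths with status labels
.scenario_gene_depths <- function(ancestors, config, scenario, sex,
                                  n_autosomal, n_x, linkage = NULL) {
  genome <- diverge_haplotypes(ancestors, config, sex_linkage = linkage,
                               materialize_hap2 = FALSE)
  genes <- place_marker_genes(genome, n_autosomal = n_autosomal, n_x = n_x,
                              seed = config$seed + 3L)
  if (scenario != "plain") {
    n_dup <- round(config$artifact_fraction * nrow(genes))
    pick <- with_seed(config$seed + 9001L,
                      sort(sample.int(nrow(genes), n_dup)))
    genes$status[pick] <- "duplicated"
    if (scenario == "true_dup") {
      genome <- apply_true_duplication(
        genome, genes[pick, c("scaffold", "start", "end"), drop = FALSE])
    }
  }
  pl <- simulate_placements(genome, sex, config, seed = config$seed + 5L)
  track <- truth_depth_track(pl, genome)
  mean_depth_per_gene(track, genes)
}

.seeded_config <- function(config, seed) {
  config$seed <- as.integer(seed)
  config
}

.replicate_ancestors <- function(config) {
  scaffolds <- c(sprintf("autosome%d", seq_len(config$n_autosomes)),
                 if (config$n_x_scaffolds > 0L)
                   sprintf("chrX_%d", seq_len(config$n_x_scaffolds)))
  anc <- stats::setNames(vapply(seq_along(scaffolds), function(i) {
    generate_ancestor(config$scaffold_length, config$gc_content,
                      seed = config$seed * 131L + i)
  }, character(1)), scaffolds)
  linkage <- stats::setNames(
    c(rep("autosome", config$n_autosomes),
      rep("X", config$n_x_scaffolds)), scaffolds)
  list(ancestors = anc, linkage = linkage)
}

#' Replicated duplication-artifact scenarios
#'
#' Runs `n_reps` independent replicates of the haplotype-artifact null
#' scenario (`scenario = "artifact"`: labelled duplications are artifacts,
#' so depth on the collapsed assembly carries no signal) or the
#' true-duplication alternative (`scenario = "true_dup"`: labelled genes are
#' tandem-duplicated in both haplotypes, so collapsed-assembly depth doubles)
#' and returns the one-sided KS p-value and the duplicated/single median
#' depth ratio of each replicate.  Used for type-I calibration and power
#' studies of [duplication_artifact_test()].
#'
#' @param n_reps Number of replicates.
#' @param config Base [sim_config()]; `artifact_fraction` sets the labelled
#'   fraction in both scenarios.
#' @param scenario `"artifact"` or `"true_dup"`.
#' @param n_genes Marker genes per replicate.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @return Data frame with `replicate`, `p_value`, `median_ratio`.
#' @export
artifact_scenario_replicates <- function(n_reps, config,
                                         scenario = c("artifact",
                                                      "true_dup"),
                                         n_genes = 100L, seed = 1L) {
  scenario <- match.arg(scenario)
  base <- .replicate_ancestors(config)
  out <- lapply(seq_len(n_reps), function(r) {
    cfg <- .seeded_config(config, seed + r)
    md <- .scenario_gene_depths(base$ancestors, cfg, scenario, "female",
                                n_autosomal = n_genes, n_x = 0L,
                                linkage = base$linkage)
    dup <- md$mean_depth[md$status == "duplicated"]
    sing <- md$mean_depth[md$status == "single_copy"]
    ks <- ks_one_sided(dup, sing)
    data.frame(replicate = r, p_value = ks$p_value,
               median_ratio = stats::median(dup) / stats::median(sing))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Replicated X-vs-autosome controls
#'
#' Runs seeded replicates of the [x_autosome_control()] scenario for one
#' sex and returns the per-replicate one-sided KS p-value (autosomal genes
#' as the putatively greater sample).
#'
#' @param n_reps Number of replicates.
#' @param config Base [sim_config()] (must include X scaffolds).
#' @param sex `"male"` or `"female"`.
#' @param n_autosomal,n_x Marker genes per class.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @return Data frame with `replicate`, `p_value`, `median_ratio`
#'   (X/autosome median depth ratio).
#' @export
xa_control_replicates <- function(n_reps, config, sex, n_autosomal = 40L,
                                  n_x = 20L, seed = 1L) {
  sex <- match.arg(sex, c("male", "female"))
  base <- .replicate_ancestors(config)
  out <- lapply(seq_len(n_reps), function(r) {
    cfg <- .seeded_config(config, seed + r)
    md <- .scenario_gene_depths(base$ancestors, cfg, "plain", sex,
                                n_autosomal = n_autosomal, n_x = n_x,
                                linkage = base$linkage)
    auto <- md$mean_depth[md$linkage == "autosome"]
    xs <- md$mean_depth[md$linkage == "X"]
    ks <- ks_one_sided(auto, xs)
    data.frame(replicate = r, p_value = ks$p_value,
               median_ratio = stats::median(xs) / stats::median(auto))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Replicated male/female scaffold classification
#'
#' Simulates a male and a female read set per replicate, computes
#' truth-placement depth tracks, windowed male/female ratios and scaffold
#' calls, and compares the calls to the simulated sex linkage.
#'
#' @param n_reps Number of replicates.
#' @param config Base [sim_config()] (must include X scaffolds).
#' @param window Window width for [scaffold_ratio()].
#' @param seed Base seed; replicate r uses `seed + r`.
#' @return Data frame with one row per scaffold and replicate: `replicate`,
#'   `scaffold`, `linkage`, `ratio`, `call`, `correct`.
#' @export
sexscan_replicates <- function(n_reps, config, window = 1e5, seed = 1L) {
  base <- .replicate_ancestors(config)
  out <- lapply(seq_len(n_reps), function(r) {
    cfg <- .seeded_config(config, seed + r)
    genome <- diverge_haplotypes(base$ancestors, cfg,
                                 sex_linkage = base$linkage,
                                 materialize_hap2 = FALSE)
    male <- truth_depth_track(
      simulate_placements(genome, "male", cfg, seed = cfg$seed + 11L),
      genome)
    female <- truth_depth_track(
      simulate_placements(genome, "female", cfg, seed = cfg$seed + 12L),
      genome)
    ratios <- classify_scaffolds(scaffold_ratio(male, female, window))
    expected <- ifelse(base$linkage[ratios$scaffold] == "X", "X_linked",
                       "autosomal")
    data.frame(replicate = r, scaffold = ratios$scaffold,
               linkage = unname(base$linkage[ratios$scaffold]),
               ratio = ratios$ratio, call = ratios$call,
               correct = ratios$call == expected,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
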