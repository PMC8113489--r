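# haplodepth

Read-depth diagnostics for haplotype-resolved genome assemblies.

When a BUSCO run reports an unusually high fraction of *duplicated*
conserved genes in an assembly, two explanations compete:

1. the genes are truly duplicated in the genome, or
2. the assembly retained **both haplotypes of the same locus** — a
   haplotype-induced duplication artifact, typical of scaffolding with
   megabubbles-style diploid assembly exports.

Unassembled reads can tell the two apart. Mapped to a collapsed
(pseudo-haplotype) assembly that represents each locus once:

* **truly duplicated but collapsed** loci attract reads from every genomic
  copy, so their mean mapped depth is ~2x that of single-copy genes;
* **haplotype artifacts** have exactly one genomic copy per haplotype, so
  their depth is indistinguishable from single-copy genes.

`haplodepth` implements this test and its companions for anyone validating
a diploid (e.g. insect) genome assembly: genome assembly QC, sex-scaffold
identification, and annotation comparison.

## The statistics

**Duplication-artifact test.** For every marker (BUSCO) gene the mean
mapped depth is taken across the gene's full genomic range (zero-depth
bases included), after removing MAPQ 0 (multi-mapped) alignments and
alignments fully contained in repeat-masked intervals. The depth
distributions of *duplicated*-labelled and *single-copy* genes are compared
with a one-sided two-sample Kolmogorov–Smirnov test with the alternative
that duplicated genes have greater depth:

    D+ = sup_x [ F̂_single(x) − F̂_dup(x) ],
    p  = exp( −2 D+² n₁n₂ / (n₁+n₂) )

with a label-permutation p-value available as a finite-sample alternative.
A non-significant result (p > α at α = 0.05) supports the artifact
interpretation. The built-in **X-vs-autosome control** applies the same
test to autosomal versus X-linked genes in a male sample (hemizygous X at
half depth), demonstrating the power to detect a two-fold copy-number
shift.

**Sex-scaffold scan.** Per-scaffold normalized male/female depth ratio
`R = (male mean / male normalizer) / (female mean / female normalizer)`
over 100-kb windows with terminal windows removed; `R ≈ 0.5` flags
X-linked scaffolds, `R ≈ 1` autosomes.

**Heterozygosity / phasing profile.** SNVs are called from strand-resolved
DP4 pileup counts; the B-allele frequency `BAF = (alt_f+alt_r)/DP4-total`
is ~0.5 at heterozygous diploid sites. Phase-block concordance reports SNV
density, the fraction of SNVs inside phased blocks, heterozygous-but-
unphased intervals and low-heterozygosity (inbred or hemizygous) scaffolds.

**Locus tools.** Strand-aware clustering of transcripts into loci by
exonic overlap, one-random-isoform-per-locus sampling (de-biasing
transcriptome-mode BUSCO duplication estimates), and reference/query locus
overlap with opposite-strand (anti-sense artifact) flagging.

Everything runs end-to-end on a bundled diploid genome + paired-end read
simulator with complete truth tables, or on real data via BAM
(`load_alignments()`), BUSCO full tables, VCF, BED and GTF/GFF.

## Worked example

Simulate a diploid genome, label 30% of marker genes "duplicated" by
building an artifact rendering that carries both haplotypes of those loci,
then map reads to the *collapsed* rendering and test:

```r
library(haplodepth)

cfg    <- sim_config(n_autosomes = 3, n_x_scaffolds = 0,
                     scaffold_length = 5e5, coverage = 30,
                     artifact_fraction = 0.3, seed = 1)
genome <- simulate_genome(cfg)
genes  <- place_marker_genes(genome, n_autosomal = 60)
rend   <- render_assemblies(genome, genes)
genes  <- assign_duplication_status(genes, rend$artifact)

reads  <- simulate_reads(genome, "female")
aln    <- place_reads(reads, rend$collapsed, seed = 2)
track  <- depth_track(aln, min_mapq = 1)
duplication_artifact_test(track, genes)
#> Duplication-artifact depth test (alpha = 0.05)
#> -- track 'depth':
#>    median depth: duplicated 29.00, single-copy 29.35 (ratio 0.99)
#>    KS one-sided: D+ = 0.119, p = 0.6997 -> no depth excess: consistent with haplotype artifacts
```

The labelled genes are haplotype artifacts, and read depth says so: both
classes sit at the 30x simulated coverage. Making the same loci *truly*
duplicated (tandem copies in both haplotypes) flips the verdict:

```r
dup_loci <- genes[genes$status == "duplicated", c("scaffold", "start", "end")]
genome2  <- apply_true_duplication(genome, dup_loci)
reads2   <- simulate_reads(genome2, "female")
aln2     <- place_reads(reads2, rend$collapsed, seed = 3)
duplication_artifact_test(depth_track(aln2, min_mapq = 1), genes)
#> Duplication-artifact depth test (alpha = 0.05)
#> -- track 'depth':
#>    median depth: duplicated 57.65, single-copy 29.55 (ratio 1.95)
#>    KS one-sided: D+ = 1.000, p = 1.137e-11 -> depth supports true duplication
```

The duplicated class now maps at twice the single-copy depth (57.65 vs
29.55) and the one-sided KS test rejects decisively.

See also `scaffold_ratio()` / `classify_scaffolds()` for the sex scan,
`call_snvs()` / `phase_concordance()` / `plot_baf()` for the
heterozygosity profile, and `cluster_loci()` / `one_isoform_per_locus()` /
`overlap_loci()` for annotation comparison. A thin command-line wrapper
with `simulate`, `depth`, `dup-test`, `sexscan` and `baf` subcommands is
installed at `inst/scripts/haplodepth`.

## Package layout

| Area | Functions |
| --- | --- |
| simulation | `sim_config`, `simulate_genome`, `render_assemblies`, `apply_true_duplication`, `simulate_reads`, `place_marker_genes` |
| placement & depth | `place_reads`, `load_alignments`, `depth_track`, `truth_depth_track`, `pileup_counts` |
| duplication diagnostics | `mean_depth_per_gene`, `ks_one_sided`, `duplication_artifact_test`, `x_autosome_control`, `parse_busco_table` |
| sex scan | `windowed_depth`, `scaffold_ratio`, `classify_scaffolds` |
| heterozygosity | `call_snvs`, `compute_baf`, `phase_concordance`, `write_vcf`/`read_vcf`, `plot_baf` |
| locus tools | `cluster_loci`, `one_isoform_per_locus`, `overlap_loci`, `read_transcripts`/`write_transcripts` |
| calibration | `artifact_scenario_replicates`, `xa_control_replicates`, `sexscan_replicates` |
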