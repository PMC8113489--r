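---
title: "Depth-based validation of haplotype-resolved assemblies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-based validation of haplotype-resolved assemblies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(haplodepth)
```

This vignette explains the models and procedures behind `haplodepth`, the
assumptions they rest on, and the design decisions taken where more than
one reasonable choice existed. It states no empirical results beyond what
the package's test suite and `scripts/acceptance.R` compute themselves.

## 1. The duplication-artifact depth test

### Model

Let an assembly represent each locus once (a collapsed pseudo-haplotype),
and let a set of conserved marker genes carry *duplicated* /
*single-copy* labels assigned by an external completeness tool (BUSCO) run
on some assembly under suspicion. Reads from the sequenced individual are
mapped to the collapsed assembly, and for each gene we take the mean
mapped depth over the complete gene interval, zero-depth bases included.

Two hypotheses make sharply different predictions for the depth
distribution of the duplicated-labelled class relative to the single-copy
class:

* **True duplication, erroneously collapsed**: both genomic copies' reads
  pile onto the one assembly copy, expected depth ratio ~2.
* **Haplotype-induced duplication artifact**: the label reflects the
  suspicious assembly having retained both haplotypes of the locus; the
  genome has one copy per haplotype, expected depth ratio 1.

The comparison is a one-sided two-sample Kolmogorov–Smirnov test with the
alternative that the duplicated class is stochastically greater:
\(D^+ = \sup_x[\hat F_{\text{single}}(x) - \hat F_{\text{dup}}(x)]\),
evaluated exactly over the pooled sample points.

### Assumptions

* Depth is proportional to copy number (no strong mappability or GC bias
  at gene scale). MAPQ-0 removal and repeat-mask filtering exist to bring
  real data closer to this assumption; the test is conventionally run both
  with and without the MAPQ filter as a robustness check
  (`duplication_artifact_test()` accepts a named list of tracks).
* Gene labels are exchangeable under the null: duplicated-labelled genes
  are an unbiased sample of ordinary loci apart from their label.
* Copy number is consistent across pooled individuals if the read set
  comes from more than one.

### The p-value

The default p-value is the classical one-sided asymptotic tail
\(p = \exp(-2 D^{+2} n_1 n_2/(n_1+n_2))\), clamped to \((0,1]\) — the form
R's `ks.test` uses for one-sided two-sample alternatives (verified against
it in the test suite). At the class sizes the diagnostic is used with
(tens of genes per class), the asymptotic form is mildly conservative;
the package therefore also offers `method = "permutation"` (label
permutation, default 2000 draws) as a finite-sample alternative. The
type-I behaviour of the default is measured directly: over 200 simulated
null replicates the acceptance suite requires the rejection fraction at
\(\alpha = 0.05\) to lie in \(5\% \pm 3\%\).

### The positive control

`x_autosome_control()` applies the identical machinery to autosomal vs
X-linked genes. In a male sample the X is hemizygous, so the control
carries a genuine two-fold copy-number shift and must reject; in a female
it carries none and must not. This demonstrates, inside each analysis, that
the test had the power to see the effect it failed to find in the
artifact case.

## 2. Sex-scaffold scan

Male and female depth tracks on the same assembly are windowed
(non-overlapping, exactly `window` bp; default 100 kb, the conventional
scale for scaffold-level copy-number structure). The trailing partial
window is always dropped; with `drop_terminal` (default) the first and
last full windows are dropped too, because scaffold ends carry assembly-
edge and alignment-edge depth artifacts. Scaffolds with fewer than three
retained windows are reported but never classified — a deliberate
restriction to scaffolds long enough for a stable mean.

The ratio is normalized per sample. Default `autosomal_median` scales each
sample by the median of its retained window means: with autosomes
dominating the assembly this is the autosomal depth level, it is exactly
invariant to global depth rescaling (tested), and it does not require the
two read sets to have been subsampled to equal input. `total_bases`
divides by the genome-wide mean depth instead, reproducing the
equal-input-bases logic; it shifts both bands upward when a large
hemizygous fraction depresses the male genome-wide mean, which is why it
is not the default.

Classification bands are configurable; defaults put "~0.5" at
\([0.35, 0.65]\) and "~1" at \([0.8, 1.2]\). The gap between the bands is
intentional: ratios in no-man's-land (e.g. 0.72) stay unclassified rather
than being forced into a call.

## 3. Heterozygosity and phasing profile

`pileup_counts()` accumulates strand-resolved base counts (DP4 semantics:
ref-forward, ref-reverse, alt-forward, alt-reverse, with the alternate
defined as the most frequent non-reference base). `call_snvs()` is a
threshold caller: a site is called when ref+alt depth ≥ `min_depth`
(default 10) and alternate fraction ≥ `min_alt_fraction` (default 0.2).
It deliberately stands in for a genotype-likelihood caller only on the
kind of data the simulator produces; the defaults were chosen so that at
30x with percent-scale substitution error, false calls stay below 1% of
the truth count while heterozygous sites (alternate fraction ~0.5 with
binomial sampling noise) are retained with high probability. Both
thresholds are exposed.

B-allele frequency is \((\text{alt}_f+\text{alt}_r)/\text{DP4 total}\);
heterozygous diploid sites are expected at ~0.5, which is the package's
acceptance expectation at 30x (tolerance 0.02 on the mean across ≥1000
sites).

`phase_concordance()` thresholds: a scaffold is flagged low-heterozygosity
below 0.1 SNV/kb (an order of magnitude under the simulator's default
4 SNV/kb, separating runs of homozygosity clearly from ordinary diploid
scaffolds); a heterozygous-but-unphased interval requires ≥5 consecutive
outside-block SNVs spanning ≥10 kb, so isolated stragglers near block
edges are not reported as phasing failures. Both are tie-break style
conventions — the phenomena are qualitative — and both are parameters.

## 4. The simulator

The generator emulates the statistical structure the diagnostics assume:

* **Diploid genome**: haplotype 1 is an i.i.d. ancestor sequence at the
  configured GC content (default 0.3221, a typical AT-rich insect
  composition); haplotype 2 differs by heterozygous SNVs (default
  4 × 10⁻³/bp, matching a sub-0.4% divergence regime) and short indels of
  1–10 bp drawn uniformly (default 4 × 10⁻⁴/bp, an order of magnitude
  rarer than SNVs). An optional contiguous homozygous block per scaffold
  emulates inbreeding-derived runs of homozygosity.
* **Phase blocks**: the heterozygous complement of each scaffold is cut
  into 100-kb chunks, each marked phased with probability
  1 − `unphased_fraction` (default 0.2), emulating an incompletely phased
  assembly where phased regions coincide with heterozygosity but some
  heterozygous segments remain unphased.
* **Assembly renderings**: `collapsed` is haplotype 1; `artifact` appends
  the haplotype-2 copy (with a fixed 1-kb flank, as a separate scaffold)
  of a randomly selected fraction of marker loci — the megabubbles-style
  injection of second haplotypes that creates duplication artifacts. The
  junction structure of real artifact scaffolds is not modelled; for
  depth diagnostics only the presence of the second near-identical copy
  matters. `apply_true_duplication()` instead makes loci genuinely
  two-copy in *both* haplotypes (tandem), with truth tables and coordinate
  maps updated.
* **Reads**: fragments are sampled uniformly from the haplotype copies
  present in the individual — both haplotypes everywhere in females, one
  X copy in males. The pair count is set so that expected autosomal depth
  equals `coverage`; male X depth is then coverage/2 by construction
  rather than by a separate parameter. Inserts are
  normal(350, 50) bp (truncated at read length), substitution errors
  i.i.d. at `error_rate` (default 10⁻³, ordinary short-read scale), base
  qualities constant Q30 (never used downstream).

Coordinates are 0-based half-open internally everywhere; BED stays
0-based at I/O, VCF/GTF/BUSCO tables are converted to their 1-based
conventions at the boundary. All operations are bit-reproducible given the
configuration seed.

**What the simulator does not emulate** — and what passing tests therefore
do not show about real data: mappability and GC-coverage bias, repeat
structure (masks are supported but no repeats are generated), structural
variation beyond the specified duplications, recombination, population
samples, quality-score error profiles, and gapped/spliced alignment. The
diagnostics' statistical calibration is demonstrated under the simulator's
idealized conditions; on real data the MAPQ/mask filters carry the burden
of approximating them.

## 5. The built-in placer

`place_reads()` is an exact-seed placer, not a general aligner: it indexes
every 31-mer of the assembly, seeds each read at five offsets on both
strands, and extends by ungapped full-length comparison. Reads whose best
score is shared by two or more placements are assigned one of them
uniformly at random and flagged MAPQ 0 — the multi-mapper convention the
depth filters act on; unique best placements get MAPQ 60.

The mismatch budget defaults to
`max(ceil(0.04·L), ceil(3·error_rate·L))`. The first term is the
important one: it tolerates haplotype divergence, so that a read drawn
from haplotype 2 still places across heterozygous sites of a haplotype-1
assembly — exactly what a practical aligner does, and what the BAF ~0.5
expectation requires. A budget tied only to sequencing error would
silently discard the alternate-allele evidence at heterozygous sites for
high-quality reads.

Two known, accepted losses: reads spanning a haplotype-2 indel have no
ungapped placement and may go unplaced (a small, locus-independent
fraction at the default indel rate), and reads whose five seed positions
all cover variants are not found (negligible at sub-percent divergence).
Both losses affect only haplotype-2 reads, which produces a slight
reference bias in depth — visible, for instance, as male/female X ratios a
few percent above 0.5, since male X reads come exclusively from the
haplotype matching the assembly. This mirrors real reference bias and
stays well inside the classification bands.

`truth_depth_track()` is the sequence-free fast path: it computes the
depth reads would produce if placed at their true origin, lifting
haplotype-2 coordinates through the indel map (and folding tandem
duplications back onto the collapsed copy). A dedicated test requires the
placer and the truth track to agree at ≥99% of bases for indel-free
error-free reads, which justifies using the truth path inside the
replicate drivers.

## 6. Replicate drivers and problem sizes

Calibration and power are measured with `artifact_scenario_replicates()`,
`xa_control_replicates()` and `sexscan_replicates()`. Each replicate
re-simulates variants, marker genes, and read placements on a fixed set of
ancestral scaffolds; the ancestor is not regenerated per replicate because
no depth statistic sees base composition, only positions. Reads in these
drivers are placements only (section 5); the full sequence-level pipeline
is exercised separately in the single-run analyses and acceptance script.

Reference problem sizes, chosen as the smallest at which the effects are
comfortably resolved: 5 × 1 Mb scaffolds (plus 2 × 1 Mb X scaffolds where
sex matters), 100 marker genes of 3 kb with 30% labelled duplicated,
30x coverage; 200 replicates for type-I calibration, 50 for power, 20
seeds for the sex-linked analyses; SNV-rate recovery and BAF use 300-kb
scaffolds where ≥1000 heterozygous sites still accrue. The acceptance
script runs the full-pipeline analyses at the 1-Mb scale with seeds
derived from its `--seed` argument.

## 7. Locus clustering choices

Loci are connected components of the graph joining same-scaffold,
same-strand transcripts that share ≥1 bp of exonic sequence. One base is
the documented threshold (configurable); clustering tools in this space
are overlap-based but publish no threshold, and the package implements
exon-overlap components only — intron-chain containment beyond exonic
overlap is not considered, which can merge slightly less aggressively than
annotation-comparison tools that do. Single-exon transcripts with unknown
strand are excluded from clustering and reported separately, since
strand-aware clustering is undefined for them. Locus identifiers are
assigned by (scaffold, leftmost coordinate), making clustering
deterministic and order-invariant (tested). Opposite-strand exonic
overlaps between reference and query loci are flagged as anti-sense
artifact candidates but never contribute to overlap counts.

## 8. Known limitations

* The placer is ungapped and unspliced; real-data workflows should map
  with a general aligner and enter via `load_alignments()`.
* The threshold SNV caller has no genotype-likelihood model; it is not
  intended for real variant calling, only for closing the loop on
  simulated data and for BAF profiling given DP4 counts from any caller.
* The asymptotic one-sided KS p-value is approximate at small class
  sizes; use the permutation option when a class has fewer than ~10
  genes.
* Sex-scaffold calls assume the female is the homogametic sex (X/Y-style
  systems); Y/W detection is out of scope.
* `apply_true_duplication()` assumes duplication loci clear of indel
  edit footprints at their boundaries (the simulator's gene placement
  guarantees this); truth variants exactly at an excised boundary would
  be shifted conservatively.
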