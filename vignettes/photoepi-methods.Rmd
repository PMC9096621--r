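---
title: "Methods and design of photoepi"
author: "photoepi maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of photoepi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photoepi)
```

`photoepi` implements the statistical core of an integrative
methylome/transcriptome/sRNAome comparison between two plant genotypes
(typically a photoreceptor mutant against its wild type, profiled at one
or more fruit-development stages). This vignette describes the models,
the rules each stage applies, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, and the
design decisions taken where the methodology left genuine choices.

## Coordinates and formats

All internal coordinates are 0-based half-open (the BED convention).
The GFF3 reader and the cytosine-report reader convert from 1-based
input on ingest; the writers convert back. These converters are the only
places where ±1 arithmetic occurs, which confines the usual off-by-one
failure modes to two functions that are round-trip tested.

The cytosine report follows the Bismark per-cytosine dialect: `chrom`,
`pos` (1-based), `strand`, methylated count, unmethylated count,
context. TE features in GFF3 are recognised by a configurable type list
(default `transposable_element`, `repeat_region`) because annotation
dialects differ in how they label repeats.

## Differential methylation

A cytosine's context is CG, CHG or CHH (H = A, C or T), read from the
two bases 3' of the cytosine on its own strand; minus-strand sites apply
the same rule to the reverse complement. Sites closer than two bases to
a chromosome end, where the trinucleotide cannot be completed, are
classed CHH (the asymmetric catch-all). The rule is tested against an
exhaustive enumeration of all 64 trinucleotide completions
(16 CG / 12 CHG / 36 CHH).

Differential methylation between two (pooled) samples is assessed at two
levels within each context:

* **Per cytosine** — a two-sided Fisher exact test of
  `[[meth_a, unmeth_a], [meth_b, unmeth_b]]`, over all cytosines covered
  at least `min_coverage` (default 10×) in *both* samples, BH-adjusted
  across all tested cytosines. A cytosine is a DMC when its adjusted
  p-value is below `c_fdr` (default 0.05) and its absolute methylation
  difference reaches `min_diff_c` (default 0, i.e. the FDR rule alone;
  0.25 mimics a common per-cytosine difference cutoff).
* **Per region** — a Fisher test on the counts pooled over the region's
  cytosines, BH-adjusted across regions.

A region (promoter, or sRNA-cluster-targeted region) is called
hyper- or hypomethylated — by the sign of its pooled difference, test
minus reference — only when the region-level adjusted p-value is below
`region_fdr` (default 0.05) **and** it contains at least `min_dmc`
(default 10) DMCs in that context. Applying both the region FDR and the
10-DMC floor is deliberately the conservative reading of a rule that
could be interpreted per-cytosine or per-region; both thresholds are
arguments. BH was chosen as the adjustment throughout because it is
standard and reproducible.

Promoters are the 2 kb upstream of the TSS, strand-aware and clipped at
chromosome edges; genes whose promoter clips to zero length are dropped
with a warning rather than silently tested on nothing.

Because the design this models pools biological replicates into a
single library per genotype, the region test sees no replicate-level
variance; with biological overdispersion present the pooled Fisher test
is anticonservative at the margin, and it is the 10-DMC requirement that
keeps the null call rate at or below the nominal level (measured 0 calls
on null simulations at 20× coverage). This is a documented limitation of
pooled designs, not of the implementation.

Binned chromosome profiles tile each chromosome with 1-Mb windows (the
last window may be short), report the pooled methylation level per
context over cytosines covered in all compared samples, classify each
bin as hypo-/hyper-methylated at ±5% difference, and annotate gene and
TE density as feature nucleotides per million.

## Differential counts

Gene-level RNA-seq counts and sRNA-cluster counts share one testing
path. Features with counts per million below 2 in more than
`n - min_samples` samples are removed first (`min_samples` defaults to
the smallest group size — the rule's sample requirement is exposed
because reasonable analysts disagree on it). Normalisation is
total-count (library-size) scaling; TMM-style composition correction is
deliberately out of scope, and the synthetic-data tests show the
composition bias this implies when planted changes are unbalanced.

The test is a self-contained two-group negative-binomial
likelihood-ratio test:

1. per-feature dispersion by method of moments on normalised counts,
   pooled within groups;
2. shrinkage 50/50 toward the common dispersion, floored at `1e-4`;
3. NB means refitted by Newton iterations per group and under the null
   with the shrunk dispersion fixed; LRT against `chi-squared(1)`;
4. BH adjustment; fold changes from normalised group means with a
   prior count of 0.5; the reference group is the first factor level
   (or alphabetically first label).

The common dispersion is the *untrimmed* mean of the per-feature moment
estimates (the `trim` argument exists for outlier-heavy data). This was
settled by a calibration study: per-feature moment estimates at n = 3
per group are strongly right-skewed, so a symmetric trim biases the
common dispersion downward and inflates the type-I error of the LRT
(measured 0.059 at trim 0 versus 0.071 at trim 0.1 against a nominal
0.05, over ten null simulations of 2,000 features). The residual ~0.01
inflation is the cost of treating an n = 3 moment estimate as known; it
is accepted and measured rather than hidden.

Exact invariance under jointly rescaling one library's counts and
library size is **not** a property of a genuine count likelihood —
tripling a library's counts adds counting information — so the package
asserts near-invariance (fold changes within 0.01, p-values within
0.05, identical status calls) instead of pretending to exactness.

## sRNA clusters

Cluster calling is a declared simplification of aligner-native cluster
discovery: reads of 18–24 nt from all samples are unioned, coverage
islands closer than `pad = 75` bp are merged, and islands supported by
fewer than `min_reads = 3` reads are dropped. No multi-mapper
redistribution and no phasing analysis are attempted — downstream
statistics need intervals and counts, not placement internals. Calling
on the union of samples guarantees every sample has a count for every
cluster, which the differential test requires.

Clusters are categorised with precedence gene body > promoter > TE >
intergenic; overlap means at least 1 bp of intersection (configurable),
and the linked gene is the one with the largest overlap. The precedence
order is a package decision — it makes the four categories a partition,
which the category-count outputs rely on.

sCTGR methylation delegates to the region caller with cluster intervals
as regions and additionally records whether the pooled difference
reaches the 5% floor used by the sRNA × methylation association.

## Positional motif enrichment

PFMs become log2-odds PWMs with a total pseudocount of 1 per column
against a uniform background (0.25 per base; the background is an
argument — genome-composition backgrounds are supported but not the
default, since the scanning background of the original analyses is not
recorded). The score threshold for a scan p-value (default `1e-5`) is
computed *exactly* by dynamic programming over the per-column score
distributions, with scores discretised to 1e-3 bits; the DP tail is
tested against exhaustive enumeration of all sequences up to motif
length 8. Both strands of the 20-kb upstream region of every gene are
scanned; a hit's distance is measured from the TSS to the hit's nearest
edge, 0 at the TSS.

The enrichment statistic compares the cumulative fraction of genes in a
regulated set having a hit within distance *x* against the same curve
for all genes, on a grid from 0 to 20 kb in 100-bp steps. The
per-position difference is the enrichment score (ES); the scalar summary
is its maximum over positions (the standard scan reduction; mean-ES and
ES-at-a-position are selectable). The null distribution comes from
random gene subsets of the same size drawn without replacement
(default 1,000 permutations), giving `z = (ES - mean) / sd` and
`p = (1 + #{null >= observed}) / (n_perm + 1)`. Per-gene minimum hit
distances are precomputed once, so a thousand permutations take well
under a second. Multiple hits per gene count once by construction
(curves are per-gene indicators), so strand-duplicate hits at one
position are harmless. When a TF class has several PFMs, hits are pooled
across the class's PFMs before the curve is built.

One calibration caveat is documented and tested: with very small
regulated sets (fewer than ~10 genes) the max-ES null is highly
discrete and the permutation p-value is conservative. Calibration is
therefore assessed at set sizes of ~25 on a 100-gene universe, where the
measured 0.05-level rejection rate on null landscapes is 0.035–0.055.

## Integration statistics

* **DEG × DMP overlap** joins gene-level differential-expression calls
  with promoter methylation calls per context; a gene is a DMP if any
  context is non-`ns`. Counts, both percentages, and a per-gene table
  (fold change, per-context promoter differences, statuses) are emitted.
* **sRNA × methylation association** classifies each covered cluster as
  differentially accumulated (count test non-`ns`) and differentially
  methylated (region test non-`ns` *and* pooled difference ≥ 5%) and
  applies a two-sided Fisher exact test to the 2×2 table, with a
  Haldane 0.5 correction for the odds ratio when a cell is empty.
  Requiring both significance and the 5% floor combines the Methods-
  style definition of differential methylation with the display floor of
  the original association analysis.
* **Promoter vs gene-body sRNA** collects cluster fold changes linked
  to up- and downregulated genes, split by compartment, and runs a
  two-sided Wilcoxon–Mann–Whitney test: exact enumeration when both
  sides have ≤ 8 observations (ties handled exactly), otherwise the
  normal approximation with tie and continuity corrections. Both the
  location contrast within a direction and the direction contrast
  within a location are reported, since either reading of the original
  comparison is defensible. Genes with clusters in both compartments
  contribute to both strata.
* **Category distributions** report per-category fractions over the
  categorised genes of a set, collapsing categories below 2% into
  `other`; a warning is raised when the category map covers less than
  half of the set.

## The synthetic-study generator

The generator builds a complete miniature study under one seed, and its
defaults are the study conditions the tests exercise:

| parameter | default | meaning |
|---|---|---|
| `n_chroms`, `chrom_len` | 2 × 400 kb | miniature multi-chromosome genome |
| `gc` | 0.36 | tomato-like GC content |
| `context_means` | CG 0.80 / CHG 0.67 / CHH 0.23 | context methylation means |
| `coverage_mean` | 20 | Poisson per-cytosine coverage |
| `overdispersion` | 0.03 | beta-binomial intra-class correlation |
| `dmr_fraction`, `dmr_delta` | 0.15, −0.3 | planted promoter DMRs |
| `n_samples_per_group` | 3 | count replicates (methylomes stay pooled, 1/group) |
| `deg_fraction`, `deg_lfc` | 0.1, 2 | planted DEGs |
| `nb_dispersion` | 0.05 | NB dispersion of counts |
| `motif_rate_bg`, `motif_p_extra`, `motif_tss_window` | 1, 0.6, 1 kb | background and planted TSS-proximal motif occurrences |

Genes are placed preferentially on the outer thirds of each chromosome
and TEs in the middle third (emulating gene-rich arms versus TE-rich
pericentromeres); features never overlap. Methylation counts are
beta-binomial rather than binomial because biological overdispersion is
what makes differential-methylation calling hard; a plain binomial
generator would flatter the caller. One pooled methylome per group
mirrors the pooled-WGBS design; three replicates per group mirror the
count designs. sRNA reads of 18–24 nt are emitted at 100–400 bp loci
with NB-distributed counts so the cluster caller is exercised from raw
intervals. Motif occurrences are planted as distances, and optionally as
consensus sequence written into the genome so the scanner is exercised
end to end. `couple_dmr_to_deg` places the planted DMRs on planted-DEG
promoters, giving the integration stage a recoverable signal.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: realistic TE sequence families and
methylation spreading from TEs, linkage between gene-body methylation
and expression (no quantitative model for it exists in the source
material, so only the optional DEG–DMR coupling is provided), read-level
artefacts (the generator emits counts and intervals, not FASTQ), spatial
autocorrelation of methylation beyond planted regions, and multi-factor
designs.

## Numerical choices and degenerate inputs

* Fisher p-values sum hypergeometric probabilities `<= p_obs` with a
  `1 + 1e-7` relative tie guard (the same convention as
  `stats::fisher.test`, against which the implementation is tested).
* The PWM DP discretises scores to 1e-3 bits; the threshold is the
  smallest discretised score with tail probability below the target.
* NB mean fits run damped Newton iterations on log-mean (steps clamped
  to ±2, 50 iterations, tolerance 1e-10); all-zero features get a tiny
  positive mean so likelihood differences stay finite.
* Regions with zero covered cytosines are reported `ns` with
  `n_covered_c = 0` and an `NA` p-value — never treated as level 0.
* Degenerate permutation nulls (`sd = 0`) report `z = NA` with the
  permutation p-value still valid.
* A zero margin in the association table fixes `p = 1` with a warning.
* Bins without covered cytosines have `NA` levels and status.

## Determinism and the pipeline

Every simulation stage derives its own sub-seed from the master seed, so
identical configurations are byte-identical across runs while stages
remain independently reproducible. `run_pipeline()` validates its
configuration against an explicit schema (unknown keys are errors, so a
misspelt parameter cannot silently fall back to a default), runs the
stages in dependency order with all coupling through files, and writes a
manifest with parameters, input checksums, seed and package version.
Floating-point columns in TSV outputs are formatted to six significant
digits so outputs are byte-stable; category counts in the JSON summary
are keyed by fixed factor levels so output does not depend on the
session locale.

The bundled demo (`demo_config()`) uses two 200-kb chromosomes, 40
genes, 20 TEs, 60 sRNA loci and planted effects throughout; it runs the
full pipeline in a few seconds. The test suite's simulation sizes
(chromosomes of 50–500 kb, 100–2,000 count features, 200 permutation
repetitions) were chosen as the smallest problems at which the
calibration and recovery statements are statistically meaningful.

## Known limitations

* The NB test is calibrated but approximate at n = 3 per group
  (~0.01 type-I inflation, measured and documented above); it is not a
  numerical reimplementation of any specific published testing
  framework, and makes no attempt at bit-compatibility with one.
* The pooled methylome design precludes replicate-level variance in the
  region test; the 10-DMC floor is what controls its practical error
  rate.
* Total-count normalisation carries composition bias under unbalanced
  differential expression.
* Cluster calling ignores multi-mapping and strandedness.
* The permutation p-value is conservative for very small regulated sets.
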