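---
title: "Quantifying strain-level gene content variation from metagenomic coverage"
author: "panstrain authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying strain-level gene content variation from metagenomic coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panstrain)
```

## The problem

Phylogenetic marker genes identify which bacterial species live in a gut
community, but strains of one species can carry substantially different gene
complements. When metagenomic reads are recruited to a species'
representative reference genome, genes of that genome that attract no reads
in a given individual are candidate gene deletions in that individual's
strain population. `panstrain` turns per-gene read-coverage summaries into a
quantitative account of this variation: which genes are core to a cohort,
which are accessory, how large the accessory complement would become with
more individuals, how missing genes cluster into contiguous deletion blocks
along the genome, and how different two individuals' strain gene contents
are.

Because the approach only sees the reference, gene *insertions* carried by
an individual's strain but absent from the reference are invisible; every
accessory-content estimate the package produces is therefore a lower bound,
and is documented as such.

## Presence calling and filtering

A gene is called **present** in a sample when reads cover at least a
fraction `lengthCutoff` of its length (`callGenePresence()`, default 0.40,
boundary inclusive). The cutoff suppresses presence calls caused by
spuriously mapped reads or reads from orthologues of close relatives. It can
be recalibrated per dataset with `calibrateLengthCutoff()`, which sweeps
cutoffs 0, 0.1, ..., 1.0 over biological replicate pairs and picks the value
minimising the mean replicate-to-replicate gene content distance; ties break
toward the smallest minimising cutoff (retaining more genes), and a cutoff
at which both replicates call no genes at all contributes zero difference
(identical calls).

A sample×species combination enters the analysis only if
(`filterSampleSpecies()`):

1. **breadth** — at least 40% of the genome is covered by at least one read;
2. **markers** — all flagged universal single-copy marker genes are called
   present (the species, not a relative with similar composition, was
   detected);
3. **depth** — mean genome coverage is at least 30×, so presence calls are
   not limited by sequencing effort.

All three thresholds read "at least" as `>=`. When genome-wide breadth and
depth are not supplied with the profile they are recomputed from the
per-gene records weighted by gene length; this ignores intergenic sequence
and is therefore an approximation, which is why externally computed values
take precedence when present. Whether the 30× depth is averaged over all
genome positions including uncovered ones is treated the same way: supplied
values are authoritative, the gene-level fallback is documented.

A species is analysed only when at least `k = 10` individuals pass; `k`
individuals are then drawn uniformly at random (seeded) — or all of them
when exactly `k` pass — and one **primary sample** per individual is kept.
The primary sample is the passing sample with the earliest time point
(lowest lane as tie-break); this rule is a deterministic convention, chosen
because selection among a handful of equivalent samples should not be a
source of run-to-run variation.

## Core, accessory, unobserved

Over the cohort's presence matrix (`classifyGenes()`): a gene present in
every individual is **core**; present in none, **unobserved** (specific to
the reference genome); otherwise **accessory**. The three labels partition
the reference genes.

## Rarefaction and extrapolation

`subsampleFractions()` computes, for each subsample size *k*, the fraction
of genes missing in at least one member of a *k*-subset of individuals. Two
conventions were genuinely open:

* **Denominator.** The fraction's denominator is fixed to the universe of
  genes observed in ≥1 of *all* cohort individuals, not recomputed per
  subset. With a fixed universe the mean fraction is provably
  non-decreasing in *k* (the event "missing in at least one of *k*" can
  only gain probability as the subset grows), and the value at *k = n*
  recovers the cohort accessory fraction exactly. The package asserts this
  monotonicity on every exhaustive run; under capped random subsampling it
  holds in expectation, and only a material drop (> 0.005) triggers a
  warning.
* **Mean vs median.** Model fitting consumes the per-size mean by default;
  the median is exposed via `stat = "median"` for users who prefer a
  robust curve.

All C(n, k) combinations are enumerated when no cap is set (the intended
mode for 10-individual cohorts, where the largest size has 252
combinations); larger cohorts use up to 500 distinct random combinations
per size, drawn by rejection under a seed.

`fitAccessoryModel()` fits the per-size fractions with one of four
families:

| family | form | asymptote |
|---|---|---|
| exponential | $f(k) = a - b\,e^{-k/c}$ | $a$ |
| negative exponential | $f(k) = a\,(1 - e^{-bk})$ | $a$ |
| power law | $f(k) = a\,k^{b}$ | none (unbounded for $b>0$) |
| monotone spline | Fritsch–Carlson cubic through the means | none |

The three-parameter exponential form was chosen because it has a finite
asymptote, reduces to pure saturation, and — under the package's own
generative model, where each variable locus is independently absent with a
fixed per-individual rate $q$ — is exact: the expected curve is
$d/u - (d/u)\,e^{k\ln(1-q)}$. Fits use Levenberg–Marquardt
(`minpack.lm::nlsLM`) with analytic starts ($a_0$ = last mean + 0.05, $b_0,
c_0$ from a log-linear fit of the residuals $a_0 - f$) and up to 20 jittered
restarts, keeping the best residual sum of squares; a constant table is
handled as the degenerate limit $b = 0$ with the asymptote equal to the
constant. `estimateAccessoryPercent()` converts the asymptote to a
percentage; for the power law it returns the value at a stated horizon
(default *k* = 100) with a warning, and for the spline it refuses and points
at `predict()` — neither family has an asymptote, and silently reporting one
would be wrong.

`modelDeviation()` scores a fitted curve against **expected fractions** —
the same subsample statistic computed on all available individuals beyond
the analysis cohort — as the mean absolute gap in percentage points. In the
package's validation the exponential family consistently extrapolates
saturating cohorts better than the power law, which mirrors how these two
classic pan-genome models behave on saturating data.

## Deletion blocks

`findDeletionBlocks()` extracts maximal runs of absent genes per individual
within each contig; runs never cross contig boundaries, so on fragmented
assemblies one biological block can be reported as two. Every absent gene
belongs to exactly one block. `classifyBlocks()` assigns classes:

* **single** — one gene, interior, both flanking genes present. "Both
  flanks" is interpreted as one gene on each side (by maximality these are
  always present for an interior size-1 run); the stricter two-on-each-side
  reading is available as `flankDepth = 2`.
* **large** — at least `minLarge` (default 50) genes.
* size-1 blocks at a contig start or end are flagged **not counted**, so
  contig breaks do not inflate the single-gene tally. The exclusion applies
  only to size-1 blocks; multi-gene edge blocks stay counted but carry the
  edge flag, and `blockSizeSpectrum(excludeEdgeBlocks = TRUE)` emits the
  alternative tally for users who want edge blocks dropped entirely.

`blockSizeSpectrum()` computes, per individual, the percentage of counted
blocks and of counted deleted genes at each block size, then averages
across individuals (absent sizes contribute zero; individuals with no
counted blocks are omitted with a warning).

## Distances, tests, diagnostics

`pairwiseDifference()` implements the symmetric-difference distance: genes
present in exactly one individual divided by genes present in either — the
Jaccard distance on presence sets, and a metric (identity, symmetry,
triangle inequality are property-tested). `replicateDifferences()` labels
every sample pair as inter-individual, biological replicate (same
individual, different time points) or technical replicate (same sample,
different lanes). `referenceConditionedDifference()` reproduces the
reference-genome dependency when comparing completely sequenced genomes:
only genes present in the designated reference can contribute, which makes
genome-pair distances commensurable with metagenome-pair distances.

`compareDistanceDistributions()` is a two-sided Wilcoxon–Mann–Whitney test,
exact when both groups have ≤ 20 observations and no ties, otherwise the
tie-corrected normal approximation — exactness where it is cheap, the
standard approximation elsewhere. `fisherEnrichment()` tests
accessory-vs-core enrichment per functional category with the two-sided
Fisher exact test (minimum-likelihood definition, as in `fisher.test`; a
tail-doubling variant is exposed) and Benjamini–Hochberg adjustment — the
conventional choice where only "FDR" is specified.
`abundanceIndependenceCheck()` correlates per-sample accessory fractions
with depth and abundance (Pearson by default, Spearman optional — the
estimator is a user choice, not a claim); it is diagnostic only and gates
nothing, flagging constant inputs instead of failing.

## The synthetic strain community

No public generative model exists for strain populations in a cohort, so
the generator's distributional choices are explicit stand-ins, chosen once
to emulate the regime the pipeline targets and documented here rather than
claimed as biology.

`SimulationConfig()` defaults describe a gut-survey-like regime: 11
species, reference genomes of 2,000 genes on 4 contigs, 40 single-copy
marker genes, 10 individuals per cohort, per-species target accessory
fractions spanning 0.21–0.45, ~3% of reference genes never observed, 50×
mean depth.

* **Variable loci.** A cohort-wide layout of candidate deletion blocks is
  drawn from a size mixture — 35% single-gene, 60% geometric (mean 4), 5%
  uniform on 50–175 genes — and placed uniformly at random without overlap,
  with one-gene gaps, never covering marker genes, and never exceeding half
  the largest contig (a block cannot exceed its contig, and headroom keeps
  placement feasible). Each individual then loses each locus independently
  with probability `deletionRate` (default 0.3). Shared loci of variable
  occupancy are what give real rarefaction curves their saturation; a model
  in which every gene were independently deletable per individual would
  produce curves that climb toward 1 instead of an asymptote, and would
  contradict the saturating behaviour the estimator exists to exploit. The
  number of loci is calibrated so the expected fraction of genes absent in
  ≥1 of *n* individuals, $d\,(1-(1-q)^n)$, hits the configured target; the
  realized fraction is recounted exactly from the emitted matrix and
  reported. `deletionRate` = 0.3 was fixed a priori as a moderate per-locus
  rate that brings the curve near saturation within ten individuals.
* **Markers.** The 40 marker genes sit in one operon-like run per contig —
  spread across contigs, as ribosomal-protein clusters are, while leaving
  long marker-free stretches where large blocks can occur. Markers are
  never deleted (they are universal single-copy genes) and biological
  drift never flips them.
* **Coverage.** Present genes draw covered fractions ≥ 0.5 (mean ≈ 0.93)
  and depths around `meanDepth`; absent genes get exactly zero. Coverage is
  simulated at gene resolution only — the decision rule consumes nothing
  finer, and per-base simulation would add cost without exercising more
  logic. Three noise processes are separated: `presenceNoise` flips a
  gene's observed covered fraction across the 0.40 boundary per sample
  (mapping artefacts, default 0.002); `biologicalNoise` flips true gene
  content between an individual's time points (default 0.01);
  `technicalNoise` flips observations between sequencing lanes of one
  sample (default 0.001), plus a small covered-fraction jitter that cannot
  change a call. The defaults order technical < biological < strain-level
  divergence, the ordering the replicate analysis is designed to detect.

What the generator does **not** emulate: read-level sampling noise, GC or
mappability bias, genuinely novel (non-reference) gene content, SNP-level
divergence, paralog cross-mapping, horizontal transfer dynamics, and
hotspot (genomic-island) placement of variable loci — placement is uniform,
which suffices for correctness testing but understates the spatial
clustering of real accessory regions. Passing tests therefore demonstrate
algorithmic correctness under a controlled model, not robustness to every
artefact of real metagenomes.

## Validation sizes and numerical conventions

The shipped validation uses problem sizes chosen to exercise every code
path while staying comfortably interactive: block-boundary equivalence
against an independent brute-force scanner on 1,000 random multi-contig
genomes; an 11-species × 10-individual × 2,000-gene noiseless community
round-tripped exactly (calls, labels, planted blocks); asymptote recovery
at target fractions 0.20 / 0.32 / 0.45 over 10 seeds against a brute-force
30-individual super-cohort truth, judged by mean absolute error under 5
percentage points with at least 9 of 10 seeds inside the band (the
asymptote is an extrapolation; an occasional seed at the band's edge is
expected noise, and the mean is the estimator a study would report);
exhaustive Fisher agreement with hypergeometric enumeration for every
margin-distinct 2×2 table with N ≤ 60; Jaccard metric axioms on 10,000
random triples; replicate-noise ordering in ≥ 19/20 seeds and equal-noise
non-significance in ≥ 18/20; and exponential-vs-power-law extrapolation
wins in ≥ 9/10 seeds.

Other numerical conventions: combination subsampling guarantees distinct
subsets by rejection; `which.min` tie-breaking selects the smallest cutoff
in calibration; the monotone spline uses `monoH.FC` (well-defined on
non-monotone inputs, unlike Hyman filtering); and all RNG flows from a
single integer seed — fixing it makes communities bit-identical.

## Known limitations

Estimates are conditional on the representative reference genome: a
distant reference inflates apparent deletions, and individual-specific
genes are invisible (everything is a lower bound). Fragmented assemblies
split blocks and can hide single-gene deletions at contig edges; the
package mitigates by edge-flagging and by refusing to count edge singles,
but cannot recover what the assembly does not order. Pooling distances
across species for a single headline number is left to the caller, since
any weighting (per pair, per species) embeds a judgement the package should
not hard-code.
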