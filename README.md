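# panstrain

Strain-level gene content variation of gut bacterial species from
metagenomic coverage profiles.

Strains of one bacterial species can differ substantially in gene content,
and marker-gene profiling cannot see it. When shotgun reads from an
individual's gut metagenome are recruited to a species' representative
reference genome, the reference genes that attract essentially no reads are
candidate gene deletions in that individual's strain population. `panstrain`
implements the full analysis built on that idea, for microbiome researchers
who have per-gene coverage summaries (from any read mapper) and a reference
annotation:

* **presence calling** — a gene is present when reads cover ≥ 40% of its
  length (cutoff recalibratable from biological replicates);
* **filtering** — a sample×species combination is analysed only with ≥ 40%
  genome breadth, all 40 universal single-copy marker genes present, and
  ≥ 30× mean depth; species need ≥ 10 passing individuals;
* **core/accessory classification** — over a 10-individual cohort, genes
  present in all are core, in none unobserved, otherwise accessory;
* **accessory-fraction extrapolation** — rarefaction over subsample sizes
  *k* with the fraction of genes missing in ≥ 1 member, fitted with
  `f(k) = a − b·exp(−k/c)` (plus power-law, negative-exponential and
  monotone-spline alternatives); the asymptote `a` estimates the accessory
  fraction, a lower bound since gene insertions are invisible to
  reference mapping;
* **deletion blocks** — maximal runs of contiguous absent genes per contig,
  classified as single-gene (flanks present; edge singles not counted),
  large (≥ 50 genes) or other, with per-size spectra;
* **distances and tests** — the symmetric-difference (Jaccard) gene content
  distance `|A Δ B| / |A ∪ B|` between individuals and replicates, a
  reference-conditioned variant for sequenced-genome pairs,
  Wilcoxon–Mann–Whitney comparison of distance distributions, and Fisher /
  Benjamini–Hochberg functional-category enrichment of accessory genes;
* **a synthetic strain-community generator** with complete ground truth
  (planted variable loci, replicate structure, separated technical /
  biological / strain-level noise), so the whole pipeline is testable
  without any sequence data.

Data objects follow Bioconductor conventions: references are `GRanges`-based
`ReferenceGeneSet` objects (GFF3 I/O via `rtracklayer`), presence matrices
extend `RangedSummarizedExperiment`, and blocks export as BED.

## Worked example

A single synthetic species with a known 32% target accessory fraction,
analysed end to end:

```r
library(panstrain)

cfg <- SimulationConfig(nSpecies = 1, nGenes = 2000, nIndividuals = 10,
                        trueAccessoryFraction = 0.32, seed = 42)
com   <- simulateCommunity(cfg)
ref   <- com[[1]]$reference
truth <- com[[1]]$truth
truth
#> TruthSet: sp01 - 10 individuals, 2000 genes
#>   realized accessory fraction: 0.3280 (unobserved 0.0300)
#>   129 candidate variable loci; 16 samples

decisions <- do.call(rbind, lapply(com[[1]]$profiles, filterSampleSpecies,
                                   reference = ref))
cohort <- selectCohort(decisions, replicateMap(truth), k = 10, seed = 1)
pm  <- buildPresenceMatrix(com[[1]]$profiles[cohort$sample_id], ref)
attr(classifyGenes(pm), "summary")
#>       core  accessory unobserved
#>       1259        681         60

fit <- fitAccessoryModel(subsampleFractions(pm), "exponential")
estimateAccessoryPercent(fit)
#> [1] 37.39
```

The cohort realized 32.8% accessory genes (absent in ≥ 1 but not all of the
10 individuals) plus 3.0% never observed; the presence calls recover 681
accessory and 60 unobserved genes from noisy coverage, and the exponential
asymptote extrapolates to 37.4% — what the accessory fraction would
approach with more individuals, slightly above the 10-individual count, as
it should be.

```r
blocks <- cohortDeletionBlocks(pm, ref)
head(blockSizeSpectrum(blocks), 3)
#>   size mean_block_frequency_pct mean_gene_fraction_pct total_blocks total_genes
#> 1    1                56.29                  14.60          305         305
#> 2    2                 8.98                   4.83           49          98
#> 3    3                 6.90                   5.33           37         111

rd <- replicateDifferences(pm, replicateMap(truth))
100 * mean(rd$value[rd$comparison_class == "inter_individual"])
#> [1] 14.2
```

Single-gene deletions are the most frequent block class (56% of counted
blocks here), and two individuals' strain populations differ in about 14%
of their observed genes — an order of magnitude above the replicate-level
differences the generator plants.

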