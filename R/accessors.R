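#' Construct a simulation configuration
#'
#' Defaults emulate a gut-microbiome strain survey: 11 species observed in 10
#' individuals each, reference genomes of ~2000 genes on 4 contigs with 40
#' universal single-copy marker genes, per-species target accessory fractions
#' spanning 0.21--0.45, a block-size mixture dominated by single-gene
#' deletions (35%) with a geometric body (60%, mean 4 genes) and rare large
#' blocks of 50--175 genes (5%), ~3% of reference genes never observed in the
#' cohort, 50x mean depth, and technical < biological noise.
#'
#' @param nSpecies,nIndividuals,nContigs,nGenes community and genome layout.
#' @param geneLengthMean,geneLengthSd,geneLengthMin gene length model (bp).
#' @param nMarkers number of single-copy marker genes to flag.
#' @param trueAccessoryFraction target accessory fraction(s); recycled over
#'   species. Default spans 0.21--0.45 evenly.
#' @param unobservedFraction fraction of genes absent in every individual.
#' @param deletionRate per-individual probability a variable locus is absent.
#' @param blockSizeWeights named mixture weights (single/geometric/large).
#' @param geomMean mean of the geometric block-size component.
#' @param largeMin,largeMax size range of large blocks (genes).
#' @param meanDepth mean fold-coverage of present genes.
#' @param presenceNoise,biologicalNoise,technicalNoise per-gene noise rates
#'   (see [SimulationConfig-class]).
#' @param nBiologicalReplicates individuals given a second time point.
#' @param nTechnicalLanes sequencing lanes of the first individual's primary
#'   sample.
#' @param seed integer seed.
#' @return a [SimulationConfig-class] object.
#' @examples
#' cfg <- SimulationConfig(nSpecies = 1, nGenes = 200, seed = 1)
#' @export
SimulationConfig <- function(nSpecies = 11L, nIndividuals = 10L,
    nContigs = 4L, nGenes = 2000L, geneLengthMean = 1000, geneLengthSd = 300,
    geneLengthMin = 100, nMarkers = 40L,
    trueAccessoryFraction = seq(0.21, 0.45, length.out = nSpecies),
    unobservedFraction = 0.03, deletionRate = 0.3,
    blockSizeWeights = c(single = 0.35, geometric = 0.60, large = 0.05),
    geomMean = 4, largeMin = 50L, largeMax = 175L, meanDepth = 50,
    presenceNoise = 0.002, biologicalNoise = 0.01, technicalNoise = 0.001,
    nBiologicalReplicates = 3L, nTechnicalLanes = 4L, seed = 1L) {
  new("SimulationConfig",
      nSpecies = as.integer(nSpecies), nIndividuals = as.integer(nIndividuals),
      nContigs = as.integer(nContigs), nGenes = as.integer(nGenes),
      geneLengthMean = geneLengthMean, geneLengthSd = geneLengthSd,
      geneLengthMin = geneLengthMin, nMarkers = as.integer(nMarkers),
      trueAccessoryFraction = trueAccessoryFraction,
      unobservedFraction = unobservedFraction, deletionRate = deletionRate,
      blockSizeWeights = blockSizeWeights, geomMean = geomMean,
      largeMin = as.integer(largeMin), largeMax = as.integer(largeMax),
      meanDepth = meanDepth, presenceNoise = presenceNoise,
      biologicalNoise = biologicalNoise, technicalNoise = technicalNoise,
      nBiologicalReplicates = as.integer(nBiologicalReplicates),
      nTechnicalLanes = as.integer(nTechnicalLanes), seed = as.integer(seed))
}

#' Accessors for ReferenceGeneSet
#'
#' @param x a [ReferenceGeneSet-class].
#' @return \code{speciesId}: the species identifier; \code{geneRanges}: the
#'   gene GRanges; \code{geneIds}: character vector of gene ids in genome
#'   order; \code{nGenes}: gene count; \code{markerIds}: ids of flagged
#'   single-copy marker genes; \code{contigs}: data.frame of contig ids and
#'   lengths.
#' @name ReferenceGeneSet-accessors
NULL

#' @rdname ReferenceGeneSet-accessors
#' @export
setMethod("speciesId", "ReferenceGeneSet", function(x) x@speciesId)

#' @rdname ReferenceGeneSet-accessors
#' @export
setMethod("geneRanges", "ReferenceGeneSet", function(x) x@genes)

#' @rdname ReferenceGeneSet-accessors
#' @export
setMethod("geneIds", "ReferenceGeneSet",
          function(x) as.character(mcols(x@genes)$gene_id))

#' @rdname ReferenceGeneSet-accessors
#' @export
setMethod("nGenes", "ReferenceGeneSet", function(x) length(x@genes))

#' @rdname ReferenceGeneSet-accessors
#' @export
setMethod("markerIds", "ReferenceGeneSet",
          function(x) as.character(mcols(x@genes)$gene_id[mcols(x@genes)$is_marker]))

#' @rdname ReferenceGeneSet-accessors
#' @export
setMethod("contigs", "ReferenceGeneSet", function(x) {
  sl <- seqlengths(x@genes)
  data.frame(contig_id = names(sl), length_bp = unname(as.numeric(sl)),
             stringsAsFactors = FALSE)
})

setMethod("show", "ReferenceGeneSet", function(object) {
  cat("ReferenceGeneSet for species", object@speciesId, "\n")
  cat(" ", length(object@genes), "genes on",
      length(unique(as.character(seqnames(object@genes)))), "contig(s);",
      sum(mcols(object@genes)$is_marker), "marker genes\n")
})

#' Accessors for TruthSet
#'
#' @param x a [TruthSet-class].
#' @return \code{truePresence}: logical genes x individuals matrix;
#'   \code{replicateMap}: the sample sheet (sample_id, individual_id,
#'   time_point, lane, replicate_class); \code{realizedAccessoryFraction}:
#'   exact accessory fraction realized in the emitted cohort;
#'   \code{candidateBlocks}: the planted variable loci.
#' @name TruthSet-accessors
NULL

#' @rdname TruthSet-accessors
#' @export
setMethod("truePresence", "TruthSet", function(x) x@truePresence)

#' @rdname TruthSet-accessors
#' @export
setMethod("replicateMap", "TruthSet", function(x) x@replicateMap)

#' @rdname TruthSet-accessors
#' @export
setMethod("realizedAccessoryFraction", "TruthSet",
          function(x) x@realizedAccessoryFraction)

#' @rdname TruthSet-accessors
#' @export
setMethod("candidateBlocks", "TruthSet", function(x) x@candidateBlocks)

setMethod("show", "TruthSet", function(object) {
  cat("TruthSet:", speciesId(object@reference), "-",
      ncol(object@truePresence), "individuals,",
      nrow(object@truePresence), "genes\n")
  cat(sprintf("  realized accessory fraction: %.4f (unobserved %.4f)\n",
              object@realizedAccessoryFraction,
              object@realizedUnobservedFraction))
  cat(" ", nrow(object@candidateBlocks), "candidate variable loci;",
      nrow(object@replicateMap), "samples\n")
})

setMethod("show", "CoverageProfile", function(object) {
  cat("CoverageProfile:", object@sampleId, "x", object@speciesId, "\n")
  cat(sprintf("  %d genes; breadth %.3f; mean depth %.1f\n",
              nrow(object@coverage), genomeBreadth(object),
              genomeMeanDepth(object)))
})

#' Genome-wide breadth and depth of a coverage profile
#'
#' Returns the stored genome-wide values when present; otherwise recomputes
#' them from the per-gene records, weighting by gene length. The
#' recomputation is an approximation: intergenic regions are not visible at
#' gene resolution.
#'
#' @param profile a [CoverageProfile-class].
#' @return a single numeric value.
#' @export
genomeBreadth <- function(profile) {
  if (!is.na(profile@genomeBreadth)) return(profile@genomeBreadth)
  cov <- profile@coverage
  sum(cov$covered_bp) / sum(cov$length_bp)
}

#' @rdname genomeBreadth
#' @export
genomeMeanDepth <- function(profile) {
  if (!is.na(profile@genomeMeanDepth)) return(profile@genomeMeanDepth)
  cov <- profile@coverage
  sum(cov$mean_depth * cov$length_bp) / sum(cov$length_bp)
}

#' Accessors for PresenceMatrix
#'
#' @param x a [PresenceMatrix-class].
#' @return \code{presence}: the logical genes x samples matrix;
#'   \code{individualIds}: individual id per column.
#' @name PresenceMatrix-accessors
NULL

#' @rdname PresenceMatrix-accessors
#' @export
setMethod("presence", "PresenceMatrix",
          function(x) SummarizedExperiment::assay(x, "presence"))

#' @rdname PresenceMatrix-accessors
#' @export
setMethod("individualIds", "PresenceMatrix",
          function(x) as.character(SummarizedExperiment::colData(x)$individual_id))

#' Accessors for AccessoryModelFit
#'
#' @param x an [AccessoryModelFit-class].
#' @return \code{modelName}: the fitted model family; \code{asymptote}: the
#'   fitted asymptotic accessory fraction (NA for families without one).
#' @name AccessoryModelFit-accessors
NULL

#' @rdname AccessoryModelFit-accessors
#' @export
setMethod("modelName", "AccessoryModelFit", function(x) x@modelName)

#' @rdname AccessoryModelFit-accessors
#' @export
setMethod("asymptote", "AccessoryModelFit", function(x) x@asymptote)

setMethod("show", "AccessoryModelFit", function(object) {
  cat("AccessoryModelFit:", object@modelName, "\n")
  if (is.finite(object@asymptote))
    cat(sprintf("  asymptote: %.4f (%.2f%% accessory)\n", object@asymptote,
                100 * object@asymptote))
  else
    cat(sprintf("  no finite asymptote; value at k=%g: %.4f\n",
                object@horizon, object@horizonValue))
  cat(sprintf("  RSS: %.3e over %d sizes\n", object@rss,
              length(object@fittedSizes)))
})

#' Evaluate a fitted rarefaction model at new sample sizes
#'
#' @param object an [AccessoryModelFit-class].
#' @param newSizes numeric vector of sample sizes.
#' @param ... unused.
#' @return numeric vector of model values.
#' @export
setMethod("predict", "AccessoryModelFit", function(object, newSizes, ...) {
  object@predictor(newSizes)
})
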