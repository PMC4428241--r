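#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlengths seqlevels seqinfo Seqinfo
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData rowRanges
NULL

#' Configuration of a synthetic strain community
#'
#' Holds every tunable of the synthetic-community generator: genome layout,
#' the strain-level gene content model, replicate structure and noise rates.
#' Construct with [SimulationConfig()]; all downstream generator functions
#' consume this object so a single seed reproduces the whole community.
#'
#' @slot nSpecies number of species (independent reference genomes).
#' @slot nIndividuals individuals carrying each species.
#' @slot nContigs contigs per reference genome (assembly fragmentation).
#' @slot nGenes genes per reference genome.
#' @slot geneLengthMean,geneLengthSd,geneLengthMin gene length model (bp).
#' @slot nMarkers universal single-copy marker genes flagged per genome.
#' @slot trueAccessoryFraction per-species target fraction of genes absent in
#'   at least one (but not all) individuals of the cohort; recycled across
#'   species.
#' @slot unobservedFraction fraction of reference genes absent in every
#'   individual (reference-specific genes never seen in the cohort).
#' @slot deletionRate per-individual, per-locus probability that a variable
#'   locus (candidate deletion block) is absent.
#' @slot blockSizeWeights mixture weights over the three block-size
#'   components: \code{single} (size 1), \code{geometric} (geometric sizes,
#'   mean \code{geomMean}) and \code{large} (uniform on
#'   \code{largeMin..largeMax}).
#' @slot geomMean mean of the geometric block-size component (genes).
#' @slot largeMin,largeMax size range of the large-block component (genes).
#' @slot meanDepth mean fold-coverage of present genes.
#' @slot presenceNoise per-gene probability that an observed covered fraction
#'   is flipped across the presence decision boundary (mapping artefacts).
#' @slot biologicalNoise per-gene probability that the underlying strain gene
#'   content flips between two time points of the same individual.
#' @slot technicalNoise per-gene probability that a re-sequencing lane of the
#'   same sample flips an observed covered fraction across the boundary.
#' @slot nBiologicalReplicates number of individuals (taken from the start of
#'   the cohort) with a second time point.
#' @slot nTechnicalLanes number of sequencing lanes for the first
#'   individual's primary sample (1 = no technical replicates).
#' @slot seed integer seed governing the whole community.
#' @export
setClass("SimulationConfig",
  representation(
    nSpecies = "integer", nIndividuals = "integer", nContigs = "integer",
    nGenes = "integer", geneLengthMean = "numeric", geneLengthSd = "numeric",
    geneLengthMin = "numeric", nMarkers = "integer",
    trueAccessoryFraction = "numeric", unobservedFraction = "numeric",
    deletionRate = "numeric", blockSizeWeights = "numeric",
    geomMean = "numeric", largeMin = "integer", largeMax = "integer",
    meanDepth = "numeric", presenceNoise = "numeric",
    biologicalNoise = "numeric", technicalNoise = "numeric",
    nBiologicalReplicates = "integer", nTechnicalLanes = "integer",
    seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  prop <- c(trueAccessoryFraction = object@trueAccessoryFraction,
            unobservedFraction = object@unobservedFraction,
            deletionRate = object@deletionRate,
            presenceNoise = object@presenceNoise,
            biologicalNoise = object@biologicalNoise,
            technicalNoise = object@technicalNoise)
  if (any(prop < 0 | prop > 1))
    msg <- c(msg, "all proportions/rates must lie in [0, 1]")
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (object@nSpecies < 1L) msg <- c(msg, "nSpecies must be >= 1")
  if (object@nIndividuals < 1L) msg <- c(msg, "nIndividuals must be >= 1")
  if (object@nContigs < 1L) msg <- c(msg, "nContigs must be >= 1")
  if (object@largeMin < 1L || object@largeMax < object@largeMin)
    msg <- c(msg, "large block size range must satisfy 1 <= largeMin <= largeMax")
  if (length(object@blockSizeWeights) != 3L ||
      !all(c("single", "geometric", "large") %in% names(object@blockSizeWeights)))
    msg <- c(msg, "blockSizeWeights must be named single/geometric/large")
  else if (any(object@blockSizeWeights < 0) ||
           sum(object@blockSizeWeights) <= 0)
    msg <- c(msg, "blockSizeWeights must be non-negative with positive sum")
  if (object@geomMean < 1) msg <- c(msg, "geomMean must be >= 1")
  if (object@meanDepth <= 0) msg <- c(msg, "meanDepth must be positive")
  if (object@nTechnicalLanes < 1L) msg <- c(msg, "nTechnicalLanes must be >= 1")
  if (object@nBiologicalReplicates < 0L ||
      object@nBiologicalReplicates > object@nIndividuals)
    msg <- c(msg, "nBiologicalReplicates must be in 0..nIndividuals")
  if (length(msg)) msg else TRUE
})

#' Ordered gene complement of one reference genome
#'
#' The genes of one species' representative genome, ordered along its
#' contigs, with per-contig ordinal indices and universal single-copy marker
#' flags. Wraps a \link[GenomicRanges]{GRanges} whose seqnames are contigs
#' (lengths in its seqinfo) and whose metadata columns are \code{gene_id},
#' \code{ordinal} (0-based within contig) and \code{is_marker}.
#'
#' @slot speciesId species identifier.
#' @slot genes GRanges of genes, sorted by (contig, start).
#' @export
setClass("ReferenceGeneSet",
  representation(speciesId = "character", genes = "GRanges"))

setValidity("ReferenceGeneSet", function(object) {
  g <- object@genes
  msg <- character(0)
  req <- c("gene_id", "ordinal", "is_marker")
  if (!all(req %in% colnames(mcols(g))))
    return("genes must carry gene_id, ordinal and is_marker metadata columns")
  if (anyDuplicated(mcols(g)$gene_id))
    msg <- c(msg, "gene_id values must be unique")
  sn <- as.character(seqnames(g))
  if (is.unsorted(order(match(sn, unique(sn)), start(g))))
    msg <- c(msg, "genes must be sorted by (contig, start)")
  ords <- split(mcols(g)$ordinal, factor(sn, levels = unique(sn)))
  ok <- vapply(ords, function(o) identical(as.integer(o),
                                           seq_len(length(o)) - 1L), logical(1))
  if (!all(ok))
    msg <- c(msg, "within-contig ordinal indices must run 0,1,2,... per contig")
  if (length(msg)) msg else TRUE
})

#' Per-gene read coverage of one sample x species combination
#'
#' One sample's per-gene coverage summary against one reference genome:
#' gene length, bases covered by at least one read, and mean fold-coverage.
#' Genome-wide breadth/depth are carried when known from read mapping and
#' otherwise recomputed from the per-gene records (gene-length weighted; an
#' approximation, since intergenic regions are invisible at gene resolution).
#'
#' @slot sampleId,individualId,speciesId identifiers.
#' @slot coverage data.frame with columns gene_id, length_bp, covered_bp,
#'   mean_depth.
#' @slot genomeBreadth fraction of the genome covered by >= 1 read (NA to
#'   recompute from genes).
#' @slot genomeMeanDepth mean fold-coverage of the genome (NA to recompute).
#' @slot speciesAbundance relative abundance of the species in the sample
#'   (diagnostics only; NA when unknown).
#' @export
setClass("CoverageProfile",
  representation(sampleId = "character", individualId = "character",
                 speciesId = "character", coverage = "data.frame",
                 genomeBreadth = "numeric", genomeMeanDepth = "numeric",
                 speciesAbundance = "numeric"))

setValidity("CoverageProfile", function(object) {
  cov <- object@coverage
  msg <- character(0)
  req <- c("gene_id", "length_bp", "covered_bp", "mean_depth")
  if (!all(req %in% names(cov)))
    return("coverage needs columns gene_id, length_bp, covered_bp, mean_depth")
  if (any(cov$covered_bp < 0) || any(cov$covered_bp > cov$length_bp))
    msg <- c(msg, "covered_bp must satisfy 0 <= covered_bp <= length_bp")
  if (!is.na(object@genomeBreadth) &&
      (object@genomeBreadth < 0 || object@genomeBreadth > 1))
    msg <- c(msg, "genomeBreadth must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic strain cohort
#'
#' The generator's full knowledge of one synthetic species: the reference,
#' the true per-individual gene complement, the candidate variable loci and
#' which individual lost which, the replicate structure, and the realized
#' accessory / unobserved fractions (exact counts over the emitted matrix).
#'
#' @slot reference a [ReferenceGeneSet-class].
#' @slot truePresence logical genes x individuals matrix.
#' @slot candidateBlocks data.frame of candidate variable loci (block_id,
#'   contig_id, first_ordinal, n_genes, first_gene, unobserved).
#' @slot deletions data.frame (individual_id, block_id) listing which
#'   candidate locus is absent in which individual.
#' @slot replicateMap data.frame (sample_id, individual_id, time_point,
#'   lane, replicate_class).
#' @slot realizedAccessoryFraction fraction of reference genes absent in
#'   >= 1 and present in >= 1 individual.
#' @slot realizedUnobservedFraction fraction absent in every individual.
#' @export
setClass("TruthSet",
  representation(reference = "ReferenceGeneSet", truePresence = "matrix",
                 candidateBlocks = "data.frame", deletions = "data.frame",
                 replicateMap = "data.frame",
                 realizedAccessoryFraction = "numeric",
                 realizedUnobservedFraction = "numeric"))

setValidity("TruthSet", function(object) {
  msg <- character(0)
  tp <- object@truePresence
  if (!is.logical(tp)) msg <- c(msg, "truePresence must be a logical matrix")
  if (nrow(tp) != length(object@reference@genes))
    msg <- c(msg, "truePresence rows must match reference genes")
  # every absent gene is accounted for by exactly one planted block
  if (is.logical(tp) && nrow(tp) == length(object@reference@genes) &&
      nrow(object@deletions) > 0L) {
    cb <- object@candidateBlocks
    for (i in seq_len(ncol(tp))) {
      ind <- colnames(tp)[i]
      bids <- object@deletions$block_id[object@deletions$individual_id == ind]
      rows <- match(bids, cb$block_id)
      planted <- unlist(lapply(rows, function(r)
        seq(cb$first_gene[r], length.out = cb$n_genes[r])), use.names = FALSE)
      if (!setequal(which(!tp[, i]), planted)) {
        msg <- c(msg, sprintf(
          "absent genes of individual %s do not match planted blocks", ind))
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Presence/absence matrix of reference genes across samples
#'
#' A \link[SummarizedExperiment]{RangedSummarizedExperiment} with one logical
#' assay \code{presence} (genes x samples), rowRanges taken from the
#' reference gene set (so genome order and contig structure travel with the
#' matrix) and colData carrying \code{sample_id} and \code{individual_id}.
#'
#' @export
setClass("PresenceMatrix",
  contains = "RangedSummarizedExperiment")

setValidity("PresenceMatrix", function(object) {
  msg <- character(0)
  if (!"presence" %in% SummarizedExperiment::assayNames(object))
    return("PresenceMatrix needs an assay named 'presence'")
  p <- SummarizedExperiment::assay(object, "presence")
  if (!is.logical(p)) msg <- c(msg, "assay 'presence' must be logical")
  if (anyNA(p)) msg <- c(msg, "assay 'presence' must not contain NA")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("sample_id", "individual_id") %in% colnames(cd)))
    msg <- c(msg, "colData needs sample_id and individual_id")
  if (length(msg)) msg else TRUE
})

#' Fitted rarefaction model for the accessory-gene fraction
#'
#' A least-squares fit of the mean subsample-based accessory fraction versus
#' subsample size, under one of four model families. Exponential and
#' negative-exponential fits carry a finite asymptote; the power law and the
#' monotone spline do not and instead report the curve value at a stated
#' extrapolation horizon.
#'
#' @slot modelName one of exponential, power_law, negative_exponential,
#'   spline.
#' @slot parameters named numeric parameter vector (empty for spline).
#' @slot asymptote fitted asymptotic accessory fraction (NA when the model
#'   family has none).
#' @slot rss residual sum of squares at the fitted sizes.
#' @slot horizon extrapolation sample size used when no asymptote exists.
#' @slot horizonValue model value at \code{horizon}.
#' @slot fittedSizes,fittedValues the (size, fraction) points that were fit.
#' @slot predictor function(k) evaluating the fitted curve.
#' @export
setClass("AccessoryModelFit",
  representation(modelName = "character", parameters = "numeric",
                 asymptote = "numeric", rss = "numeric", horizon = "numeric",
                 horizonValue = "numeric", fittedSizes = "numeric",
                 fittedValues = "numeric", predictor = "function"))

setValidity("AccessoryModelFit", function(object) {
  ok <- c("exponential", "power_law", "negative_exponential", "spline")
  if (!object@modelName %in% ok)
    return(sprintf("modelName must be one of %s", paste(ok, collapse = ", ")))
  if (object@modelName %in% c("exponential", "negative_exponential") &&
      !is.finite(object@asymptote))
    return("exponential-family fits must carry a finite asymptote")
  TRUE
})
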