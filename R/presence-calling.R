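#' Call per-gene presence from a coverage profile
#'
#' A gene is called present when it is covered by reads over at least
#' \code{lengthCutoff} of its length (covered_bp / length_bp >=
#' lengthCutoff; the boundary is inclusive). The gene-length coverage filter
#' guards against spuriously assigned reads and orthologous reads from close
#' relative species; its default of 0.40 can be recalibrated from biological
#' replicates with [calibrateLengthCutoff()].
#'
#' @param profile a [CoverageProfile-class] covering every reference gene.
#' @param reference a [ReferenceGeneSet-class].
#' @param lengthCutoff minimum covered fraction of gene length, in [0, 1].
#' @return named logical vector in reference genome order.
#' @examples
#' cfg <- SimulationConfig(nSpecies = 1, nGenes = 100, nIndividuals = 2,
#'                         seed = 3)
#' ref <- generateReference(cfg, seed = 3)
#' truth <- generateStrainPopulation(ref, cfg)
#' prof <- simulateCoverage(truth, cfg)[[1]]
#' table(callGenePresence(prof, ref))
#' @export
callGenePresence <- function(profile, reference, lengthCutoff = 0.40) {
  stopifnot(lengthCutoff >= 0, lengthCutoff <= 1)
  cov <- profile@coverage
  ids <- geneIds(reference)
  unknown <- setdiff(cov$gene_id, c(ids, "_genome"))
  if (length(unknown))
    stop("coverage profile contains genes not in the reference: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  cov <- cov[cov$gene_id != "_genome", , drop = FALSE]
  m <- match(ids, cov$gene_id)
  if (anyNA(m))
    stop("coverage profile is missing ", sum(is.na(m)),
         " reference gene(s), e.g. ", ids[which(is.na(m))[1L]])
  frac <- cov$covered_bp[m] / cov$length_bp[m]
  out <- frac >= lengthCutoff
  names(out) <- ids
  out
}

#' Apply the three sample x species detection filters
#'
#' A sample x species combination is retained when (1) at least
#' \code{breadthMin} of the genome is covered by at least one read (breadth),
#' (2) every flagged universal single-copy marker gene is called present
#' (confirming the species rather than a close relative was detected), and
#' (3) the average genome coverage depth is at least \code{depthMin}
#' (so presence determination is not limited by sequencing depth). The
#' decision depends only on the profile, never on other samples.
#'
#' @param profile a [CoverageProfile-class].
#' @param reference a [ReferenceGeneSet-class].
#' @param breadthMin minimum genome breadth (default 0.40).
#' @param depthMin minimum mean genome depth (default 30).
#' @param lengthCutoff gene-length coverage cutoff used for the marker calls.
#' @return one-row data.frame with sample_id, species_id, breadth, depth,
#'   breadth_pass, markers_pass, depth_pass, pass and a reasons string
#'   (empty when passing).
#' @export
filterSampleSpecies <- function(profile, reference, breadthMin = 0.40,
                                depthMin = 30, lengthCutoff = 0.40) {
  breadth <- genomeBreadth(profile)
  depth <- genomeMeanDepth(profile)
  calls <- callGenePresence(profile, reference, lengthCutoff)
  mk <- markerIds(reference)
  breadth_pass <- breadth >= breadthMin
  markers_pass <- all(calls[mk])
  depth_pass <- depth >= depthMin
  reasons <- c(
    if (!breadth_pass) sprintf("genome breadth %.3f < %.2f", breadth,
                               breadthMin),
    if (!markers_pass) sprintf("%d of %d marker genes absent",
                               sum(!calls[mk]), length(mk)),
    if (!depth_pass) sprintf("mean depth %.1f < %.1f", depth, depthMin))
  data.frame(sample_id = profile@sampleId, species_id = profile@speciesId,
             individual_id = profile@individualId,
             breadth = breadth, depth = depth,
             breadth_pass = breadth_pass, markers_pass = markers_pass,
             depth_pass = depth_pass,
             pass = breadth_pass && markers_pass && depth_pass,
             reasons = paste(reasons, collapse = "; "),
             stringsAsFactors = FALSE)
}

#' Select the analysis cohort for one species
#'
#' Requires at least \code{k} individuals with a passing sample; otherwise
#' the species is excluded (empty result, with the reason attached). When
#' more than \code{k} individuals pass, \code{k} are drawn uniformly without
#' replacement under \code{seed}; when exactly \code{k} pass, all are taken
#' regardless of the seed. One primary sample is kept per chosen individual:
#' the passing sample with the earliest time point (lowest lane as
#' tie-break), so repeated runs are deterministic.
#'
#' @param decisions data.frame of filter decisions as returned by
#'   [filterSampleSpecies()] (rows for one species).
#' @param sampleInfo data.frame with sample_id, individual_id, time_point,
#'   lane (e.g. \code{replicateMap(truth)}).
#' @param k cohort size (default 10).
#' @param seed seed for the random subset.
#' @return data.frame (individual_id, sample_id) with k rows, or zero rows
#'   with attribute \code{reason} when the species is excluded.
#' @export
selectCohort <- function(decisions, sampleInfo, k = 10L, seed = 1L) {
  passing <- decisions[decisions$pass, , drop = FALSE]
  info <- merge(passing[, c("sample_id", "individual_id")], sampleInfo,
                by = c("sample_id", "individual_id"))
  inds <- sort(unique(info$individual_id))
  if (length(inds) < k) {
    out <- data.frame(individual_id = character(0), sample_id = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "reason") <- sprintf(
      "species excluded: only %d of the required %d individuals pass",
      length(inds), k)
    message(attr(out, "reason"))
    return(out)
  }
  chosen <- if (length(inds) == k) inds else {
    set.seed(seed)
    sort(sample(inds, k))
  }
  primary <- vapply(chosen, function(ind) {
    s <- info[info$individual_id == ind, , drop = FALSE]
    s <- s[order(s$time_point, s$lane), , drop = FALSE]
    s$sample_id[1L]
  }, character(1))
  data.frame(individual_id = chosen, sample_id = unname(primary),
             stringsAsFactors = FALSE)
}

#' Calibrate the gene-length coverage cutoff on biological replicates
#'
#' Sweeps candidate cutoffs (0 to 1 in steps of 0.1 by default), calls gene
#' presence in both members of each biological replicate pair at each cutoff,
#' and scores the cutoff by the mean symmetric-difference gene content
#' distance across pairs. The chosen cutoff is the minimizer; ties are broken
#' toward the smallest minimizing cutoff (retaining more genes). Pairs where
#' both members have no called genes contribute a distance of 0 (the calls
#' are identical).
#'
#' @param pairs list of length-2 lists of [CoverageProfile-class] objects
#'   (biological replicate pairs).
#' @param reference a [ReferenceGeneSet-class].
#' @param cutoffs numeric vector of candidate cutoffs.
#' @return list with \code{cutoff} (chosen value) and \code{table}
#'   (data.frame cutoff x mean_difference).
#' @export
calibrateLengthCutoff <- function(pairs, reference,
                                  cutoffs = seq(0, 1, by = 0.1)) {
  if (length(pairs) == 0L)
    stop("at least one biological replicate pair is required")
  meanDiff <- vapply(cutoffs, function(ct) {
    d <- vapply(pairs, function(pr) {
      a <- callGenePresence(pr[[1L]], reference, ct)
      b <- callGenePresence(pr[[2L]], reference, ct)
      if (!any(a | b)) return(0)
      pairwiseDifference(a, b)$value
    }, numeric(1))
    mean(d)
  }, numeric(1))
  best <- cutoffs[which.min(meanDiff)]   # which.min takes the first minimum
  list(cutoff = best,
       table = data.frame(cutoff = cutoffs, mean_difference = meanDiff))
}

#' Assemble a presence/absence matrix from coverage profiles
#'
#' Calls gene presence in every profile at the given cutoff and binds the
#' calls into a [PresenceMatrix-class] (genes x samples) whose rowRanges
#' carry the reference genome order and contig structure.
#'
#' @param profiles list of [CoverageProfile-class] objects.
#' @param reference a [ReferenceGeneSet-class].
#' @param lengthCutoff gene-length coverage cutoff.
#' @return a [PresenceMatrix-class].
#' @export
buildPresenceMatrix <- function(profiles, reference, lengthCutoff = 0.40) {
  stopifnot(length(profiles) >= 1L)
  calls <- vapply(profiles, callGenePresence, logical(nGenes(reference)),
                  reference = reference, lengthCutoff = lengthCutoff)
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = nGenes(reference))
  colnames(calls) <- vapply(profiles, function(p) p@sampleId, character(1))
  rownames(calls) <- geneIds(reference)
  cd <- DataFrame(
    sample_id = colnames(calls),
    individual_id = vapply(profiles, function(p) p@individualId, character(1)),
    species_id = vapply(profiles, function(p) p@speciesId, character(1)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(presence = calls), rowRanges = geneRanges(reference),
    colData = cd)
  new("PresenceMatrix", se)
}
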