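#' Generate a synthetic reference genome
#'
#' Lays \code{nGenes} non-overlapping genes consecutively along
#' \code{nContigs} contigs (genes split as evenly as possible across
#' contigs), with truncated-normal gene lengths and random intergenic gaps,
#' and flags \code{nMarkers} universal single-copy marker genes at evenly
#' spaced positions so they are spread across contigs.
#'
#' @param config a [SimulationConfig-class].
#' @param speciesId identifier for the genome.
#' @param seed optional seed; when NULL the current RNG stream is used (as
#'   done by [simulateCommunity()], which seeds once for the whole run).
#' @return a [ReferenceGeneSet-class].
#' @examples
#' ref <- generateReference(SimulationConfig(nGenes = 120), seed = 1)
#' @export
generateReference <- function(config, speciesId = "sp01", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config@nGenes
  if (n < config@nMarkers)
    stop("nGenes (", n, ") is smaller than the requested number of marker ",
         "genes (", config@nMarkers, ")")
  lens <- pmax(config@geneLengthMin,
               round(stats::rnorm(n, config@geneLengthMean,
                                  config@geneLengthSd)))
  gaps <- round(stats::runif(n, 20, 200))
  # split genes as evenly as possible over contigs
  percontig <- diff(floor(seq(0, n, length.out = config@nContigs + 1L)))
  contig_of <- rep(seq_len(config@nContigs), percontig)
  contig_ids <- sprintf("%s_c%02d", speciesId, seq_len(config@nContigs))
  start <- integer(n); end <- integer(n); ordinal <- integer(n)
  pos <- 1L; ord <- 0L
  for (i in seq_len(n)) {
    if (i > 1L && contig_of[i] != contig_of[i - 1L]) { pos <- 1L; ord <- 0L }
    start[i] <- pos + gaps[i]
    end[i] <- start[i] + lens[i] - 1L
    ordinal[i] <- ord
    pos <- end[i]; ord <- ord + 1L
  }
  clen <- vapply(seq_len(config@nContigs),
                 function(cc) max(end[contig_of == cc]) + 100, numeric(1))
  # markers sit in one operon-like run per contig (single-copy marker genes
  # cluster in real genomes); this spreads them across contigs while leaving
  # long marker-free stretches where large deletion blocks can occur
  share <- diff(floor(seq(0, config@nMarkers,
                          length.out = config@nContigs + 1L)))
  markers <- integer(0)
  deficit <- 0L
  for (cc in seq_len(config@nContigs)) {
    sel <- which(contig_of == cc)
    take <- min(share[cc] + deficit, length(sel))
    deficit <- share[cc] + deficit - take
    if (take == 0L) next
    st <- sample.int(length(sel) - take + 1L, 1L)
    markers <- c(markers, sel[st:(st + take - 1L)])
  }
  if (deficit > 0L) # leftovers go to any unflagged genes
    markers <- c(markers, setdiff(seq_len(n), markers)[seq_len(deficit)])
  is_marker <- seq_len(n) %in% markers
  g <- GRanges(seqnames = factor(contig_ids[contig_of], levels = contig_ids),
               ranges = IRanges(start = start, end = end),
               gene_id = sprintf("%s_g%05d", speciesId, seq_len(n)),
               ordinal = ordinal, is_marker = is_marker,
               seqinfo = Seqinfo(seqnames = contig_ids, seqlengths = clen))
  new("ReferenceGeneSet", speciesId = speciesId, genes = g)
}

# draw one block size from the mixture
.drawBlockSize <- function(config) {
  w <- config@blockSizeWeights / sum(config@blockSizeWeights)
  comp <- sample(c("single", "geometric", "large"), 1L, prob = w)
  switch(comp,
    single = 1L,
    geometric = stats::rgeom(1L, prob = 1 / config@geomMean) + 1L,
    large = sample(config@largeMin:config@largeMax, 1L))
}

# place candidate blocks of the given sizes on free genes, keeping a one-gene
# gap between blocks and never covering marker genes; returns a list of
# integer vectors of global gene indices, or stops when placement fails
.placeBlocks <- function(sizes, contig_of, is_marker, blockedInit,
                         maxRetries = 2000L) {
  n <- length(contig_of)
  blocked <- blockedInit
  out <- vector("list", length(sizes))
  ordsz <- order(sizes, decreasing = TRUE)   # large blocks first
  for (j in ordsz) {
    s <- sizes[j]
    placed <- FALSE
    for (try in seq_len(maxRetries)) {
      st <- sample.int(n - s + 1L, 1L)
      idx <- st:(st + s - 1L)
      if (contig_of[st] != contig_of[st + s - 1L]) next
      if (any(blocked[idx])) next
      out[[j]] <- idx
      lo <- max(1L, st - 1L); hi <- min(n, st + s)
      blocked[lo:hi] <- TRUE
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place a deletion block of ", s, " genes after ",
           maxRetries, " attempts; the target accessory fraction is ",
           "unreachable for this genome layout")
  }
  out
}

#' Generate strain-level gene complements for a cohort
#'
#' Draws a cohort-wide layout of candidate variable loci (deletion blocks
#' drawn from the configured block-size mixture, placed without overlap and
#' away from marker genes) and, per individual, marks each locus absent with
#' probability \code{deletionRate}. Loci are added until the expected
#' cohort-wide accessory fraction matches \code{accessoryFraction}; a further
#' \code{unobservedFraction} of genes is removed in every individual,
#' emulating reference-specific genes never seen in the cohort. Also builds
#' the replicate structure (primary sample per individual, second time points
#' for the first \code{nBiologicalReplicates} individuals, extra sequencing
#' lanes for the first individual).
#'
#' @param reference a [ReferenceGeneSet-class] from [generateReference()].
#' @param config a [SimulationConfig-class].
#' @param accessoryFraction target cohort accessory fraction; defaults to the
#'   first element of \code{config@trueAccessoryFraction}.
#' @param seed optional seed (see [generateReference()]).
#' @return a [TruthSet-class].
#' @export
generateStrainPopulation <- function(reference, config,
    accessoryFraction = config@trueAccessoryFraction[1L], seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nGenes(reference)
  nInd <- config@nIndividuals
  q <- config@deletionRate
  inds <- sprintf("%s_ind%02d", speciesId(reference), seq_len(nInd))
  g <- geneRanges(reference)
  contig_of <- as.integer(factor(as.character(seqnames(g)),
                                 levels = unique(as.character(seqnames(g)))))
  is_marker <- mcols(g)$is_marker

  tp <- matrix(TRUE, n, nInd, dimnames = list(geneIds(reference), inds))
  cb <- data.frame(block_id = integer(0), contig_id = character(0),
                   first_ordinal = integer(0), n_genes = integer(0),
                   first_gene = integer(0), unobserved = logical(0),
                   stringsAsFactors = FALSE)
  dels <- data.frame(individual_id = character(0), block_id = integer(0),
                     stringsAsFactors = FALSE)

  if (accessoryFraction > 0 || config@unobservedFraction > 0) {
    # number of variable genes needed so that, at per-locus absence rate q,
    # the expected fraction absent in >=1 of nInd individuals hits the target
    satur <- 1 - (1 - q)^nInd
    if (accessoryFraction > 0 && satur <= 0)
      stop("deletionRate 0 cannot realize a positive accessory fraction")
    dGenes <- if (accessoryFraction > 0)
      round(accessoryFraction * n / satur) else 0L
    uGenes <- round(config@unobservedFraction * n)
    # a block cannot exceed its contig; cap draws at half the largest contig
    # so several blocks and the marker cluster still fit beside each other
    capBlock <- max(1L, floor(max(tabulate(contig_of)) / 2))
    drawSizes <- function(target) {
      sizes <- integer(0); tot <- 0L
      while (tot < target) {
        s <- min(.drawBlockSize(config), capBlock)
        if (tot + s > target) s <- as.integer(target - tot)  # trim last
        sizes <- c(sizes, s); tot <- tot + s
      }
      sizes
    }
    szA <- drawSizes(dGenes)
    szU <- drawSizes(uGenes)
    sizes <- c(szA, szU)
    unobs <- c(rep(FALSE, length(szA)), rep(TRUE, length(szU)))
    blocked <- is_marker   # markers are never deletable
    placed <- .placeBlocks(sizes, contig_of, is_marker, blocked)
    firsts <- vapply(placed, function(ix) ix[1L], integer(1))
    cb <- data.frame(
      block_id = seq_along(placed),
      contig_id = as.character(seqnames(g))[firsts],
      first_ordinal = as.integer(mcols(g)$ordinal[firsts]),
      n_genes = as.integer(sizes),
      first_gene = as.integer(firsts),
      unobserved = unobs, stringsAsFactors = FALSE)
    for (b in seq_len(nrow(cb))) {
      idx <- placed[[b]]
      lost <- if (cb$unobserved[b]) rep(TRUE, nInd) else
        stats::runif(nInd) < q
      if (any(lost)) {
        tp[idx, lost] <- FALSE
        dels <- rbind(dels, data.frame(individual_id = inds[lost],
                                       block_id = cb$block_id[b],
                                       stringsAsFactors = FALSE))
      }
    }
    # drop candidate loci that no individual lost (they are invisible truth)
    kept <- cb$block_id %in% dels$block_id
    cb <- cb[kept, , drop = FALSE]
  }

  seen <- rowSums(tp)
  realizedAcc <- sum(seen > 0 & seen < nInd) / n
  realizedUnobs <- sum(seen == 0) / n

  rm <- data.frame(sample_id = sprintf("%s_t1_l1", inds),
                   individual_id = inds, time_point = 1L, lane = 1L,
                   replicate_class = "primary", stringsAsFactors = FALSE)
  if (config@nBiologicalReplicates > 0L) {
    bi <- inds[seq_len(config@nBiologicalReplicates)]
    rm <- rbind(rm, data.frame(sample_id = sprintf("%s_t2_l1", bi),
                               individual_id = bi, time_point = 2L, lane = 1L,
                               replicate_class = "biological",
                               stringsAsFactors = FALSE))
  }
  if (config@nTechnicalLanes > 1L) {
    lanes <- 2:config@nTechnicalLanes
    rm <- rbind(rm, data.frame(
      sample_id = sprintf("%s_t1_l%d", inds[1L], lanes),
      individual_id = inds[1L], time_point = 1L, lane = lanes,
      replicate_class = "technical", stringsAsFactors = FALSE))
  }
  new("TruthSet", reference = reference, truePresence = tp,
      candidateBlocks = cb, deletions = dels, replicateMap = rm,
      realizedAccessoryFraction = realizedAcc,
      realizedUnobservedFraction = realizedUnobs)
}

# observed covered fraction and depth for one presence vector
.observeCoverage <- function(present, config, flipProb) {
  n <- length(present)
  cf <- numeric(n)
  depth <- numeric(n)
  np <- sum(present)
  if (np > 0) {
    # present genes: high covered fraction, bounded away from the 0.40
    # decision boundary so that zero-noise calls are exact
    cf[present] <- pmax(0.5, stats::rbeta(np, 20, 1.5))
    depth[present] <- pmax(1, stats::rnorm(np, config@meanDepth,
                                           0.15 * config@meanDepth)) *
      cf[present]
  }
  if (flipProb > 0) {
    flip <- stats::runif(n) < flipProb
    up <- flip & cf < 0.4      # spurious coverage of an absent gene
    dn <- flip & cf >= 0.4     # dropout of a present gene
    cf[up] <- stats::runif(sum(up), 0.4, 1)
    depth[up] <- cf[up] * config@meanDepth * stats::runif(sum(up), 0.2, 1)
    cf[dn] <- stats::runif(sum(dn), 0, 0.39)
    depth[dn] <- cf[dn] * config@meanDepth * stats::runif(sum(dn), 0.2, 1)
  }
  list(cf = cf, depth = depth)
}

.makeProfile <- function(reference, sampleId, individualId, cf, depth,
                         abundance) {
  lens <- width(geneRanges(reference))
  cov <- data.frame(gene_id = geneIds(reference), length_bp = lens,
                    covered_bp = round(cf * lens), mean_depth = depth,
                    stringsAsFactors = FALSE)
  new("CoverageProfile", sampleId = sampleId, individualId = individualId,
      speciesId = speciesId(reference), coverage = cov,
      genomeBreadth = sum(cov$covered_bp) / sum(cov$length_bp),
      genomeMeanDepth = sum(depth * lens) / sum(lens),
      speciesAbundance = abundance)
}

#' Simulate per-gene coverage profiles for every sample of a cohort
#'
#' Present genes receive covered fractions near 1 (never below 0.5) and mean
#' depth near \code{meanDepth}; absent genes receive exactly 0 coverage.
#' Measurement noise then flips a small fraction of genes across the 0.40
#' decision boundary: \code{presenceNoise} per primary/biological sample,
#' \code{technicalNoise} per extra sequencing lane (lanes start from their
#' parent sample's observation, plus a small covered-fraction jitter that
#' leaves truth untouched). Biological replicate samples first flip the
#' underlying strain gene content at \code{biologicalNoise}.
#'
#' @param truth a [TruthSet-class].
#' @param config a [SimulationConfig-class].
#' @param seed optional seed (see [generateReference()]).
#' @return named list of [CoverageProfile-class], one per sample in
#'   \code{replicateMap(truth)}.
#' @export
simulateCoverage <- function(truth, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ref <- truth@reference
  rm <- truth@replicateMap
  n <- nGenes(ref)
  profiles <- vector("list", nrow(rm))
  names(profiles) <- rm$sample_id
  # per-individual abundance with a little sample-to-sample wobble
  baseAb <- stats::rlnorm(ncol(truth@truePresence), log(0.05), 0.5)
  names(baseAb) <- colnames(truth@truePresence)
  baseObs <- list()   # lane-1 observation per (individual, time)
  ord <- order(rm$time_point, rm$lane)  # parents before their lanes
  for (i in ord) {
    ind <- rm$individual_id[i]
    key <- paste(ind, rm$time_point[i], sep = "|")
    if (rm$lane[i] == 1L) {
      pres <- truth@truePresence[, ind]
      if (rm$replicate_class[i] == "biological" && config@biologicalNoise > 0) {
        # strain gene content drifts between time points; universal
        # single-copy marker genes are essential and never lost
        flip <- stats::runif(n) < config@biologicalNoise &
          !mcols(geneRanges(ref))$is_marker
        pres[flip] <- !pres[flip]
      }
      obs <- .observeCoverage(pres, config, config@presenceNoise)
      baseObs[[key]] <- obs
    } else {
      # technical lane: re-observation of the parent sample
      obs <- baseObs[[key]]
      if (is.null(obs))
        stop("technical lane found without a lane-1 parent sample")
      cf <- obs$cf
      depth <- obs$depth
      if (config@technicalNoise > 0) {
        cf <- pmin(1, pmax(0, cf + stats::rnorm(n, 0, 0.01)))
        flip <- stats::runif(n) < config@technicalNoise
        up <- flip & cf < 0.4
        dn <- flip & cf >= 0.4
        cf[up] <- stats::runif(sum(up), 0.4, 1)
        depth[up] <- cf[up] * config@meanDepth * stats::runif(sum(up), 0.2, 1)
        cf[dn] <- stats::runif(sum(dn), 0, 0.39)
        depth[dn] <- cf[dn] * config@meanDepth * stats::runif(sum(dn), 0.2, 1)
      }
      obs <- list(cf = cf, depth = depth)
    }
    ab <- baseAb[ind] * stats::rlnorm(1, 0, 0.1)
    profiles[[i]] <- .makeProfile(ref, rm$sample_id[i], ind, obs$cf,
                                  obs$depth, unname(ab))
  }
  profiles
}

#' Simulate a full multi-species strain community
#'
#' Seeds the RNG once from \code{config@seed} and generates, per species, a
#' reference genome, a cohort truth set and coverage profiles for every
#' sample. With the seed fixed the output is bit-identical between calls.
#'
#' @param config a [SimulationConfig-class].
#' @return named list with one element per species, each a list with
#'   components \code{reference}, \code{truth} and \code{profiles}.
#' @examples
#' com <- simulateCommunity(SimulationConfig(nSpecies = 1, nGenes = 150,
#'                                           nIndividuals = 4, seed = 7))
#' realizedAccessoryFraction(com[[1]]$truth)
#' @export
simulateCommunity <- function(config) {
  set.seed(config@seed)
  afs <- rep_len(config@trueAccessoryFraction, config@nSpecies)
  out <- vector("list", config@nSpecies)
  ids <- sprintf("sp%02d", seq_len(config@nSpecies))
  names(out) <- ids
  for (s in seq_len(config@nSpecies)) {
    ref <- generateReference(config, speciesId = ids[s])
    truth <- generateStrainPopulation(ref, config, accessoryFraction = afs[s])
    profiles <- simulateCoverage(truth, config)
    out[[s]] <- list(reference = ref, truth = truth, profiles = profiles)
  }
  out
}
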