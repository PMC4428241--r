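# Shared fixtures and independent oracles. Everything here is written
# without calling the code paths under test, so expected values stay
# independent.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

# build a tiny ReferenceGeneSet by hand: nPerContig genes per contig,
# unit-spaced 100 bp genes, markers at the given global indices
makeRef <- function(nPerContig, markers = integer(0), speciesId = "tst") {
  nC <- length(nPerContig)
  n <- sum(nPerContig)
  contig_ids <- sprintf("%s_c%02d", speciesId, seq_len(nC))
  contig_of <- rep(seq_len(nC), nPerContig)
  ordinal <- unlist(lapply(nPerContig, function(k) seq_len(k) - 1L))
  start <- ordinal * 150L + 1L
  g <- GRanges(
    seqnames = factor(contig_ids[contig_of], levels = contig_ids),
    ranges = IRanges(start = start, width = 100L),
    gene_id = sprintf("%s_g%04d", speciesId, seq_len(n)),
    ordinal = as.integer(ordinal),
    is_marker = seq_len(n) %in% markers,
    seqinfo = GenomeInfoDb::Seqinfo(
      seqnames = contig_ids,
      seqlengths = nPerContig * 150L + 50L))
  new("ReferenceGeneSet", speciesId = speciesId, genes = g)
}

# CoverageProfile with given covered fractions (recycled over genes)
makeProfile <- function(ref, coveredFrac, depth = 50,
                        sampleId = "s1", individualId = sampleId,
                        breadth = NA_real_, genomeDepth = NA_real_,
                        abundance = NA_real_) {
  n <- nGenes(ref)
  cf <- rep_len(coveredFrac, n)
  lens <- GenomicRanges::width(geneRanges(ref))
  new("CoverageProfile", sampleId = sampleId, individualId = individualId,
      speciesId = speciesId(ref),
      coverage = data.frame(gene_id = geneIds(ref), length_bp = lens,
                            covered_bp = floor(cf * lens),
                            mean_depth = rep_len(depth, n),
                            stringsAsFactors = FALSE),
      genomeBreadth = breadth, genomeMeanDepth = genomeDepth,
      speciesAbundance = abundance)
}

# PresenceMatrix straight from a logical matrix (columns = individuals)
makePM <- function(mat, ref) {
  rownames(mat) <- geneIds(ref)
  if (is.null(colnames(mat)))
    colnames(mat) <- sprintf("ind%02d", seq_len(ncol(mat)))
  cd <- S4Vectors::DataFrame(sample_id = colnames(mat),
                             individual_id = colnames(mat),
                             species_id = speciesId(ref))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(presence = mat), rowRanges = geneRanges(ref), colData = cd)
  new("PresenceMatrix", se)
}

# independent brute-force deletion-block scanner: walks gene by gene and
# opens/closes runs manually, never using rle()
bruteBlocks <- function(presence, contig_of) {
  out <- NULL
  n <- length(presence)
  inRun <- FALSE
  runStart <- NA_integer_
  closeRun <- function(endIdx) {
    data.frame(contig = contig_of[runStart], first = runStart,
               last = endIdx, size = endIdx - runStart + 1L)
  }
  for (i in seq_len(n)) {
    newContig <- i > 1L && contig_of[i] != contig_of[i - 1L]
    if (inRun && (newContig || presence[i])) {
      out <- rbind(out, closeRun(i - 1L))
      inRun <- FALSE
    }
    if (!presence[i] && !inRun) { inRun <- TRUE; runStart <- i }
  }
  if (inRun) out <- rbind(out, closeRun(n))
  if (is.null(out))
    out <- data.frame(contig = integer(0), first = integer(0),
                      last = integer(0), size = integer(0))
  out
}

# brute-force two-sided Fisher p: enumerate every table with the observed
# margins and sum the probabilities of those no more likely than observed
bruteFisherP <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  xs <- max(0L, r1 + c1 - N):min(r1, c1)
  probs <- exp(lchoose(c1, xs) + lchoose(N - c1, r1 - xs) - lchoose(N, r1))
  pObs <- probs[match(a, xs)]
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# exact cohort accessory fraction among observed genes, computed directly
observedAccessoryFraction <- function(mat) {
  seen <- rowSums(mat) > 0L
  sum(seen & rowSums(mat) < ncol(mat)) / sum(seen)
}
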