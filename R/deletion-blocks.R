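#' Find gene deletion blocks in one individual
#'
#' A gene deletion block is a maximal run of contiguous absent genes within
#' one contig of the reference. Runs never extend across contig boundaries
#' (on fragmented assemblies a true block may therefore be split in two),
#' and every absent gene belongs to exactly one block.
#'
#' @param presence named logical vector over the reference genes, in genome
#'   order (as returned by [callGenePresence()] or a [PresenceMatrix-class]
#'   column).
#' @param reference a [ReferenceGeneSet-class].
#' @param sampleId optional sample label carried into the result.
#' @return data.frame with columns sample_id, contig_id, first_ordinal
#'   (0-based within contig), n_genes, first_gene (1-based global index),
#'   touches_contig_edge, and a list-column gene_ids.
#' @examples
#' cfg <- SimulationConfig(nSpecies = 1, nGenes = 60, nIndividuals = 2,
#'                         nContigs = 2, nMarkers = 4, seed = 5)
#' ref <- generateReference(cfg, seed = 5)
#' v <- setNames(rep(TRUE, 60), geneIds(ref))
#' v[10:12] <- FALSE
#' findDeletionBlocks(v, ref)
#' @export
findDeletionBlocks <- function(presence, reference, sampleId = NA_character_) {
  n <- nGenes(reference)
  if (length(presence) != n)
    stop("presence vector length (", length(presence),
         ") does not match the reference (", n, " genes)")
  g <- geneRanges(reference)
  contig <- as.character(seqnames(g))
  ids <- geneIds(reference)
  ord <- mcols(g)$ordinal
  out <- list()
  for (ct in unique(contig)) {
    sel <- which(contig == ct)
    absent <- !presence[sel]
    if (!any(absent)) next
    r <- rle(absent)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    for (j in runs) {
      idx <- sel[starts[j]:ends[j]]
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sampleId, contig_id = ct,
        first_ordinal = as.integer(ord[idx[1L]]),
        n_genes = length(idx), first_gene = idx[1L],
        touches_contig_edge = starts[j] == 1L || ends[j] == length(sel),
        stringsAsFactors = FALSE)
      out[[length(out)]]$gene_ids <- I(list(ids[idx]))
    }
  }
  if (length(out) == 0L) {
    z <- data.frame(sample_id = character(0), contig_id = character(0),
                    first_ordinal = integer(0), n_genes = integer(0),
                    first_gene = integer(0), touches_contig_edge = logical(0),
                    stringsAsFactors = FALSE)
    z$gene_ids <- I(list())
    return(z)
  }
  do.call(rbind, out)
}

#' Classify gene deletion blocks
#'
#' Assigns each block a class — \code{single} (one gene, interior, flanking
#' genes present), \code{large} (at least \code{minLarge} genes) or
#' \code{other} — and a \code{counted} flag. Single-gene blocks at the start
#' or end of a contig are excluded from counting so that contig breaks do
#' not inflate the single-gene tally; multi-gene blocks touching a contig
#' edge remain counted but carry the edge flag. By maximality the immediate
#' flanks of an interior block are always present; \code{flankDepth = 2}
#' additionally requires the two genes on each side to be present (the
#' stricter reading), for which the full presence vector is needed.
#'
#' @param blocks data.frame from [findDeletionBlocks()].
#' @param reference a [ReferenceGeneSet-class].
#' @param presence the presence vector the blocks came from (required when
#'   \code{flankDepth > 1}).
#' @param minLarge minimum size of a large block (default 50).
#' @param flankDepth how many genes on each side of a size-1 block must be
#'   present for it to count as a single-gene deletion (default 1).
#' @return the blocks data.frame with block_class and counted columns added.
#' @export
classifyBlocks <- function(blocks, reference, presence = NULL, minLarge = 50L,
                           flankDepth = 1L) {
  if (flankDepth > 1L && is.null(presence))
    stop("flankDepth > 1 requires the presence vector")
  nb <- nrow(blocks)
  cls <- rep("other", nb)
  counted <- rep(TRUE, nb)
  if (nb > 0L) {
    g <- geneRanges(reference)
    contig <- as.character(seqnames(g))
    for (i in seq_len(nb)) {
      if (blocks$n_genes[i] >= minLarge) { cls[i] <- "large"; next }
      if (blocks$n_genes[i] == 1L) {
        if (blocks$touches_contig_edge[i]) { counted[i] <- FALSE; next }
        flanksOk <- TRUE
        if (flankDepth > 1L) {
          gi <- blocks$first_gene[i]
          sel <- which(contig == blocks$contig_id[i])
          for (d in seq_len(flankDepth)) {
            lo <- gi - d; hi <- gi + d
            if (!(lo %in% sel) || !(hi %in% sel) ||
                !presence[lo] || !presence[hi]) { flanksOk <- FALSE; break }
          }
        }
        if (flanksOk) cls[i] <- "single"
      }
    }
  }
  blocks$block_class <- cls
  blocks$counted <- counted
  blocks
}

#' Block-size spectrum across a cohort
#'
#' For each individual, computes the frequency of each block size among its
#' counted blocks (percent of blocks) and the fraction of its counted
#' deleted genes falling in each size (percent of genes), then averages both
#' across individuals (sizes missing in an individual contribute 0).
#' Individuals with no counted blocks are omitted from the mean with a
#' warning.
#'
#' @param blocks data.frame of classified blocks for all individuals
#'   (distinct sample_id per individual).
#' @param excludeEdgeBlocks when TRUE, multi-gene blocks touching a contig
#'   edge are also dropped from the tallies (size-1 edge blocks are always
#'   excluded via the counted flag).
#' @return data.frame with columns size, mean_block_frequency_pct,
#'   mean_gene_fraction_pct, total_blocks, total_genes; zero rows when no
#'   counted blocks exist.
#' @export
blockSizeSpectrum <- function(blocks, excludeEdgeBlocks = FALSE) {
  use <- blocks[blocks$counted, , drop = FALSE]
  if (excludeEdgeBlocks)
    use <- use[!use$touches_contig_edge, , drop = FALSE]
  if (nrow(use) == 0L)
    return(data.frame(size = integer(0), mean_block_frequency_pct = numeric(0),
                      mean_gene_fraction_pct = numeric(0),
                      total_blocks = integer(0), total_genes = integer(0)))
  samples <- unique(blocks$sample_id)
  sizes <- sort(unique(use$n_genes))
  freq <- matrix(NA_real_, length(samples), length(sizes),
                 dimnames = list(samples, sizes))
  gfrac <- freq
  empty <- character(0)
  for (s in samples) {
    b <- use[use$sample_id == s, , drop = FALSE]
    if (nrow(b) == 0L) { empty <- c(empty, s); next }
    tab <- table(factor(b$n_genes, levels = sizes))
    freq[s, ] <- 100 * as.numeric(tab) / nrow(b)
    gfrac[s, ] <- 100 * as.numeric(tab) * sizes / sum(b$n_genes)
  }
  if (length(empty)) {
    warning("omitting ", length(empty),
            " individual(s) with no counted blocks from the spectrum mean")
    keep <- setdiff(samples, empty)
    freq <- freq[keep, , drop = FALSE]
    gfrac <- gfrac[keep, , drop = FALSE]
  }
  data.frame(size = sizes,
             mean_block_frequency_pct = colMeans(freq),
             mean_gene_fraction_pct = colMeans(gfrac),
             total_blocks = as.integer(table(factor(use$n_genes,
                                                    levels = sizes))),
             total_genes = as.integer(table(factor(use$n_genes,
                                                   levels = sizes)) * sizes),
             row.names = NULL)
}

#' Deletion blocks for every individual of a presence matrix
#'
#' Convenience wrapper running [findDeletionBlocks()] and [classifyBlocks()]
#' on every column of a [PresenceMatrix-class].
#'
#' @param pm a [PresenceMatrix-class].
#' @param reference a [ReferenceGeneSet-class]; defaults to the matrix's own
#'   rowRanges structure.
#' @param minLarge,flankDepth passed to [classifyBlocks()].
#' @return data.frame of classified blocks with sample_id set per column.
#' @export
cohortDeletionBlocks <- function(pm, reference, minLarge = 50L,
                                 flankDepth = 1L) {
  p <- presence(pm)
  res <- lapply(colnames(p), function(s) {
    b <- findDeletionBlocks(p[, s], reference, sampleId = s)
    classifyBlocks(b, reference, presence = p[, s], minLarge = minLarge,
                   flankDepth = flankDepth)
  })
  do.call(rbind, res)
}
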