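#' Symmetric-difference gene content distance between two individuals
#'
#' The number of genes present in only one of the two individuals divided by
#' the number of genes present in either or both — the Jaccard distance on
#' presence sets. Both vectors must be over the same reference gene order.
#'
#' @param a,b logical presence vectors of equal length.
#' @return list with n_union, n_symmetric_difference and value
#'   (= n_symmetric_difference / n_union).
#' @examples
#' a <- c(TRUE, TRUE, TRUE, FALSE)
#' b <- c(FALSE, TRUE, TRUE, TRUE)
#' pairwiseDifference(a, b)$value  # 2/4
#' @export
pairwiseDifference <- function(a, b) {
  if (length(a) != length(b))
    stop("presence vectors have different lengths (", length(a), " vs ",
         length(b), ")")
  nUnion <- sum(a | b)
  if (nUnion == 0L)
    stop("empty union: no gene is present in either individual")
  nSym <- sum(xor(a, b))
  list(n_union = nUnion, n_symmetric_difference = nSym,
       value = nSym / nUnion)
}

#' Pairwise gene content differences across all samples, by replicate class
#'
#' Computes the symmetric-difference distance for every pair of columns and
#' labels each pair: different individuals are \code{inter_individual}; the
#' same individual at different time points is \code{biological_replicate};
#' the same individual, same time point, different lanes is
#' \code{technical_replicate}. For inter-individual summaries restrict to
#' one primary sample per individual first (as [selectCohort()] does).
#'
#' @param presenceMat logical genes x samples matrix (or a
#'   [PresenceMatrix-class]).
#' @param sampleInfo data.frame with sample_id, individual_id, time_point,
#'   lane covering every column.
#' @return data.frame in long format: id_a, id_b, comparison_class, n_union,
#'   n_symmetric_difference, value.
#' @export
replicateDifferences <- function(presenceMat, sampleInfo) {
  if (is(presenceMat, "PresenceMatrix")) presenceMat <- presence(presenceMat)
  ids <- colnames(presenceMat)
  m <- match(ids, sampleInfo$sample_id)
  if (anyNA(m))
    stop("sampleInfo is missing entries for: ",
         paste(ids[is.na(m)], collapse = ", "))
  info <- sampleInfo[m, , drop = FALSE]
  nS <- length(ids)
  rows <- list()
  for (i in seq_len(nS - 1L)) for (j in (i + 1L):nS) {
    cls <- if (info$individual_id[i] != info$individual_id[j])
      "inter_individual"
    else if (info$time_point[i] != info$time_point[j])
      "biological_replicate"
    else "technical_replicate"
    pd <- pairwiseDifference(presenceMat[, i], presenceMat[, j])
    rows[[length(rows) + 1L]] <- data.frame(
      id_a = ids[i], id_b = ids[j], comparison_class = cls,
      n_union = pd$n_union, n_symmetric_difference = pd$n_symmetric_difference,
      value = pd$value, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Reference-conditioned gene content difference between two genomes
#'
#' Emulates the reference-genome dependency of read mapping when comparing
#' completely sequenced genomes: genes present in exactly one of the two
#' genomes count only if they also occur in the designated reference genome,
#' and the denominator is the set of reference genes observed in either or
#' both genomes. Inputs are ortholog-resolved gene identifier sets.
#'
#' @param genesA,genesB character vectors of gene identifiers.
#' @param genesRef character vector: the reference genome's genes.
#' @return list with n_union (denominator), n_symmetric_difference
#'   (numerator) and value.
#' @export
referenceConditionedDifference <- function(genesA, genesB, genesRef) {
  sym <- union(setdiff(genesA, genesB), setdiff(genesB, genesA))
  num <- length(intersect(sym, genesRef))
  den <- length(intersect(genesRef, union(genesA, genesB)))
  if (den == 0L)
    stop("empty denominator: no reference gene is observed in either genome")
  list(n_union = den, n_symmetric_difference = num, value = num / den)
}

#' Compare two distributions of gene content distances
#'
#' Wilcoxon–Mann–Whitney rank-sum test, two-sided. The exact distribution is
#' used when both groups have at most \code{exactMax} observations and there
#' are no ties; otherwise the normal approximation with tie correction is
#' used.
#'
#' @param x,y numeric vectors of distances.
#' @param exactMax largest group size for the exact test (default 20).
#' @return list with U (Mann–Whitney statistic of x), p (two-sided) and
#'   exact (logical).
#' @examples
#' compareDistanceDistributions(c(1, 2, 3), c(10, 11, 12))$p  # exact 0.1
#' @export
compareDistanceDistributions <- function(x, y, exactMax = 20L) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- length(x) <= exactMax && length(y) <= exactMax && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value, exact = exact)
}

# two-sided Fisher p by doubling the smaller tail (capped at 1)
.fisherDoubling <- function(x, m, nn, k) {
  lo <- stats::phyper(x, m, nn, k)
  hi <- stats::phyper(x - 1L, m, nn, k, lower.tail = FALSE)
  min(1, 2 * min(lo, hi))
}

#' Functional-category enrichment of accessory genes
#'
#' For each category, builds the 2x2 table (accessory vs core) x (in vs out
#' of category) over the labeled genes — unobserved genes are excluded — and
#' applies the two-sided Fisher exact test, adjusting across categories with
#' the Benjamini–Hochberg FDR. Genes without a category entry count as
#' outside every category. The default two-sided p sums all tables with
#' point probability at most the observed one (the conventional definition,
#' as implemented by \code{\link[stats]{fisher.test}}); the tail-doubling
#' alternative is available.
#'
#' @param labels factor from [classifyGenes()].
#' @param categoryMap data.frame with columns gene_id and category (a gene
#'   may appear under several categories).
#' @param twoSided \code{"minlik"} (default) or \code{"doubling"}.
#' @return data.frame: category, accessory_in, accessory_out, core_in,
#'   core_out, odds_ratio, p_value, q_value.
#' @export
fisherEnrichment <- function(labels, categoryMap,
                             twoSided = c("minlik", "doubling")) {
  twoSided <- match.arg(twoSided)
  keep <- labels %in% c("core", "accessory")
  genes <- names(labels)[keep]
  lab <- labels[keep]
  cats <- unique(categoryMap$category)
  acc <- genes[lab == "accessory"]
  core <- genes[lab == "core"]
  rows <- lapply(cats, function(cc) {
    inCat <- unique(categoryMap$gene_id[categoryMap$category == cc])
    a_in <- sum(acc %in% inCat); a_out <- length(acc) - a_in
    c_in <- sum(core %in% inCat); c_out <- length(core) - c_in
    tab <- matrix(c(a_in, a_out, c_in, c_out), 2L, byrow = TRUE)
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    p <- if (twoSided == "minlik") ft$p.value else
      .fisherDoubling(a_in, a_in + c_in, a_out + c_out, a_in + a_out)
    data.frame(category = cc, accessory_in = a_in, accessory_out = a_out,
               core_in = c_in, core_out = c_out,
               odds_ratio = unname(ft$estimate), p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Diagnostic: accessory fraction versus coverage and abundance
#'
#' Correlates the per-sample accessory-gene fraction with genome coverage
#' depth and species relative abundance. An association would indicate that
#' gene detection is driven by sequencing effort rather than by strain gene
#' content; this check is diagnostic only and gates nothing. Constant inputs
#' leave the coefficient undefined and are flagged.
#'
#' @param accessoryFraction numeric per-sample accessory fractions.
#' @param coverage numeric per-sample mean genome depths.
#' @param abundance numeric per-sample species relative abundances.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @return data.frame: variable, estimate, p_value, note.
#' @export
abundanceIndependenceCheck <- function(accessoryFraction, coverage,
                                       abundance,
                                       method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(accessoryFraction) < 3L)
    stop("at least 3 samples are required")
  one <- function(v, nm) {
    if (stats::sd(accessoryFraction) == 0 || stats::sd(v) == 0)
      return(data.frame(variable = nm, estimate = NA_real_,
                        p_value = NA_real_, note = "constant input",
                        stringsAsFactors = FALSE))
    ct <- suppressWarnings(stats::cor.test(accessoryFraction, v,
                                           method = method))
    data.frame(variable = nm, estimate = unname(ct$estimate),
               p_value = ct$p.value, note = "", stringsAsFactors = FALSE)
  }
  rbind(one(coverage, "coverage_depth"), one(abundance, "abundance"))
}
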