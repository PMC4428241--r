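#' Read and write reference gene annotations as GFF3
#'
#' The reference gene set is exchanged as standard GFF3 (1-based inclusive
#' coordinates): one \code{gene} feature per gene with \code{ID} set to the
#' gene id and a \code{marker} attribute ("true"/"false") flagging the
#' universal single-copy marker genes. Contig lengths travel in
#' \code{##sequence-region} directives. On reading, genes are sorted by
#' (contig, start) and within-contig ordinals are rebuilt; fewer than 40
#' flagged markers triggers a warning, not an error.
#'
#' @param reference a [ReferenceGeneSet-class].
#' @param path file path.
#' @return \code{writeReferenceGFF3}: the path, invisibly;
#'   \code{readReferenceGFF3}: a [ReferenceGeneSet-class].
#' @export
writeReferenceGFF3 <- function(reference, path) {
  g <- geneRanges(reference)
  out <- g
  mcols(out) <- NULL
  mcols(out)$source <- "panstrain"
  mcols(out)$type <- "gene"
  mcols(out)$ID <- geneIds(reference)
  mcols(out)$marker <- ifelse(mcols(g)$is_marker, "true", "false")
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

#' @rdname writeReferenceGFF3
#' @param speciesId species identifier to attach (default: file name stem).
#' @param expectedMarkers expected marker-set size (warning when fewer).
#' @export
readReferenceGFF3 <- function(path, speciesId = NULL, expectedMarkers = 40L) {
  if (is.null(speciesId))
    speciesId <- sub("\\.gff3?$", "", basename(path))
  g <- rtracklayer::import(path, format = "gff3")
  g <- g[mcols(g)$type == "gene"]
  sn <- as.character(seqnames(g))
  g <- g[order(match(sn, unique(sn)), start(g))]
  sn <- as.character(seqnames(g))
  ord <- unlist(lapply(split(seq_along(g), factor(sn, levels = unique(sn))),
                       function(ix) seq_along(ix) - 1L), use.names = FALSE)
  mk <- mcols(g)$marker
  is_marker <- if (is.null(mk)) rep(FALSE, length(g)) else
    !is.na(mk) & tolower(as.character(mk)) %in% c("true", "1", "yes")
  ids <- as.character(mcols(g)$ID)
  mcols(g) <- NULL
  mcols(g)$gene_id <- ids
  mcols(g)$ordinal <- as.integer(ord)
  mcols(g)$is_marker <- is_marker
  if (sum(is_marker) < expectedMarkers)
    warning("only ", sum(is_marker), " marker genes flagged (expected ",
            expectedMarkers, ")")
  new("ReferenceGeneSet", speciesId = speciesId, genes = g)
}

#' Read and write per-gene coverage tables
#'
#' Coverage is exchanged as TSV with columns sample_id, individual_id,
#' species_id, gene_id, gene_length_bp, covered_bp, mean_depth. Genome-wide
#' summaries ride along as one extra row per sample keyed by
#' \code{gene_id = "_genome"}, carrying the optional columns genome_breadth,
#' genome_mean_depth and species_abundance. One file may hold any number of
#' samples.
#'
#' @param profiles list of [CoverageProfile-class] objects.
#' @param path file path.
#' @return \code{writeCoverageTable}: the path, invisibly;
#'   \code{readCoverageTable}: a named list of [CoverageProfile-class].
#' @export
writeCoverageTable <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    cov <- p@coverage
    base <- data.frame(sample_id = p@sampleId, individual_id = p@individualId,
                       species_id = p@speciesId, gene_id = cov$gene_id,
                       gene_length_bp = cov$length_bp,
                       covered_bp = cov$covered_bp,
                       mean_depth = cov$mean_depth,
                       genome_breadth = NA_real_,
                       genome_mean_depth = NA_real_,
                       species_abundance = NA_real_,
                       stringsAsFactors = FALSE)
    gen <- data.frame(sample_id = p@sampleId, individual_id = p@individualId,
                      species_id = p@speciesId, gene_id = "_genome",
                      gene_length_bp = NA_real_, covered_bp = NA_real_,
                      mean_depth = NA_real_,
                      genome_breadth = p@genomeBreadth,
                      genome_mean_depth = p@genomeMeanDepth,
                      species_abundance = p@speciesAbundance,
                      stringsAsFactors = FALSE)
    rbind(base, gen)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeCoverageTable
#' @export
readCoverageTable <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  req <- c("sample_id", "species_id", "gene_id", "gene_length_bp",
           "covered_bp", "mean_depth")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("coverage table is missing columns: ", paste(miss, collapse = ", "))
  if (!"individual_id" %in% names(tab)) tab$individual_id <- tab$sample_id
  lapply(split(tab, tab$sample_id), function(s) {
    gen <- s[s$gene_id == "_genome", , drop = FALSE]
    per <- s[s$gene_id != "_genome", , drop = FALSE]
    getOpt <- function(col) {
      if (nrow(gen) && col %in% names(gen) && !is.na(gen[[col]][1L]))
        gen[[col]][1L] else NA_real_
    }
    new("CoverageProfile", sampleId = per$sample_id[1L],
        individualId = per$individual_id[1L], speciesId = per$species_id[1L],
        coverage = data.frame(gene_id = per$gene_id,
                              length_bp = per$gene_length_bp,
                              covered_bp = per$covered_bp,
                              mean_depth = per$mean_depth,
                              stringsAsFactors = FALSE),
        genomeBreadth = getOpt("genome_breadth"),
        genomeMeanDepth = getOpt("genome_mean_depth"),
        speciesAbundance = getOpt("species_abundance"))
  })
}

#' Read and write presence/absence matrices
#'
#' Presence matrices are exchanged as TSV with genes in genome order as rows
#' (first column gene_id) and one 0/1 column per sample.
#'
#' @param pm a [PresenceMatrix-class].
#' @param path file path.
#' @param reference optional [ReferenceGeneSet-class]; when supplied on
#'   reading, rows are checked and ordered against it and the result carries
#'   its rowRanges.
#' @param sampleInfo optional data.frame (sample_id, individual_id) used to
#'   fill colData on reading; defaults to sample_id = individual_id =
#'   column name.
#' @return \code{writePresenceMatrix}: the path, invisibly;
#'   \code{readPresenceMatrix}: a [PresenceMatrix-class] (requires
#'   \code{reference}).
#' @export
writePresenceMatrix <- function(pm, path) {
  p <- presence(pm)
  out <- data.frame(gene_id = rownames(p),
                    matrix(as.integer(p), nrow(p),
                           dimnames = list(NULL, colnames(p))),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePresenceMatrix
#' @export
readPresenceMatrix <- function(path, reference, sampleInfo = NULL) {
  tab <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- match(geneIds(reference), tab$gene_id)
  if (anyNA(m))
    stop("presence matrix is missing reference genes, e.g. ",
         geneIds(reference)[which(is.na(m))[1L]])
  mat <- as.matrix(tab[m, -1L, drop = FALSE]) > 0
  rownames(mat) <- geneIds(reference)
  if (is.null(sampleInfo))
    sampleInfo <- data.frame(sample_id = colnames(mat),
                             individual_id = colnames(mat),
                             stringsAsFactors = FALSE)
  mm <- match(colnames(mat), sampleInfo$sample_id)
  cd <- DataFrame(sample_id = colnames(mat),
                  individual_id = sampleInfo$individual_id[mm])
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(presence = mat), rowRanges = geneRanges(reference),
    colData = cd)
  new("PresenceMatrix", se)
}

#' Write deletion blocks as BED
#'
#' One BED record per block, spanning from the start of its first gene to
#' the end of its last gene (0-based half-open, per the BED convention),
#' named \code{sample:size:class}.
#'
#' @param blocks data.frame of classified blocks ([classifyBlocks()]).
#' @param reference a [ReferenceGeneSet-class].
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeBlocksBED <- function(blocks, reference, path) {
  g <- geneRanges(reference)
  if (nrow(blocks) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  first <- blocks$first_gene
  last <- blocks$first_gene + blocks$n_genes - 1L
  gr <- GRanges(seqnames = blocks$contig_id,
                ranges = IRanges(start = start(g)[first], end = end(g)[last]),
                name = sprintf("%s:%d:%s", blocks$sample_id, blocks$n_genes,
                               blocks$block_class),
                seqinfo = seqinfo(g))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write a rarefaction table, and a model-fit report as JSON
#'
#' @param table data.frame from [subsampleFractions()].
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeRarefactionTable <- function(table, path) {
  utils::write.table(table[, c("size", "n_combinations", "mean_fraction",
                               "median_fraction")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRarefactionTable
#' @param fit an [AccessoryModelFit-class].
#' @param deviation optional deviation from expected fractions to include.
#' @export
writeFitReport <- function(fit, path, deviation = NULL) {
  rep <- list(model = fit@modelName, parameters = as.list(fit@parameters),
              asymptote = fit@asymptote, rss = fit@rss,
              horizon = fit@horizon, horizon_value = fit@horizonValue)
  if (!is.null(deviation)) rep$mean_deviation_pct <- deviation
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
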