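#' @rdname ReferenceGeneSet-accessors
#' @export
setGeneric("speciesId", function(x) standardGeneric("speciesId"))

#' @rdname ReferenceGeneSet-accessors
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname ReferenceGeneSet-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname ReferenceGeneSet-accessors
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' @rdname ReferenceGeneSet-accessors
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))

#' @rdname ReferenceGeneSet-accessors
#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))

#' @rdname TruthSet-accessors
#' @export
setGeneric("truePresence", function(x) standardGeneric("truePresence"))

#' @rdname TruthSet-accessors
#' @export
setGeneric("replicateMap", function(x) standardGeneric("replicateMap"))

#' @rdname TruthSet-accessors
#' @export
setGeneric("realizedAccessoryFraction",
           function(x) standardGeneric("realizedAccessoryFraction"))

#' @rdname TruthSet-accessors
#' @export
setGeneric("candidateBlocks", function(x) standardGeneric("candidateBlocks"))

#' @rdname PresenceMatrix-accessors
#' @export
setGeneric("presence", function(x) standardGeneric("presence"))

#' @rdname PresenceMatrix-accessors
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' @rdname AccessoryModelFit-accessors
#' @export
setGeneric("modelName", function(x) standardGeneric("modelName"))

#' @rdname AccessoryModelFit-accessors
#' @export
setGeneric("asymptote", function(x) standardGeneric("asymptote"))
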