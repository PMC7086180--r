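#' Accessors for nachrevo classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object of the relevant class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cladeOf", function(x) standardGeneric("cladeOf"))
#' @rdname accessors
#' @export
setMethod("cladeOf", "CladeAlignment", function(x) x@cladeOf)

#' @rdname accessors
#' @export
setGeneric("alignedSequences", function(x) standardGeneric("alignedSequences"))
#' @rdname accessors
#' @export
setMethod("alignedSequences", "CladeAlignment", function(x) x@sequences)

#' @rdname accessors
#' @export
setGeneric("type2Sites", function(x) standardGeneric("type2Sites"))
#' @rdname accessors
#' @export
setMethod("type2Sites", "CladeAlignment", function(x) x@type2Sites)

#' @rdname accessors
#' @export
setGeneric("identityValues", function(x) standardGeneric("identityValues"))
#' @rdname accessors
#' @export
setMethod("identityValues", "SeqIdentityMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("deletionMode", function(x) standardGeneric("deletionMode"))
#' @rdname accessors
#' @export
setMethod("deletionMode", "SeqIdentityMatrix", function(x) x@deletionMode)

#' @rdname accessors
#' @export
setGeneric("theta2", function(x) standardGeneric("theta2"))
#' @rdname accessors
#' @export
setMethod("theta2", "TypeIIDivergence", function(x) x@theta2)

#' @rdname accessors
#' @export
setGeneric("zScore", function(x) standardGeneric("zScore"))
#' @rdname accessors
#' @export
setMethod("zScore", "TypeIIDivergence", function(x) x@z)

#' @rdname accessors
#' @export
setGeneric("sitePosteriors", function(x) standardGeneric("sitePosteriors"))
#' @rdname accessors
#' @export
setMethod("sitePosteriors", "TypeIIDivergence", function(x) x@sitePosteriors)

#' @rdname accessors
#' @export
setGeneric("sitePatterns", function(x) standardGeneric("sitePatterns"))
#' @rdname accessors
#' @export
setMethod("sitePatterns", "TypeIIDivergence", function(x) x@sitePatterns)

#' @rdname accessors
#' @export
setGeneric("posteriorMean", function(x) standardGeneric("posteriorMean"))
#' @rdname accessors
#' @export
setMethod("posteriorMean", "ExpressionPosterior", function(x) x@posteriorMean)

#' @rdname accessors
#' @export
setGeneric("posteriorGrid", function(x) standardGeneric("posteriorGrid"))
#' @rdname accessors
#' @export
setMethod("posteriorGrid", "ExpressionPosterior", function(x) x@grid)

#' @rdname accessors
#' @export
setGeneric("posteriorWeights", function(x) standardGeneric("posteriorWeights"))
#' @rdname accessors
#' @export
setMethod("posteriorWeights", "ExpressionPosterior", function(x) x@weights)

#' @rdname accessors
#' @export
setGeneric("assemblies", function(x) standardGeneric("assemblies"))
#' @rdname accessors
#' @export
setMethod("assemblies", "PentamerCatalog", function(x) x@assemblies)

#' @rdname accessors
#' @export
setGeneric("pcaScores", function(x) standardGeneric("pcaScores"))
#' @rdname accessors
#' @export
setMethod("pcaScores", "PCAModel", function(x) x@scores)

#' @rdname accessors
#' @export
setGeneric("pcaLoadings", function(x) standardGeneric("pcaLoadings"))
#' @rdname accessors
#' @export
setMethod("pcaLoadings", "PCAModel", function(x) x@loadings)

#' @rdname accessors
#' @export
setGeneric("varianceFractions", function(x) standardGeneric("varianceFractions"))
#' @rdname accessors
#' @export
setMethod("varianceFractions", "PCAModel", function(x) x@varianceFractions)

#' @rdname accessors
#' @export
setGeneric("ancestralEstimates", function(x) standardGeneric("ancestralEstimates"))
#' @rdname accessors
#' @export
setMethod("ancestralEstimates", "AncestralTraits", function(x) x@estimates)

#' @rdname accessors
#' @export
setGeneric("bmSigma2", function(x) standardGeneric("bmSigma2"))
#' @rdname accessors
#' @export
setMethod("bmSigma2", "AncestralTraits", function(x) x@sigma2)
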