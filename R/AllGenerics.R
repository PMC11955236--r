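#' Accessors for genostab classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x a genostab object.
#' @return the corresponding component; see the class documentation.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname accessors
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname accessors
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' @rdname accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @rdname accessors
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname accessors
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("rowLabels", function(x) standardGeneric("rowLabels"))

#' @rdname accessors
#' @export
setGeneric("embeddingLevel", function(x) standardGeneric("embeddingLevel"))

#' @rdname accessors
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))

#' @rdname accessors
#' @export
setGeneric("distanceValues", function(x) standardGeneric("distanceValues"))

#' @rdname accessors
#' @export
setGeneric("distanceMetric", function(x) standardGeneric("distanceMetric"))

#' @rdname accessors
#' @export
setGeneric("disparity", function(x) standardGeneric("disparity"))

#' @rdname accessors
#' @export
setGeneric("similarity", function(x) standardGeneric("similarity"))

#' @rdname accessors
#' @export
setGeneric("replicateEmbeddings", function(x) standardGeneric("replicateEmbeddings"))

#' @rdname accessors
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))

#' @rdname accessors
#' @export
setGeneric("stabilityScore", function(x) standardGeneric("stabilityScore"))

#' @rdname accessors
#' @export
setGeneric("clusterStabilityScore", function(x) standardGeneric("clusterStabilityScore"))

#' @rdname accessors
#' @export
setGeneric("supportValueVector", function(x) standardGeneric("supportValueVector"))
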