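#' @rdname accessors
#' @export
setGeneric("nogIds", function(x) standardGeneric("nogIds"))

#' @rdname accessors
#' @export
setGeneric("nogCategories", function(x) standardGeneric("nogCategories"))

#' @rdname accessors
#' @export
setGeneric("entityIds", function(x) standardGeneric("entityIds"))

#' @rdname accessors
#' @export
setGeneric("nogSets", function(x) standardGeneric("nogSets"))

#' @rdname accessors
#' @export
setGeneric("entityPhyla", function(x) standardGeneric("entityPhyla"))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname sampleFrequency
#' @export
setGeneric("sampleFrequency", function(x) standardGeneric("sampleFrequency"))

#' Accessors for asfscreen containers
#'
#' \code{nogIds} and \code{nogCategories} extract the identifier and category
#' columns of a [NogCatalog()]; \code{entityIds}, \code{nogSets} and
#' \code{entityPhyla} access a [NogSetList()]; \code{nSamples} counts the
#' samples of a [MetagenomeCollection()]; \code{conditionIds} lists the
#' distinct condition ids of a [PeakExperiment()].
#'
#' @param x the container.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
setMethod("nogIds", "NogCatalog", function(x) x@table$nog_id)

#' @rdname accessors
setMethod("nogCategories", "NogCatalog", function(x)
  stats::setNames(x@table$category, x@table$nog_id))

#' @rdname accessors
setMethod("entityIds", "NogSetList", function(x) names(x@sets))

#' @rdname accessors
setMethod("nogSets", "NogSetList", function(x) x@sets)

#' @rdname accessors
setMethod("entityPhyla", "NogSetList", function(x) x@phylum)

#' @rdname accessors
setMethod("nSamples", "MetagenomeCollection", function(x) length(x@samples))

#' @rdname accessors
#' @export
conditionIds <- function(x) {
  stopifnot(is(x, "PeakExperiment"))
  unique(SummarizedExperiment::colData(x)$condition)
}
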