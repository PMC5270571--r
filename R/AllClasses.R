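#' NogCatalog: the universe of orthologous groups
#'
#' Maps every NOG identifier to its single functional-category code.  NOGs
#' annotated in more than one functional category carry the sentinel category
#' \code{"multi"}; they are kept in the catalog but removed at analysis entry
#' by [discardMulticategory()], since multi-category orthologs are ambiguous
#' units of function.
#'
#' @param nog_id character vector of unique NOG identifiers.
#' @param category character vector of single-letter functional-category codes
#'   (COG-style), or \code{"multi"} for NOGs with more than one category.
#' @return A \code{NogCatalog} object.
#' @examples
#' cat <- NogCatalog(c("NOG1", "NOG2"), c("J", "multi"))
#' nogCategories(cat)
#' @export
NogCatalog <- function(nog_id, category) {
  new("NogCatalog",
      table = data.frame(nog_id = as.character(nog_id),
                         category = as.character(category),
                         stringsAsFactors = FALSE))
}

setClass("NogCatalog", slots = c(table = "data.frame"))

setValidity("NogCatalog", function(object) {
  tb <- object@table
  if (!all(c("nog_id", "category") %in% names(tb)))
    return("catalog table must have columns 'nog_id' and 'category'")
  if (anyNA(tb$nog_id) || anyNA(tb$category))
    return("catalog must not contain NA ids or categories")
  if (anyDuplicated(tb$nog_id))
    return("nog_ids must be unique")
  TRUE
})

#' NogSetList: named collections of NOG annotation sets
#'
#' Holds one NOG set per entity (a species genome or a metagenomic sample),
#' with set semantics (duplicates are collapsed), plus an optional phylum
#' label per entity used for stratified random-consortium sampling.
#'
#' @param sets named list of character vectors (one annotation set per
#'   entity); names are entity ids.
#' @param phylum optional character vector of phylum labels, one per entity
#'   (recycled names from \code{sets} if unnamed).
#' @return A \code{NogSetList}.
#' @examples
#' nsl <- NogSetList(list(sp1 = c("NOG1", "NOG2"), sp2 = "NOG2"),
#'                   phylum = c("Firmicutes", "Bacteroidetes"))
#' nogSets(nsl)$sp1
#' @export
NogSetList <- function(sets, phylum = NULL) {
  sets <- lapply(sets, function(s) sort(unique(as.character(s))))
  if (is.null(phylum)) phylum <- rep(NA_character_, length(sets))
  phylum <- as.character(phylum)
  names(phylum) <- names(sets)
  new("NogSetList", sets = sets, phylum = phylum)
}

setClass("NogSetList", slots = c(sets = "list", phylum = "character"))

setValidity("NogSetList", function(object) {
  if (length(object@sets) && is.null(names(object@sets)))
    return("sets must be named by entity id")
  if (anyDuplicated(names(object@sets)))
    return("entity ids must be unique")
  if (!all(vapply(object@sets, is.character, logical(1))))
    return("each annotation set must be a character vector")
  if (any(vapply(object@sets, anyDuplicated, integer(1)) > 0))
    return("annotation sets must not contain duplicates")
  if (length(object@phylum) != length(object@sets))
    return("phylum must have one entry per entity")
  TRUE
})

#' MetagenomeCollection: per-sample NOG sets of a reference metagenome survey
#'
#' @param samples named list of character vectors, one NOG set per
#'   metagenomic sample (15 wild-mouse fecal samples in the motivating
#'   study).
#' @return A \code{MetagenomeCollection}.
#' @examples
#' mc <- MetagenomeCollection(list(s1 = c("NOG1", "NOG2"), s2 = "NOG1"))
#' nSamples(mc)
#' @export
MetagenomeCollection <- function(samples) {
  samples <- lapply(samples, function(s) sort(unique(as.character(s))))
  new("MetagenomeCollection", samples = samples)
}

setClass("MetagenomeCollection", slots = c(samples = "list"))

setValidity("MetagenomeCollection", function(object) {
  if (length(object@samples) < 1L)
    return("a metagenome collection needs at least one sample")
  if (is.null(names(object@samples)) || anyDuplicated(names(object@samples)))
    return("samples must have unique names")
  if (!all(vapply(object@samples, is.character, logical(1))))
    return("each sample must be a character vector of NOG ids")
  TRUE
})

#' PeakExperiment: NMR peak-integral matrix with condition metadata
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' peak-integral table of the spent-media screen: rows are NMR peaks
#' (named metabolites and \code{"Unknown NN"} peaks alike), columns are
#' replicate measurements of media conditions.  Condition ids follow the
#' grammar \code{fresh}, \code{spent<species>} and
#' \code{ds<grower>_in_spent<donor>}.
#'
#' @param integrals numeric matrix, peaks x replicate columns, non-negative
#'   relative spectral intensities; rownames are peak ids.
#' @param condition character vector of condition ids, one per column.
#' @param replicate integer vector of replicate indices, one per column.
#' @return A \code{PeakExperiment}.
#' @examples
#' m <- matrix(runif(6), nrow = 2,
#'             dimnames = list(c("glucose", "Unknown 1"), NULL))
#' pe <- PeakExperiment(m, condition = c("fresh", "fresh", "spentsp1"),
#'                      replicate = c(1L, 2L, 1L))
#' conditionIds(pe)
#' @export
PeakExperiment <- function(integrals, condition, replicate = NULL) {
  integrals <- as.matrix(integrals)
  if (is.null(replicate)) replicate <- stats::ave(seq_along(condition),
                                                  condition, FUN = seq_along)
  colnames(integrals) <- paste(condition, replicate, sep = ".")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(integrals = integrals),
    colData = S4Vectors::DataFrame(condition = as.character(condition),
                                   replicate = as.integer(replicate)))
  new("PeakExperiment", se)
}

setClass("PeakExperiment", contains = "SummarizedExperiment")

setValidity("PeakExperiment", function(object) {
  if (!"integrals" %in% SummarizedExperiment::assayNames(object))
    return("assay 'integrals' is required")
  m <- SummarizedExperiment::assay(object, "integrals")
  if (is.null(rownames(m)))
    return("peak ids (rownames) are required")
  if (any(m < 0, na.rm = TRUE))
    return("peak integrals must be non-negative")
  if (!all(c("condition", "replicate") %in%
           names(SummarizedExperiment::colData(object))))
    return("colData must carry 'condition' and 'replicate'")
  TRUE
})

setMethod("show", "NogCatalog", function(object) {
  tb <- object@table
  n_multi <- sum(tb$category == "multi")
  cat(sprintf("NogCatalog with %d NOGs (%d multi-category) in %d categories\n",
              nrow(tb), n_multi,
              length(unique(tb$category[tb$category != "multi"]))))
})

setMethod("show", "NogSetList", function(object) {
  sz <- lengths(object@sets)
  cat(sprintf("NogSetList with %d entities (set sizes %s)\n",
              length(sz),
              if (length(sz)) paste0(min(sz), "-", max(sz)) else "-"))
  if (any(!is.na(object@phylum)))
    cat("  phyla:", paste(unique(stats::na.omit(object@phylum)),
                          collapse = ", "), "\n")
})

setMethod("show", "MetagenomeCollection", function(object) {
  cat(sprintf("MetagenomeCollection with %d samples, %d distinct NOGs\n",
              length(object@samples),
              length(unique(unlist(object@samples, use.names = FALSE)))))
})
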