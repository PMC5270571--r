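#' Read and write asfscreen file formats
#'
#' Plain-text serializations of the pipeline's inputs and outputs:
#' hit tables (TSV \code{query_id, nog_id, e_value}), NOG catalogs (TSV
#' \code{nog_id, category}), annotation-set pair files (TSV
#' \code{entity_id, nog_id}, one pair per line), peak-integral tables
#' (CSV \code{condition_id, replicate, <peak columns>}), and the long
#' growth-curve CSVs.
#'
#' @param path file path.
#' @name asfscreen-io
NULL

#' @rdname asfscreen-io
#' @export
readHitTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("query_id", "nog_id", "e_value")
  if (!all(req %in% names(df)))
    stop("hit table must have columns ", paste(req, collapse = ", "),
         ": ", path)
  df
}

#' @rdname asfscreen-io
#' @export
readNogCatalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("nog_id", "category") %in% names(df)))
    stop("catalog must have columns nog_id, category: ", path)
  NogCatalog(df$nog_id, df$category)
}

#' @rdname asfscreen-io
#' @param catalog a [NogCatalog()].
#' @export
writeNogCatalog <- function(catalog, path) {
  stopifnot(is(catalog, "NogCatalog"))
  utils::write.table(catalog@table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname asfscreen-io
#' @param phyla optional named character vector (entity id -> phylum) to
#'   attach when reading annotation pairs.
#' @export
readAnnotationPairs <- function(path, phyla = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("entity_id", "nog_id") %in% names(df)))
    stop("annotation pairs must have columns entity_id, nog_id: ", path)
  sets <- split(df$nog_id, df$entity_id)
  ph <- if (is.null(phyla)) NULL else unname(phyla[names(sets)])
  NogSetList(sets, phylum = ph)
}

#' @rdname asfscreen-io
#' @param nsl a [NogSetList()].
#' @export
writeAnnotationPairs <- function(nsl, path) {
  stopifnot(is(nsl, "NogSetList"))
  sets <- nogSets(nsl)
  df <- data.frame(entity_id = rep(names(sets), lengths(sets)),
                   nog_id = unlist(sets, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname asfscreen-io
#' @export
readPeakTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (!all(c("condition_id", "replicate") %in% names(df)))
    stop("peak table must have columns condition_id, replicate: ", path)
  peak_cols <- setdiff(names(df), c("condition_id", "replicate"))
  m <- t(as.matrix(df[, peak_cols, drop = FALSE]))
  rownames(m) <- peak_cols
  PeakExperiment(m, condition = df$condition_id,
                 replicate = df$replicate)
}

#' @rdname asfscreen-io
#' @param pe a [PeakExperiment()].
#' @export
writePeakTable <- function(pe, path) {
  stopifnot(is(pe, "PeakExperiment"))
  cd <- SummarizedExperiment::colData(pe)
  m <- SummarizedExperiment::assay(pe, "integrals")
  df <- cbind(data.frame(condition_id = cd$condition,
                         replicate = cd$replicate),
              as.data.frame(t(m), check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname asfscreen-io
#' @param tab an \code{InteractionTable} from [tabulateTransitions()].
#' @export
writeInteractionTable <- function(tab, path) {
  stopifnot(inherits(tab, "InteractionTable"))
  sub <- attr(tab, "group_subtotals")
  tot <- attr(tab, "growth_totals")
  out <- as.data.frame(tab)
  out$subtotal <- sub$count[match(paste(out$growth, out$group),
                                  paste(sub$growth, sub$group))]
  out$growth_total <- tot[out$growth]
  out$grand_total <- attr(tab, "grand_total")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Published classification counts of the ASF spent-media screen
#'
#' Loads the reference 18-cell classification table (growth status x
#' spent-to-double-spent transition) from the published ASF screen, shipped
#' as plain text with the package, in the format accepted by
#' [recordsFromScenarioCounts()].
#'
#' @return data.frame \code{growth, spent_call, double_call, count}.
#' @export
publishedScenarioCounts <- function() {
  utils::read.delim(system.file("extdata", "asf_screen_scenario_counts.tsv",
                                package = "asfscreen"),
                    stringsAsFactors = FALSE)
}

#' Published core-NOG summary counts of the ASF coverage analysis
#'
#' Loads the reference core-NOG counts of the published ASF metagenome
#' coverage analysis: the number of unique NOGs observed across the wild
#' murine metagenomes, the core set size, how many core NOGs the ASF
#' covers, how many of those are unique to a single ASF member, and how
#' many of the unique ones the top contributor carries.
#'
#' @return Named numeric vector.
#' @export
publishedCoreNogCounts <- function() {
  df <- utils::read.delim(system.file("extdata", "asf_core_nog_counts.tsv",
                                      package = "asfscreen"),
                          stringsAsFactors = FALSE)
  stats::setNames(df$count, df$quantity)
}
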