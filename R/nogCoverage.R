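#' Assign each query its best ortholog hit below an E-value threshold
#'
#' Implements the best-hit annotation rule used to build per-entity NOG
#' annotation sets from profile-HMM hit tables: every query (gene call)
#' receives at most one NOG — the hit with the lowest E-value, provided that
#' E-value is strictly below the threshold.  Queries whose best hit does not
#' pass the threshold receive no annotation.  Ties on the minimal E-value are
#' broken by lexicographic NOG id, for reproducibility.
#'
#' @param hits data.frame with columns \code{query_id}, \code{nog_id},
#'   \code{e_value}.
#' @param threshold positive E-value cutoff; a hit qualifies only if
#'   \code{e_value < threshold}.  Default \code{1e-10}.
#' @return A list with \code{assignments} (named character vector,
#'   query id -> NOG id, only annotated queries) and \code{nogs} (the
#'   entity's annotation set: sorted unique assigned NOG ids).
#' @examples
#' h <- data.frame(query_id = c("g1", "g1"), nog_id = c("NOG_A", "NOG_B"),
#'                 e_value = c(1e-20, 1e-5))
#' selectBestAnnotation(h)$nogs
#' @export
selectBestAnnotation <- function(hits, threshold = 1e-10) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  req <- c("query_id", "nog_id", "e_value")
  if (!is.data.frame(hits) || !all(req %in% names(hits)))
    stop("hits must be a data.frame with columns ",
         paste(req, collapse = ", "))
  if (nrow(hits) == 0L)
    return(list(assignments = stats::setNames(character(0), character(0)),
                nogs = character(0)))
  ev <- suppressWarnings(as.numeric(hits$e_value))
  bad <- which(is.na(ev) | is.na(hits$query_id) | is.na(hits$nog_id) |
                 hits$query_id == "" | hits$nog_id == "")
  if (length(bad))
    stop("malformed hit rows (missing field or non-numeric E-value): row(s) ",
         paste(head(bad, 10L), collapse = ", "))
  if (any(ev < 0))
    stop("E-values must be non-negative; offending row(s): ",
         paste(head(which(ev < 0), 10L), collapse = ", "))
  keep <- ev < threshold
  if (!any(keep))
    return(list(assignments = stats::setNames(character(0), character(0)),
                nogs = character(0)))
  h <- data.frame(query_id = as.character(hits$query_id)[keep],
                  nog_id = as.character(hits$nog_id)[keep],
                  e_value = ev[keep], stringsAsFactors = FALSE)
  h <- h[order(h$query_id, h$e_value, h$nog_id), , drop = FALSE]
  best <- h[!duplicated(h$query_id), , drop = FALSE]
  list(assignments = stats::setNames(best$nog_id, best$query_id),
       nogs = sort(unique(best$nog_id)))
}

#' Drop NOGs annotated in more than one functional category
#'
#' NOGs carrying functional annotations in more than one category (sentinel
#' category \code{"multi"} in the catalog) are ambiguous functional units and
#' are removed at the entry of every analysis.
#'
#' @param nogs character vector (an annotation set).
#' @param catalog a [NogCatalog()] resolving every id in \code{nogs}.
#' @return The subset of \code{nogs} whose catalog category is not
#'   \code{"multi"}.
#' @examples
#' cat <- NogCatalog(c("A", "B"), c("J", "multi"))
#' discardMulticategory(c("A", "B"), cat)
#' @export
discardMulticategory <- function(nogs, catalog) {
  stopifnot(is(catalog, "NogCatalog"))
  nogs <- as.character(nogs)
  cats <- nogCategories(catalog)
  missing <- setdiff(nogs, names(cats))
  if (length(missing))
    stop("NOG id(s) not in catalog: ", paste(head(missing, 10L),
                                             collapse = ", "))
  nogs[cats[nogs] != "multi"]
}

#' Sample frequency of every NOG in a metagenome collection
#'
#' Counts, for each NOG observed anywhere in the collection, the number of
#' samples containing it — the frequency axis along which coverage is
#' stratified (1 to 15 samples in the motivating survey).
#'
#' @param x a [MetagenomeCollection()].
#' @return Named integer vector, NOG id -> sample frequency, sorted by id.
#' @examples
#' mc <- MetagenomeCollection(list(s1 = c("A", "B"), s2 = "B"))
#' sampleFrequency(mc)
#' @rdname sampleFrequency
#' @export
setMethod("sampleFrequency", "MetagenomeCollection", function(x) {
  ids <- unlist(x@samples, use.names = FALSE)
  if (!length(ids))
    stop("metagenome collection contains no NOGs")
  tab <- table(ids)
  stats::setNames(as.integer(tab), names(tab))
})

#' Core NOGs of a metagenome collection
#'
#' The core set is defined as the NOGs present in every sample of the
#' collection (frequency equal to the sample count).
#'
#' @param freq named integer vector from [sampleFrequency()].
#' @param n_samples number of samples in the collection.
#' @return Character vector of core NOG ids.
#' @examples
#' coreNogs(c(A = 15L, B = 14L), 15L)
#' @export
coreNogs <- function(freq, n_samples) {
  stopifnot(is.numeric(n_samples), n_samples >= 1)
  names(freq)[freq == n_samples]
}

#' Coverage of metagenomic NOGs by a consortium, stratified by frequency
#'
#' For each sample-frequency bin, the percentage of metagenomic NOGs at that
#' frequency present in the union of the consortium members' annotation
#' sets.  Bins containing no metagenomic NOGs are absent from the result
#' (rather than reported as 0\%), so per-bin conservation
#' (covered + uncovered = bin size) holds exactly.
#'
#' @param consortium a [NogSetList()] or plain list of character vectors —
#'   the annotation sets of the consortium members.
#' @param collection a [MetagenomeCollection()].
#' @return data.frame with columns \code{bin}, \code{n_nogs},
#'   \code{covered}, \code{percent}; attribute \code{overall} carries the
#'   overall percent coverage across all metagenomic NOGs.
#' @examples
#' mc <- MetagenomeCollection(list(s1 = c("A", "B"), s2 = c("A", "B")))
#' coverageByFrequency(list(sp1 = "A"), mc)
#' @export
coverageByFrequency <- function(consortium, collection) {
  stopifnot(is(collection, "MetagenomeCollection"))
  if (is(consortium, "NogSetList")) consortium <- nogSets(consortium)
  if (!length(consortium))
    stop("consortium must contain at least one annotation set")
  cons_union <- unique(unlist(consortium, use.names = FALSE))
  freq <- sampleFrequency(collection)
  bins <- sort(unique(freq))
  covered_all <- names(freq) %in% cons_union
  res <- do.call(rbind, lapply(bins, function(f) {
    in_bin <- freq == f
    n <- sum(in_bin)
    cov <- sum(covered_all & in_bin)
    data.frame(bin = as.integer(f), n_nogs = n, covered = cov,
               percent = 100 * cov / n)
  }))
  attr(res, "overall") <- 100 * sum(covered_all) / length(freq)
  class(res) <- c("CoverageResult", "data.frame")
  res
}

#' Scale a phylum ratio to stratum counts for a consortium size
#'
#' The null-model consortia mirror the dominant phyla of the mouse gut in a
#' 6:2 Firmicutes:Bacteroidetes ratio; for sizes 8, 16 and 32 this yields
#' strata of 6+2, 12+4 and 24+8 members.
#'
#' @param size total consortium size.
#' @param ratio named numeric vector of phylum proportions (default
#'   \code{c(Firmicutes = 6, Bacteroidetes = 2)}).
#' @return Named integer vector of per-phylum counts summing to \code{size}.
#' @examples
#' scaleStrata(16)
#' @export
scaleStrata <- function(size, ratio = c(Firmicutes = 6, Bacteroidetes = 2)) {
  counts <- size * ratio / sum(ratio)
  if (any(abs(counts - round(counts)) > 1e-9))
    stop("size ", size, " is not divisible in the ratio ",
         paste(ratio, collapse = ":"))
  stats::setNames(as.integer(round(counts)), names(ratio))
}

#' Draw stratified random consortia from phylum pools
#'
#' Samples \code{n_draws} random consortia; within each draw the stratum
#' count for every phylum is sampled uniformly without replacement from that
#' phylum's candidate pool.  Draws are independent of each other and fully
#' reproducible given the seed.
#'
#' @param pools named list, phylum -> character vector of candidate species
#'   ids.
#' @param strata named integer vector, phylum -> number of members to draw
#'   (see [scaleStrata()]).
#' @param n_draws number of consortia to draw.
#' @param seed integer RNG seed.
#' @return List of length \code{n_draws}; each element a character vector of
#'   member ids (Firmicutes first, then remaining strata in \code{strata}
#'   order).
#' @examples
#' drawConsortia(list(F = letters[1:6], B = LETTERS[1:3]),
#'               c(F = 2L, B = 1L), n_draws = 2, seed = 1)
#' @export
drawConsortia <- function(pools, strata, n_draws, seed) {
  stopifnot(is.list(pools), !is.null(names(pools)),
            all(names(strata) %in% names(pools)),
            n_draws >= 1)
  for (ph in names(strata)) {
    if (strata[[ph]] < 0) stop("stratum counts must be >= 0")
    if (strata[[ph]] > length(pools[[ph]]))
      stop("stratum count for ", ph, " (", strata[[ph]],
           ") exceeds pool size (", length(pools[[ph]]), ")")
  }
  set.seed(as.integer(seed))
  lapply(seq_len(n_draws), function(i)
    unlist(lapply(names(strata), function(ph)
      sample(pools[[ph]], strata[[ph]], replace = FALSE)),
      use.names = FALSE))
}

#' Replace one member of a given phylum in a consortium
#'
#' Used for the substitution variant of the null model: e.g. replacing one
#' Bacteroidetes member of a random consortium with the Deferribacteres
#' species \emph{Mucispirillum} to test whether that phylum explains core
#' coverage.  The member to remove is chosen uniformly among the members of
#' \code{remove_phylum}; consortium size is preserved.
#'
#' @param consortium character vector of member ids.
#' @param phyla named character vector mapping species id -> phylum (must
#'   cover all consortium members).
#' @param remove_phylum phylum whose member is replaced.
#' @param add_id replacement species id (must not already be a member).
#' @return Character vector of member ids, same length as \code{consortium}.
#' @examples
#' substituteMember(c("a", "b"), c(a = "F", b = "B"), "B", "m")
#' @export
substituteMember <- function(consortium, phyla, remove_phylum, add_id) {
  if (add_id %in% consortium)
    stop("'", add_id, "' is already a consortium member")
  unknown <- setdiff(consortium, names(phyla))
  if (length(unknown))
    stop("no phylum known for member(s): ", paste(unknown, collapse = ", "))
  cand <- which(phyla[consortium] == remove_phylum)
  if (!length(cand))
    stop("consortium has no member of phylum '", remove_phylum, "'")
  drop <- if (length(cand) == 1L) cand else sample(cand, 1L)
  consortium[drop] <- add_id
  consortium
}

#' Unique contributions of each species to a target NOG set
#'
#' For each NOG of \code{target} present in exactly one species, attribute
#' it to that species, tallied overall and per functional category.  This
#' quantifies which member carries the consortium's non-redundant coverage
#' of, say, the core metagenomic NOGs.
#'
#' @param species a [NogSetList()] or named list of character vectors
#'   (at least 2 species).
#' @param target character vector of NOG ids (e.g. the core set).
#' @param catalog a [NogCatalog()] supplying functional categories.
#' @return data.frame with columns \code{species_id}, \code{category},
#'   \code{n}; attribute \code{total} gives the per-species totals (named
#'   integer vector over all species, zero included).
#' @examples
#' cat <- NogCatalog(c("A", "B"), c("J", "K"))
#' uniqueContributions(list(s1 = c("A", "B"), s2 = "B"), c("A", "B"), cat)
#' @export
uniqueContributions <- function(species, target, catalog) {
  if (is(species, "NogSetList")) species <- nogSets(species)
  if (length(species) < 2L) stop("need at least 2 species")
  stopifnot(is(catalog, "NogCatalog"))
  target <- unique(as.character(target))
  memb <- vapply(species, function(s) target %in% s,
                 logical(length(target)))
  if (length(target) == 1L) memb <- matrix(memb, nrow = 1L)
  n_holders <- rowSums(memb)
  uniq <- which(n_holders == 1L)
  cats <- nogCategories(catalog)
  rows <- lapply(uniq, function(i) {
    sp <- names(species)[which(memb[i, ])]
    data.frame(species_id = sp, category = unname(cats[target[i]]),
               nog_id = target[i], stringsAsFactors = FALSE)
  })
  long <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species_id = character(0), category = character(0),
               nog_id = character(0))
  agg <- if (nrow(long))
    stats::aggregate(list(n = long$nog_id),
                     by = list(species_id = long$species_id,
                               category = long$category),
                     FUN = length) else
    data.frame(species_id = character(0), category = character(0),
               n = integer(0))
  tot <- stats::setNames(integer(length(species)), names(species))
  if (nrow(long)) {
    t2 <- table(long$species_id)
    tot[names(t2)] <- as.integer(t2)
  }
  attr(agg, "total") <- tot
  agg
}

#' Percentile bands of coverage across random draws
#'
#' Summarizes a list of per-bin coverage results (one per random consortium
#' draw) as the empirical median and 5th/95th percentiles per frequency bin.
#' Percentiles use the linear-interpolation convention
#' (\code{stats::quantile} type 7), recorded in the output's
#' \code{"percentile_convention"} attribute.
#'
#' @param coverages non-empty list of [coverageByFrequency()] results.
#' @param probs lower/upper band probabilities (default \code{c(0.05, 0.95)}).
#' @return data.frame with columns \code{bin}, \code{median}, \code{lower},
#'   \code{upper}.
#' @examples
#' mc <- MetagenomeCollection(list(s1 = c("A", "B")))
#' cov <- coverageByFrequency(list("A"), mc)
#' percentileBands(list(cov, cov))
#' @export
percentileBands <- function(coverages, probs = c(0.05, 0.95)) {
  if (!length(coverages)) stop("need at least one coverage result")
  bins <- sort(unique(unlist(lapply(coverages, `[[`, "bin"))))
  res <- do.call(rbind, lapply(bins, function(b) {
    vals <- unlist(lapply(coverages, function(cv)
      cv$percent[cv$bin == b]))
    q <- stats::quantile(vals, probs = probs, type = 7, names = FALSE)
    data.frame(bin = b, median = stats::median(vals),
               lower = q[1], upper = q[2])
  }))
  attr(res, "percentile_convention") <-
    "linear interpolation between closest ranks (quantile type 7)"
  res
}
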