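#' Jaccard distance between two sets
#'
#' \code{1 − |a ∩ b| / |a ∪ b|}; two empty sets are at distance 0.
#'
#' @param a,b character vectors treated as sets.
#' @return Distance in \code{[0, 1]}.
#' @examples
#' jaccardDistance(c("a", "b"), c("b", "c"))  # 2/3
#' @export
jaccardDistance <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  1 - length(intersect(a, b)) / u
}

#' Tagged metabolic-profile set of a species
#'
#' Converts a species' single-spent abundance profile into the set used for
#' metabolic Jaccard distances: the tagged union of (peak, consumed) and
#' (peak, produced) elements, so that one species consuming and another
#' producing the same peak count as different elements.
#'
#' @param profile data.frame with \code{peak_id} and \code{z} (the species'
#'   single-spent profile).
#' @param threshold SD threshold (default 2).
#' @return Character vector of tagged elements, e.g.
#'   \code{"glucose|consumed"}.
#' @export
metabolicProfileSet <- function(profile, threshold = 2) {
  cp <- consumedProducedSets(profile, threshold)
  c(if (length(cp$consumed)) paste0(cp$consumed, "|consumed"),
    if (length(cp$produced)) paste0(cp$produced, "|produced"))
}

#' Genetic and metabolic Jaccard distances for all species pairs
#'
#' For every unordered pair of species, the Jaccard distance between their
#' NOG annotation sets (genetic) and between their tagged
#' consumed/produced metabolite sets (metabolic).
#'
#' @param genetic named list (or [NogSetList()]) of annotation sets.
#' @param metabolic named list of tagged metabolite sets (see
#'   [metabolicProfileSet()]); must cover the same species as
#'   \code{genetic}.
#' @return data.frame \code{species_a, species_b, genetic_distance,
#'   metabolic_distance} with \code{choose(n, 2)} rows.
#' @export
pairwiseDistances <- function(genetic, metabolic) {
  if (is(genetic, "NogSetList")) genetic <- nogSets(genetic)
  if (!setequal(names(genetic), names(metabolic)))
    stop("genetic and metabolic maps must cover the same species")
  sp <- sort(names(genetic))
  if (length(sp) < 2L) stop("need at least 2 species")
  pairs <- utils::combn(sp, 2L)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    data.frame(species_a = a, species_b = b,
               genetic_distance = jaccardDistance(genetic[[a]],
                                                  genetic[[b]]),
               metabolic_distance = jaccardDistance(metabolic[[a]],
                                                    metabolic[[b]]),
               stringsAsFactors = FALSE)
  }))
}

#' Spearman rank correlation with t-approximation or exact permutation p
#'
#' Rank correlation with midranks for ties.  The default p-value uses the
#' t approximation \code{t = rho * sqrt((n−2)/(1−rho²))} with n−2 degrees
#' of freedom (two-sided).  For \code{n <= 8} an exact permutation p-value
#' is available, enumerating all \code{n!} orderings of one vector.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @param method \code{"t"} (default) or \code{"exact"}.
#' @return List with \code{rho} and \code{p}.  If either vector is
#'   constant the correlation is undefined and both are \code{NA}.
#' @export
spearmanTest <- function(x, y, method = c("t", "exact")) {
  method <- match.arg(method)
  n <- length(x)
  stopifnot(length(y) == n, n >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_))
  rho <- stats::cor(x, y, method = "spearman")
  if (method == "t") {
    if (abs(rho) >= 1) return(list(rho = rho, p = 0))
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    return(list(rho = rho, p = 2 * stats::pt(-abs(tt), df = n - 2)))
  }
  if (n > 8L) stop("exact permutation p only supported for n <= 8")
  perms <- .permutations(n)
  rx <- rank(x)
  ry <- rank(y)
  rho_perm <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
  p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  list(rho = rho, p = p)
}

# all permutations of 1..n as an (n! x n) matrix
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Correlate NOG presence with metabolite response across species
#'
#' For every (NOG, peak) pair, the Spearman correlation between the NOG's
#' presence/absence vector across species and the peak's response vector
#' (the species' single-spent z-score for that peak), with Bonferroni
#' correction over an explicitly supplied number of tests.  Pairs where
#' either vector is constant have undefined correlation and are reported
#' as \code{NA}, excluded from significance counts.
#'
#' @param nog_presence logical/numeric matrix, species x NOGs.
#' @param metabolite_response numeric matrix, species x peaks (z-scores).
#' @param n_tests number of tests for the Bonferroni correction; defaults
#'   to the number of (NOG, peak) pairs with defined correlation.
#' @param alpha significance level on the corrected p (default 0.05).
#' @return data.frame \code{nog_id, peak_id, rho, p_raw, p_bonf,
#'   significant}.
#' @export
nogMetaboliteCorrelation <- function(nog_presence, metabolite_response,
                                     n_tests = NULL, alpha = 0.05) {
  nog_presence <- as.matrix(nog_presence) * 1
  metabolite_response <- as.matrix(metabolite_response)
  n <- nrow(nog_presence)
  if (nrow(metabolite_response) != n)
    stop("matrices must have one row per species, in the same order")
  if (n < 3L) stop("need at least 3 species")
  rx <- apply(nog_presence, 2L, rank)
  ry <- apply(metabolite_response, 2L, rank)
  const_x <- apply(nog_presence, 2L, function(v) stats::sd(v) == 0)
  const_y <- apply(metabolite_response, 2L, function(v) stats::sd(v) == 0)
  rho <- suppressWarnings(stats::cor(rx, ry))
  rho[const_x, ] <- NA
  rho[, const_y] <- NA
  if (is.null(n_tests)) n_tests <- sum(!is.na(rho))
  stopifnot(n_tests >= 1)
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p_raw <- 2 * stats::pt(-abs(tt), df = n - 2)
  p_raw[abs(rho) >= 1 - 1e-12] <- 0
  p_bonf <- pmin(1, p_raw * n_tests)
  out <- data.frame(
    nog_id = rep(colnames(nog_presence), times = ncol(metabolite_response)),
    peak_id = rep(colnames(metabolite_response),
                  each = ncol(nog_presence)),
    rho = as.vector(rho), p_raw = as.vector(p_raw),
    p_bonf = as.vector(p_bonf), stringsAsFactors = FALSE)
  out$significant <- !is.na(out$p_bonf) & out$p_bonf < alpha
  out$significant[is.na(out$rho)] <- NA
  attr(out, "n_tests") <- n_tests
  out
}

#' Drop correlations driven by single-species NOGs or metabolites
#'
#' Because the screen has few species, most significant NOG-metabolite
#' correlations are trivially driven by a NOG found in a single species
#' paired with a metabolite consumed or produced only by that species.
#' This filter removes pairs where the NOG is present in exactly one
#' species or the peak is consumed/produced by exactly one species.
#'
#' @param pairs data.frame from [nogMetaboliteCorrelation()].
#' @param nog_presence the species x NOG presence matrix used there.
#' @param activity_counts named integer vector, peak id -> number of
#'   species that consumed or produced it (see [consumedProducedSets()]).
#' @return \code{pairs} with an added logical column
#'   \code{retained_after_filter}, subset to the retained rows.
#' @export
filterInformative <- function(pairs, nog_presence, activity_counts) {
  presence_counts <- colSums(as.matrix(nog_presence) > 0)
  unknown <- setdiff(pairs$nog_id, names(presence_counts))
  if (length(unknown))
    stop("NOGs absent from presence matrix: ",
         paste(head(unknown, 5L), collapse = ", "))
  act <- activity_counts[pairs$peak_id]
  act[is.na(act)] <- 0L
  keep <- presence_counts[pairs$nog_id] > 1L & act > 1L
  out <- pairs[keep, , drop = FALSE]
  out$retained_after_filter <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}
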