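# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive enumeration, not the package's code paths.

# per-bin coverage by looping NOG by NOG over explicit membership checks
oracle_coverage <- function(consortium_sets, sample_sets) {
  all_nogs <- unique(unlist(sample_sets))
  freq <- vapply(all_nogs, function(nog)
    sum(vapply(sample_sets, function(s) nog %in% s, logical(1))),
    integer(1))
  in_union <- vapply(all_nogs, function(nog)
    any(vapply(consortium_sets, function(s) nog %in% s, logical(1))),
    logical(1))
  bins <- sort(unique(freq))
  data.frame(bin = bins,
             n_nogs = vapply(bins, function(b) sum(freq == b), integer(1)),
             covered = vapply(bins, function(b)
               sum(in_union[freq == b]), integer(1)))
}

# unique contributions by explicit per-NOG holder enumeration
oracle_unique <- function(species_sets, target) {
  counts <- setNames(integer(length(species_sets)), names(species_sets))
  for (nog in target) {
    holders <- names(species_sets)[vapply(species_sets, function(s)
      nog %in% s, logical(1))]
    if (length(holders) == 1L) counts[holders] <- counts[holders] + 1L
  }
  counts
}

# Spearman rho from the explicit rank-covariance formula (midranks)
oracle_spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# exact two-sided permutation p for Spearman by full enumeration
oracle_spearman_p <- function(x, y) {
  n <- length(x)
  perms <- asfscreen:::.permutations(n)
  obs <- abs(oracle_spearman_rho(x, y))
  hits <- 0L
  for (i in seq_len(nrow(perms)))
    if (abs(oracle_spearman_rho(x, y[perms[i, ]])) >= obs - 1e-12)
      hits <- hits + 1L
  hits / nrow(perms)
}

# random comparison-record sets for property tests
random_records <- function(n, seed) {
  set.seed(seed)
  calls <- c("Low", "Medium", "High")
  data.frame(donor = "d1",
             grower = "g1",
             peak_id = sprintf("p%04d", seq_len(n)),
             spent_call = sample(calls, n, replace = TRUE),
             double_call = sample(calls, n, replace = TRUE),
             grew = sample(c(TRUE, FALSE), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# tiny scenario defaults for fast generator tests
small_scenario <- function(seed, ...) {
  args <- list(seed = seed, n_nogs = 200L,
               pool_sizes = c(Firmicutes = 15L, Bacteroidetes = 6L),
               od_interval_h = 7, n_wells = 2L)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(syntheticScenario, args)
}
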