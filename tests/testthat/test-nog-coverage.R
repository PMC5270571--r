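test_that("best-hit annotation keeps the minimum E-value strictly below threshold", {
  expect_identical(
    selectBestAnnotation(data.frame(query_id = character(0),
                                    nog_id = character(0),
                                    e_value = numeric(0)))$nogs,
    character(0))

  h <- data.frame(query_id = c("g1", "g1"),
                  nog_id = c("NOG_A", "NOG_B"),
                  e_value = c(1e-20, 1e-5))
  expect_identical(selectBestAnnotation(h)$nogs, "NOG_A")

  # at-threshold hit does not qualify (strictly below)
  h2 <- data.frame(query_id = "g1", nog_id = "NOG_A", e_value = 1e-9)
  expect_identical(selectBestAnnotation(h2, threshold = 1e-10)$nogs,
                   character(0))
  expect_identical(
    selectBestAnnotation(data.frame(query_id = "g1", nog_id = "NOG_A",
                                    e_value = 1e-10))$nogs,
    character(0))

  # ties on minimal E-value resolve to the lexicographically first NOG
  h3 <- data.frame(query_id = "g1", nog_id = c("NOG_Z", "NOG_B"),
                   e_value = c(1e-20, 1e-20))
  expect_identical(unname(selectBestAnnotation(h3)$assignments), "NOG_B")

  # union across queries
  h4 <- data.frame(query_id = c("g1", "g2", "g3"),
                   nog_id = c("NOG_A", "NOG_A", "NOG_C"),
                   e_value = c(1e-20, 1e-30, 1e-15))
  expect_identical(selectBestAnnotation(h4)$nogs, c("NOG_A", "NOG_C"))

  bad <- data.frame(query_id = c("g1", "g2"), nog_id = c("NOG_A", "NOG_B"),
                    e_value = c("1e-20", "oops"))
  expect_error(selectBestAnnotation(bad), "row")
  expect_error(selectBestAnnotation(
    data.frame(query_id = "g1", nog_id = "N", e_value = -1)),
    "non-negative")
})

test_that("multi-category NOGs are discarded and unknown ids rejected", {
  cat <- NogCatalog(c("A", "B", "C"), c("J", "multi", "K"))
  expect_identical(discardMulticategory(c("A", "B"), cat), "A")
  expect_identical(discardMulticategory(c("A", "C"), cat), c("A", "C"))
  expect_identical(discardMulticategory(c("B"), cat), character(0))
  expect_error(discardMulticategory(c("A", "zzz"), cat), "zzz")
})

test_that("sample frequency counts samples containing each NOG", {
  mc <- MetagenomeCollection(list(s1 = c("A", "B"), s2 = "B", s3 = "B"))
  f <- sampleFrequency(mc)
  expect_identical(f[["A"]], 1L)
  expect_identical(f[["B"]], 3L)
  mc2 <- MetagenomeCollection(list(s1 = c("A", "B"), s2 = "B"))
  expect_identical(sampleFrequency(mc2), c(A = 1L, B = 2L))
  expect_error(sampleFrequency(MetagenomeCollection(list(s1 = character(0)))),
               "no NOGs")
})

test_that("core set is exactly the NOGs at maximal frequency", {
  expect_identical(coreNogs(c(A = 15L, B = 14L), 15), "A")
  expect_identical(coreNogs(setNames(integer(0), character(0)), 15),
                   character(0))
  expect_identical(coreNogs(c(A = 3L, B = 3L), 3), c("A", "B"))
})

test_that("coverage by frequency matches counting and omits empty bins", {
  mc <- MetagenomeCollection(list(s1 = c("A", "B", "C"),
                                  s2 = c("A", "B"),
                                  s3 = c("A", "B")))
  # bin 3 holds {A,B}; union holds A only -> 50%
  cov <- coverageByFrequency(list(sp = "A"), mc)
  expect_equal(cov$percent[cov$bin == 3], 50)
  expect_equal(cov$percent[cov$bin == 1], 0)   # C uncovered
  expect_false(2 %in% cov$bin)                  # empty bin absent
  # superset union -> 100% everywhere
  cov2 <- coverageByFrequency(list(sp = c("A", "B", "C", "Z")), mc)
  expect_true(all(cov2$percent == 100))
  expect_equal(attr(cov2, "overall"), 100)
  # disjoint union -> 0% everywhere
  cov3 <- coverageByFrequency(list(sp = "Q"), mc)
  expect_true(all(cov3$percent == 0))
})

test_that("coverage agrees with the brute-force oracle on small universes", {
  for (seed in 1:5) {
    set.seed(seed)
    universe <- sprintf("N%02d", 1:50)
    samples <- lapply(1:6, function(i)
      sample(universe, sample(10:40, 1)))
    names(samples) <- paste0("s", 1:6)
    species <- lapply(1:4, function(i) sample(universe, sample(5:25, 1)))
    names(species) <- paste0("sp", 1:4)
    mc <- MetagenomeCollection(samples)
    cov <- coverageByFrequency(species, mc)
    orc <- oracle_coverage(species, samples)
    orc <- orc[order(orc$bin), ]
    expect_equal(cov$bin, orc$bin)
    expect_equal(cov$n_nogs, orc$n_nogs)
    expect_equal(cov$covered, orc$covered)
    # conservation: covered + uncovered = bin size
    expect_true(all(cov$covered <= cov$n_nogs))
    expect_equal(sum(cov$n_nogs),
                 length(unique(unlist(samples))))
  }
})

test_that("coverage is monotone under consortium-union supersets", {
  for (seed in 1:5) {
    set.seed(seed)
    universe <- sprintf("N%02d", 1:40)
    samples <- lapply(1:5, function(i) sample(universe, 20))
    names(samples) <- paste0("s", 1:5)
    mc <- MetagenomeCollection(samples)
    small <- list(a = sample(universe, 8))
    big <- c(small, list(b = sample(universe, 12)))
    cs <- coverageByFrequency(small, mc)
    cb <- coverageByFrequency(big, mc)
    m <- merge(cs, cb, by = "bin")
    expect_true(all(m$percent.y >= m$percent.x))
  }
})

test_that("stratified draws honor strata, pools and the seed", {
  pools <- list(Firmicutes = sprintf("F%02d", 1:20),
                Bacteroidetes = sprintf("B%02d", 1:8))
  strata <- scaleStrata(8)
  expect_identical(strata, c(Firmicutes = 6L, Bacteroidetes = 2L))
  expect_identical(scaleStrata(16), c(Firmicutes = 12L, Bacteroidetes = 4L))
  expect_identical(scaleStrata(32), c(Firmicutes = 24L, Bacteroidetes = 8L))
  expect_error(scaleStrata(9), "not divisible")

  draws <- drawConsortia(pools, strata, n_draws = 25, seed = 42)
  expect_length(draws, 25)
  for (d in draws) {
    expect_length(d, 8)
    expect_false(anyDuplicated(d) > 0)
    expect_equal(sum(startsWith(d, "F")), 6)
    expect_equal(sum(startsWith(d, "B")), 2)
  }
  # determinism
  draws2 <- drawConsortia(pools, strata, n_draws = 25, seed = 42)
  expect_identical(draws, draws2)
  # pool exactly the stratum -> every draw is the full pool
  tight <- drawConsortia(list(F = c("f1", "f2")), c(F = 2L),
                         n_draws = 3, seed = 1)
  expect_true(all(vapply(tight, function(d)
    setequal(d, c("f1", "f2")), logical(1))))
  expect_error(drawConsortia(pools, c(Firmicutes = 21L, Bacteroidetes = 2L),
                             n_draws = 1, seed = 1), "exceeds pool size")
})

test_that("member substitution preserves size and rejects bad input", {
  phyla <- c(f1 = "Firmicutes", f2 = "Firmicutes", b1 = "Bacteroidetes")
  out <- substituteMember(c("f1", "f2", "b1"), phyla, "Bacteroidetes", "m457")
  expect_length(out, 3)
  expect_true("m457" %in% out)
  expect_false("b1" %in% out)
  expect_error(substituteMember(c("f1", "f2"), phyla, "Bacteroidetes", "m"),
               "no member")
  expect_error(substituteMember(c("f1", "b1"), phyla, "Bacteroidetes", "f1"),
               "already")
})

test_that("unique contributions match per-NOG holder enumeration", {
  cat <- NogCatalog(sprintf("N%02d", 1:50),
                    sample(c("J", "K", "L"), 50, replace = TRUE))
  for (seed in 1:5) {
    set.seed(seed)
    universe <- sprintf("N%02d", 1:50)
    species <- lapply(1:4, function(i) sample(universe, sample(5:30, 1)))
    names(species) <- paste0("sp", 1:4)
    target <- sample(universe, 25)
    uc <- uniqueContributions(species, target, cat)
    orc <- oracle_unique(species, target)
    tot <- attr(uc, "total")
    expect_equal(tot[names(orc)], orc)
    # decomposition: totals sum to the uniquely held target NOGs
    expect_equal(sum(tot), sum(orc))
    expect_lte(sum(tot), length(intersect(target,
                                          unique(unlist(species)))))
    # per-category counts sum to totals
    if (nrow(uc))
      expect_equal(sum(uc$n), sum(tot))
  }
  # shared NOG attributed to nobody, singleton to its holder
  uc <- uniqueContributions(list(s1 = c("N01", "N02"), s2 = "N02"),
                            c("N01", "N02"), cat)
  expect_equal(unname(attr(uc, "total")["s1"]), 1L)
  expect_equal(unname(attr(uc, "total")["s2"]), 0L)
})

test_that("percentile bands use linear interpolation per bin", {
  mk <- function(pct) {
    df <- data.frame(bin = 1L, n_nogs = 10L, covered = 1L, percent = pct)
    class(df) <- c("CoverageResult", "data.frame")
    df
  }
  single <- percentileBands(list(mk(40)))
  expect_equal(single$median, 40)
  expect_equal(single$lower, 40)
  expect_equal(single$upper, 40)
  ident <- percentileBands(list(mk(30), mk(30), mk(30)))
  expect_equal(ident$upper - ident$lower, 0)
  three <- percentileBands(list(mk(0), mk(50), mk(100)))
  expect_equal(three$median, 50)
  expect_equal(three$lower, quantile(c(0, 50, 100), 0.05, names = FALSE))
  expect_match(attr(three, "percentile_convention"), "linear")
})
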