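test_that("Jaccard distance matches counting and handles empty sets", {
  expect_equal(jaccardDistance(c("a", "b"), c("a", "b")), 0)
  expect_equal(jaccardDistance(c("a", "b"), c("c", "d")), 1)
  expect_equal(jaccardDistance(c("a", "b"), c("b", "c")), 2 / 3)
  expect_equal(jaccardDistance(character(0), character(0)), 0)
  expect_equal(jaccardDistance(c("a", "a", "b"), c("b", "c")), 2 / 3)
})

test_that("Jaccard satisfies the metric axioms on random set triples", {
  set.seed(10)
  universe <- letters
  for (i in 1:50) {
    a <- sample(universe, sample(0:15, 1))
    b <- sample(universe, sample(0:15, 1))
    c <- sample(universe, sample(0:15, 1))
    dab <- jaccardDistance(a, b)
    expect_equal(dab, jaccardDistance(b, a))          # symmetry
    expect_equal(jaccardDistance(a, a), 0)            # identity
    expect_gte(dab, 0); expect_lte(dab, 1)            # bounds
    expect_lte(dab, jaccardDistance(a, c) + jaccardDistance(c, b) + 1e-12)
  }
})

test_that("pairwise distances cover all unordered pairs of shared species", {
  genetic <- list(s1 = c("n1", "n2"), s2 = c("n2", "n3"), s3 = "n4")
  metabolic <- list(s1 = "glucose|consumed", s2 = "glucose|consumed",
                    s3 = "glucose|produced")
  pd <- pairwiseDistances(genetic, metabolic)
  expect_equal(nrow(pd), choose(3, 2))
  expect_true(all(pd$genetic_distance >= 0 & pd$genetic_distance <= 1))
  expect_false(any(pd$species_a == pd$species_b))
  # consumed and produced of the same peak are different elements
  row <- pd[pd$species_a == "s2" & pd$species_b == "s3", ]
  expect_equal(row$metabolic_distance, 1)
  # 7 species -> 21 pairs
  g7 <- setNames(replicate(7, sample(letters, 5), simplify = FALSE),
                 paste0("sp", 1:7))
  m7 <- setNames(replicate(7, "x|produced", simplify = FALSE),
                 paste0("sp", 1:7))
  expect_equal(nrow(pairwiseDistances(g7, m7)), 21L)
  expect_error(pairwiseDistances(genetic, metabolic[1:2]), "same species")
})

test_that("tagged metabolic sets separate producers from consumers", {
  prof <- data.frame(peak_id = c("glucose", "propionate", "x"),
                     z = c(-5, 4, 0))
  expect_setequal(metabolicProfileSet(prof),
                  c("glucose|consumed", "propionate|produced"))
})

test_that("Spearman rho and exact p agree with brute-force enumeration at n=7", {
  set.seed(11)
  # includes tied (binary presence) vectors: the screen's actual use case
  for (i in 1:100) {
    x <- if (i %% 2) sample(c(0, 1), 7, replace = TRUE) else rnorm(7)
    y <- rnorm(7)
    if (sd(x) == 0) next
    st <- spearmanTest(x, y, method = "exact")
    expect_equal(st$rho, oracle_spearman_rho(x, y), tolerance = 1e-12)
    expect_equal(st$p, oracle_spearman_p(x, y), tolerance = 1e-12)
  }
  # perfectly concordant / anti-concordant ranks
  expect_equal(spearmanTest(1:7, 2 * (1:7))$rho, 1)
  expect_equal(spearmanTest(1:7, -(1:7))$rho, -1)
  # constant vector: undefined
  expect_true(is.na(spearmanTest(rep(1, 7), rnorm(7))$rho))
  # binary presence vs a heavily tied response vector
  st <- spearmanTest(c(1, 1, 0, 0, 0, 0, 0), c(5, 4, 1, 1, 1, 1, 1),
                     method = "exact")
  expect_equal(st$rho, oracle_spearman_rho(c(1, 1, 0, 0, 0, 0, 0),
                                           c(5, 4, 1, 1, 1, 1, 1)))
})

test_that("NOG-metabolite correlation table is Bonferroni-corrected and complete", {
  set.seed(12)
  presence <- matrix(rbinom(7 * 10, 1, 0.5), nrow = 7,
                     dimnames = list(paste0("sp", 1:7),
                                     sprintf("N%02d", 1:10)))
  z <- matrix(rnorm(7 * 5), nrow = 7,
              dimnames = list(paste0("sp", 1:7), sprintf("pk%d", 1:5)))
  presence[, 1] <- 1                     # constant -> NA
  res <- nogMetaboliteCorrelation(presence, z, n_tests = 160746)
  expect_equal(nrow(res), 50L)
  expect_true(all(is.na(res$rho[res$nog_id == "N01"])))
  ok <- !is.na(res$p_raw)
  expect_true(all(res$p_bonf[ok] >= res$p_raw[ok]))   # Bonferroni monotone
  expect_true(all(res$p_bonf[ok] <= 1))
  expect_equal(res$p_bonf[ok], pmin(1, res$p_raw[ok] * 160746))
  # rho agrees with the element-wise oracle
  for (j in c(2, 5, 9)) for (k in 1:3) {
    row <- res[res$nog_id == sprintf("N%02d", j) &
                 res$peak_id == paste0("pk", k), ]
    expect_equal(row$rho, oracle_spearman_rho(presence[, j], z[, k]))
  }
})

test_that("single-species NOGs and metabolites are filtered out", {
  presence <- rbind(sp1 = c(N1 = 1, N2 = 1), sp2 = c(1, 0), sp3 = c(1, 0))
  z <- rbind(sp1 = c(pk1 = 1, pk2 = 2), sp2 = c(2, 1), sp3 = c(3, 3))
  res <- nogMetaboliteCorrelation(presence, z)
  kept <- filterInformative(res, presence,
                            activity_counts = c(pk1 = 3L, pk2 = 1L))
  expect_setequal(unique(kept$nog_id), "N1")     # N2 in one species only
  expect_setequal(unique(kept$peak_id), "pk1")   # pk2 active in one species
  expect_true(all(kept$retained_after_filter))
  none <- filterInformative(res, presence,
                            activity_counts = c(pk1 = 0L, pk2 = 1L))
  expect_equal(nrow(none), 0L)
})
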