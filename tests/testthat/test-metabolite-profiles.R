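test_that("reference stats use the n-1 sample SD and reject zero-SD peaks", {
  m <- cbind(p1 = c(1, 1, 3, 3), p2 = c(0, 2, 0, 2))
  ref <- referenceStats(m)
  expect_equal(ref$mean, c(2, 1))
  expect_equal(ref$sd[1], sd(c(1, 1, 3, 3)))  # ~1.1547
  expect_equal(ref$sd[1], 2 / sqrt(3))
  ref2 <- referenceStats(cbind(p1 = c(0, 2)))
  expect_equal(ref2$mean, 1)
  expect_equal(ref2$sd, sqrt(2))
  degenerate <- cbind(p1 = c(1, 1, 1), p2 = c(0, 1, 2))
  expect_error(referenceStats(degenerate), "p1")
  expect_error(referenceStats(cbind(p1 = 1)), "at least 2")
})

test_that("z-scores and calls follow the strict ±2 SD rule", {
  ref <- data.frame(peak_id = c("a", "b", "c", "d"),
                    mean = c(1, 1, 1, 1), sd = c(0.5, 0.5, 0.5, 0.5))
  x <- c(a = 1, b = 1 + 3 * 0.5, c = 1 - 2 * 0.5, d = 1 - 2.5 * 0.5)
  prof <- zscoreProfile(x, ref)
  expect_equal(prof$z, c(0, 3, -2, -2.5))
  expect_identical(prof$call, c("Medium", "High", "Medium", "Low"))
  # boundary: z exactly ±2 is Medium (strict inequalities)
  expect_identical(zscoreProfile(c(a = 2, b = 1, c = 1, d = 1),
                                 ref)$call[1], "Medium")
  expect_error(zscoreProfile(c(a = 1), ref), "missing peak")
})

test_that("every peak gets exactly one call and sets are disjoint", {
  set.seed(3)
  ref <- data.frame(peak_id = sprintf("p%02d", 1:30),
                    mean = runif(30, 0.5, 2), sd = runif(30, 0.1, 0.5))
  x <- setNames(ref$mean + rnorm(30, 0, 3 * ref$sd), ref$peak_id)
  prof <- zscoreProfile(x, ref)
  expect_true(all(prof$call %in% c("High", "Medium", "Low")))
  cp <- consumedProducedSets(prof)
  expect_length(intersect(cp$consumed, cp$produced), 0)
  expect_setequal(cp$produced, prof$peak_id[prof$z > 2])
  expect_setequal(cp$consumed, prof$peak_id[prof$z < -2])
})

test_that("z-scores are invariant to a positive rescaling of all integrals", {
  set.seed(4)
  fresh <- matrix(runif(40, 0.5, 2), nrow = 5,
                  dimnames = list(NULL, sprintf("p%d", 1:8)))
  x <- setNames(runif(8, 0.2, 3), colnames(fresh))
  for (k in c(0.2, 3, 17)) {
    z1 <- zscoreProfile(x, referenceStats(fresh))
    z2 <- zscoreProfile(k * x, referenceStats(k * fresh))
    expect_equal(z1$z, z2$z)
    expect_identical(z1$call, z2$call)
  }
})

test_that("the fresh mean row scores all-Medium against its own reference", {
  set.seed(5)
  fresh <- matrix(runif(60, 0.5, 2), nrow = 6,
                  dimnames = list(NULL, sprintf("p%d", 1:10)))
  ref <- referenceStats(fresh)
  prof <- zscoreProfile(setNames(colMeans(fresh), colnames(fresh)), ref)
  expect_true(all(prof$z == 0))
  expect_true(all(prof$call == "Medium"))
})

test_that("display clipping bounds z at ±6 and never affects calls", {
  expect_equal(clipForDisplay(8), 6)
  expect_equal(clipForDisplay(-7), -6)
  expect_equal(clipForDisplay(1.5), 1.5)
  expect_equal(clipForDisplay(c(-10, 0, 10), bound = 3), c(-3, 0, 3))
})

test_that("consumed/produced sets use strict inequalities", {
  prof <- data.frame(peak_id = c("glucose", "propionate", "edge"),
                     z = c(-5, 4, 2))
  cp <- consumedProducedSets(prof)
  expect_identical(cp$consumed, "glucose")
  expect_identical(cp$produced, "propionate")
  none <- consumedProducedSets(data.frame(peak_id = "a", z = 0))
  expect_length(none$consumed, 0)
  expect_length(none$produced, 0)
})

test_that("abundanceProfiles averages replicates then z-scores every condition", {
  set.seed(6)
  peaks <- c("glucose", "butyrate")
  base <- c(1, 1)
  m <- cbind(base + rnorm(2, 0, 0.05), base + rnorm(2, 0, 0.05),
             base + rnorm(2, 0, 0.05),
             c(0.2, 1), c(0.25, 1),       # spent: glucose consumed
             c(0.2, 1.9), c(0.25, 1.9))   # double spent: butyrate up
  rownames(m) <- peaks
  pe <- PeakExperiment(m, condition = c("fresh", "fresh", "fresh",
                                        "spentsp1", "spentsp1",
                                        "dssp2_in_spentsp1",
                                        "dssp2_in_spentsp1"))
  prof <- abundanceProfiles(pe)
  expect_setequal(unique(prof$condition_id),
                  c("spentsp1", "dssp2_in_spentsp1"))
  glc <- prof[prof$peak_id == "glucose" &
                prof$condition_id == "spentsp1", ]
  expect_identical(glc$call, "Low")
  # planted recovery sharpens as replicate noise shrinks
  hits <- vapply(1:20, function(seed) {
    set.seed(seed)
    noise <- 0.02
    fresh <- matrix(1 + rnorm(20, 0, noise), nrow = 10,
                    dimnames = list(NULL, c("up", "down")))
    ref <- referenceStats(fresh)
    x <- c(up = 1 + 4 * noise, down = 1 - 4 * noise)
    identical(zscoreProfile(x, ref)$call, c("High", "Low"))
  }, logical(1))
  expect_true(mean(hits) >= 0.95)
})
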