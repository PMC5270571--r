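test_that("call pairs map deterministically onto the 9 transitions", {
  expect_identical(classifyTransition("High", "Medium"),
                   data.frame(transition = "High to Medium",
                              group = "Lower"))
  expect_identical(classifyTransition("Medium", "Medium")$group,
                   "NoChange")
  expect_identical(classifyTransition("Low", "High"),
                   data.frame(transition = "Low to High",
                              group = "Higher"))
  # the 9 pairs partition into 3 groups of 3
  grid <- expand.grid(s = c("Low", "Medium", "High"),
                      d = c("Low", "Medium", "High"),
                      stringsAsFactors = FALSE)
  cls <- classifyTransition(grid$s, grid$d)
  expect_equal(as.vector(table(cls$group)[c("NoChange", "Lower", "Higher")]),
               c(3L, 3L, 3L))
  expect_error(classifyTransition("high", "Low"), "calls must be")
})

test_that("tabulation reproduces counts with exact marginal conservation", {
  r <- data.frame(donor = "a", grower = "b", peak_id = "p",
                  spent_call = "High", double_call = "Medium", grew = TRUE)
  tab <- tabulateTransitions(r)
  expect_equal(attr(tab, "grand_total"), 1L)
  expect_equal(tab$count[tab$growth == "growth" &
                           tab$transition == "High to Medium"], 1L)
  # empty input -> all-zero 18-cell table
  tab0 <- tabulateTransitions(r[0, ])
  expect_equal(nrow(tab0), 18L)
  expect_equal(sum(tab0$count), 0L)
  # duplicates rejected
  expect_error(tabulateTransitions(rbind(r, r)), "duplicate")
  # arbitrary record sets: grand total = n, marginals consistent
  for (seed in 1:8) {
    rec <- random_records(200, seed)
    tab <- tabulateTransitions(rec)
    expect_equal(attr(tab, "grand_total"), 200L)
    sub <- attr(tab, "group_subtotals")
    for (i in seq_len(nrow(sub)))
      expect_equal(sub$count[i],
                   sum(tab$count[tab$growth == sub$growth[i] &
                                   tab$group == sub$group[i]]))
    tot <- attr(tab, "growth_totals")
    expect_equal(unname(tot["growth"]),
                 sum(tab$count[tab$growth == "growth"]))
    expect_equal(sum(tot), 200L)
  }
})

test_that("published screen counts reproduce the reference marginals", {
  counts <- publishedScenarioCounts()
  rec <- recordsFromScenarioCounts(counts)
  tab <- tabulateTransitions(rec)
  sub <- attr(tab, "group_subtotals")
  g <- function(gr, st) sub$count[sub$growth == gr & sub$group == st]
  expect_equal(g("growth", "NoChange"), 614L)
  expect_equal(g("growth", "Lower"), 73L)
  expect_equal(g("growth", "Higher"), 333L)
  expect_equal(unname(attr(tab, "growth_totals")["growth"]), 1020L)
  expect_equal(g("no_growth", "NoChange"), 2081L)
  expect_equal(unname(attr(tab, "growth_totals")["no_growth"]), 2550L)
  expect_equal(attr(tab, "grand_total"), 3570L)
})

test_that("cross-feeding requires growth and a donor-produced decrease", {
  rec <- data.frame(
    donor = "sp519", grower = "sp356",
    peak_id = c("nicotinamide", "lactate", "alanine", "uracil"),
    spent_call = c("High", "High", "Medium", "High"),
    double_call = c("Low", "Medium", "Low", "High"),
    grew = c(TRUE, TRUE, TRUE, TRUE))
  cf <- detectCrossFeeding(rec)
  expect_setequal(cf$peak_id, c("nicotinamide", "lactate"))
  # no growth -> never cross-feeding even for High -> Low
  rec$grew <- FALSE
  expect_equal(nrow(detectCrossFeeding(rec)), 0L)
})

test_that("emergent calls compare double-spent behavior to fresh behavior", {
  fresh_calls <- data.frame(
    species = c("sp519", "sp519", "sp519"),
    peak_id = c("butyrate", "glucose", "3-hydroxybutyrate"),
    call = c("Medium", "Low", "High"))
  rec <- data.frame(
    donor = "sp356", grower = "sp519",
    peak_id = c("butyrate", "glucose", "3-hydroxybutyrate"),
    spent_call = c("Medium", "Medium", "Medium"),
    double_call = c("High", "Low", "Low"),
    grew = TRUE)
  em <- detectEmergent(rec, fresh_calls)
  # producing butyrate only in spent media: emergent production
  expect_identical(em$call[em$peak_id == "butyrate"],
                   "emergent_production")
  # consuming glucose as in fresh media: not emergent
  expect_false("glucose" %in% em$peak_id)
  # switching from producing to consuming: emergent consumption
  expect_identical(em$call[em$peak_id == "3-hydroxybutyrate"],
                   "emergent_consumption")
  # growth is required
  rec$grew <- FALSE
  expect_equal(nrow(detectEmergent(rec, fresh_calls)), 0L)
  expect_error(detectEmergent(transform(rec, grower = "spX"), fresh_calls),
               "spX")
})

test_that("competition markers are peaks consumed by both species", {
  fresh_calls <- data.frame(
    species = rep(c("sp356", "sp519"), each = 3),
    peak_id = rep(c("glucose", "lactate", "alanine"), 2),
    call = c("Low", "Low", "High", "Low", "Medium", "Low"))
  cm <- competitionMarkers(fresh_calls)
  expect_identical(cm$peak_id, "glucose")
  none <- competitionMarkers(data.frame(
    species = c("a", "b"), peak_id = c("x", "y"), call = "Low"))
  expect_equal(nrow(none), 0L)
  expect_error(competitionMarkers(fresh_calls[fresh_calls$species ==
                                                "sp356", ]), "2 species")
})

test_that("comparison records pair spent and double-spent profiles with growth", {
  profiles <- data.frame(
    condition_id = rep(c("spentsp1", "dssp2_in_spentsp1"), each = 2),
    peak_id = rep(c("a", "b"), 2),
    z = c(4, 0, 0.5, -4),
    call = c("High", "Medium", "Medium", "Low"))
  growth <- data.frame(species = "sp2", medium = "spentsp1", grew = TRUE)
  rec <- buildComparisonRecords(profiles, growth)
  expect_equal(nrow(rec), 2L)
  expect_identical(rec$donor, c("sp1", "sp1"))
  expect_identical(rec$grower, c("sp2", "sp2"))
  expect_identical(rec$spent_call[rec$peak_id == "a"], "High")
  expect_identical(rec$double_call[rec$peak_id == "b"], "Low")
  expect_true(all(rec$grew))
  # self pairs are structurally impossible
  bad <- transform(profiles,
                   condition_id = sub("dssp2", "dssp1", condition_id))
  expect_error(buildComparisonRecords(bad, growth), "self pair")
})
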