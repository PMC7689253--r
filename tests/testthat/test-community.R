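# Relative abundance, guild composition, shift metrics and clone libraries.

test_that("relative abundances sum to 100 per sample", {
  m <- matrix(c(50, 50, 1, 0, 3, 7), nrow = 2,
              dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
  tab <- TaxonCountTable(m, depth = rep("top_0_20", 3),
                         timepoint = rep("day0", 3))
  ra <- relativeAbundance(tab)
  expect_equal(ra[, "s1"], c(A = 50, B = 50))
  expect_equal(ra[, "s2"], c(A = 100, B = 0))
  expect_equal(ra[, "s3"], c(A = 30, B = 70))
  expect_equal(colSums(ra), c(s1 = 100, s2 = 100, s3 = 100),
               tolerance = 1e-9)
  set.seed(3)
  rm <- matrix(rpois(60, 40) + 1, nrow = 6,
               dimnames = list(paste0("t", 1:6), paste0("s", 1:10)))
  rt <- TaxonCountTable(rm, depth = rep("top_0_20", 10),
                        timepoint = rep("day0", 10))
  expect_equal(unname(colSums(relativeAbundance(rt))), rep(100, 10),
               tolerance = 1e-9)
})

test_that("zero-total samples are rejected at construction", {
  m <- matrix(c(1, 2, 0, 0), nrow = 2,
              dimnames = list(c("A", "B"), c("s1", "s2")))
  expect_error(TaxonCountTable(m, depth = c("d", "d"),
                               timepoint = c("t", "t")),
               "positive total")
})

test_that("guild composition reproduces the in-situ fixture anchors", {
  fx <- buildPaperFixtures()
  gc <- guildComposition(fx$community)
  expect_equal(colSums(gc), setNames(rep(100, 6), colnames(gc)),
               tolerance = 1e-9)
  expect_equal(gc["Methylosinus", "top_insitu"], 50)
  expect_equal(gc["Methylocaldum", "top_insitu"], 21)
  expect_equal(gc["Methylosinus", "deep_insitu"], 50)
  expect_equal(gc["Methylobacter", "deep_insitu"], 42)
  expect_equal(gc["Crenothrix", "mid_insitu"], 37)
  expect_equal(gc["Methylosinus", "mid_insitu"], 29)
  expect_equal(gc["Methylocaldum", "mid_insitu"], 22)
})

test_that("guild matching is case-insensitive and flags empty guilds", {
  m <- matrix(c(10, 90, 5, 95), nrow = 2,
              dimnames = list(c("METHYLOBACTER", "Other"), c("s1", "s2")))
  tab <- TaxonCountTable(m, depth = c("d", "d"), timepoint = c("t", "t"))
  gc <- guildComposition(tab)
  expect_equal(gc["Methylobacter", "s1"], 100)
  single <- guildComposition(tab, GuildPanel("one", "Methylobacter"))
  expect_equal(unname(single[1, ]), c(100, 100))
  noGuild <- TaxonCountTable(
    matrix(c(1, 1), 1, 2, dimnames = list("Other", c("s1", "s2"))),
    depth = c("d", "d"), timepoint = c("t", "t"))
  expect_error(guildComposition(noGuild), "no panel member")
})

test_that("abundance shifts report points and folds consistently", {
  s <- abundanceShift(2.35, 35.25)
  expect_equal(s$pp_change, 32.9)
  expect_equal(s$fold_change, 15)
  same <- abundanceShift(12.5, 12.5)
  expect_equal(same$pp_change, 0)
  expect_equal(same$fold_change, 1)
  zero <- abundanceShift(0, 5)
  expect_equal(zero$pp_change, 5)
  expect_true(is.na(zero$fold_change))
  # round-trip: (pp, fold) with fold != 1 determine the two abundances
  set.seed(5)
  for (i in 1:25) {
    init <- runif(1, 0.5, 40); fin <- runif(1, 0.5, 60)
    if (abs(fin - init) < 1e-6) next
    m <- abundanceShift(init, fin)
    expect_equal(m$pp_change / (m$fold_change - 1), init,
                 tolerance = 1e-9)
    expect_equal(m$fold_change * init, fin, tolerance = 1e-9)
  }
})

test_that("clone percentages use half-up display rounding", {
  cpm <- clonePercentages(c(Methylobacter = 15, other = 37))
  expect_equal(cpm$percent_display[cpm$taxon == "Methylobacter"], 28.85)
  cp <- clonePercentages(c(Methanothrix = 19, rest = 13))
  expect_equal(cp$percent_display[cp$taxon == "Methanothrix"], 59.38)
  cp0 <- clonePercentages(c(a = 0, b = 10))
  expect_equal(cp0$percent_display[cp0$taxon == "a"], 0)
  expect_error(clonePercentages(numeric(0)), "empty")
  expect_error(clonePercentages(c(a = 0, b = 0)), "empty")
  # percentages sum to 100 within display rounding
  fx <- buildPaperFixtures()
  for (lib in c(fx$clones$bacterial, fx$clones$archaeal)) {
    cp <- clonePercentages(lib)
    expect_equal(sum(cp$percent), 100, tolerance = 1e-9)
    expect_lte(abs(sum(cp$percent_display) - 100), 0.01 * nrow(cp))
  }
})

test_that("clone fixtures reproduce the reported library percentages", {
  fx <- buildPaperFixtures()
  pctOf <- function(lib, taxon)
    clonePercentages(lib)$percent_display[
      clonePercentages(lib)$taxon == taxon]
  expect_equal(vapply(fx$clones$bacterial, pctOf, numeric(1),
                      taxon = "Methylobacter"),
               c(top_0_20 = 28.85, mid_40_60 = 24.00, deep_60_80 = 21.28))
  expect_equal(vapply(fx$clones$archaeal, pctOf, numeric(1),
                      taxon = "Methanothrix"),
               c(top_0_20 = 59.38, mid_40_60 = 32.26, deep_60_80 = 38.71))
  expect_equal(vapply(fx$clones$archaeal, pctOf, numeric(1),
                      taxon = "Methanosarcina"),
               c(top_0_20 = 21.88, mid_40_60 = 25.81, deep_60_80 = 22.58))
  expect_equal(sum(vapply(fx$clones$bacterial, sum, numeric(1))), 149)
  expect_equal(sum(vapply(fx$clones$archaeal, sum, numeric(1))), 94)
})

test_that("dominant taxon is the row maximum with alphabetical ties", {
  fx <- buildPaperFixtures()
  for (depth in names(fx$clones$bacterial)) {
    cp <- clonePercentages(fx$clones$bacterial[[depth]])
    m <- matrix(cp$percent, ncol = 1, dimnames = list(cp$taxon, "lib"))
    expect_equal(dominantTaxon(m, "lib"), "Methylobacter")
  }
  tie <- matrix(c(40, 40, 20), ncol = 1,
                dimnames = list(c("B", "A", "C"), "s"))
  expect_equal(dominantTaxon(tie, "s"), "A")
  single <- matrix(100, dimnames = list("X", "s"))
  expect_equal(dominantTaxon(single, "s"), "X")
  # agrees with brute-force max on random tables
  set.seed(8)
  for (i in 1:20) {
    m <- matrix(runif(12), nrow = 4,
                dimnames = list(letters[1:4], paste0("s", 1:3)))
    for (s in colnames(m))
      expect_equal(dominantTaxon(m, s),
                   rownames(m)[which.max(m[, s])])
  }
})

test_that("communityShifts tracks taxa across timepoints", {
  fx <- buildPaperFixtures()
  sh <- communityShifts(fx$community, taxa = "Methylobacter")
  top <- sh[sh$depth_label == "top_0_20", ]
  expect_equal(top$ra_initial_pct, 2.35)
  expect_equal(top$ra_final_pct, 35.25)
  expect_equal(top$pp_change, 32.9)
  expect_equal(top$fold_change, 15)
  mid <- sh[sh$depth_label == "mid_40_60", ]
  expect_equal(mid$fold_change, 5) # count fixture carries the fold anchor
  deep <- sh[sh$depth_label == "deep_60_80", ]
  expect_equal(deep$pp_change, 10.6, tolerance = 1e-9)
  expect_equal(round(deep$fold_change, 1), 1.3)
})

test_that("the shift fixture inverts every reported pp/fold pair", {
  fx <- buildPaperFixtures()
  s <- abundanceShift(fx$shifts$ra_initial_pct, fx$shifts$ra_final_pct,
                      taxon = fx$shifts$taxon)
  expect_equal(s$pp_change, c(32.9, 52.9, 10.6), tolerance = 1e-9)
  expect_equal(s$fold_change, c(15, 5, 1.3), tolerance = 1e-9)
})
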