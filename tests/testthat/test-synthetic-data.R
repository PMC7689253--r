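# Simulators: determinism, noiseless round trips, fixture self-consistency.

test_that("noiseless microcosm simulation round-trips the ground truth", {
  cfg <- simConfig(noiseSd = 0, controlDriftSd = 0, seed = 1)
  m <- simulateMicrocosm(cfg)
  pot <- computePotentials(m, cfg$setup)
  lab <- pot[pot$treatment == "labeled", ]
  means <- vapply(split(lab$total_ch4_oxidation, lab$depth_label), mean,
                  numeric(1))
  expect_equal(means[cfg$truth$depth_label],
               setNames(cfg$truth$ch4_total, cfg$truth$depth_label),
               tolerance = 1e-9)
  n2 <- vapply(split(lab$n2_fixation, lab$depth_label), mean, numeric(1))
  expect_equal(n2[cfg$truth$depth_label],
               setNames(cfg$truth$n2_fixation, cfg$truth$depth_label),
               tolerance = 1e-9)
  fr <- vapply(split(lab$co2_fraction, lab$depth_label), mean, numeric(1))
  expect_equal(fr[cfg$truth$depth_label],
               setNames(cfg$truth$co2_share, cfg$truth$depth_label),
               tolerance = 1e-9)
})

test_that("simulators are pure functions of config and seed", {
  cfg <- simConfig(seed = 42)
  expect_identical(simulateMicrocosm(cfg), simulateMicrocosm(cfg))
  expect_false(identical(simulateMicrocosm(cfg),
                         simulateMicrocosm(simConfig(seed = 43))))
  gcfg <- gradientSimConfig(seed = 42)
  expect_identical(simulateGradient(gcfg), simulateGradient(gcfg))
  ccfg <- communitySimConfig(seed = 7)
  expect_identical(taxonCounts(simulateCommunity(ccfg)),
                   taxonCounts(simulateCommunity(ccfg)))
  # the caller's RNG stream is left untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulateMicrocosm(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("the default density grid contains both canonical band centers", {
  g <- defaultDensityGrid()
  expect_length(g, 15)
  expect_true(all(diff(g) > 0))
  expect_gte(min(g), 1.70 - 1e-12)
  expect_lte(max(g), 1.75 + 1e-12)
  expect_true(1.720 %in% g)
  expect_true(1.734 %in% g)
})

test_that("noiseless gradient bands peak at their configured centers", {
  g <- simulateGradient(gradientSimConfig(noiseSdLog = 0))
  peakOf <- function(gene, tr) {
    sub <- g[g$gene_name == gene & g$treatment_label == tr, ]
    peakDensity(GradientProfile(sub$buoyant_density_g_per_ml,
                                sub$copy_number, gene, tr))
  }
  expect_equal(peakOf("pmoA", "labeled_13C"), 1.734)
  expect_equal(peakOf("pmoA", "control_12C"), 1.720)
  expect_equal(peakOf("nifH", "labeled_13C"), 1.720)
  expect_equal(peakOf("nifH", "control_12C"), 1.720)
})

test_that("very wide bands flatten toward a uniform profile", {
  g <- simulateGradient(gradientSimConfig(
    noiseSdLog = 0, bandWidthSd = 10,
    bandCenters = data.frame(gene_name = "pmoA",
                             treatment_label = "labeled_13C",
                             center_g_per_ml = 1.734)))
  p <- GradientProfile(g$buoyant_density_g_per_ml, g$copy_number)
  rel <- copyNumbers(normalizeProfile(p))
  expect_lt(max(rel) - min(rel), 1e-4)
  grid <- defaultDensityGrid()
  expect_equal(weightedMeanDensity(p), mean(grid), tolerance = 1e-3)
})

test_that("community draws concentrate on targets for large libraries", {
  ccfg <- communitySimConfig(overdispersion = 0, seed = 12)
  ccfg$librarySizes[] <- 200000L
  tab <- simulateCommunity(ccfg)
  ra <- relativeAbundance(tab)
  pr <- ccfg$proportions
  for (s in colnames(ra)) {
    target <- setNames(pr$proportion[pr$sample_id == s] * 100,
                       pr$taxon[pr$sample_id == s])
    expect_lt(max(abs(ra[names(target), s] - target)), 0.5)
  }
})

test_that("fixtures are self-consistent with the reported summaries", {
  fx <- buildPaperFixtures()
  pot <- computePotentials(fx$measurements, fx$setup)
  lab <- pot[pot$treatment == "labeled", ]
  ch4 <- vapply(split(lab$total_ch4_oxidation, lab$depth_label), mean,
                numeric(1))
  fr <- depthFoldRatios(ch4)
  expect_equal(fr$ratioDisplay[fr$numerator == "mid_40_60" &
                               fr$denominator == "top_0_20"], 2.5)
  expect_equal(fr$ratioDisplay[fr$numerator == "mid_40_60" &
                               fr$denominator == "deep_60_80"], 1.2)
  expect_true(all(lab$co2_fraction >= 0.67 - 1e-9 &
                  lab$co2_fraction <= 0.81 + 1e-9))
  # replicate sd equals the configured spread
  s <- summarizePotentials(pot)
  expect_equal(s$ch4_total_sd[s$depth_label == "mid_40_60"], 3.10,
               tolerance = 1e-9)
  expect_equal(s$n2_fixation_sd[s$depth_label == "mid_40_60"], 0.04,
               tolerance = 1e-9)
  # clone fixture mode is fixed, not sampled
  expect_equal(sum(fx$clones$bacterial$top_0_20), 52)
  expect_equal(fx$clones$bacterial$top_0_20[["Methylobacter"]], 15)
})

test_that("config validation rejects malformed inputs", {
  expect_error(simConfig(noiseSd = -0.1), ">= 0")
  tr <- simConfig()$truth
  tr$co2_share[1] <- 1.2
  expect_error(simConfig(truth = tr), "co2_share")
  expect_error(gradientSimConfig(densityGrid = c(1.7, 1.9)), "1.60")
  expect_error(gradientSimConfig(bandWidthSd = 0), "bandWidthSd")
  pr <- data.frame(sample_id = "s", depth_label = "d", timepoint = "t",
                   taxon = c("A", "B"), proportion = c(0.6, 0.6))
  expect_error(communitySimConfig(proportions = pr), "sum to 1")
})
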