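# Isotope mass-balance equations and their algebraic inverse.

test_that("atom-percent excess is plain subtraction with domain checks", {
  expect_equal(atomPercentExcess(10.5, 0.5), 10.0)
  expect_equal(atomPercentExcess(1.08, 1.08), 0.0)
  expect_equal(atomPercentExcess(0.5, 1.0), -0.5) # propagated, not clamped
  expect_error(atomPercentExcess(101, 0.5), "\\[0, 100\\]")
  expect_error(atomPercentExcess(10, -1), "\\[0, 100\\]")
})

test_that("CO2 oxidation potential matches the hand unit-conversion oracle", {
  setup <- IncubationSetup(dryMassG = 5, incubationDays = 90,
                           headspaceVolumeMl = 360,
                           molarVolumeLPerMol = 22.4)
  # 0.01 * 0.10 * 0.360 / 22.4 * 1e9 / 450
  expect_equal(co2OxidationPotential(1.0, 10.0, setup),
               0.01 * 0.10 * 0.360 / 22.4 * 1e9 / 450, tolerance = 1e-12)
  expect_equal(round(co2OxidationPotential(1.0, 10.0, setup), 2), 35.71)
  expect_identical(co2OxidationPotential(3.3, 0, setup), 0)
  expect_error(co2OxidationPotential(1, 10, IncubationSetup(dryMassG = -1)))
})

test_that("SOC assimilation potential uses the molar mass and m cancels", {
  setup <- IncubationSetup(dryMassG = 5, incubationDays = 90)
  # 0.05 * 5 * 1e-4 / 13 * 1e9 / 450 (m cancels)
  expect_equal(socAssimilationPotential(5.0, 0.01, setup),
               0.05 * 5 * 1e-4 / 13 * 1e9 / 450, tolerance = 1e-12)
  expect_equal(round(socAssimilationPotential(5.0, 0.01, setup), 3), 4.274)
  expect_identical(socAssimilationPotential(5.0, 0, setup), 0)
  # doubling the excess doubles the result
  expect_equal(socAssimilationPotential(5.0, 0.02, setup),
               2 * socAssimilationPotential(5.0, 0.01, setup))
  # invariant to the soil mass
  expect_equal(socAssimilationPotential(5.0, 0.01,
                                        IncubationSetup(dryMassG = 50)),
               socAssimilationPotential(5.0, 0.01, setup))
})

test_that("N2 fixation potential matches the hand oracle", {
  setup <- IncubationSetup()
  expect_equal(n2FixationPotential(0.50, 0.005, setup),
               0.005 * 5 * 5e-5 / 15 * 1e9 / 450, tolerance = 1e-12)
  expect_equal(round(n2FixationPotential(0.50, 0.005, setup), 4), 0.1852)
  expect_identical(n2FixationPotential(0.50, 0, setup), 0)
})

test_that("total and CO2 fraction partition the oxidized methane", {
  r <- totalMethaneOxidation(106.69, 37.48)
  expect_equal(r$total, 144.17)
  expect_equal(round(r$co2Fraction, 2), 0.74)
  r0 <- totalMethaneOxidation(0, 0)
  expect_equal(r0$total, 0)
  expect_true(is.na(r0$co2Fraction))
  expect_equal(totalMethaneOxidation(1, 1)$co2Fraction, 0.5)
})

test_that("depth fold ratios report ordered pairs with display rounding", {
  ch4 <- c(top = 57.67, mid = 144.17, deep = 120.14)
  fr <- depthFoldRatios(ch4)
  get <- function(a, b) fr$ratioDisplay[fr$numerator == a &
                                        fr$denominator == b]
  expect_equal(get("mid", "top"), 2.5)
  expect_equal(get("mid", "deep"), 1.2)
  n2 <- c(top = 0.41, mid = 0.57, deep = 0.13)
  frn <- depthFoldRatios(n2)
  getn <- function(a, b) frn$ratioDisplay[frn$numerator == a &
                                          frn$denominator == b]
  expect_equal(getn("mid", "deep"), 4.4)
  expect_equal(getn("mid", "top"), 1.4)
  same <- depthFoldRatios(c(a = 3, b = 3))
  expect_true(all(same$ratio == 1))
  zero <- depthFoldRatios(c(a = 1, b = 0))
  expect_false(zero$defined[zero$denominator == "b"])
  expect_true(is.na(zero$ratio[zero$denominator == "b"]))
})

test_that("forward/inverse round-trip is exact to 1e-9 relative", {
  expect_equal(inverseAtomExcess(35.71, "co2", IncubationSetup(),
                                 co2ConcentrationPct = 1.0),
               10.0, tolerance = 1e-3)
  expect_identical(inverseAtomExcess(0, "soc", IncubationSetup(),
                                     socContentPct = 5), 0)
  expect_error(inverseAtomExcess(1, "co2", IncubationSetup(),
                                 co2ConcentrationPct = 0), "positive")
  set.seed(11)
  for (i in 1:100) {
    setup <- randomSetup()
    target <- runif(1, 0, 500)
    pool <- runif(1, 0.1, 10)
    dA <- inverseAtomExcess(target, "co2", setup,
                            co2ConcentrationPct = pool)
    expect_equal(co2OxidationPotential(pool, dA, setup), target,
                 tolerance = 1e-9)
    dA <- inverseAtomExcess(target, "soc", setup, socContentPct = pool)
    expect_equal(socAssimilationPotential(pool, dA, setup), target,
                 tolerance = 1e-9)
    dA <- inverseAtomExcess(target, "son", setup, sonContentPct = pool)
    expect_equal(n2FixationPotential(pool, dA, setup), target,
                 tolerance = 1e-9)
  }
})

test_that("potentials are linear in excess and pool, 1/m in gas only", {
  set.seed(7)
  for (i in 1:20) {
    setup <- randomSetup()
    pool <- runif(1, 0.5, 5); dA <- runif(1, 0.01, 5)
    # linear in dA
    expect_equal(co2OxidationPotential(pool, 2 * dA, setup),
                 2 * co2OxidationPotential(pool, dA, setup))
    # linear in pool content
    expect_equal(n2FixationPotential(2 * pool, dA, setup),
                 2 * n2FixationPotential(pool, dA, setup))
    # gas potential scales as 1/m
    s2 <- IncubationSetup(dryMassG = 2 * setup@dryMassG,
                          incubationDays = setup@incubationDays,
                          headspaceVolumeMl = setup@headspaceVolumeMl,
                          molarVolumeLPerMol = setup@molarVolumeLPerMol)
    expect_equal(co2OxidationPotential(pool, dA, s2),
                 co2OxidationPotential(pool, dA, setup) / 2)
    # non-negative excess gives non-negative potential
    expect_gte(socAssimilationPotential(pool, dA, setup), 0)
  }
})

test_that("computePotentials flags negative excess and sums components", {
  fx <- buildPaperFixtures()
  pot <- computePotentials(fx$measurements, fx$setup)
  expect_equal(pot$total_ch4_oxidation,
               pot$co2_potential + pot$soc_potential, tolerance = 1e-9)
  lab <- pot[pot$treatment == "labeled", ]
  expect_true(all(lab$co2_fraction >= 0.67 - 1e-9 &
                  lab$co2_fraction <= 0.81 + 1e-9))
  expect_true(all(pot$flags == ""))
  m <- fx$measurements[1, ]
  m$atom13_co2_day90_pct <- m$atom13_co2_day0_pct - 0.01
  potNeg <- computePotentials(m, fx$setup)
  expect_equal(potNeg$flags, "negative_excess")
  expect_lt(potNeg$co2_potential, 0) # propagated, not clamped
  expect_error(computePotentials(m[, -4], fx$setup), "lacks columns")
})

test_that("setup validity rejects non-positive or malformed constants", {
  expect_error(IncubationSetup(dryMassG = 0))
  expect_error(IncubationSetup(incubationDays = 0.5), "incubationDays")
  expect_error(IncubationSetup(molarVolumeLPerMol = -1))
  expect_s4_class(IncubationSetup(molarMass13C = 13.00335),
                  "IncubationSetup")
})
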