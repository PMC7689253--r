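## Isotope mass-balance potentials.
##
## Methane oxidation is traced by feeding 13CH4 and measuring where the heavy
## carbon ends up after incubation: respired to headspace CO2, or assimilated
## into soil organic carbon (SOC). N2 fixation is traced by 15N2 appearing in
## soil organic nitrogen (SON). Each potential is the amount of heavy atoms
## accumulated in a pool, divided by soil dry mass and incubation time:
##
##   gas  pool (CO2):  (Cgas/100) * (dA/100) * (Vh/1000) / Vs * 1e9 / (m*t)
##   soil pools (SOC, SON): (C/100) * m * (dA/100) / M * 1e9 / (m*t)
##
## with Cgas the headspace CO2 volume-%, dA the atom-% excess over day 0,
## Vh the headspace volume (mL at 1 atm), Vs the molar gas volume (L/mol),
## C the pool content (% of dry soil mass), M the isotope molar mass (g/mol),
## m the dry soil mass (g) and t the incubation time (days). All conversions
## (percent -> fraction, mL -> L, mol -> nmol) are explicit; no composite
## scale constants are hard-coded. Note m cancels in the soil-pool form.

.checkPct <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 100))
    stop(what, " must be within [0, 100] atom-%/percent", call. = FALSE)
  invisible(x)
}

#' Atom-percent excess over the day-0 baseline
#'
#' The enrichment of the heavy isotope above its pre-incubation abundance.
#' Negative values (control drift, measurement error) are returned unchanged;
#' callers flag them rather than clamping, so QC problems stay visible.
#'
#' @param aDay90Pct atom-% of the heavy isotope at the end of incubation
#' @param aDay0Pct atom-% at day 0 (natural abundance for controls)
#' @return atom-% excess (may be negative); vectorized
#' @examples
#' atomPercentExcess(10.5, 0.5)   # 10
#' atomPercentExcess(1.08, 1.08)  # 0
#' @export
atomPercentExcess <- function(aDay90Pct, aDay0Pct) {
  .checkPct(aDay90Pct, "aDay90Pct")
  .checkPct(aDay0Pct, "aDay0Pct")
  aDay90Pct - aDay0Pct
}

#' Methane-oxidation potential recovered as headspace 13C-CO2
#'
#' Converts the 13C excess in headspace CO2 into nmol C per g dry soil per
#' day. The headspace CO2 inventory is
#' \code{(co2Pct/100) * (Vh/1000) / Vs} mol; multiplying by the atom-fraction
#' excess and scaling to nmol gives the labeled carbon, normalized by
#' \code{m * t}.
#'
#' @param co2ConcentrationPct headspace CO2 concentration at day 90, volume-%
#' @param atomExcessPct 13C atom-% excess in CO2 (day 90 minus day 0)
#' @param setup an \linkS4class{IncubationSetup}
#' @return nmol C / g dws / day; vectorized over the first two arguments
#' @examples
#' co2OxidationPotential(1.0, 10.0, IncubationSetup())  # 35.71
#' @export
co2OxidationPotential <- function(co2ConcentrationPct, atomExcessPct,
                                  setup = IncubationSetup()) {
  stopifnot(is(setup, "IncubationSetup"))
  validObject(setup)
  .checkPct(co2ConcentrationPct, "co2ConcentrationPct")
  molCO2 <- (co2ConcentrationPct / 100) * (setup@headspaceVolumeMl / 1000) /
    setup@molarVolumeLPerMol
  molCO2 * (atomExcessPct / 100) * 1e9 /
    (setup@dryMassG * setup@incubationDays)
}

#' Methane-oxidation potential assimilated into 13C-SOC
#'
#' Converts the 13C excess in soil organic carbon into nmol C per g dry soil
#' per day. The SOC pool is \code{(socPct/100) * m} g of carbon, i.e.
#' \code{.../M} mol; the soil mass m cancels against the per-gram
#' normalization.
#'
#' @param socContentPct soil organic carbon content, % of dry soil mass
#' @param atomExcessPct 13C atom-% excess in SOC
#' @inheritParams co2OxidationPotential
#' @return nmol C / g dws / day
#' @examples
#' socAssimilationPotential(5.0, 0.01, IncubationSetup())  # 4.274
#' @export
socAssimilationPotential <- function(socContentPct, atomExcessPct,
                                     setup = IncubationSetup()) {
  stopifnot(is(setup, "IncubationSetup"))
  validObject(setup)
  .checkPct(socContentPct, "socContentPct")
  (socContentPct / 100) * (atomExcessPct / 100) / setup@molarMass13C *
    1e9 / setup@incubationDays
}

#' Nitrogen-fixation potential as 15N in soil organic nitrogen
#'
#' Same mass balance as the SOC pool, on the SON pool with the 15N molar
#' mass.
#'
#' @param sonContentPct soil organic nitrogen content, % of dry soil mass
#' @param atomExcessPct 15N atom-% excess in SON
#' @inheritParams co2OxidationPotential
#' @return nmol N / g dws / day
#' @examples
#' n2FixationPotential(0.5, 0.005, IncubationSetup())  # 0.1852
#' @export
n2FixationPotential <- function(sonContentPct, atomExcessPct,
                                setup = IncubationSetup()) {
  stopifnot(is(setup, "IncubationSetup"))
  validObject(setup)
  .checkPct(sonContentPct, "sonContentPct")
  (sonContentPct / 100) * (atomExcessPct / 100) / setup@molarMass15N *
    1e9 / setup@incubationDays
}

#' Total methane oxidation and its CO2 / SOC partition
#'
#' The total potential is the sum of the respired (CO2) and assimilated (SOC)
#' components; the CO2 fraction is the respired share of the total,
#' \code{NA} when the total is zero.
#'
#' @param gasPotential 13C-CO2 component, nmol C / g dws / day
#' @param socPotential 13C-SOC component, nmol C / g dws / day
#' @return data.frame with columns \code{total} and \code{co2Fraction};
#'   vectorized
#' @examples
#' totalMethaneOxidation(106.69, 37.48)
#' @export
totalMethaneOxidation <- function(gasPotential, socPotential) {
  stopifnot(all(is.finite(gasPotential)), all(is.finite(socPotential)))
  total <- gasPotential + socPotential
  frac <- ifelse(total > 0, gasPotential / total, NA_real_)
  data.frame(total = total, co2Fraction = frac)
}

#' Fold ratios between per-depth mean potentials
#'
#' For every ordered pair of depths, the ratio of their mean potentials.
#' Full precision is kept in \code{ratio}; \code{ratioDisplay} rounds to one
#' decimal as conventionally reported. Non-positive denominators give
#' \code{NA} with \code{defined = FALSE}.
#'
#' @param perDepthMeans named numeric vector of mean potentials, one per
#'   depth
#' @return data.frame with columns \code{numerator}, \code{denominator},
#'   \code{ratio}, \code{ratioDisplay}, \code{defined}
#' @examples
#' depthFoldRatios(c(top_0_20 = 57.67, mid_40_60 = 144.17,
#'                   deep_60_80 = 120.14))
#' @export
depthFoldRatios <- function(perDepthMeans) {
  stopifnot(!is.null(names(perDepthMeans)), length(perDepthMeans) >= 2)
  nm <- names(perDepthMeans)
  pairs <- expand.grid(numerator = nm, denominator = nm,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$numerator != pairs$denominator, , drop = FALSE]
  den <- perDepthMeans[pairs$denominator]
  num <- perDepthMeans[pairs$numerator]
  defined <- is.finite(den) & den > 0
  ratio <- ifelse(defined, num / den, NA_real_)
  out <- data.frame(pairs, ratio = as.numeric(ratio),
                    ratioDisplay = .roundHalfUp(as.numeric(ratio), 1),
                    defined = as.logical(defined), row.names = NULL)
  out
}

#' Invert a potential to the atom-% excess that produces it
#'
#' Exact algebraic inversion of the mass-balance equations: given a target
#' potential and the pool sizes, returns the atom-% excess such that the
#' forward calculation reproduces the target. Used to construct measurement
#' tables with known ground truth.
#'
#' @param targetPotential target potential, nmol / g dws / day (>= 0)
#' @param which which pool: \code{"co2"}, \code{"soc"} or \code{"son"}
#' @param setup an \linkS4class{IncubationSetup}
#' @param co2ConcentrationPct,socContentPct,sonContentPct the pool size for
#'   the chosen equation (only the matching one is used)
#' @return required atom-% excess
#' @examples
#' inverseAtomExcess(35.71, "co2", IncubationSetup(),
#'                   co2ConcentrationPct = 1.0)  # ~10
#' @export
inverseAtomExcess <- function(targetPotential,
                              which = c("co2", "soc", "son"),
                              setup = IncubationSetup(),
                              co2ConcentrationPct = NULL,
                              socContentPct = NULL,
                              sonContentPct = NULL) {
  which <- match.arg(which)
  stopifnot(is(setup, "IncubationSetup"))
  validObject(setup)
  if (any(!is.finite(targetPotential)) || any(targetPotential < 0))
    stop("targetPotential must be finite and >= 0", call. = FALSE)
  pool <- switch(which, co2 = co2ConcentrationPct, soc = socContentPct,
                 son = sonContentPct)
  if (is.null(pool))
    stop("pool size for '", which, "' must be supplied", call. = FALSE)
  if (any(!is.finite(pool)) || any(pool <= 0))
    stop("pool size must be strictly positive", call. = FALSE)
  switch(which,
    co2 = targetPotential * setup@dryMassG * setup@incubationDays *
      setup@molarVolumeLPerMol /
      ((pool / 100) * (setup@headspaceVolumeMl / 1000) * 1e9) * 100,
    soc = targetPotential * setup@incubationDays * setup@molarMass13C /
      ((pool / 100) * 1e9) * 100,
    son = targetPotential * setup@incubationDays * setup@molarMass15N /
      ((pool / 100) * 1e9) * 100)
}

## round-half-up at given decimals (the display convention for potentials,
## fold ratios and percentages; round() half-to-even would disagree on e.g.
## 59.375)
.roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Per-bottle potentials from a microcosm measurement table
#'
#' Applies the mass-balance equations to each bottle of a measurement table
#' (see \code{\link{readMeasurementTable}} for the schema) and returns one
#' row per bottle with the CO2, SOC and total methane-oxidation potentials,
#' the CO2 fraction, the N2-fixation potential and quality flags. A
#' \code{negative_excess} flag marks bottles where any atom-% excess is
#' negative (the value is propagated, not clamped).
#'
#' @param measurements data.frame in the microcosm measurement schema
#' @param setup an \linkS4class{IncubationSetup}
#' @return data.frame with columns depth_label, replicate_id, treatment,
#'   co2_potential, soc_potential, total_ch4_oxidation, co2_fraction,
#'   n2_fixation, flags
#' @export
computePotentials <- function(measurements, setup = IncubationSetup()) {
  m <- measurements
  need <- .schemas$microcosm
  miss <- setdiff(need, names(m))
  if (length(miss) > 0)
    stop("measurement table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  dGas <- atomPercentExcess(m$atom13_co2_day90_pct, m$atom13_co2_day0_pct)
  dSoc <- atomPercentExcess(m$atom13_soc_day90_pct, m$atom13_soc_day0_pct)
  dSon <- atomPercentExcess(m$atom15_son_day90_pct, m$atom15_son_day0_pct)
  gas <- co2OxidationPotential(m$co2_concentration_pct, dGas, setup)
  soc <- socAssimilationPotential(m$soc_content_pct, dSoc, setup)
  son <- n2FixationPotential(m$son_content_pct, dSon, setup)
  tot <- totalMethaneOxidation(gas, soc)
  flags <- ifelse(dGas < 0 | dSoc < 0 | dSon < 0, "negative_excess", "")
  data.frame(
    depth_label = m$depth_label,
    replicate_id = m$replicate_id,
    treatment = m$treatment,
    co2_potential = gas,
    soc_potential = soc,
    total_ch4_oxidation = tot$total,
    co2_fraction = tot$co2Fraction,
    n2_fixation = son,
    flags = flags,
    stringsAsFactors = FALSE)
}

#' Per-depth summary of labeled-bottle potentials
#'
#' Means and standard deviations of each potential across labeled replicates,
#' by depth.
#'
#' @param potentials output of \code{\link{computePotentials}}
#' @return data.frame with one row per depth: means and sds of the total
#'   CH4-oxidation and N2-fixation potentials, and the mean CO2 fraction
#' @export
summarizePotentials <- function(potentials) {
  p <- potentials[potentials$treatment == "labeled", , drop = FALSE]
  if (nrow(p) == 0) stop("no labeled bottles in table", call. = FALSE)
  sp <- split(p, p$depth_label)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(
      depth_label = d$depth_label[1],
      n = nrow(d),
      ch4_total_mean = mean(d$total_ch4_oxidation),
      ch4_total_sd = sd(d$total_ch4_oxidation),
      co2_fraction_mean = mean(d$co2_fraction),
      n2_fixation_mean = mean(d$n2_fixation),
      n2_fixation_sd = sd(d$n2_fixation),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
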