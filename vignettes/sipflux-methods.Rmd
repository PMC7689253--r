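---
title: "Methods and design notes for sipflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for sipflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sipflux)
```

# The measurement model

`sipflux` analyzes a stable-isotope-probing (SIP) microcosm design: soil
from several depths is sealed in bottles, the headspace is flushed with
argon to impose suboxic conditions, and a ¹³CH₄ / ¹⁵N₂ / Ar mixture is
added. After a fixed incubation, isotope-ratio mass spectrometry gives the
atom-% of ¹³C in headspace CO₂ and in soil organic carbon (SOC), and of
¹⁵N in soil organic nitrogen (SON). The *potential* of each process is the
heavy-atom accumulation in a pool, normalized per gram dry soil per day.

For the gas pool, the headspace CO₂ inventory in moles is
`(Cgas/100) · (Vh/1000) / Vs`; multiplying by the atom-fraction excess
`ΔA/100`, scaling moles to nmol, and dividing by `m · t` gives the
¹³C-CO₂ potential. For the soil pools the inventory is
`(C/100) · m / M` moles, and the dry mass `m` cancels against the
per-gram normalization, so the SOC and SON potentials do not depend on
it. All unit conversions are written out explicitly in the code rather
than collapsed into composite scale constants; this makes the percent
conventions auditable and keeps the forward equations exactly invertible
(`inverseAtomExcess`), which the package exploits for fixture
construction and simulation ground truth.

Two modeling conventions deserve note:

* **Soil-pool denominator.** The soil-pool equations use the isotope molar
  mass `M` (g/mol), as dimensional analysis requires for a mass pool; the
  molar gas volume `Vs` applies only to the gas pool.
* **Headspace volume.** `Vh` is interpreted as the gas volume expressed at
  1 atm equivalent. The default of 360 mL corresponds to a 120-mL bottle
  over-pressurized to 3 atm. An alternative reading (120 mL at 3 atm with
  explicit pressure correction) is numerically close but not identical;
  users who prefer it can set `headspaceVolumeMl` accordingly.

Key assumptions: a single endpoint (no kinetics — the design measures a
90-day integral, not a rate curve); day-0 subtraction is the only
natural-abundance correction; negative atom-% excesses (possible through
control drift or instrument noise) are propagated unchanged and flagged
`negative_excess`, because clamping them to zero would hide QC problems
and bias replicate means upward.

# Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| `dryMassG` | 5 | g | typical bottle loading |
| `incubationDays` | 90 | days | endpoint of the emulated design |
| `headspaceVolumeMl` | 360 | mL (1 atm eq.) | 120-mL bottle at 3 atm |
| `molarVolumeLPerMol` | 22.4 | L/mol | STP; exact/temperature-adjusted values selectable |
| `molarMass13C` / `molarMass15N` | 13.0 / 15.0 | g/mol | nominal; exact isotopic masses selectable |
| labeling threshold | 0.010 | g/mL | separates a full heavy-band shift (≈0.014) from no shift |
| `smoothWindow` | 1 | fractions | peaks are read directly; 3-point smoothing available for noisy profiles |
| `alpha` | 0.05 | — | conventional significance level |

The gradient reporting windows are [1.725, 1.745] g/mL (heavy,
¹³C-enriched DNA) and [1.700, 1.725) g/mL (light), anchored to the
canonical band centers of 1.734 and 1.720 g/mL.

# Gradient analysis choices

The peak is a strict argmax over fractions by default, because reported
SIP profiles are typically read directly; optional moving-average
smoothing handles noisy qPCR replicates. Ties break toward the **lower**
density, which can only make a labeling call more conservative. Fractions
are sorted by density on ingest and duplicate densities are averaged, so
the analysis is deterministic regardless of input order. Profiles can be
analyzed on absolute copies or ratio-normalized (`normalizeProfile`);
normalization changes neither the peak nor the weighted mean, so the
labeling call is invariant to it.

# Statistics

Depth comparisons use classical one-way fixed-effects ANOVA (via
`stats::aov`). The post-hoc method is Tukey HSD — the standard choice for
small balanced designs — with letters assigned by the insert-absorb
compact-letter-display algorithm: two groups share a letter exactly when
their Tukey-adjusted p value is at least `alpha`. Fisher's LSD is
available behind `method = "lsd"` for sensitivity analysis only.
Labeled-vs-control contrasts use the two-sided Welch (unequal-variance)
t-test, since variance homogeneity between treatments is not guaranteed;
the degenerate zero-variance case returns p = 1 for equal means. A fully
degenerate ANOVA (all values identical) returns F = 0, p = 1.

# The synthetic-data generator

`simulateMicrocosm` emulates the study conditions: three depths
(0–20, 40–60, 60–80 cm), three replicate bottles per depth and treatment,
90 days. Ground-truth potentials are inverted to atom-% excesses and the
noise is placed **on the atom-% excess** as multiplicative Gaussian error
(default relative sd 0.05), because the IRMS atom-% measurement is the
noisy quantity in this design; pool contents are treated as fixed.
Control bottles receive the day-0 baseline plus a small absolute drift
(sd 0.005 atom-%). `simulateGradient` draws Gaussian bands over a 15-point
density grid spanning 1.70–1.75 g/mL (with 1.720 and 1.734 snapped onto
the grid so the canonical band centers are representable) with
multiplicative lognormal noise. `simulateCommunity` draws
Dirichlet-multinomial counts around target genus proportions.

The default ground truth is the packaged study scenario: CH₄-oxidation
totals of 57.67 / 144.17 / 120.14 nmol C/g dws/day for top / intermediate
/ deep soil, CO₂ shares of 67 / 74 / 81%, and N₂-fixation potentials of
0.41 / 0.57 / 0.13 nmol N/g dws/day. Where the emulated study reports
only a range (the CO₂ share: "67–81%, increasing with depth") the
intermediate value is the midpoint, 74% — an assumption recorded in the
fixture metadata. Replicate spreads are reported only for the
intermediate depth (± 3.10 nmol C, ± 0.04 nmol N); those ± values are
treated as replicate standard deviations (sd vs sem is ambiguous in such
reports; sd is the conservative reading), and the other depths use the
same relative spread (CH₄: 1.24 / 2.58) or a comparable realistic value
(N₂: 0.03 / 0.01). These choices were made once, up front, and define the
scenario.

What the generator does **not** emulate: qPCR efficiency bias and
standard-curve error, GC-content effects on buoyant density, band
broadening, compositional coupling between taxa beyond the multinomial
constraint, and any temporal dynamics. Passing recovery tests therefore
show that the pipeline arithmetic is unbiased under the stated noise
model — not that the model captures every error source of real
measurements.

## Fixture reconstruction notes

`buildPaperFixtures` produces a deterministic input set whose analysis
lands exactly on the emulated study's reported summaries. Replicate
triplets are `{mean − sd, mean, mean + sd}`, which reproduces both the
reported mean and sd exactly for n = 3. Clone libraries are fixed integer
counts (52/50/47 bacterial, 32/31/31 archaeal clones per depth, summing to
the reported 149 and 94) that reproduce every reported percentage at two
decimals.

One genuine inconsistency surfaced during reconstruction: the
intermediate-depth day-0 Methylobacter relative abundance implied by its
reported percentage-point/fold pair (+52.9 points, 5-fold ⇒ 13.2% of the
community at day 0) cannot coexist with the reported in-situ guild
composition (Methylobacter a minor guild member) in any single count
table. The count fixture therefore anchors the guild compositions (and
the top-soil Methylobacter trajectory, which is consistent), while a
dedicated shift table carries the exact pp/fold pairs for all depths via
the inversion `initial = pp/(fold − 1)`.

# Numerical conventions

* Percentages and atom-% are stored on the [0, 100] scale everywhere;
  conversion to fractions happens only inside the mass-balance equations.
* Display rounding is half-up (2 decimals for potentials and percentages,
  1 for fold ratios), matching reporting convention; full precision is
  kept in all data structures and files.
* Forward/inverse round trips are exact to < 1e-9 relative error; this is
  tested over random parameter sets.
* Undefined quantities (CO₂ fraction of a zero total, fold change from a
  zero baseline, ratio over a non-positive denominator) are `NA` with an
  explicit `defined` flag where applicable, never silently dropped.
* Simulators are pure functions of (config, seed): they use a private RNG
  stream and restore the caller's RNG state.

# Problem sizes in the test suite

The suite exercises the property tests at sizes chosen to be decisive but
quick: 100 random parameter sets for the inversion round trip, 50 random
profiles for the peak/argmax equivalence, a 10,000-permutation oracle for
one ANOVA fixture (3 × 8 balanced design), and 200 seeded simulations for
the bias check of the parameter-recovery loop (each estimate within 3
standard errors of its truth). These sizes are the package's validation
design, documented here so they can be scaled up by anyone wanting
tighter Monte-Carlo bounds.

# Known limitations

* The labeling call is categorical; the package deliberately does not
  estimate atom-fraction excess from density shifts (quantitative SIP),
  which needs per-taxon GC corrections and a different error model.
* Guild composition assumes genus-level annotations; finer structure
  within Methylobacter-like phylotypes is invisible.
* The ANOVA assumes independent bottles; pseudo-replication from shared
  soil cores is not modeled.
* With n = 3 replicates per depth, the Tukey letters are sensitive to the
  assumed replicate sds; the fixture letters reproduce the separated
  regime reported for the emulated study, not a general claim.
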