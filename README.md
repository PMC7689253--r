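# sipflux

Analysis toolkit for DNA stable-isotope-probing (SIP) microcosm studies of
methane oxidation and nitrogen fixation in soils.

In a SIP microcosm experiment, soil is incubated with isotopically heavy
substrates (¹³CH₄, ¹⁵N₂). Active methanotrophs oxidize the labeled methane —
part of the heavy carbon is respired to headspace CO₂ and part is
assimilated into soil organic carbon (SOC) — while diazotrophs fix the heavy
dinitrogen into soil organic nitrogen (SON). Because active populations
also build ¹³C into their DNA, marker-gene qPCR across a CsCl buoyant-density
gradient reveals which guilds incorporated the label. `sipflux` implements
the downstream arithmetic of such a study:

- **Isotope mass balance.** The potential of each process is the heavy-atom
  accumulation in a pool per gram dry soil per day. With `Cgas` the
  headspace CO₂ volume-%, `A − A0` the atom-% excess over day 0, `Vh` the
  headspace volume (mL at 1 atm), `Vs` the molar gas volume (L/mol), `C` a
  soil pool content (% of dry mass), `M` the isotope molar mass (g/mol),
  `m` the dry soil mass (g) and `t` the incubation time (days):

  ```
  P_CO2 = (Cgas/100) (ΔA/100) (Vh/1000) / Vs · 1e9 / (m t)   [nmol C/g dws/day]
  P_SOC = (Csoc/100) (ΔA/100) / M · 1e9 / t                  [nmol C/g dws/day]
  P_SON = (Cson/100) (ΔA/100) / M · 1e9 / t                  [nmol N/g dws/day]
  ```

  Total methane oxidation is `P_CO2 + P_SOC`, with the respired share
  `P_CO2 / (P_CO2 + P_SOC)`. An exact algebraic inverse
  (`inverseAtomExcess`) turns target potentials back into atom-% excesses,
  which drives both the synthetic-data generator and fixture construction.
- **Gradient labeling calls.** Gene-copy profiles over buoyant density
  (`GradientProfile`) are reduced to peak and copy-weighted-mean densities;
  a labeled-vs-control peak shift of at least 0.010 g/mL calls the gene's
  carriers labeled (`densityShiftAndCall`).
- **Community metrics.** Relative abundances, within-guild compositions
  for the aerobic methanotroph panel (Methylosinus, Methylocaldum,
  Methylobacter, Methylomicrobium, Crenothrix), percentage-point and fold
  abundance shifts, and clone-library percentages.
- **Group statistics.** One-way ANOVA across depths, Tukey HSD pairwise
  comparisons with an insert-absorb compact letter display, and Welch
  tests for labeled-vs-control contrasts.
- **Synthetic data.** Seeded generators for microcosm measurement tables,
  Gaussian-band gradient profiles and Dirichlet-multinomial community
  counts, plus `buildPaperFixtures()`, a deterministic input set anchored
  to a published alpine swamp-soil study of suboxic methane oxidation.

## Worked example

```r
library(sipflux)

fx <- buildPaperFixtures()
res <- runPipeline(pipelineConfig(
  measurements = fx$measurements, gradients = fx$gradients,
  community = fx$community, clones = fx$clones, shifts = fx$shifts,
  outDir = "sip_out"))

res$summary
#>   depth_label n ch4_total_mean ch4_total_sd co2_fraction_mean n2_fixation_mean n2_fixation_sd
#> 1  deep_60_80 3         120.14         2.58              0.81             0.13           0.01
#> 2   mid_40_60 3         144.17         3.10              0.74             0.57           0.04
#> 3    top_0_20 3          57.67         1.24              0.67             0.41           0.03
```

The intermediate depth (40–60 cm) shows the highest methane-oxidation
potential, 144.17 ± 3.10 nmol C/g dws/day — a 2.5-fold increase over the
top soil — and the highest N₂-fixation potential, 0.57 ± 0.04 nmol N/g
dws/day. The respired (CO₂) share of the oxidized methane rises with depth
from 67% to 81%.

```r
res$labelingCalls[, c("gene_name", "peak_bd_labeled", "peak_bd_control",
                      "shift_g_per_ml", "is_labeled")]
#>   gene_name peak_bd_labeled peak_bd_control shift_g_per_ml is_labeled
#> 1      pmoA           1.734            1.72          0.014       TRUE
#> 2      nifH           1.720            1.72          0.000      FALSE
```

The pmoA (methanotroph) copies peak 0.014 g/mL heavier in the ¹³C
treatment — clear labeling — while nifH shows no shift, so the diazotroph
community as a whole is not called labeled. In the heavy-DNA clone
libraries, Methylobacter is the dominant genus at every depth
(28.85 / 24.00 / 21.28% of bacterial clones), and its whole-community
relative abundance in the top soil rises from 2.35% to 35.25% over the
incubation (+32.9 points, 15-fold). `sip_out/report.md` collects all of
this with Tukey letters per depth.

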