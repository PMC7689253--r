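Package: sipflux
Title: Stable-Isotope-Probing Analysis of Methane Oxidation and Nitrogen
    Fixation in Soil Microcosms
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for DNA stable-isotope-probing (SIP) microcosm studies of
    methane-oxidizing and nitrogen-fixing soil communities. Implements isotope
    mass-balance calculations of methane-oxidation and N2-fixation potentials
    from 13C/15N atom-percent-excess measurements, peak-shift analysis of qPCR
    gene-copy distributions across CsCl buoyant-density gradients to call
    isotopic labeling of marker genes (pmoA, nifH), methanotroph guild
    composition and abundance-shift metrics from genus-level count tables and
    clone libraries, one-way ANOVA with Tukey compact-letter displays, and a
    synthetic-data generator that emulates the full study design for
    validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
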