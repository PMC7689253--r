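#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats sd aov anova TukeyHSD pt t.test setNames dnorm rnorm
#'   rlnorm rgamma rmultinom
#' @importFrom utils read.csv write.csv packageVersion
NULL

#' Incubation setup: bottle geometry and physical constants
#'
#' Holds the constants of a microcosm labeling incubation: soil dry weight,
#' incubation length, headspace gas volume (expressed at 1-atm equivalent),
#' molar gas volume and the molar masses of the heavy isotopes. These are the
#' denominator terms of the isotope mass-balance equations.
#'
#' @slot dryMassG soil dry weight, g
#' @slot incubationDays length of the incubation, days
#' @slot headspaceVolumeMl headspace gas volume at 1-atm equivalent, mL
#' @slot molarVolumeLPerMol molar volume of an ideal gas, L/mol (22.4 at STP)
#' @slot molarMass13C molar mass of 13C, g/mol
#' @slot molarMass15N molar mass of 15N, g/mol
#'
#' @export
setClass("IncubationSetup",
  representation(
    dryMassG = "numeric",
    incubationDays = "numeric",
    headspaceVolumeMl = "numeric",
    molarVolumeLPerMol = "numeric",
    molarMass13C = "numeric",
    molarMass15N = "numeric"
  )
)

setValidity("IncubationSetup", function(object) {
  vals <- c(
    dryMassG = object@dryMassG,
    incubationDays = object@incubationDays,
    headspaceVolumeMl = object@headspaceVolumeMl,
    molarVolumeLPerMol = object@molarVolumeLPerMol,
    molarMass13C = object@molarMass13C,
    molarMass15N = object@molarMass15N
  )
  if (any(lengths(list(object@dryMassG, object@incubationDays,
                       object@headspaceVolumeMl, object@molarVolumeLPerMol,
                       object@molarMass13C, object@molarMass15N)) != 1L))
    return("all slots must be length-1 numerics")
  if (any(!is.finite(vals)) || any(vals <= 0))
    return(paste0("all setup values must be strictly positive; got ",
                  paste(names(vals)[!is.finite(vals) | vals <= 0],
                        collapse = ", ")))
  if (object@incubationDays < 1)
    return("incubationDays must be >= 1")
  TRUE
})

#' Construct an IncubationSetup
#'
#' Defaults reproduce a 90-day suboxic microcosm: 5 g dry soil in a 120-mL
#' bottle over-pressurized to 3 atm, i.e. about 360 mL of gas at 1 atm.
#'
#' @param dryMassG soil dry weight, g
#' @param incubationDays incubation length, days (>= 1)
#' @param headspaceVolumeMl headspace gas volume at 1-atm equivalent, mL
#' @param molarVolumeLPerMol molar gas volume, L/mol
#' @param molarMass13C molar mass of 13C, g/mol (nominal 13.0; set 13.00335
#'   for the exact isotopic mass)
#' @param molarMass15N molar mass of 15N, g/mol (nominal 15.0)
#' @return an \linkS4class{IncubationSetup}
#' @examples
#' IncubationSetup()
#' IncubationSetup(dryMassG = 10, headspaceVolumeMl = 240)
#' @export
IncubationSetup <- function(dryMassG = 5, incubationDays = 90,
                            headspaceVolumeMl = 360,
                            molarVolumeLPerMol = 22.4,
                            molarMass13C = 13.0, molarMass15N = 15.0) {
  new("IncubationSetup",
      dryMassG = as.numeric(dryMassG),
      incubationDays = as.numeric(incubationDays),
      headspaceVolumeMl = as.numeric(headspaceVolumeMl),
      molarVolumeLPerMol = as.numeric(molarVolumeLPerMol),
      molarMass13C = as.numeric(molarMass13C),
      molarMass15N = as.numeric(molarMass15N))
}

#' @describeIn IncubationSetup-class soil dry weight, g
#' @param object,x an \code{IncubationSetup}
#' @export
dryMassG <- function(x) x@dryMassG
#' @describeIn IncubationSetup-class incubation length, days
#' @export
incubationDays <- function(x) x@incubationDays
#' @describeIn IncubationSetup-class headspace volume, mL
#' @export
headspaceVolumeMl <- function(x) x@headspaceVolumeMl
#' @describeIn IncubationSetup-class molar gas volume, L/mol
#' @export
molarVolumeLPerMol <- function(x) x@molarVolumeLPerMol

setMethod("show", "IncubationSetup", function(object) {
  cat("IncubationSetup\n")
  cat(sprintf("  dry soil mass      : %g g\n", object@dryMassG))
  cat(sprintf("  incubation         : %g days\n", object@incubationDays))
  cat(sprintf("  headspace volume   : %g mL (1-atm equivalent)\n",
              object@headspaceVolumeMl))
  cat(sprintf("  molar gas volume   : %g L/mol\n", object@molarVolumeLPerMol))
  cat(sprintf("  molar mass 13C/15N : %g / %g g/mol\n",
              object@molarMass13C, object@molarMass15N))
})

#' CsCl buoyant-density gradient profile of a marker gene
#'
#' An ordered set of (buoyant density, qPCR gene copy number) fractions for
#' one gene in one treatment. Fractions are sorted by density on construction
#' and duplicate densities are averaged, so downstream peak analysis is
#' deterministic.
#'
#' @slot geneName marker gene, e.g. "pmoA" or "nifH"
#' @slot treatmentLabel "labeled_13C" or "control_12C"
#' @slot sampleId sample identifier
#' @slot density buoyant densities, g/mL, strictly increasing
#' @slot copies gene copy numbers per unit DNA, non-negative
#'
#' @export
setClass("GradientProfile",
  representation(
    geneName = "character",
    treatmentLabel = "character",
    sampleId = "character",
    density = "numeric",
    copies = "numeric"
  )
)

setValidity("GradientProfile", function(object) {
  d <- object@density; k <- object@copies
  if (length(d) != length(k))
    return("density and copies must have equal length")
  if (length(d) < 4L)
    return("a gradient profile needs at least 4 fractions")
  if (any(!is.finite(d)) || any(d < 1.60) || any(d > 1.80))
    return("densities must lie in [1.60, 1.80] g/mL")
  if (any(diff(d) <= 0))
    return("densities must be strictly increasing")
  if (any(!is.finite(k)) || any(k < 0))
    return("copy numbers must be finite and non-negative")
  if (all(k == 0))
    return("profile must not be all zero")
  TRUE
})

#' Construct a GradientProfile
#'
#' Fractions are sorted by buoyant density; fractions reported at the same
#' density are merged by averaging their copy numbers.
#'
#' @param density buoyant densities, g/mL
#' @param copies gene copy numbers, same length as \code{density}
#' @param geneName marker gene name
#' @param treatmentLabel "labeled_13C" or "control_12C"
#' @param sampleId sample identifier
#' @return a \linkS4class{GradientProfile}
#' @examples
#' GradientProfile(density = c(1.71, 1.72, 1.73, 1.74),
#'                 copies  = c(1e5, 8e5, 2e6, 3e5), geneName = "pmoA")
#' @export
GradientProfile <- function(density, copies, geneName = "pmoA",
                            treatmentLabel = "labeled_13C",
                            sampleId = "sample1") {
  o <- order(density)
  density <- as.numeric(density)[o]
  copies <- as.numeric(copies)[o]
  if (anyDuplicated(density)) {
    copies <- as.numeric(tapply(copies, density, mean))
    density <- sort(unique(density))
  }
  new("GradientProfile", geneName = geneName,
      treatmentLabel = treatmentLabel, sampleId = sampleId,
      density = density, copies = copies)
}

#' @describeIn GradientProfile-class buoyant densities, g/mL
#' @param x a \code{GradientProfile}
#' @export
density_g_per_ml <- function(x) x@density
#' @describeIn GradientProfile-class gene copy numbers
#' @export
copyNumbers <- function(x) x@copies
#' @describeIn GradientProfile-class marker gene name
#' @export
geneName <- function(x) x@geneName

setMethod("show", "GradientProfile", function(object) {
  cat(sprintf("GradientProfile: %s (%s), sample %s\n", object@geneName,
              object@treatmentLabel, object@sampleId))
  cat(sprintf("  %d fractions, BD %.4f-%.4f g/mL, total copies %.4g\n",
              length(object@density), min(object@density),
              max(object@density), sum(object@copies)))
})

#' Isotopic labeling call for one marker gene
#'
#' Result of comparing a labeled (13C) against a control (12C) buoyant-density
#' profile of the same gene: peak densities, intensity-weighted mean
#' densities, the peak shift and the categorical labeled/unlabeled call.
#'
#' @slot geneName marker gene
#' @slot peakBdLabeled,peakBdControl peak buoyant densities, g/mL
#' @slot weightedMeanLabeled,weightedMeanControl copy-weighted mean densities
#' @slot shiftGPerMl peak(labeled) - peak(control), g/mL
#' @slot thresholdGPerMl minimum shift counted as labeling, g/mL
#' @slot isLabeled TRUE iff shift >= threshold
#'
#' @export
setClass("LabelingCall",
  representation(
    geneName = "character",
    peakBdLabeled = "numeric",
    peakBdControl = "numeric",
    weightedMeanLabeled = "numeric",
    weightedMeanControl = "numeric",
    shiftGPerMl = "numeric",
    thresholdGPerMl = "numeric",
    isLabeled = "logical"
  )
)

setValidity("LabelingCall", function(object) {
  if (!isTRUE(all.equal(object@shiftGPerMl,
                        object@peakBdLabeled - object@peakBdControl)))
    return("shiftGPerMl must equal peakBdLabeled - peakBdControl")
  if (object@isLabeled != (object@shiftGPerMl >= object@thresholdGPerMl))
    return("isLabeled must equal (shift >= threshold)")
  TRUE
})

setMethod("show", "LabelingCall", function(object) {
  cat(sprintf("LabelingCall: %s — %s\n", object@geneName,
              if (object@isLabeled) "LABELED" else "not labeled"))
  cat(sprintf("  peak BD labeled/control : %.4f / %.4f g/mL\n",
              object@peakBdLabeled, object@peakBdControl))
  cat(sprintf("  shift %.4f g/mL (threshold %.4f)\n",
              object@shiftGPerMl, object@thresholdGPerMl))
  cat(sprintf("  weighted means          : %.4f / %.4f g/mL\n",
              object@weightedMeanLabeled, object@weightedMeanControl))
})

#' @describeIn LabelingCall-class TRUE iff the gene is called labeled
#' @param x a \code{LabelingCall}
#' @export
isLabeled <- function(x) x@isLabeled
#' @describeIn LabelingCall-class peak shift, g/mL
#' @export
densityShift <- function(x) x@shiftGPerMl

#' Genus-level taxon count table
#'
#' A \linkS4class{SummarizedExperiment} with taxa as rows and samples as
#' columns, a \code{counts} assay of non-negative integers, and sample
#' metadata columns \code{depth_label} and \code{timepoint}.
#'
#' @export
setClass("TaxonCountTable", contains = "SummarizedExperiment")

setValidity("TaxonCountTable", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  m <- SummarizedExperiment::assay(object, "counts")
  if (any(!is.finite(m)) || any(m < 0))
    return("counts must be finite and non-negative")
  if (any(colSums(m) <= 0))
    return("every sample must have a positive total count")
  if (anyDuplicated(rownames(object)))
    return("taxon names must be unique")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("depth_label", "timepoint") %in% colnames(cd)))
    return("colData must contain depth_label and timepoint")
  TRUE
})

#' Construct a TaxonCountTable
#'
#' @param counts taxa x samples matrix of non-negative counts with rownames
#'   (taxa) and colnames (samples)
#' @param depth character vector of depth labels, one per sample
#' @param timepoint character vector of timepoints, one per sample
#'   (e.g. "insitu", "day0", "day90")
#' @return a \linkS4class{TaxonCountTable}
#' @examples
#' m <- matrix(c(50, 50, 30, 70), nrow = 2,
#'             dimnames = list(c("Methylobacter", "Methylosinus"),
#'                             c("s1", "s2")))
#' TaxonCountTable(m, depth = c("top_0_20", "top_0_20"),
#'                 timepoint = c("day0", "day90"))
#' @export
TaxonCountTable <- function(counts, depth, timepoint) {
  counts <- as.matrix(counts)
  cd <- S4Vectors::DataFrame(depth_label = as.character(depth),
                             timepoint = as.character(timepoint),
                             row.names = colnames(counts))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
  new("TaxonCountTable", se)
}

#' @describeIn TaxonCountTable-class the counts assay
#' @param x a \code{TaxonCountTable}
#' @export
taxonCounts <- function(x) SummarizedExperiment::assay(x, "counts")

setMethod("show", "TaxonCountTable", function(object) {
  cat(sprintf("TaxonCountTable: %d taxa x %d samples\n",
              nrow(object), ncol(object)))
  cd <- SummarizedExperiment::colData(object)
  cat("  depths    :", paste(unique(cd$depth_label), collapse = ", "), "\n")
  cat("  timepoints:", paste(unique(cd$timepoint), collapse = ", "), "\n")
})

#' Taxonomic guild panel
#'
#' A named set of genera treated as one functional guild, e.g. the aerobic
#' methanotroph panel. Member names are matched case-insensitively.
#'
#' @slot guildName name of the guild
#' @slot memberTaxa genus names belonging to the guild
#' @export
setClass("GuildPanel",
  representation(guildName = "character", memberTaxa = "character"))

setValidity("GuildPanel", function(object) {
  if (length(object@memberTaxa) < 1L) return("panel must be non-empty")
  if (anyDuplicated(tolower(object@memberTaxa)))
    return("panel members must be unique (case-insensitive)")
  TRUE
})

#' @describeIn GuildPanel-class construct a guild panel
#' @param guildName guild name
#' @param memberTaxa character vector of genus names
#' @export
GuildPanel <- function(guildName, memberTaxa) {
  new("GuildPanel", guildName = guildName,
      memberTaxa = as.character(memberTaxa))
}

#' @describeIn GuildPanel-class member genera
#' @param x a \code{GuildPanel}
#' @export
memberTaxa <- function(x) x@memberTaxa

setMethod("show", "GuildPanel", function(object) {
  cat(sprintf("GuildPanel '%s': %s\n", object@guildName,
              paste(object@memberTaxa, collapse = ", ")))
})

#' The aerobic methanotroph guild panel
#'
#' The five methanotrophic genera detected by 16S amplicon sequencing in the
#' swamp-soil profile: Methylosinus, Methylocaldum, Methylobacter,
#' Methylomicrobium and Crenothrix.
#'
#' @return a \linkS4class{GuildPanel}
#' @export
methanotrophPanel <- function() {
  GuildPanel("methanotrophs",
             c("Methylosinus", "Methylocaldum", "Methylobacter",
               "Methylomicrobium", "Crenothrix"))
}

#' The ANME (anaerobic methanotrophic archaea) panel
#'
#' @return a \linkS4class{GuildPanel}
#' @export
anmePanel <- function() {
  GuildPanel("ANME", "Candidatus Methanoperedens")
}
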