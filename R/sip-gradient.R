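## Buoyant-density gradient analysis.
##
## 13C-labeled DNA equilibrates at higher CsCl buoyant density than unlabeled
## DNA. qPCR of a marker gene across gradient fractions gives a copy-number
## profile over density; a peak shifted to the heavy region in the labeled
## treatment relative to the 12C control indicates that the gene's carriers
## incorporated the label.

#' Normalize a gradient profile to relative copy numbers
#'
#' Divides each fraction's copy number by the profile total so labeled and
#' control profiles are directly comparable; relative values sum to 1.
#' Normalization preserves the peak location and the weighted mean density
#' exactly.
#'
#' @param profile a \linkS4class{GradientProfile}
#' @return a \linkS4class{GradientProfile} with relative copy numbers
#' @examples
#' p <- GradientProfile(c(1.71, 1.72, 1.73, 1.74), c(1e5, 8e5, 2e6, 3e5))
#' sum(copyNumbers(normalizeProfile(p)))  # 1
#' @export
normalizeProfile <- function(profile) {
  stopifnot(is(profile, "GradientProfile"))
  total <- sum(profile@copies)
  if (total <= 0) stop("profile total must be positive", call. = FALSE)
  initialize(profile, copies = profile@copies / total)
}

## centered moving average; window must be odd; edge windows shrink
.movingAverage <- function(x, window) {
  if (window == 1L) return(x)
  h <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Buoyant density at the copy-number maximum
#'
#' The density of the fraction with the highest (optionally moving-average
#' smoothed) copy number. Ties are broken toward the lower density, which is
#' conservative against false labeling calls.
#'
#' @param profile a \linkS4class{GradientProfile}
#' @param smoothWindow odd integer window for centered moving-average
#'   smoothing; 1 (default) means no smoothing
#' @return peak buoyant density, g/mL
#' @examples
#' p <- GradientProfile(c(1.71, 1.72, 1.73, 1.74), c(1e5, 8e5, 2e6, 3e5))
#' peakDensity(p)  # 1.73
#' @export
peakDensity <- function(profile, smoothWindow = 1L) {
  stopifnot(is(profile, "GradientProfile"))
  smoothWindow <- as.integer(smoothWindow)
  if (smoothWindow < 1L || smoothWindow %% 2L == 0L)
    stop("smoothWindow must be an odd integer >= 1", call. = FALSE)
  if (sum(profile@copies) <= 0)
    stop("profile total must be positive", call. = FALSE)
  y <- .movingAverage(profile@copies, smoothWindow)
  ## densities are sorted ascending, so the first maximum is the lowest
  profile@density[which(y == max(y))[1L]]
}

#' Copy-weighted mean buoyant density
#'
#' The first moment of the profile, \eqn{\sum d_i k_i / \sum k_i}; a
#' peak-free diagnostic of where the gene's DNA sits in the gradient.
#'
#' @param profile a \linkS4class{GradientProfile}
#' @return weighted mean density, g/mL
#' @export
weightedMeanDensity <- function(profile) {
  stopifnot(is(profile, "GradientProfile"))
  total <- sum(profile@copies)
  if (total <= 0) stop("profile total must be positive", call. = FALSE)
  sum(profile@density * profile@copies) / total
}

#' Compare labeled vs control profiles and call isotopic labeling
#'
#' Computes the peak shift \code{peak(labeled) - peak(control)} and calls the
#' gene labeled when the shift reaches the threshold. The default threshold
#' of 0.010 g/mL separates a clear heavy-band shift (about 0.014 g/mL for an
#' actively assimilating population, e.g. 1.734 vs 1.720) from the no-shift
#' regime. Weighted-mean densities are reported alongside as a smoother
#' diagnostic.
#'
#' @param labeled \linkS4class{GradientProfile} from the heavy-isotope
#'   treatment
#' @param control \linkS4class{GradientProfile} from the light-isotope
#'   control; must be the same gene
#' @param thresholdGPerMl minimum peak shift counted as labeling, g/mL
#' @param smoothWindow passed to \code{\link{peakDensity}}
#' @return a \linkS4class{LabelingCall}
#' @export
densityShiftAndCall <- function(labeled, control,
                                thresholdGPerMl = 0.010,
                                smoothWindow = 1L) {
  stopifnot(is(labeled, "GradientProfile"), is(control, "GradientProfile"))
  if (!identical(labeled@geneName, control@geneName))
    stop("labeled and control profiles are for different genes: ",
         labeled@geneName, " vs ", control@geneName, call. = FALSE)
  pkL <- peakDensity(labeled, smoothWindow)
  pkC <- peakDensity(control, smoothWindow)
  shift <- pkL - pkC
  new("LabelingCall",
      geneName = labeled@geneName,
      peakBdLabeled = pkL,
      peakBdControl = pkC,
      weightedMeanLabeled = weightedMeanDensity(labeled),
      weightedMeanControl = weightedMeanDensity(control),
      shiftGPerMl = shift,
      thresholdGPerMl = thresholdGPerMl,
      isLabeled = shift >= thresholdGPerMl)
}

## reporting windows for the gradient (g/mL): heavy = 13C-enriched DNA band,
## light = unlabeled band
.heavyWindow <- c(1.725, 1.745)
.lightWindow <- c(1.700, 1.725)

#' Classify a buoyant density as heavy or light
#'
#' Heavy fractions are [1.725, 1.745] g/mL; light fractions are
#' [1.700, 1.725). Densities outside both windows return "outside".
#'
#' @param density buoyant densities, g/mL
#' @return character vector: "heavy", "light" or "outside"
#' @export
classifyFraction <- function(density) {
  ifelse(density >= .heavyWindow[1] & density <= .heavyWindow[2], "heavy",
         ifelse(density >= .lightWindow[1] & density < .lightWindow[2],
                "light", "outside"))
}

#' Labeling calls for every gene and sample of a gradient fraction table
#'
#' Splits a long-format fraction table (see
#' \code{\link{readGradientTable}}) into per-gene, per-sample labeled and
#' control profiles and calls labeling for each pair. Samples lacking one of
#' the two treatments are skipped with a warning.
#'
#' @param fractions data.frame in the gradient fraction schema
#' @param thresholdGPerMl labeling threshold, g/mL
#' @param smoothWindow passed to \code{\link{peakDensity}}
#' @return data.frame with one row per gene x sample: peak and weighted-mean
#'   densities for both treatments, the shift and the call
#' @export
analyzeGradients <- function(fractions, thresholdGPerMl = 0.010,
                             smoothWindow = 1L) {
  need <- .schemas$gradient
  miss <- setdiff(need, names(fractions))
  if (length(miss) > 0)
    stop("gradient table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  keys <- unique(fractions[, c("sample_id", "gene_name")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- fractions[fractions$sample_id == keys$sample_id[i] &
                     fractions$gene_name == keys$gene_name[i], ]
    lab <- sub[sub$treatment_label == "labeled_13C", ]
    ctl <- sub[sub$treatment_label == "control_12C", ]
    if (nrow(lab) == 0 || nrow(ctl) == 0) {
      warning("sample ", keys$sample_id[i], " gene ", keys$gene_name[i],
              ": missing labeled or control profile; skipped",
              call. = FALSE)
      return(NULL)
    }
    mk <- function(d, lbl) GradientProfile(
      density = d$buoyant_density_g_per_ml, copies = d$copy_number,
      geneName = keys$gene_name[i], treatmentLabel = lbl,
      sampleId = keys$sample_id[i])
    call <- densityShiftAndCall(mk(lab, "labeled_13C"),
                                mk(ctl, "control_12C"),
                                thresholdGPerMl, smoothWindow)
    data.frame(
      sample_id = keys$sample_id[i],
      gene_name = call@geneName,
      peak_bd_labeled = call@peakBdLabeled,
      peak_bd_control = call@peakBdControl,
      weighted_mean_labeled = call@weightedMeanLabeled,
      weighted_mean_control = call@weightedMeanControl,
      shift_g_per_ml = call@shiftGPerMl,
      threshold_g_per_ml = call@thresholdGPerMl,
      is_labeled = call@isLabeled,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  out
}
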