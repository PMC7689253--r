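## Synthetic study generator.
##
## Emulates the microcosm design the analysis assumes: three soil depths,
## three replicate bottles per depth, a 90-day labeled incubation plus
## unlabeled controls. Ground-truth potentials are inverted to atom-% excess
## through the exact mass-balance inverse, so the generator's outputs have a
## known truth that the forward pipeline should recover.

.depthLabels <- c("top_0_20", "mid_40_60", "deep_60_80")

## Default per-depth ground truth. CH4-oxidation totals, CO2 shares and
## N2-fixation potentials follow the study conditions (intermediate depth
## highest, CO2 share increasing with depth across the 67-81% range);
## pool sizes decline with depth as organic matter does.
.defaultTruth <- function() {
  data.frame(
    depth_label = .depthLabels,
    ch4_total = c(57.67, 144.17, 120.14),      # nmol C/g dws/day
    co2_share = c(0.67, 0.74, 0.81),           # respired fraction of total
    n2_fixation = c(0.41, 0.57, 0.13),         # nmol N/g dws/day
    co2_concentration_pct = c(1.0, 1.0, 1.0),  # headspace CO2, vol-%
    soc_content_pct = c(5.0, 4.0, 3.0),        # SOC, % dws
    son_content_pct = c(0.50, 0.40, 0.30),     # SON, % dws
    stringsAsFactors = FALSE)
}

## natural-abundance day-0 baselines (atom-%)
.day0Atom13 <- 1.08
.day0Atom15 <- 0.3663

#' Configuration for the microcosm simulator
#'
#' @param truth data.frame with one row per depth: depth_label, ch4_total,
#'   co2_share, n2_fixation, co2_concentration_pct, soc_content_pct,
#'   son_content_pct. Defaults to the package's study conditions.
#' @param nReplicates bottles per depth and treatment (default 3)
#' @param noiseSd relative (multiplicative Gaussian) sd on each atom-%
#'   excess, emulating IRMS measurement noise (default 0.05)
#' @param controlDriftSd absolute sd of day-90 atom-% drift in control
#'   bottles (default 0.005 atom-%)
#' @param setup an \linkS4class{IncubationSetup}
#' @param seed integer random seed, recorded in the output
#' @return a validated config list of class \code{simConfig}
#' @export
simConfig <- function(truth = .defaultTruth(), nReplicates = 3,
                      noiseSd = 0.05, controlDriftSd = 0.005,
                      setup = IncubationSetup(), seed = 1) {
  need <- c("depth_label", "ch4_total", "co2_share", "n2_fixation",
            "co2_concentration_pct", "soc_content_pct", "son_content_pct")
  miss <- setdiff(need, names(truth))
  if (length(miss) > 0)
    stop("truth lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(truth$ch4_total < 0) || any(truth$n2_fixation < 0))
    stop("true potentials must be >= 0", call. = FALSE)
  if (any(truth$co2_share < 0 | truth$co2_share > 1))
    stop("co2_share must be in [0, 1]", call. = FALSE)
  if (noiseSd < 0 || controlDriftSd < 0)
    stop("noise sds must be >= 0", call. = FALSE)
  if (nReplicates < 1) stop("nReplicates must be >= 1", call. = FALSE)
  validObject(setup)
  structure(list(truth = truth, nReplicates = nReplicates,
                 noiseSd = noiseSd, controlDriftSd = controlDriftSd,
                 setup = setup, seed = as.integer(seed)),
            class = "simConfig")
}

## run expr with a private RNG stream derived from seed, restoring the
## caller's RNG state afterwards (simulators are pure in (config, seed))
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a microcosm measurement table
#'
#' For each depth and replicate, the configured true potentials are inverted
#' to ground-truth atom-% excesses; labeled bottles receive
#' \code{day0 + dA * (1 + eps)} with \code{eps ~ N(0, noiseSd)}, and control
#' bottles receive the day-0 baseline plus a small Gaussian drift. The same
#' (config, seed) always yields the identical table.
#'
#' @param config a \code{\link{simConfig}}
#' @return data.frame in the microcosm measurement schema, labeled and
#'   control bottles; the seed is attached as attribute \code{"seed"}
#' @export
simulateMicrocosm <- function(config = simConfig()) {
  stopifnot(inherits(config, "simConfig"))
  tr <- config$truth
  su <- config$setup
  .withSeed(config$seed, {
    rows <- list()
    for (i in seq_len(nrow(tr))) {
      dGas <- inverseAtomExcess(tr$ch4_total[i] * tr$co2_share[i], "co2",
                                su, co2ConcentrationPct =
                                  tr$co2_concentration_pct[i])
      dSoc <- inverseAtomExcess(tr$ch4_total[i] * (1 - tr$co2_share[i]),
                                "soc", su,
                                socContentPct = tr$soc_content_pct[i])
      dSon <- inverseAtomExcess(tr$n2_fixation[i], "son", su,
                                sonContentPct = tr$son_content_pct[i])
      for (r in seq_len(config$nReplicates)) {
        eps <- rnorm(3, 0, config$noiseSd)
        drift <- rnorm(3, 0, config$controlDriftSd)
        rows[[length(rows) + 1L]] <- data.frame(
          depth_label = rep(tr$depth_label[i], 2),
          replicate_id = sprintf("%s_r%d", tr$depth_label[i], r),
          treatment = c("labeled", "control"),
          co2_concentration_pct = tr$co2_concentration_pct[i],
          atom13_co2_day90_pct = c(.day0Atom13 + dGas * (1 + eps[1]),
                                   .day0Atom13 + drift[1]),
          atom13_co2_day0_pct = .day0Atom13,
          soc_content_pct = tr$soc_content_pct[i],
          atom13_soc_day90_pct = c(.day0Atom13 + dSoc * (1 + eps[2]),
                                   .day0Atom13 + drift[2]),
          atom13_soc_day0_pct = .day0Atom13,
          son_content_pct = tr$son_content_pct[i],
          atom15_son_day90_pct = c(.day0Atom15 + dSon * (1 + eps[3]),
                                   .day0Atom15 + drift[3]),
          atom15_son_day0_pct = .day0Atom15,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "seed") <- config$seed
    out
  })
}

#' Default CsCl buoyant-density grid
#'
#' Fifteen fractions spanning 1.70-1.75 g/mL, with the grid points nearest
#' 1.720 and 1.734 snapped to those exact densities so the canonical light-
#' and heavy-band centers are grid-representable.
#'
#' @return increasing numeric vector of 15 densities, g/mL
#' @export
defaultDensityGrid <- function() {
  g <- seq(1.70, 1.75, length.out = 15)
  g[which.min(abs(g - 1.720))] <- 1.720
  g[which.min(abs(g - 1.734))] <- 1.734
  g
}

#' Configuration for the gradient simulator
#'
#' Band centers default to the canonical values: the labeled pmoA band at
#' 1.734 g/mL (13C-DNA), the control pmoA and both nifH bands at 1.720 g/mL
#' (unlabeled DNA), i.e. pmoA carriers assimilate the label and nifH
#' carriers as a whole do not.
#'
#' @param densityGrid increasing densities, g/mL, within [1.60, 1.80]
#' @param bandCenters data.frame with columns gene_name, treatment_label,
#'   center_g_per_ml
#' @param bandWidthSd Gaussian band width, g/mL (default 0.008)
#' @param totalCopies total gene copies per profile (default 1e7)
#' @param noiseSdLog sd of multiplicative lognormal noise on copy numbers
#'   (default 0.1); 0 gives noiseless profiles
#' @param sampleId sample identifier stamped on the output
#' @param seed integer random seed
#' @return a validated config list of class \code{gradientSimConfig}
#' @export
gradientSimConfig <- function(densityGrid = defaultDensityGrid(),
                              bandCenters = data.frame(
                                gene_name = c("pmoA", "pmoA", "nifH",
                                              "nifH"),
                                treatment_label = c("labeled_13C",
                                                    "control_12C",
                                                    "labeled_13C",
                                                    "control_12C"),
                                center_g_per_ml = c(1.734, 1.720, 1.720,
                                                    1.720),
                                stringsAsFactors = FALSE),
                              bandWidthSd = 0.008, totalCopies = 1e7,
                              noiseSdLog = 0.1, sampleId = "sample1",
                              seed = 1) {
  if (any(densityGrid < 1.60) || any(densityGrid > 1.80) ||
      any(diff(densityGrid) <= 0))
    stop("densityGrid must be increasing within [1.60, 1.80]",
         call. = FALSE)
  if (bandWidthSd <= 0) stop("bandWidthSd must be > 0", call. = FALSE)
  if (noiseSdLog < 0) stop("noiseSdLog must be >= 0", call. = FALSE)
  structure(list(densityGrid = densityGrid, bandCenters = bandCenters,
                 bandWidthSd = bandWidthSd, totalCopies = totalCopies,
                 noiseSdLog = noiseSdLog, sampleId = sampleId,
                 seed = as.integer(seed)),
            class = "gradientSimConfig")
}

#' Simulate a gradient fraction table
#'
#' Each profile is a Gaussian band over the density grid, normalized to the
#' configured total copies, times multiplicative lognormal noise.
#'
#' @param config a \code{\link{gradientSimConfig}}
#' @return data.frame in the gradient fraction schema
#' @export
simulateGradient <- function(config = gradientSimConfig()) {
  stopifnot(inherits(config, "gradientSimConfig"))
  .withSeed(config$seed, {
    g <- config$densityGrid
    bc <- config$bandCenters
    rows <- lapply(seq_len(nrow(bc)), function(i) {
      shape <- dnorm(g, bc$center_g_per_ml[i], config$bandWidthSd)
      copies <- config$totalCopies * shape / sum(shape)
      if (config$noiseSdLog > 0)
        copies <- copies * rlnorm(length(g), 0, config$noiseSdLog)
      data.frame(sample_id = config$sampleId,
                 gene_name = bc$gene_name[i],
                 treatment_label = bc$treatment_label[i],
                 buoyant_density_g_per_ml = g,
                 copy_number = copies,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "seed") <- config$seed
    out
  })
}

#' Configuration for the community simulator
#'
#' Baseline and endpoint genus proportions default to the packaged study
#' conditions (see \code{\link{buildPaperFixtures}}): a methanotroph guild
#' embedded in an "Other" background, with Methylobacter strongly enriched
#' by day 90.
#'
#' @param proportions data.frame with columns sample_id, depth_label,
#'   timepoint, taxon, proportion; proportions sum to 1 per sample
#' @param librarySizes named integer vector of reads per sample (names =
#'   sample_id)
#' @param overdispersion Dirichlet-multinomial overdispersion; 0 gives plain
#'   multinomial draws
#' @param seed integer random seed
#' @return a validated config list of class \code{communitySimConfig}
#' @export
communitySimConfig <- function(proportions = .defaultCommunityProportions(),
                               librarySizes = NULL,
                               overdispersion = 0.02, seed = 1) {
  sums <- tapply(proportions$proportion, proportions$sample_id, sum)
  if (any(abs(sums - 1) > 1e-8))
    stop("proportions must sum to 1 per sample", call. = FALSE)
  if (overdispersion < 0)
    stop("overdispersion must be >= 0", call. = FALSE)
  if (is.null(librarySizes)) {
    ids <- unique(proportions$sample_id)
    librarySizes <- setNames(rep(10000L, length(ids)), ids)
  }
  if (any(librarySizes <= 0))
    stop("library sizes must be positive", call. = FALSE)
  structure(list(proportions = proportions, librarySizes = librarySizes,
                 overdispersion = overdispersion, seed = as.integer(seed)),
            class = "communitySimConfig")
}

.defaultCommunityProportions <- function() {
  counts <- .fixtureCommunityCounts()
  long <- do.call(rbind, lapply(colnames(counts$counts), function(s) {
    data.frame(sample_id = s,
               depth_label = counts$depth[match(s, colnames(counts$counts))],
               timepoint = counts$timepoint[match(s,
                                                  colnames(counts$counts))],
               taxon = rownames(counts$counts),
               proportion = counts$counts[, s] / sum(counts$counts[, s]),
               stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  long
}

#' Simulate a community count table
#'
#' Per-sample counts are drawn multinomially from the target proportions;
#' with positive overdispersion the proportions are first perturbed by a
#' Dirichlet draw with concentration \code{proportions / overdispersion}
#' (gamma construction), giving Dirichlet-multinomial counts.
#'
#' @param config a \code{\link{communitySimConfig}}
#' @return a \linkS4class{TaxonCountTable}
#' @export
simulateCommunity <- function(config = communitySimConfig()) {
  stopifnot(inherits(config, "communitySimConfig"))
  .withSeed(config$seed, {
    pr <- config$proportions
    ids <- unique(pr$sample_id)
    taxa <- unique(pr$taxon)
    counts <- matrix(0L, nrow = length(taxa), ncol = length(ids),
                     dimnames = list(taxa, ids))
    depth <- character(length(ids)); tp <- character(length(ids))
    for (j in seq_along(ids)) {
      sub <- pr[pr$sample_id == ids[j], ]
      p <- setNames(sub$proportion, sub$taxon)[taxa]
      p[is.na(p)] <- 0
      if (config$overdispersion > 0) {
        conc <- p / config$overdispersion
        gam <- ifelse(conc > 0, rgamma(length(conc), shape = conc), 0)
        if (sum(gam) > 0) p <- gam / sum(gam)
      }
      counts[, j] <- rmultinom(1, config$librarySizes[ids[j]], p)[, 1]
      depth[j] <- sub$depth_label[1]
      tp[j] <- sub$timepoint[1]
    }
    ## a multinomial draw can zero out a sample only if all p are 0, which
    ## the config validation excludes
    TaxonCountTable(counts, depth = depth, timepoint = tp)
  })
}
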