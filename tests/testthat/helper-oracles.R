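# Independent oracles used across the suite.

# brute-force peak: density of the max copy number, lowest density on ties
bruteForcePeak <- function(density, copies) {
  o <- order(density)
  density <- density[o]; copies <- copies[o]
  density[which(copies == max(copies))[1]]
}

# one-way ANOVA F statistic from explicit sums of squares
bruteForceF <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ssb <- sum(lengths(groups) * (vapply(groups, mean, numeric(1)) - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  k <- length(groups); n <- length(all)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# permutation p value for the one-way ANOVA F statistic
permutationAnovaP <- function(groups, nPerm = 10000, seed = 20240901) {
  set.seed(seed)
  values <- unlist(groups, use.names = FALSE)
  sizes <- lengths(groups)
  idx <- rep(seq_along(groups), sizes)
  fObs <- bruteForceF(groups)
  hits <- 0L
  for (i in seq_len(nPerm)) {
    perm <- split(sample(values), idx)
    if (bruteForceF(perm) >= fObs - 1e-12) hits <- hits + 1L
  }
  hits / nPerm
}

# pairwise Tukey p by direct studentized-range computation
bruteForceTukeyP <- function(groups) {
  k <- length(groups)
  ns <- lengths(groups)
  dfw <- sum(ns) - k
  msw <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                    numeric(1))) / dfw
  mns <- vapply(groups, mean, numeric(1))
  pairs <- combn(names(groups), 2)
  p <- apply(pairs, 2, function(pr) {
    se <- sqrt(msw / 2 * (1 / ns[pr[1]] + 1 / ns[pr[2]]))
    q <- abs(mns[pr[1]] - mns[pr[2]]) / se
    stats::ptukey(q, k, dfw, lower.tail = FALSE)
  })
  names(p) <- paste(pairs[1, ], pairs[2, ], sep = "-")
  p
}

randomSetup <- function() {
  IncubationSetup(dryMassG = runif(1, 1, 20),
                  incubationDays = runif(1, 1, 365),
                  headspaceVolumeMl = runif(1, 50, 1000),
                  molarVolumeLPerMol = runif(1, 20, 25),
                  molarMass13C = 13.00335,
                  molarMass15N = 15.0001)
}
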