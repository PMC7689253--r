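## Group comparisons: one-way ANOVA across depths with a Tukey compact
## letter display, and Welch tests for labeled-vs-control contrasts.

.checkGroups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a named list of >= 2 groups", call. = FALSE)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be named", call. = FALSE)
  if (any(vapply(groups, length, 1L) < 2L))
    stop("every group needs >= 2 replicate values", call. = FALSE)
  invisible(groups)
}

.stackGroups <- function(groups) {
  data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)),
                   levels = names(groups)))
}

#' One-way fixed-effects ANOVA
#'
#' Classical decomposition of a one-factor design, as used to compare
#' potentials across soil depths. A degenerate design with zero within- and
#' between-group variance returns F = 0, p = 1.
#'
#' @param groups named list of numeric vectors, one per group, each with at
#'   least 2 replicates
#' @return list with elements \code{F}, \code{p}, \code{dfBetween},
#'   \code{dfWithin}
#' @examples
#' oneWayAnova(list(a = c(1, 2, 3), b = c(11, 12, 13), c = c(21, 22, 23)))
#' @export
oneWayAnova <- function(groups) {
  .checkGroups(groups)
  d <- .stackGroups(groups)
  # fully degenerate design (MSB = MSW = 0): no evidence of differences
  if (max(d$value) == min(d$value))
    return(list(F = 0, p = 1, dfBetween = length(groups) - 1L,
                dfWithin = nrow(d) - length(groups)))
  fit <- aov(value ~ group, data = d)
  tab <- anova(fit)
  Fv <- tab[["F value"]][1]
  pv <- tab[["Pr(>F)"]][1]
  if (is.na(Fv)) { Fv <- 0; pv <- 1 }
  list(F = Fv, p = pv,
       dfBetween = tab[["Df"]][1], dfWithin = tab[["Df"]][2])
}

## Tukey-adjusted pairwise p values from stats::TukeyHSD, as a data.frame
## with group1/group2/p columns. With zero residual variance the adjusted p
## is NaN; pairs with equal means get p = 1, unequal means p = 0.
.tukeyPairwise <- function(groups) {
  d <- .stackGroups(groups)
  fit <- aov(value ~ group, data = d)
  tk <- TukeyHSD(fit)$group
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  p <- tk[, "p adj"]
  if (any(!is.finite(p))) {
    mns <- vapply(groups, mean, numeric(1))
    for (i in which(!is.finite(p))) {
      pair <- nm[[i]]
      p[i] <- if (isTRUE(all.equal(mns[pair[1]], mns[pair[2]]))) 1 else 0
    }
  }
  data.frame(group1 = vapply(nm, `[`, "", 1L),
             group2 = vapply(nm, `[`, "", 2L),
             p = as.numeric(p), stringsAsFactors = FALSE)
}

## Unadjusted pairwise comparisons using the pooled ANOVA error (Fisher's
## LSD); available for sensitivity analysis.
.lsdPairwise <- function(groups) {
  mns <- vapply(groups, mean, numeric(1))
  ns <- lengths(groups)
  k <- length(groups)
  dfw <- sum(ns) - k
  msw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) /
    dfw
  pairs <- utils::combn(names(groups), 2)
  p <- apply(pairs, 2, function(pr) {
    se <- sqrt(msw * (1 / ns[pr[1]] + 1 / ns[pr[2]]))
    if (se == 0)
      return(if (isTRUE(all.equal(mns[pr[1]], mns[pr[2]]))) 1 else 0)
    2 * pt(-abs((mns[pr[1]] - mns[pr[2]]) / se), dfw)
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], p = as.numeric(p),
             stringsAsFactors = FALSE)
}

## Insert-absorb compact letter display. Input: group names and the
## significant pairs; output: named character vector of letter strings such
## that two groups share a letter iff they are NOT significantly different.
.insertAbsorb <- function(groupNames, sigPairs) {
  cols <- list(groupNames) # each column = set of groups sharing one letter
  if (nrow(sigPairs) > 0) {
    for (i in seq_len(nrow(sigPairs))) {
      a <- sigPairs$group1[i]; b <- sigPairs$group2[i]
      hit <- vapply(cols, function(s) all(c(a, b) %in% s), logical(1))
      for (j in which(hit)) {
        s <- cols[[j]]
        cols[[j]] <- setdiff(s, a)
        cols[[length(cols) + 1L]] <- setdiff(s, b)
      }
      ## absorb columns that are subsets of another column
      keep <- rep(TRUE, length(cols))
      for (j in seq_along(cols)) {
        for (l in seq_along(cols)) {
          if (j != l && keep[l] &&
              all(cols[[j]] %in% cols[[l]]) &&
              !(all(cols[[l]] %in% cols[[j]]) && j < l))
            keep[j] <- FALSE
        }
      }
      cols <- cols[keep]
    }
  }
  ## order columns by the first group they contain, for stable letters
  first <- vapply(cols, function(s) min(match(s, groupNames)), numeric(1))
  cols <- cols[order(first)]
  lett <- vapply(groupNames, function(g) {
    paste(letters[which(vapply(cols, function(s) g %in% s, logical(1)))],
          collapse = "")
  }, character(1))
  lett
}

#' Compact letter display from Tukey-adjusted pairwise comparisons
#'
#' Groups sharing a letter are not significantly different at \code{alpha}
#' after Tukey HSD adjustment (the post-hoc standard for balanced small-n
#' designs); groups sharing no letter differ. Letters are assigned by the
#' insert-absorb algorithm. Fisher's LSD (unadjusted pooled-t) is available
#' for sensitivity checks via \code{method = "lsd"}.
#'
#' @param groups named list of numeric vectors
#' @param alpha significance level (default 0.05)
#' @param method \code{"tukey"} (default) or \code{"lsd"}
#' @return list with elements \code{letters} (named character vector),
#'   \code{pairwise} (data.frame of adjusted pairwise p values),
#'   \code{alpha}, \code{method}
#' @examples
#' tukeyLetters(list(top = c(1, 2, 3), mid = c(11, 12, 13),
#'                   deep = c(21, 22, 23)))$letters
#' @export
tukeyLetters <- function(groups, alpha = 0.05,
                         method = c("tukey", "lsd")) {
  method <- match.arg(method)
  .checkGroups(groups)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  pw <- switch(method, tukey = .tukeyPairwise(groups),
               lsd = .lsdPairwise(groups))
  sig <- pw[pw$p < alpha, , drop = FALSE]
  list(letters = .insertAbsorb(names(groups), sig),
       pairwise = pw, alpha = alpha, method = method)
}

#' Two-sided Welch t-test between labeled and control values
#'
#' Unequal-variance t-test, the safe default for labeled-vs-control bottle
#' comparisons where variance homogeneity is not guaranteed. Degenerate
#' inputs (zero variance on both sides) return p = 1 for equal means and
#' p = 0 otherwise.
#'
#' @param labeled,control numeric vectors with at least 2 values each
#' @return two-sided p value
#' @examples
#' pairwiseWelch(c(1, 2, 3), c(2, 3, 4))  # ~0.29
#' @export
pairwiseWelch <- function(labeled, control) {
  if (length(labeled) < 2L || length(control) < 2L)
    stop("each side needs >= 2 values", call. = FALSE)
  if (sd(labeled) == 0 && sd(control) == 0)
    return(if (isTRUE(all.equal(mean(labeled), mean(control)))) 1 else 0)
  t.test(labeled, control, var.equal = FALSE)$p.value
}

#' Group-comparison summary for a potentials table
#'
#' For each potential (total CH4 oxidation, N2 fixation), runs the one-way
#' ANOVA across depths on labeled bottles and attaches Tukey letters per
#' depth.
#'
#' @param potentials output of \code{\link{computePotentials}}
#' @param alpha significance level
#' @return data.frame with one row per depth x metric: n, mean, sd, letter,
#'   and the metric-level F and p
#' @export
statsSummary <- function(potentials, alpha = 0.05) {
  p <- potentials[potentials$treatment == "labeled", , drop = FALSE]
  metrics <- c(ch4_total = "total_ch4_oxidation", n2_fixation = "n2_fixation")
  out <- lapply(names(metrics), function(mn) {
    col <- metrics[[mn]]
    groups <- split(p[[col]], p$depth_label)
    an <- oneWayAnova(groups)
    cld <- tukeyLetters(groups, alpha = alpha)
    data.frame(
      metric = mn,
      depth_label = names(groups),
      n = lengths(groups),
      mean = vapply(groups, mean, numeric(1)),
      sd = vapply(groups, sd, numeric(1)),
      letter = cld$letters[names(groups)],
      F_statistic = an$F,
      p_value = an$p,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
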