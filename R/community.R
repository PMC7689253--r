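## Community composition arithmetic: relative abundances, methanotroph guild
## composition, day-0 -> day-90 shift metrics, and clone-library percentages.

#' Per-sample relative abundances (percent)
#'
#' @param table a \linkS4class{TaxonCountTable}
#' @return taxa x samples matrix of percentages; each column sums to 100
#' @examples
#' m <- matrix(c(3, 7), nrow = 2,
#'             dimnames = list(c("A", "B"), "s1"))
#' relativeAbundance(TaxonCountTable(m, "top_0_20", "day0"))
#' @export
relativeAbundance <- function(table) {
  stopifnot(is(table, "TaxonCountTable"))
  m <- taxonCounts(table)
  tot <- colSums(m)
  if (any(tot <= 0)) stop("zero-total sample", call. = FALSE)
  sweep(m, 2, tot, "/") * 100
}

#' Within-guild composition per sample (percent)
#'
#' Percentages computed over the counts of the panel members only, so each
#' sample's guild composition sums to 100. Genus names are matched
#' case-insensitively against the panel. Samples with no panel counts are
#' returned as \code{NA} columns and flagged in the \code{"empty_guild"}
#' attribute.
#'
#' @param table a \linkS4class{TaxonCountTable}
#' @param panel a \linkS4class{GuildPanel} (default: the aerobic
#'   methanotrophs)
#' @return panel-members x samples matrix of within-guild percentages, with
#'   an \code{empty_guild} attribute naming flagged samples
#' @export
guildComposition <- function(table, panel = methanotrophPanel()) {
  stopifnot(is(table, "TaxonCountTable"), is(panel, "GuildPanel"))
  m <- taxonCounts(table)
  idx <- match(tolower(memberTaxa(panel)), tolower(rownames(m)))
  sub <- matrix(0, nrow = length(memberTaxa(panel)), ncol = ncol(m),
                dimnames = list(memberTaxa(panel), colnames(m)))
  present <- !is.na(idx)
  sub[present, ] <- m[idx[present], , drop = FALSE]
  tot <- colSums(sub)
  empty <- tot <= 0
  if (all(empty))
    stop("no panel member has a nonzero count in any sample", call. = FALSE)
  out <- sweep(sub, 2, ifelse(empty, NA_real_, tot), "/") * 100
  attr(out, "empty_guild") <- colnames(m)[empty]
  out
}

#' Shift metrics between two relative abundances
#'
#' An abundance change is reported both ways it is conventionally quoted:
#' as a percentage-point change (final minus initial) and as a fold change
#' (final over initial). The fold change is \code{NA} when the initial
#' abundance is zero.
#'
#' @param raInitialPct initial relative abundance, percent
#' @param raFinalPct final relative abundance, percent
#' @param taxon optional taxon label(s) carried into the result
#' @return data.frame with columns taxon, ra_initial_pct, ra_final_pct,
#'   pp_change, fold_change; vectorized
#' @examples
#' abundanceShift(2.35, 35.25)  # +32.9 points, 15-fold
#' @export
abundanceShift <- function(raInitialPct, raFinalPct, taxon = NA_character_) {
  .checkPct(raInitialPct, "raInitialPct")
  .checkPct(raFinalPct, "raFinalPct")
  data.frame(
    taxon = taxon,
    ra_initial_pct = raInitialPct,
    ra_final_pct = raFinalPct,
    pp_change = raFinalPct - raInitialPct,
    fold_change = ifelse(raInitialPct > 0, raFinalPct / raInitialPct,
                         NA_real_),
    stringsAsFactors = FALSE)
}

#' Shift metrics for chosen taxa between two timepoints of a count table
#'
#' Computes per-depth relative abundances at the initial and final timepoint
#' and returns \code{\link{abundanceShift}} metrics for each taxon. Each
#' depth must have exactly one sample per timepoint.
#'
#' @param table a \linkS4class{TaxonCountTable}
#' @param taxa taxa to report (default: all)
#' @param from,to timepoint labels of the initial and final samples
#' @return data.frame of shift metrics, one row per depth x taxon
#' @export
communityShifts <- function(table, taxa = rownames(table),
                            from = "insitu", to = "day90") {
  stopifnot(is(table, "TaxonCountTable"))
  ra <- relativeAbundance(table)
  cd <- SummarizedExperiment::colData(table)
  depths <- unique(cd$depth_label)
  rows <- lapply(depths, function(d) {
    s0 <- rownames(cd)[cd$depth_label == d & cd$timepoint == from]
    s1 <- rownames(cd)[cd$depth_label == d & cd$timepoint == to]
    if (length(s0) != 1L || length(s1) != 1L)
      stop("depth ", d, ": need exactly one sample at each of '", from,
           "' and '", to, "'", call. = FALSE)
    cbind(depth_label = d,
          abundanceShift(ra[taxa, s0], ra[taxa, s1], taxon = taxa))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Clone-library percentages
#'
#' Converts clone counts to percentages of the library. \code{percent} keeps
#' full precision; \code{percent_display} applies half-up rounding to two
#' decimals, the convention for reporting clone libraries.
#'
#' @param counts named numeric vector of clone counts per taxon
#' @return data.frame with columns taxon, clone_count, percent,
#'   percent_display, sorted by decreasing count
#' @examples
#' clonePercentages(c(Methylobacter = 15, Methylosinus = 8, other = 29))
#' @export
clonePercentages <- function(counts) {
  if (length(counts) == 0 || sum(counts) <= 0)
    stop("empty clone library", call. = FALSE)
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be named by taxon", call. = FALSE)
  if (any(counts < 0)) stop("negative clone count", call. = FALSE)
  pct <- 100 * counts / sum(counts)
  out <- data.frame(taxon = names(counts),
                    clone_count = as.numeric(counts),
                    percent = as.numeric(pct),
                    percent_display = .roundHalfUp(as.numeric(pct), 2),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$clone_count, out$taxon), ]
  rownames(out) <- NULL
  out
}

#' Most abundant taxon in a sample
#'
#' Ties are broken alphabetically for determinism.
#'
#' @param percentTable taxa x samples matrix of percentages (or counts)
#' @param sample column name or index
#' @return the dominant taxon's name
#' @export
dominantTaxon <- function(percentTable, sample = 1L) {
  row <- percentTable[, sample]
  mx <- max(row)
  sort(rownames(percentTable)[row == mx])[1L]
}
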