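## CSV I/O with schema validation. Dialect is fixed: UTF-8, comma delimiter,
## "." decimal, mandatory header. Provenance is carried in '#'-prefixed
## comment lines above the header and skipped on read.

.schemas <- list(
  microcosm = c("depth_label", "replicate_id", "treatment",
                "co2_concentration_pct", "atom13_co2_day90_pct",
                "atom13_co2_day0_pct", "soc_content_pct",
                "atom13_soc_day90_pct", "atom13_soc_day0_pct",
                "son_content_pct", "atom15_son_day90_pct",
                "atom15_son_day0_pct"),
  gradient = c("sample_id", "gene_name", "treatment_label",
               "buoyant_density_g_per_ml", "copy_number"),
  community = c("sample_id", "depth_label", "timepoint", "taxon", "count"),
  clones = c("library_id", "domain", "depth_label", "taxon", "clone_count")
)

.numericCols <- list(
  microcosm = .schemas$microcosm[4:12],
  gradient = c("buoyant_density_g_per_ml", "copy_number"),
  community = "count",
  clones = "clone_count"
)

#' Read a validated pipeline CSV
#'
#' Reads one of the pipeline's input tables and validates it against the
#' named schema: the header must contain exactly the schema's columns, and
#' numeric columns must parse; violations are reported with the offending
#' column and data row numbers.
#'
#' @param path CSV file path
#' @param schemaName one of \code{"microcosm"}, \code{"gradient"},
#'   \code{"community"}, \code{"clones"}
#' @return validated data.frame with typed columns
#' @export
readTable <- function(path, schemaName = names(.schemas)) {
  schemaName <- match.arg(schemaName)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, comment.char = "#", colClasses = "character",
                 check.names = FALSE, fileEncoding = "UTF-8")
  need <- .schemas[[schemaName]]
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("schema '", schemaName, "': missing column(s) ",
         paste(miss, collapse = ", "), " in ", path, call. = FALSE)
  extra <- setdiff(names(df), need)
  if (length(extra) > 0)
    stop("schema '", schemaName, "': unexpected column(s) ",
         paste(extra, collapse = ", "), " in ", path, call. = FALSE)
  df <- df[, need, drop = FALSE]
  for (col in .numericCols[[schemaName]]) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (length(bad) > 0)
      stop("column '", col, "': unparseable numeric at data row(s) ",
           paste(bad, collapse = ", "), " of ", path, call. = FALSE)
    df[[col]] <- v
  }
  df
}

#' Convenience readers for the individual schemas
#'
#' @param path CSV file path
#' @return validated data.frame
#' @name schemaReaders
NULL

#' @rdname schemaReaders
#' @export
readMeasurementTable <- function(path) readTable(path, "microcosm")
#' @rdname schemaReaders
#' @export
readGradientTable <- function(path) readTable(path, "gradient")
#' @rdname schemaReaders
#' @export
readCommunityTable <- function(path) readTable(path, "community")
#' @rdname schemaReaders
#' @export
readCloneTable <- function(path) readTable(path, "clones")

#' Write a pipeline CSV with a provenance header
#'
#' Writes comment lines (\code{# key: value}) above the header, then the
#' table in the fixed dialect. Values written at full precision;
#' \code{\link{readTable}} round-trips them.
#'
#' @param df data.frame
#' @param path output path
#' @param provenance named list written as comment lines (e.g. config hash,
#'   seed, package version)
#' @return \code{path}, invisibly
#' @export
writeTable <- function(df, path, provenance = list()) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (k in names(provenance))
    writeLines(sprintf("# %s: %s", k, provenance[[k]]), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a long-format community CSV table to a TaxonCountTable
#'
#' @param df data.frame in the community schema (see
#'   \code{\link{readCommunityTable}})
#' @return a \linkS4class{TaxonCountTable}
#' @export
communityFromLong <- function(df) {
  ids <- unique(df$sample_id)
  taxa <- unique(df$taxon)
  m <- matrix(0, nrow = length(taxa), ncol = length(ids),
              dimnames = list(taxa, ids))
  m[cbind(match(df$taxon, taxa), match(df$sample_id, ids))] <- df$count
  meta <- df[!duplicated(df$sample_id), ]
  TaxonCountTable(m,
                  depth = meta$depth_label[match(ids, meta$sample_id)],
                  timepoint = meta$timepoint[match(ids, meta$sample_id)])
}

#' Convert a TaxonCountTable to the long community CSV schema
#'
#' @param table a \linkS4class{TaxonCountTable}
#' @return data.frame in the community schema
#' @export
communityToLong <- function(table) {
  m <- taxonCounts(table)
  cd <- SummarizedExperiment::colData(table)
  out <- do.call(rbind, lapply(colnames(m), function(s) {
    data.frame(sample_id = s,
               depth_label = cd[s, "depth_label"],
               timepoint = cd[s, "timepoint"],
               taxon = rownames(m),
               count = m[, s],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
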