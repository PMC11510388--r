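#' Construct a feature table
#'
#' A feature table is a non-negative numeric matrix with features (ASVs,
#' taxa or functional categories) as rows and samples as columns, carrying a
#' mode flag that records whether the values are raw counts or relative
#' abundances (per-sample columns summing to one).
#'
#' @param values numeric matrix (features x samples) with unique, non-empty
#'   row and column names.
#' @param mode `"counts"` or `"relative"`.
#' @return A `feature_table`: the matrix with a `mode` attribute.
#' @export
feature_table <- function(values, mode = c("counts", "relative")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("feature table needs feature (row) and sample (column) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicated feature ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample ids")
  if (anyNA(values) || any(values < 0))
    stop("feature table values must be non-negative and non-missing")
  if (mode == "relative") {
    cs <- colSums(values)
    if (any(abs(cs - 1) > 1e-9))
      stop("relative-mode columns must each sum to 1 (zero-sum columns forbidden)")
  }
  structure(values, mode = mode, class = c("feature_table", "matrix", "array"))
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table [%s]: %d features x %d samples\n",
              table_mode(x), nrow(x), ncol(x)))
  invisible(x)
}

#' Mode of a feature table
#' @param x a `feature_table`.
#' @return `"counts"` or `"relative"`.
#' @export
table_mode <- function(x) {
  m <- attr(x, "mode")
  if (is.null(m)) "counts" else m
}

# plain numeric matrix, attributes stripped
ft_values <- function(x) {
  y <- unclass(x)
  attr(y, "mode") <- NULL
  class(y) <- NULL
  matrix(as.numeric(y), nrow(x), ncol(x), dimnames = dimnames(x))
}

stopifnot_counts <- function(x, what) {
  if (table_mode(x) != "counts")
    stop(sprintf("%s requires a counts-mode feature table", what))
}

#' Read a feature table from disk
#'
#' Accepts a dense TSV (first column feature id, remaining columns one per
#' sample) or a BIOM-style sparse triplet TSV with columns
#' `feature_id`, `sample_id`, `value` (detected from the header).
#'
#' @param path file path.
#' @param mode value mode of the stored table, `"counts"` by default.
#' @return a `feature_table`.
#' @export
read_feature_table <- function(path, mode = "counts") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("feature table file needs at least two columns")
  triplet <- ncol(df) == 3L &&
    identical(tolower(names(df)), c("feature_id", "sample_id", "value"))
  if (triplet) {
    feats <- unique(df[[1L]]); samps <- unique(df[[2L]])
    vals <- suppressWarnings(as.numeric(df[[3L]]))
    if (anyNA(vals)) stop("non-numeric value in sparse feature table")
    m <- matrix(0, length(feats), length(samps), dimnames = list(feats, samps))
    m[cbind(match(df[[1L]], feats), match(df[[2L]], samps))] <- vals
    return(feature_table(m, mode))
  }
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  if (anyNA(m)) stop("non-numeric cell in feature table")
  rownames(m) <- ids
  feature_table(m, mode)
}

#' Write a feature table as dense TSV
#' @param table a `feature_table`.
#' @param path output path.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(feature_id = rownames(table), ft_values(table),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Taxonomy ranks used throughout the package
#' @export
TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")

#' Read a taxonomy map
#'
#' Two-column TSV: `feature_id` and a semicolon-joined 7-rank lineage
#' (domain;phylum;class;order;family;genus;species). Greengenes-style rank
#' prefixes (`d__`, `p__`, ..., `s__`) are stripped; suffix-disambiguated
#' names (e.g. `Bacteroides_H`) are kept verbatim. Empty ranks become
#' `"unassigned"`.
#'
#' @param path file path.
#' @return data.frame with columns `feature_id` and the seven ranks.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("taxonomy file needs feature_id and lineage columns")
  parts <- strsplit(as.character(df[[2L]]), ";", fixed = TRUE)
  lin <- t(vapply(parts, function(p) {
    p <- trimws(p)
    p <- sub("^[dpcofgs]__", "", p)
    p[p == "" | is.na(p)] <- "unassigned"
    length(p) <- 7L
    p[is.na(p)] <- "unassigned"
    p
  }, character(7L)))
  colnames(lin) <- TAX_RANKS
  out <- data.frame(feature_id = as.character(df[[1L]]), lin,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$feature_id)) stop("duplicated feature id in taxonomy")
  out
}

#' Write a taxonomy map as two-column TSV
#' @param tax taxonomy data.frame as from [read_taxonomy()].
#' @param path output path.
#' @export
write_taxonomy <- function(tax, path) {
  lineage <- apply(tax[, TAX_RANKS, drop = FALSE], 1L, paste, collapse = ";")
  utils::write.table(
    data.frame(feature_id = tax$feature_id, lineage = lineage),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' @param table counts-mode `feature_table`; every sample total must be > 0.
#' @return relative-mode `feature_table` with unit column sums.
#' @export
to_relative <- function(table) {
  if (table_mode(table) == "relative") return(table)
  m <- ft_values(table)
  tot <- colSums(m)
  if (any(tot <= 0)) {
    bad <- colnames(m)[tot <= 0]
    stop("zero-total sample(s): ", paste(bad, collapse = ", "))
  }
  feature_table(sweep(m, 2L, tot, "/"), "relative")
}
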