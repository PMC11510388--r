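#' Prevalence and relative-abundance filtering of ASVs
#'
#' Implements the two standard amplicon filtering rules: a feature is kept
#' iff (i) it is non-zero in at least `ceiling(prevalence_min * n_samples)`
#' samples and (ii) its relative abundance exceeds `rel_abund_min` — in at
#' least one sample (`rel_abund_rule = "any_sample"`, the default) or on
#' average across samples (`"mean_across_samples"`). The kept set is the
#' intersection of the two rules, so filtering is order-insensitive.
#'
#' @param table counts-mode `feature_table` (relative abundances are
#'   computed internally for the abundance rule).
#' @param prevalence_min fraction of samples, default 0.25.
#' @param rel_abund_min relative-abundance fraction, default 0.01.
#' @param rel_abund_rule `"any_sample"` or `"mean_across_samples"`.
#' @return list with `table` (filtered) and `removed`, a data.frame logging
#'   each dropped feature and the rule(s) that removed it.
#' @export
filter_features <- function(table, prevalence_min = 0.25, rel_abund_min = 0.01,
                            rel_abund_rule = c("any_sample", "mean_across_samples")) {
  rel_abund_rule <- match.arg(rel_abund_rule)
  stopifnot(prevalence_min >= 0, prevalence_min <= 1,
            rel_abund_min >= 0, rel_abund_min < 1)
  stopifnot_counts(table, "filter_features")
  m <- ft_values(table)
  n <- ncol(m)
  need <- ceiling(prevalence_min * n)
  prev_ok <- rowSums(m > 0) >= need
  rel <- ft_values(to_relative(table))
  ab_ok <- switch(rel_abund_rule,
    any_sample = apply(rel, 1L, max) > rel_abund_min,
    mean_across_samples = rowMeans(rel) > rel_abund_min)
  keep <- prev_ok & ab_ok
  dropped <- rownames(m)[!keep]
  rule <- character(length(dropped))
  if (length(dropped)) {
    p_fail <- !prev_ok[dropped]
    a_fail <- !ab_ok[dropped]
    rule <- ifelse(p_fail & a_fail, "prevalence+abundance",
                   ifelse(p_fail, "prevalence", "abundance"))
  }
  if (!any(keep)) warning("all features removed by filtering")
  list(table = feature_table(m[keep, , drop = FALSE], "counts"),
       removed = data.frame(feature_id = dropped, rule = rule,
                            stringsAsFactors = FALSE))
}

#' Rarefy a count table to even depth
#'
#' Without-replacement subsampling of each sample's counts to a common
#' depth. With `depth = "min"` the minimum sample total is used; with an
#' explicit depth, samples below it are dropped (logged via attribute
#' `dropped_samples`).
#'
#' @param table counts-mode `feature_table` with integer counts.
#' @param depth target depth (positive integer) or `"min"`.
#' @param seed integer seed making the subsampling reproducible.
#' @return counts-mode `feature_table`; every retained sample sums to `depth`.
#' @export
rarefy <- function(table, depth = "min", seed = 1L) {
  stopifnot_counts(table, "rarefy")
  m <- ft_values(table)
  tot <- colSums(m)
  if (identical(depth, "min")) depth <- min(tot)
  depth <- as.numeric(depth)
  if (length(depth) != 1L || is.na(depth) || depth <= 0)
    stop("rarefaction depth must be a positive count")
  dropped <- colnames(m)[tot < depth]
  keep <- tot >= depth
  if (!any(keep)) stop("no sample reaches the requested depth")
  m <- m[, keep, drop = FALSE]
  set.seed(seed)
  # rrarefy's "observed counts" heuristic warning is spurious here: depth
  # and integrality are validated above
  r <- t(suppressWarnings(vegan::rrarefy(t(round(m)), sample = depth)))
  res <- feature_table(r, "counts")
  attr(res, "dropped_samples") <- dropped
  res
}

#' Cumulative sum scaling normalization
#'
#' Per sample, the scaling factor is the sum of counts at or below the
#' sample's `percentile`-th quantile of its non-zero counts; each count is
#' divided by that factor and multiplied by `scale`. The result is
#' invariant to multiplying a sample by a positive constant and robust to
#' dominance by a few highly abundant features.
#'
#' @param table counts-mode `feature_table`.
#' @param percentile quantile of the non-zero counts, default 0.5.
#' @param scale output scale, default 1000.
#' @return `feature_table` of normalized abundances (relative-mode flag not
#'   set; columns do not sum to one by construction).
#' @export
css_normalize <- function(table, percentile = 0.5, scale = 1000) {
  stopifnot_counts(table, "css_normalize")
  stopifnot(percentile > 0, percentile <= 1, scale > 0)
  m <- ft_values(table)
  s <- vapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    nz <- x[x > 0]
    if (!length(nz)) return(0)
    q <- stats::quantile(nz, probs = percentile, names = FALSE)
    sum(x[x <= q])
  }, numeric(1L))
  if (any(s <= 0)) {
    bad <- colnames(m)[s <= 0]
    stop("zero CSS scaling factor for sample(s): ", paste(bad, collapse = ", "))
  }
  out <- sweep(m, 2L, s, "/") * scale
  feature_table(out, "counts") # normalized abundances; not a simplex
}

#' Aggregate features at a taxonomic rank
#'
#' Counts are summed over features sharing the rank label; features whose
#' label is `"unassigned"` are pooled into a single explicit
#' `"unassigned"` taxon. Per-sample totals are conserved.
#'
#' @param table `feature_table` whose rows all appear in `tax`.
#' @param tax taxonomy data.frame as from [read_taxonomy()].
#' @param rank one of `TAX_RANKS`.
#' @return `feature_table` (taxa x samples), same mode as the input.
#' @export
aggregate_at_rank <- function(table, tax, rank) {
  rank <- match.arg(rank, TAX_RANKS)
  m <- ft_values(table)
  idx <- match(rownames(m), tax$feature_id)
  if (anyNA(idx)) {
    missing <- rownames(m)[is.na(idx)]
    stop("features without taxonomy: ", paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) sprintf(" (+%d more)", length(missing) - 5L) else "")
  }
  lab <- tax[[rank]][idx]
  lab[is.na(lab) | lab == ""] <- "unassigned"
  agg <- rowsum(m, group = lab, reorder = TRUE)
  feature_table(agg, table_mode(table))
}
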