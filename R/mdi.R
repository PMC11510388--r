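#' Build a control reference profile at a taxonomic rank
#'
#' Aggregates the control cohort's counts at `rank`, converts each sample
#' to relative abundance, and takes the coordinate-wise median across
#' control samples. Coordinate-wise medians of compositions need not sum
#' to one, so by default the median vector is renormalized back onto the
#' simplex (required for the dysbiosis index's [0, 100] bound to hold).
#'
#' @param control_table counts-mode `feature_table` of control samples
#'   (at least 3).
#' @param tax taxonomy data.frame.
#' @param rank taxonomic rank, one of `TAX_RANKS`.
#' @param renormalize rescale medians to sum to 1 (default TRUE).
#' @return list of class `reference_profile`: `rank`, `f_controls`
#'   (named numeric), `renormalized`, `n_controls`.
#' @export
build_reference <- function(control_table, tax, rank, renormalize = TRUE) {
  if (ncol(control_table) == 0L) stop("empty control table")
  if (ncol(control_table) < 3L)
    warning("fewer than 3 control samples: median reference is ill-conditioned")
  agg <- aggregate_at_rank(control_table, tax, rank)
  rel <- ft_values(to_relative(agg))
  med <- apply(rel, 1L, stats::median)
  if (renormalize) med <- med / sum(med)
  structure(list(rank = rank, f_controls = med,
                 renormalized = renormalize, n_controls = ncol(control_table)),
            class = "reference_profile")
}

#' Microbial Dysbiosis Index of one profile against a reference
#'
#' Quadratic dissimilarity between a subject's relative-abundance profile
#' and the control median profile:
#' \deqn{Z = \sqrt{\tfrac12 \sum_t (f_{case,t} - f_{controls,t})^2} \times 100}
#' Z ranges from 0 (identical profiles) to 100 (fully disjoint support)
#' when both vectors lie on the simplex; taxa present in only one vector
#' are zero-filled in the other.
#'
#' @param case_profile named numeric vector of relative abundances
#'   (fractions summing to 1).
#' @param reference a `reference_profile` or a named numeric reference
#'   vector summing to 1.
#' @param as_percent return the percentage (default) or the 0-1 fraction.
#' @param tol tolerance on the unit-sum check, default 1e-6.
#' @return scalar Z.
#' @export
mdi_score <- function(case_profile, reference, as_percent = TRUE, tol = 1e-6) {
  ref <- if (inherits(reference, "reference_profile")) reference$f_controls else reference
  check_sum <- function(v, what) {
    if (abs(sum(v) - 1) > tol)
      stop(sprintf("%s does not sum to 1 (sum = %.6g); Z bound unguaranteed", what, sum(v)))
  }
  check_sum(case_profile, "case profile")
  if (!inherits(reference, "reference_profile") ||
      isTRUE(reference$renormalized)) check_sum(ref, "reference profile")
  taxa <- union(names(case_profile), names(ref))
  a <- stats::setNames(numeric(length(taxa)), taxa)
  b <- a
  a[names(case_profile)] <- case_profile
  b[names(ref)] <- ref
  z <- sqrt(0.5 * sum((a - b)^2))
  if (as_percent) 100 * z else z
}

#' Per-subject Microbial Dysbiosis Index across taxonomic ranks
#'
#' Scores every case sample against the control median reference at each
#' requested rank and combines the ranks by unweighted mean into a
#' composite. Cohort mean and SD of the composite are attached as
#' attributes `cohort_mean` and `cohort_sd`.
#'
#' @param case_table counts-mode `feature_table` of case samples.
#' @param control_table counts-mode `feature_table` of control samples.
#' @param tax taxonomy covering both tables.
#' @param ranks ranks scored, default phylum/family/genus.
#' @param renormalize passed to [build_reference()].
#' @return data.frame: `subject_id`, one Z column per rank, `composite`.
#' @export
cohort_mdi <- function(case_table, control_table, tax,
                       ranks = c("phylum", "family", "genus"),
                       renormalize = TRUE) {
  ranks <- match.arg(ranks, TAX_RANKS, several.ok = TRUE)
  refs <- lapply(ranks, function(r)
    build_reference(control_table, tax, r, renormalize = renormalize))
  names(refs) <- ranks
  per_rank <- sapply(ranks, function(r) {
    rel <- ft_values(to_relative(aggregate_at_rank(case_table, tax, r)))
    vapply(seq_len(ncol(rel)), function(j)
      mdi_score(rel[, j], refs[[r]]), numeric(1L))
  })
  per_rank <- matrix(per_rank, ncol = length(ranks),
                     dimnames = list(colnames(case_table), ranks))
  out <- data.frame(subject_id = colnames(case_table), per_rank,
                    composite = rowMeans(per_rank),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "cohort_mean") <- mean(out$composite)
  attr(out, "cohort_sd") <- stats::sd(out$composite)
  out
}

#' Compare MDI between clinical subgroups
#'
#' Two-sided Mann-Whitney test for every pair of subgroup labels, with
#' group medians and boxplot-ready five-number summaries.
#'
#' @param mdi data.frame from [cohort_mdi()].
#' @param labels factor of subgroup labels named by subject id.
#' @param column which MDI column to compare, default `"composite"`.
#' @return list with `medians`, `summaries`, and `pairwise` data.frame.
#' @export
mdi_group_compare <- function(mdi, labels, column = "composite") {
  g <- labels[mdi$subject_id]
  keep <- !is.na(g)
  x <- mdi[[column]][keep]
  g <- droplevels(as.factor(g[keep]))
  if (nlevels(g) < 2L) stop("need at least two groups")
  med <- tapply(x, g, stats::median)
  summ <- do.call(rbind, lapply(levels(g), function(l)
    data.frame(label = l, n = sum(g == l),
               t(stats::setNames(stats::fivenum(x[g == l]),
                 c("min", "q1", "median", "q3", "max"))),
               stringsAsFactors = FALSE)))
  pairs <- utils::combn(levels(g), 2L)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    xa <- x[g == a]; xb <- x[g == b]
    if (length(xa) < 2L || length(xb) < 2L)
      return(data.frame(group1 = a, group2 = b, p = NA_real_,
                        flag = "group_too_small", stringsAsFactors = FALSE))
    p <- suppressWarnings(stats::wilcox.test(xa, xb)$p.value)
    data.frame(group1 = a, group2 = b, p = p, flag = "",
               stringsAsFactors = FALSE)
  }))
  list(medians = med, summaries = summ, pairwise = pw)
}
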