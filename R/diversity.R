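#' Alpha diversity per sample
#'
#' Chao1 (bias-corrected richness estimate), Shannon entropy (natural
#' log) and the Gini-Simpson index \eqn{1 - \sum p_i^2}. Chao1 requires
#' integer counts; Shannon and Simpson are computed from the per-sample
#' relative abundances.
#'
#' @param table counts-mode `feature_table` with positive sample totals.
#' @param indices subset of `c("chao1", "shannon", "simpson")`.
#' @param base logarithm base for Shannon, default `exp(1)` (nats).
#' @return data.frame with one row per sample.
#' @export
alpha_diversity <- function(table, indices = c("chao1", "shannon", "simpson"),
                            base = exp(1)) {
  indices <- match.arg(indices, several.ok = TRUE)
  m <- ft_values(table)
  if (any(colSums(m) <= 0)) stop("zero-total sample")
  out <- data.frame(sample_id = colnames(m), stringsAsFactors = FALSE)
  if ("chao1" %in% indices) {
    stopifnot_counts(table, "chao1")
    if (max(abs(m - round(m))) > 1e-8)
      stop("chao1 requires integer counts")
    out$chao1 <- apply(m, 2L, function(x) {
      s <- sum(x > 0); f1 <- sum(x == 1); f2 <- sum(x == 2)
      s + f1 * (f1 - 1) / (2 * (f2 + 1))
    })
  }
  p <- sweep(m, 2L, colSums(m), "/")
  if ("shannon" %in% indices)
    out$shannon <- apply(p, 2L, function(q) {
      q <- q[q > 0]; -sum(q * log(q, base = base))
    })
  if ("simpson" %in% indices)
    out$simpson <- apply(p, 2L, function(q) 1 - sum(q^2))
  out
}

#' Group comparison of an alpha-diversity index
#'
#' Omnibus Kruskal-Wallis test (tie-corrected H, chi-square p) across all
#' groups, followed by pairwise two-sided Mann-Whitney tests for every
#' label pair. Pairs where either group has fewer than two samples are
#' flagged and not computed.
#'
#' @param values per-sample index values, named by sample id.
#' @param labels factor of group labels aligned with (or named like)
#'   `values`; NA labels are dropped.
#' @param p_adjust method for the pairwise p-values, default `"none"`
#'   (`"BH"` available).
#' @return list with `H`, `omnibus_p`, and `pairwise` data.frame
#'   (`group1`, `group2`, `n1`, `n2`, `p`, `flag`).
#' @export
alpha_group_test <- function(values, labels, p_adjust = "none") {
  if (!is.null(names(values)) && !is.null(names(labels)))
    labels <- labels[names(values)]
  keep <- !is.na(labels) & !is.na(values)
  x <- values[keep]; g <- droplevels(as.factor(labels[keep]))
  if (nlevels(g) < 2L) stop("need at least two non-empty groups")
  kw <- stats::kruskal.test(x, g)
  levs <- levels(g)
  pairs <- utils::combn(levs, 2L)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    xa <- x[g == a]; xb <- x[g == b]
    if (length(xa) < 2L || length(xb) < 2L)
      return(data.frame(group1 = a, group2 = b, n1 = length(xa),
                        n2 = length(xb), p = NA_real_,
                        flag = "group_too_small", stringsAsFactors = FALSE))
    p <- suppressWarnings(stats::wilcox.test(xa, xb, exact = FALSE,
                                             correct = TRUE)$p.value)
    data.frame(group1 = a, group2 = b, n1 = length(xa), n2 = length(xb),
               p = p, flag = "", stringsAsFactors = FALSE)
  }))
  ok <- !is.na(pw$p)
  pw$p_adj <- NA_real_
  pw$p_adj[ok] <- stats::p.adjust(pw$p[ok], method = p_adjust)
  list(H = unname(kw$statistic), omnibus_p = kw$p.value, pairwise = pw)
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d(x, y) = 1 - 2 \sum_i \min(x_i, y_i) / (\sum x + \sum y)},
#' computed between sample columns.
#'
#' @param table `feature_table` with positive sample totals.
#' @return symmetric `dist`-backed square matrix with zero diagonal.
#' @export
bray_curtis <- function(table) {
  m <- ft_values(table)
  if (any(colSums(m) <= 0)) stop("zero-total sample")
  as.matrix(vegan::vegdist(t(m), method = "bray"))
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: partitions the
#' distance matrix's sum of squares by group labels and tests the
#' pseudo-F statistic against label permutations,
#' \eqn{p = (1 + \#\{F^* \ge F\}) / (1 + n_{perm})}.
#'
#' @param dist square symmetric dissimilarity matrix with sample ids.
#' @param labels factor of group labels aligned with (or named like) the
#'   matrix rows; NA labels drop those samples.
#' @param n_permutations default 999.
#' @param seed integer seed for the permutation stream.
#' @return list of class `permanova_result` with `pseudo_F`, `p_value`,
#'   `r2`, `n_permutations`, `seed`, `n`.
#' @export
permanova <- function(dist, labels, n_permutations = 999, seed = 1L) {
  dist <- as.matrix(dist)
  if (!isSymmetric(unname(dist))) stop("distance matrix must be symmetric")
  if (!is.null(names(labels)) && !is.null(rownames(dist)))
    labels <- labels[rownames(dist)]
  keep <- !is.na(labels)
  g <- droplevels(as.factor(labels[keep]))
  if (nlevels(g) < 2L) stop("PERMANOVA needs at least two groups")
  d <- stats::as.dist(dist[keep, keep, drop = FALSE])
  set.seed(seed)
  fit <- vegan::adonis2(d ~ group, data = data.frame(group = g),
                        permutations = n_permutations)
  structure(list(pseudo_F = fit$F[1L], p_value = fit$`Pr(>F)`[1L],
                 r2 = fit$R2[1L], n_permutations = n_permutations,
                 seed = seed, n = sum(keep)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f, R2 = %.3f, p = %.4g (%d permutations, n = %d)\n",
              x$pseudo_F, x$r2, x$p_value, x$n_permutations, x$n))
  invisible(x)
}

#' Principal coordinates analysis
#'
#' Classical metric MDS of a dissimilarity matrix via double-centering
#' and eigendecomposition. Axes are ordered by eigenvalue; negative
#' eigenvalues are reported, never silently dropped.
#'
#' @param dist square symmetric dissimilarity matrix.
#' @return list with `coordinates` (samples x axes, positive-eigenvalue
#'   axes), `eigenvalues` (all, including negatives) and
#'   `explained` (fractions relative to the sum of positive eigenvalues).
#' @export
pcoa <- function(dist) {
  dist <- as.matrix(dist)
  if (!isSymmetric(unname(dist))) stop("distance matrix must be symmetric")
  n <- nrow(dist)
  ev <- stats::cmdscale(stats::as.dist(dist), k = 1, eig = TRUE)$eig
  npos <- sum(ev > sqrt(.Machine$double.eps) * max(abs(ev)))
  if (npos < 1L) stop("no positive eigenvalue: degenerate distance matrix")
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(dist), k = npos, eig = TRUE))
  coords <- fit$points
  colnames(coords) <- paste0("Axis.", seq_len(ncol(coords)))
  list(coordinates = coords,
       eigenvalues = ev,
       explained = pmax(ev, 0) / sum(ev[seq_len(npos)]))
}
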