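#' LEfSe-style analysis settings
#'
#' @param kw_alpha Kruskal-Wallis screen significance level (default 0.05).
#' @param lda_min log10 effect-size threshold; features are called when
#'   the score exceeds it (default 2.0, the conventional "LDA > 2").
#' @param n_boot bootstrap iterations (default 30).
#' @param boot_fraction per-class subsample fraction (default 2/3).
#' @param seed integer seed for the bootstrap stream.
#' @return list of class `lefse_config`.
#' @export
lefse_config <- function(kw_alpha = 0.05, lda_min = 2.0, n_boot = 30L,
                         boot_fraction = 2 / 3, seed = 1L) {
  stopifnot(kw_alpha > 0, kw_alpha < 1, lda_min > 0, n_boot >= 1,
            boot_fraction > 0, boot_fraction <= 1)
  structure(list(kw_alpha = kw_alpha, lda_min = lda_min,
                 n_boot = as.integer(n_boot), boot_fraction = boot_fraction,
                 seed = as.integer(seed)),
            class = "lefse_config")
}

align_labels <- function(table, labels) {
  if (!is.null(names(labels))) labels <- labels[colnames(table)]
  keep <- !is.na(labels)
  list(m = ft_values(table)[, keep, drop = FALSE],
       g = droplevels(as.factor(labels[keep])))
}

#' Kruskal-Wallis screen across features
#'
#' Per-feature tie-corrected Kruskal-Wallis test of abundance across
#' groups (equivalent, for two groups, to a Mann-Whitney decision).
#' Features constant across all samples have no defined p-value and
#' auto-fail the screen with a logged reason.
#'
#' @param table normalized-abundance `feature_table`.
#' @param labels factor of group labels named by sample id; NA drops.
#' @param alpha screen level, default 0.05.
#' @return data.frame: `feature_id`, `kw_p`, `pass`, `reason`.
#' @export
kruskal_screen <- function(table, labels, alpha = 0.05) {
  al <- align_labels(table, labels)
  if (nlevels(al$g) < 2L) stop("need at least two groups")
  if (min(table(al$g)) < 2L) stop("each group needs at least two samples")
  res <- apply(al$m, 1L, function(x) {
    if (stats::var(x) == 0) return(NA_real_)
    stats::kruskal.test(x, al$g)$p.value
  })
  data.frame(feature_id = rownames(al$m), kw_p = res,
             pass = !is.na(res) & res < alpha,
             reason = ifelse(is.na(res), "constant_feature", ""),
             stringsAsFactors = FALSE)
}

# per-class means of a feature matrix (features x samples)
class_means <- function(m, g) {
  t(rowsum(t(m), g) / as.vector(table(g)))
}

#' Bootstrapped linear-discriminant effect size
#'
#' For each bootstrap iteration a `boot_fraction` subsample is drawn from
#' every class and a one-dimensional linear discriminant is evaluated per
#' feature (for a single-feature design the unit-norm discriminant axis
#' is trivial, so the combined class-mean/axis-weight effect reduces to
#' the signed difference between the feature's most- and least-enriched
#' classes, the pair being fixed from the full data as in a one-vs-all
#' scheme). The effect is the signed mean over bootstraps — so a feature
#' whose class distributions coincide cancels toward zero — and the
#' reported score is \eqn{\log_{10}(1 + |\bar e|)}. Scores are covariant
#' with the input scale: [discover_biomarkers()] feeds abundances
#' rescaled to per-million sample totals, on which the conventional
#' "LDA > 2" threshold corresponds to a mean separation of about 100
#' parts per million.
#'
#' @param table normalized-abundance `feature_table` (typically restricted
#'   to features passing [kruskal_screen()]).
#' @param labels factor of group labels named by sample id.
#' @param cfg a [lefse_config()].
#' @return data.frame: `feature_id`, `lda_score`, `enriched_group`.
#' @export
lda_effect_size <- function(table, labels, cfg = lefse_config()) {
  al <- align_labels(table, labels)
  if (nlevels(al$g) < 2L) stop("need at least two groups")
  m <- al$m
  idx_by_class <- split(seq_along(al$g), al$g)
  n_take <- vapply(idx_by_class, function(i)
    as.integer(max(1, ceiling(cfg$boot_fraction * length(i)))), integer(1L))
  mu_all <- class_means(m, al$g)
  top <- max.col(mu_all, "first")
  bot <- max.col(-mu_all, "last")
  rows <- seq_len(nrow(m))
  set.seed(cfg$seed)
  eff <- matrix(0, nrow(m), cfg$n_boot)
  for (b in seq_len(cfg$n_boot)) {
    take <- unlist(lapply(seq_along(idx_by_class), function(k)
      sample(idx_by_class[[k]], n_take[k])))
    mu_b <- class_means(m[, take, drop = FALSE], al$g[take])
    eff[, b] <- mu_b[cbind(rows, top)] - mu_b[cbind(rows, bot)]
  }
  data.frame(feature_id = rownames(m),
             lda_score = log10(1 + abs(rowMeans(eff))),
             enriched_group = colnames(mu_all)[top],
             stringsAsFactors = FALSE)
}

#' Covariate-adjusted linear models per feature
#'
#' Fits, per feature, `log(abundance + pseudocount) ~ group + age +
#' gender` on the normalized table and reports the p-value of the group
#' term (for more than two groups, an omnibus nested-model F comparison
#' against the covariate-only model). The pseudocount is half the
#' smallest non-zero value of the table and is recorded as an attribute.
#'
#' @param table normalized-abundance `feature_table`.
#' @param labels factor of group labels named by sample id.
#' @param covariates data.frame with `subject_id`, `age`, `gender` (any
#'   additional numeric/factor columns are included as extra covariates).
#' @return data.frame: `feature_id`, `lm_group_p`, `reason`; attributes
#'   `pseudocount` and `covariates`.
#' @export
confounder_lm <- function(table, labels, covariates) {
  al <- align_labels(table, labels)
  cov <- covariates[match(colnames(al$m), covariates$subject_id), , drop = FALSE]
  if (anyNA(cov$age) || anyNA(cov$gender))
    stop("covariates must be complete for modeled samples")
  cov_cols <- setdiff(names(cov), "subject_id")
  df <- data.frame(group = al$g, cov[cov_cols], stringsAsFactors = TRUE)
  X <- stats::model.matrix(~ ., data = df)
  if (qr(X)$rank < ncol(X)) {
    cc <- abs(stats::cor(X[, -1L, drop = FALSE]))
    diag(cc) <- 0
    worst <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
    stop(sprintf("collinear covariates: %s ~ %s",
                 colnames(cc)[worst[1L]], colnames(cc)[worst[2L]]))
  }
  nz <- al$m[al$m > 0]
  pseudo <- if (length(nz)) min(nz) / 2 else 1e-6
  res <- apply(al$m, 1L, function(x) {
    if (stats::var(x) == 0) return(NA_real_)
    y <- log(x + pseudo)
    fit1 <- stats::lm(y ~ ., data = df)
    fit0 <- stats::lm(y ~ . - group, data = df)
    stats::anova(fit0, fit1)[2L, "Pr(>F)"]
  })
  out <- data.frame(feature_id = rownames(al$m), lm_group_p = res,
                    reason = ifelse(is.na(res), "constant_feature", ""),
                    stringsAsFactors = FALSE)
  attr(out, "pseudocount") <- pseudo
  attr(out, "covariates") <- cov_cols
  out
}

#' Dual-method consensus biomarker report
#'
#' Joins the Kruskal-Wallis/LDA effect-size arm with the covariate-
#' adjusted linear-model arm. A feature is a consensus biomarker iff
#' `kw_p < kw_alpha`, `lda_score > lda_min` and `lm_group_p < 0.05`;
#' features supported by one arm only are retained and marked
#' `single-method`. Benjamini-Hochberg adjusted columns are always
#' emitted alongside the raw p-values.
#'
#' @param screen output of [kruskal_screen()].
#' @param lda output of [lda_effect_size()].
#' @param lm output of [confounder_lm()].
#' @param cfg a [lefse_config()].
#' @return data.frame of class `biomarker_report`: one row per feature
#'   with `kw_p`, `lda_score`, `enriched_group`, `lm_group_p`,
#'   `consensus`, `method`, `kw_q`, `lm_q`.
#' @export
consensus <- function(screen, lda, lm, cfg = lefse_config()) {
  out <- merge(screen[c("feature_id", "kw_p", "pass")],
               lda[c("feature_id", "lda_score", "enriched_group")],
               by = "feature_id", all.x = TRUE)
  out <- merge(out, lm[c("feature_id", "lm_group_p")],
               by = "feature_id", all.x = TRUE)
  lefse_hit <- out$pass & !is.na(out$lda_score) & out$lda_score > cfg$lda_min
  lm_hit <- !is.na(out$lm_group_p) & out$lm_group_p < 0.05
  out$consensus <- lefse_hit & lm_hit
  out$method <- ifelse(out$consensus, "both",
                ifelse(lefse_hit, "lefse_only",
                ifelse(lm_hit, "lm_only", "none")))
  out$enriched_group[!lefse_hit & !out$consensus & is.na(out$lda_score)] <- NA
  out$kw_q <- stats::p.adjust(out$kw_p, "BH")
  out$lm_q <- stats::p.adjust(out$lm_group_p, "BH")
  out$pass <- NULL
  class(out) <- c("biomarker_report", "data.frame")
  out
}

#' Run the full dual-method biomarker discovery
#'
#' Convenience wrapper: Kruskal-Wallis screen, LDA effect size on the
#' screened features, covariate-adjusted linear models on all features,
#' consensus intersection.
#'
#' @inheritParams confounder_lm
#' @param cfg a [lefse_config()].
#' @return a `biomarker_report` (see [consensus()]).
#' @export
discover_biomarkers <- function(table, labels, covariates,
                                cfg = lefse_config()) {
  scr <- kruskal_screen(table, labels, alpha = cfg$kw_alpha)
  passers <- scr$feature_id[scr$pass]
  lda <- if (length(passers)) {
    # LDA arm runs on per-million-total abundances so the lda_min
    # threshold has its conventional meaning
    ppm <- sweep(ft_values(table), 2L, colSums(ft_values(table)), "/") * 1e6
    sub <- feature_table(ppm[passers, , drop = FALSE], "counts")
    lda_effect_size(sub, labels, cfg)
  } else data.frame(feature_id = character(), lda_score = numeric(),
                    enriched_group = character(), stringsAsFactors = FALSE)
  lm <- confounder_lm(table, labels, covariates)
  consensus(scr, lda, lm, cfg)
}

#' Differential analysis of a functional (KO/pathway) table
#'
#' Applies the same dual-method consensus machinery to a pathway-by-
#' sample table. All-zero rows are excluded (logged in attribute
#' `excluded`). The linear-model arm runs on log-transformed
#' totals-scaled values; with `use_voom = TRUE` it is replaced by a
#' mean-variance-weighted fit (limma's voom precision weights), the
#' unweighted log-linear model remaining the reference arm.
#'
#' @param ko_table counts-mode `feature_table` of functional categories.
#' @param labels factor of group labels named by sample id.
#' @param covariates clinical covariates as in [confounder_lm()]; when
#'   NULL an intercept-plus-group model is used.
#' @param cfg a [lefse_config()].
#' @param use_voom use limma-voom precision weights for the model arm.
#' @return a `biomarker_report`.
#' @export
pathway_differential <- function(ko_table, labels, covariates = NULL,
                                 cfg = lefse_config(), use_voom = FALSE) {
  m <- ft_values(ko_table)
  zero <- rowSums(m) == 0
  tab <- feature_table(m[!zero, , drop = FALSE], table_mode(ko_table))
  al <- align_labels(tab, labels)
  if (is.null(covariates))
    covariates <- data.frame(subject_id = colnames(ft_values(tab)),
                             age = 0, gender = "male",
                             stringsAsFactors = FALSE)
  scaled <- feature_table(sweep(al$m, 2L, colSums(al$m), "/") * 1e6, "counts")
  scr <- kruskal_screen(scaled, al$g, alpha = cfg$kw_alpha)
  passers <- scr$feature_id[scr$pass]
  lda <- if (length(passers)) {
    lda_effect_size(feature_table(ft_values(scaled)[passers, , drop = FALSE],
                                  "counts"), al$g, cfg)
  } else data.frame(feature_id = character(), lda_score = numeric(),
                    enriched_group = character(), stringsAsFactors = FALSE)
  lm_res <- if (use_voom) {
    voom_arm(al$m, al$g)
  } else {
    cov_ok <- covariates[match(colnames(al$m), covariates$subject_id), ,
                         drop = FALSE]
    drop_cov <- vapply(cov_ok, function(x) length(unique(x)) < 2L, logical(1L))
    drop_cov["subject_id"] <- FALSE
    confounder_lm(scaled, al$g, cov_ok[!drop_cov])
  }
  rep <- consensus(scr, lda, lm_res, cfg)
  attr(rep, "excluded") <- rownames(m)[zero]
  rep
}

# limma-voom weighted linear model arm: moderated F/t p for the group term
voom_arm <- function(counts, g) {
  design <- stats::model.matrix(~ g)
  v <- limma::voom(round(counts), design)
  fit <- limma::eBayes(limma::lmFit(v, design))
  p <- if (ncol(design) > 2L) {
    limma::topTable(fit, coef = 2:ncol(design), number = Inf,
                    sort.by = "none")$P.Value
  } else {
    fit$p.value[, 2L]
  }
  data.frame(feature_id = rownames(counts), lm_group_p = as.numeric(p),
             reason = "", stringsAsFactors = FALSE)
}
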