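#' Pipeline run configuration
#'
#' Bundles the per-stage settings and seeds for [run_all()]. Every
#' stochastic stage (rarefaction, PERMANOVA permutations, LEfSe
#' bootstraps) has its own explicit seed.
#'
#' @param strat a [strat_config()].
#' @param prevalence_min,rel_abund_min,rel_abund_rule filtering settings
#'   (see [filter_features()]).
#' @param lefse a [lefse_config()].
#' @param mdi_ranks taxonomic ranks for the dysbiosis index.
#' @param biomarker_rank rank at which biomarker discovery runs
#'   (default genus).
#' @param depth_floor minimum sample depth retained before rarefaction
#'   (default 1000 reads).
#' @param n_permutations PERMANOVA permutations (default 999).
#' @param age_break age-class boundary in years for the confounder check
#'   (default 6).
#' @param seed_rarefy,seed_permanova seeds for the stochastic stages.
#' @return list of class `run_config`.
#' @export
run_config <- function(strat = strat_config(),
                       prevalence_min = 0.25, rel_abund_min = 0.01,
                       rel_abund_rule = "any_sample",
                       lefse = lefse_config(),
                       mdi_ranks = c("phylum", "family", "genus"),
                       biomarker_rank = "genus",
                       depth_floor = 1000,
                       n_permutations = 999,
                       age_break = 6,
                       seed_rarefy = 11L, seed_permanova = 12L) {
  structure(as.list(environment()), class = "run_config")
}

#' Check age and gender as ecological confounders
#'
#' Bins age into two classes (default at 6 years), then runs a
#' Kruskal-Wallis test on Shannon alpha diversity and a Bray-Curtis
#' PERMANOVA for each factor. A factor whose PERMANOVA p-value falls
#' below `alpha` is flagged as a confounder; the flags feed the linear
#' models' covariate list. Degenerate factors (a single level) are
#' skipped with a logged reason.
#'
#' @param table counts-mode `feature_table` (typically rarefied).
#' @param clinical `clinical_table` covering the table's samples.
#' @param age_break age-class boundary in years (default 6).
#' @param alpha flag level (default 0.05).
#' @param n_permutations,seed PERMANOVA settings.
#' @return data.frame: `factor`, `alpha_p`, `permanova_p`, `confounder`,
#'   `skipped`.
#' @export
confounder_check <- function(table, clinical, age_break = 6, alpha = 0.05,
                             n_permutations = 999, seed = 1L) {
  cl <- clinical[match(colnames(table), clinical$subject_id), , drop = FALSE]
  facs <- list(
    age_class = factor(ifelse(cl$age <= age_break,
                              sprintf("age<=%g", age_break),
                              sprintf("age>%g", age_break))),
    gender = factor(cl$gender))
  shannon <- alpha_diversity(table, "shannon")$shannon
  d <- bray_curtis(table)
  out <- do.call(rbind, lapply(names(facs), function(f) {
    g <- facs[[f]]
    if (nlevels(droplevels(g)) < 2L)
      return(data.frame(factor = f, alpha_p = NA_real_,
                        permanova_p = NA_real_, confounder = NA,
                        skipped = "single_level", stringsAsFactors = FALSE))
    ap <- stats::kruskal.test(shannon, g)$p.value
    pm <- permanova(d, stats::setNames(g, colnames(table)),
                    n_permutations = n_permutations, seed = seed)
    data.frame(factor = f, alpha_p = ap, permanova_p = pm$p_value,
               confounder = pm$p_value < alpha, skipped = "",
               stringsAsFactors = FALSE)
  }))
  out
}

run_stage <- function(expr) {
  tryCatch(list(ok = TRUE, value = expr, error = NULL),
           error = function(e) list(ok = FALSE, value = NULL,
                                    error = conditionMessage(e)))
}

#' Run the full stratified analysis
#'
#' Orchestrates the end-to-end pipeline on in-memory inputs: clinical
#' stratification; prevalence/abundance filtering; rarefaction feeding
#' alpha/beta diversity (with per-variable Kruskal-Wallis, Mann-Whitney
#' and PERMANOVA); cumulative-sum-scaling normalization feeding the
#' dual-method biomarker discovery at `biomarker_rank`; the Microbial
#' Dysbiosis Index against the control table; and the age/gender
#' confounder check. Failure of one stratification variable's analysis
#' is recorded and does not abort the others.
#'
#' @param case_table counts-mode `feature_table` of case samples.
#' @param control_table counts-mode `feature_table` of control samples
#'   (for the MDI reference).
#' @param taxonomy taxonomy data.frame covering both tables.
#' @param clinical `clinical_table` for the case subjects.
#' @param cfg a [run_config()].
#' @return list of class `run_report`.
#' @export
run_all <- function(case_table, control_table, taxonomy, clinical,
                    cfg = run_config()) {
  labels <- stratify_all(clinical, cfg$strat)
  cohort <- lapply(labels, function(l)
    run_stage(cohort_summary(l)))

  filt <- filter_features(case_table, cfg$prevalence_min,
                          cfg$rel_abund_min, cfg$rel_abund_rule)
  ft <- filt$table

  # diversity branch: QC floor, rarefy to min depth
  deep <- colSums(ft) >= cfg$depth_floor
  rar <- rarefy(feature_table(ft_values(ft)[, deep, drop = FALSE], "counts"),
                depth = "min", seed = cfg$seed_rarefy)
  alpha <- alpha_diversity(rar)
  d_bc <- bray_curtis(rar)
  alpha_tests <- lapply(labels, function(l) run_stage({
    lapply(c(chao1 = "chao1", shannon = "shannon", simpson = "simpson"),
           function(ix) alpha_group_test(
             stats::setNames(alpha[[ix]], alpha$sample_id), l))
  }))
  beta_tests <- lapply(labels, function(l) run_stage(
    permanova(d_bc, l, n_permutations = cfg$n_permutations,
              seed = cfg$seed_permanova)))
  ord <- pcoa(d_bc)

  # normalization branch: CSS-normalized, rank-aggregated biomarkers
  norm <- css_normalize(ft)
  norm_rank <- aggregate_at_rank(norm, taxonomy, cfg$biomarker_rank)
  covars <- clinical[c("subject_id", "age", "gender")]
  biom <- lapply(labels, function(l) run_stage(
    discover_biomarkers(norm_rank, l, covars, cfg$lefse)))

  # dysbiosis index on the filtered counts
  mdi <- run_stage(cohort_mdi(ft, control_table, taxonomy,
                              ranks = cfg$mdi_ranks))
  mdi_compare <- if (mdi$ok) {
    lapply(labels, function(l) run_stage(mdi_group_compare(mdi$value, l)))
  } else NULL

  conf <- run_stage(confounder_check(rar, clinical,
                                     age_break = cfg$age_break,
                                     n_permutations = cfg$n_permutations,
                                     seed = cfg$seed_permanova))

  structure(list(labels = labels, cohort = cohort,
                 filter_log = filt$removed,
                 rarefaction = list(depth = min(colSums(ft_values(rar))),
                                    seed = cfg$seed_rarefy,
                                    dropped = colnames(ft)[!deep]),
                 alpha = alpha, alpha_tests = alpha_tests,
                 beta_tests = beta_tests, pcoa = ord,
                 biomarkers = biom, mdi = mdi, mdi_compare = mdi_compare,
                 confounders = conf, config = cfg),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("stratified gut-microbiota analysis report\n")
  for (v in names(x$cohort)) {
    st <- x$cohort[[v]]
    if (st$ok) {
      s <- st$value
      cat(sprintf("  %-9s n=%d: %s\n", v, attr(s, "n_scored"),
                  paste(sprintf("%s %d (%d%%)", s$label, s$count, s$percent),
                        collapse = ", ")))
    } else cat(sprintf("  %-9s failed: %s\n", v, st$error))
  }
  if (x$mdi$ok)
    cat(sprintf("  MDI composite: mean %.1f, sd %.2f\n",
                attr(x$mdi$value, "cohort_mean"),
                attr(x$mdi$value, "cohort_sd")))
  invisible(x)
}

#' Write a run report's tables to a directory
#'
#' @param report a `run_report`.
#' @param dir output directory (created if absent).
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  write_labels(report$labels, file.path(dir, "subgroup_labels.tsv"))
  coh <- do.call(rbind, lapply(names(report$cohort), function(v) {
    st <- report$cohort[[v]]
    if (!st$ok) return(NULL)
    cbind(variable = v, st$value)
  }))
  if (!is.null(coh)) w(coh, "cohort_summary.tsv")
  w(report$filter_log, "filter_removed.tsv")
  w(report$alpha, "alpha_diversity.tsv")
  beta <- do.call(rbind, lapply(names(report$beta_tests), function(v) {
    st <- report$beta_tests[[v]]
    if (!st$ok) return(data.frame(variable = v, pseudo_F = NA, p = NA,
                                  error = st$error))
    data.frame(variable = v, pseudo_F = st$value$pseudo_F,
               p = st$value$p_value, error = "")
  }))
  w(beta, "permanova.tsv")
  if (report$mdi$ok) w(report$mdi$value, "mdi_per_subject.tsv")
  for (v in names(report$biomarkers)) {
    st <- report$biomarkers[[v]]
    if (st$ok) w(st$value, sprintf("biomarkers_%s.tsv", v))
  }
  if (report$confounders$ok) w(report$confounders$value, "confounders.tsv")
  invisible(dir)
}
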