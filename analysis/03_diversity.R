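#!/usr/bin/env Rscript
# Ecology of the case cohort: prevalence/abundance filtering, rarefaction
# to even depth, Chao1/Shannon/Simpson alpha diversity with per-variable
# Kruskal-Wallis tests, Bray-Curtis beta diversity with PERMANOVA, PCoA
# ordination, and the age/gender confounder check.

source("analysis/_common.R")
co <- build_cohort()
labels <- stratify_all(co$clinical)
out <- res_dir("diversity")

filt <- filter_features(co$case)
cat(sprintf("filtering: %d of %d ASVs retained (%d by prevalence, %d by abundance, %d by both)\n",
            nrow(filt$table), nrow(co$case),
            sum(filt$removed$rule == "prevalence"),
            sum(filt$removed$rule == "abundance"),
            sum(filt$removed$rule == "prevalence+abundance")))
write_tsv(filt$removed, file.path(out, "filter_removed.tsv"))

rar <- rarefy(filt$table, depth = "min", seed = 11)
cat(sprintf("rarefied to %d reads/sample\n", min(colSums(rar))))

alpha <- alpha_diversity(rar)
write_tsv(alpha, file.path(out, "alpha_diversity.tsv"))

alpha_rows <- list()
for (v in names(labels)) {
  for (ix in c("chao1", "shannon", "simpson")) {
    t <- tryCatch(alpha_group_test(setNames(alpha[[ix]], alpha$sample_id),
                                   labels[[v]]),
                  error = function(e) NULL)
    if (!is.null(t))
      alpha_rows[[paste(v, ix)]] <- data.frame(variable = v, index = ix,
                                               H = t$H, p = t$omnibus_p)
  }
}
alpha_tests <- do.call(rbind, alpha_rows)
write_tsv(alpha_tests, file.path(out, "alpha_group_tests.tsv"))
cat(sprintf("alpha group tests: %d/%d comparisons with KW p < 0.05\n",
            sum(alpha_tests$p < 0.05), nrow(alpha_tests)))

d <- bray_curtis(rar)
beta <- do.call(rbind, lapply(names(labels), function(v) {
  pm <- tryCatch(permanova(d, labels[[v]], n_permutations = 999, seed = 12),
                 error = function(e) NULL)
  if (is.null(pm)) return(NULL)
  data.frame(variable = v, pseudo_F = pm$pseudo_F, R2 = pm$r2, p = pm$p_value)
}))
write_tsv(beta, file.path(out, "permanova.tsv"))
for (i in seq_len(nrow(beta)))
  cat(sprintf("PERMANOVA %-9s: pseudo-F %.2f, R2 %.3f, p %.3f\n",
              beta$variable[i], beta$pseudo_F[i], beta$R2[i], beta$p[i]))

ord <- pcoa(d)
coords <- data.frame(sample_id = rownames(ord$coordinates),
                     ord$coordinates[, 1:3])
write_tsv(coords, file.path(out, "pcoa_coordinates.tsv"))
cat(sprintf("PCoA axes 1-3 explain %.1f%%, %.1f%%, %.1f%% of positive inertia\n",
            100 * ord$explained[1], 100 * ord$explained[2], 100 * ord$explained[3]))

conf <- confounder_check(rar, co$clinical, n_permutations = 999, seed = 13)
write_tsv(conf, file.path(out, "confounders.tsv"))
for (i in seq_len(nrow(conf)))
  cat(sprintf("confounder %-9s: PERMANOVA p %.3f -> %s\n", conf$factor[i],
              conf$permanova_p[i],
              ifelse(isTRUE(conf$confounder[i]), "adjust for it", "not flagged")))
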