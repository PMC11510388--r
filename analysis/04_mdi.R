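#!/usr/bin/env Rscript
# Microbial Dysbiosis Index: each case subject scored against the control
# cohort's median profile at phylum, family and genus rank, then compared
# between clinical subgroups.

source("analysis/_common.R")
co <- build_cohort()
labels <- stratify_all(co$clinical)
out <- res_dir("mdi")

filt <- filter_features(co$case)$table
mdi <- cohort_mdi(filt, co$control, co$taxonomy)
write_tsv(mdi, file.path(out, "mdi_per_subject.tsv"))
cat(sprintf("MDI composite: cohort mean %.1f +/- %.2f (phylum %.1f, family %.1f, genus %.1f)\n",
            attr(mdi, "cohort_mean"), attr(mdi, "cohort_sd"),
            mean(mdi$phylum), mean(mdi$family), mean(mdi$genus)))

rows <- list()
for (v in names(labels)) {
  cmp <- tryCatch(mdi_group_compare(mdi, labels[[v]]),
                  error = function(e) NULL)
  if (is.null(cmp)) next
  med <- paste(sprintf("%s %.1f", names(cmp$medians), cmp$medians),
               collapse = ", ")
  cat(sprintf("%-9s medians: %s\n", v, med))
  rows[[v]] <- cbind(variable = v, cmp$pairwise)
}
write_tsv(do.call(rbind, rows), file.path(out, "mdi_group_tests.tsv"))
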