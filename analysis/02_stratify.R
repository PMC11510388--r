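#!/usr/bin/env Rscript
# Stratify the cohort on each neuropsychological variable and tabulate
# subgroup sizes, mirroring the clinical-characterization step that
# anchors every downstream comparison.

source("analysis/_common.R")
co <- build_cohort()

labels <- stratify_all(co$clinical)
out <- res_dir("cohort")
write_labels(labels, file.path(out, "subgroup_labels.tsv"))

summaries <- do.call(rbind, lapply(names(labels), function(v) {
  s <- cohort_summary(labels[[v]])
  cbind(variable = v, n_scored = attr(s, "n_scored"), s)
}))
write_tsv(summaries, file.path(out, "subgroup_summary.tsv"))

for (v in names(labels)) {
  s <- summaries[summaries$variable == v, ]
  cat(sprintf("%-9s (n=%d scored): %s\n", v, s$n_scored[1],
              paste(sprintf("%s %d/%d (%d%%)", s$label, s$count,
                            s$n_scored[1], s$percent), collapse = ", ")))
}
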