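# Shared setup for the analysis drivers: one default synthetic cohort,
# regenerated deterministically by each script (cheap, seed-fixed), with
# five biomarker taxa planted in the severe-autism subgroup.

library(asdgm)

COHORT_SEED <- 101L

build_cohort <- function() {
  pre <- generate_cohort(synth_config(seed = COHORT_SEED))
  planted <- default_planted_effects(pre$truth$base)
  co <- generate_cohort(synth_config(planted_effects = planted,
                                     seed = COHORT_SEED))
  co$planted <- planted
  co
}

res_dir <- function(sub) {
  d <- file.path("results", sub)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
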