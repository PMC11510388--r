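#!/usr/bin/env Rscript
# Build the synthetic study cohort: 70 cases / 70 controls, 300 ASVs,
# clinical scores mirroring the target cohort's marginals, and five
# biomarker taxa planted in the severe-autism subgroup. The full count
# tables are regenerable from the seed, so only the compact tables
# (clinical metadata, taxonomy, ground truth, depth summary) are kept
# under results/; scratch/ holds the bulky intermediates.

source("analysis/_common.R")
co <- build_cohort()

out <- res_dir("cohort")
write_tsv(co$clinical, file.path(out, "clinical.tsv"))
write_taxonomy(co$taxonomy, file.path(out, "taxonomy.tsv"))
write_tsv(co$planted, file.path(out, "ground_truth_planted.tsv"))

dir.create("scratch", showWarnings = FALSE)
write_feature_table(co$case, "scratch/case_counts.tsv")
write_feature_table(co$control, "scratch/control_counts.tsv")

depths <- data.frame(cohort = rep(c("case", "control"), c(70, 70)),
                     sample_id = c(colnames(co$case), colnames(co$control)),
                     depth = c(colSums(co$case), colSums(co$control)))
write_tsv(depths, file.path(out, "sequencing_depths.tsv"))

cat(sprintf("cohort: %d cases (%d male / %d female), %d controls\n",
            ncol(co$case), sum(co$clinical$gender == "male"),
            sum(co$clinical$gender == "female"), ncol(co$control)))
cat(sprintf("age %.2f +/- %.2f y; CSS %.2f +/- %.2f (%d missing); IQ/DQ %.1f +/- %.1f\n",
            mean(co$clinical$age), sd(co$clinical$age),
            mean(co$clinical$css, na.rm = TRUE), sd(co$clinical$css, na.rm = TRUE),
            sum(is.na(co$clinical$css)),
            mean(co$clinical$iq_dq, na.rm = TRUE), sd(co$clinical$iq_dq, na.rm = TRUE)))
cat(sprintf("depths: %d-%d reads (floor 1000); planted taxa: %s\n",
            min(depths$depth), max(depths$depth),
            paste(co$planted$taxon, collapse = ", ")))
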