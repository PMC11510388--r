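Package: asdgm
Title: Stratified Gut-Microbiota Analysis for Autism Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end analysis of 16S amplicon sequence variant (ASV)
    tables for neuropsychologically stratified autism-spectrum cohorts:
    clinical subgrouping by ADOS-2 calibrated severity score, CBCL t-score
    bands and IQ/DQ; feature-table filtering, rarefaction, cumulative sum
    scaling and taxonomic rank aggregation; alpha/beta diversity with
    Kruskal-Wallis, Mann-Whitney, PERMANOVA and principal coordinates;
    a Microbial Dysbiosis Index against a matched control reference; and
    dual-method biomarker discovery intersecting an LDA effect-size screen
    with covariate-adjusted linear models. Includes a Dirichlet-multinomial
    synthetic cohort generator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    limma
Suggests: testthat (>= 3.0.0), jsonlite, withr, knitr
Config/testthat/edition: 3
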