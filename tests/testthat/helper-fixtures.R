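# small in-code fixtures shared across test files

# 4-feature, 3-sample toy count table
toy_table <- function() {
  m <- matrix(c(5, 5, 0, 10,
                2, 0, 6, 2,
                1, 1, 1, 1),
              nrow = 4L,
              dimnames = list(paste0("f", 1:4), paste0("s", 1:3)))
  feature_table(m, "counts")
}

# taxonomy for n features: two phyla, features alternate genus within
toy_taxonomy <- function(ids) {
  n <- length(ids)
  data.frame(feature_id = ids,
             domain = "Bacteria",
             phylum = rep(c("PhyA", "PhyB"), length.out = n),
             class = rep(c("ClsA", "ClsB"), length.out = n),
             order = rep(c("OrdA", "OrdB"), length.out = n),
             family = rep(c("FamA", "FamB"), length.out = n),
             genus = rep(c("GenA", "GenB", "GenC"), length.out = n),
             species = paste0("sp", seq_len(n)),
             stringsAsFactors = FALSE)
}

# random composition over k taxa
random_composition <- function(k, names = paste0("t", seq_len(k))) {
  x <- stats::rgamma(k, shape = 1)
  stats::setNames(x / sum(x), names)
}

# minimal clinical covariate frame for n samples named ids
toy_covariates <- function(ids, seed = 1) {
  set.seed(seed)
  data.frame(subject_id = ids,
             age = round(runif(length(ids), 3, 17), 1),
             gender = sample(c("male", "female"), length(ids), replace = TRUE),
             stringsAsFactors = FALSE)
}
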