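make_groups <- function(n_per, labels = c("a", "b")) {
  ids <- paste0("s", seq_len(n_per * length(labels)))
  setNames(factor(rep(labels, each = n_per)), ids)
}

test_that("Kruskal screen passes separated features, fails constants, reuses the hand oracle", {
  g <- make_groups(5)
  sep <- c(rnorm(5, 1, 0.01), rnorm(5, 100, 0.01))
  flat <- rep(3, 10)
  noise <- runif(10, 0, 5)
  m <- rbind(sep = sep, flat = flat, noise = noise)
  colnames(m) <- names(g)
  res <- kruskal_screen(feature_table(m, "counts"), g)
  expect_true(res$pass[res$feature_id == "sep"])
  expect_false(res$pass[res$feature_id == "flat"])
  expect_equal(res$reason[res$feature_id == "flat"], "constant_feature")
  # 3x3 toy: H = 7.2 -> p = pchisq(7.2, 2, lower = FALSE)
  g3 <- make_groups(3, c("a", "b", "c"))
  m3 <- matrix(1:9, 1, dimnames = list("f", names(g3)))
  res3 <- kruskal_screen(feature_table(m3, "counts"), g3)
  expect_equal(res3$kw_p, pchisq(7.2, df = 2, lower.tail = FALSE))
  expect_error(kruskal_screen(feature_table(m3, "counts"),
                              setNames(factor(rep("a", 9)), names(g3))),
               "two groups")
})

test_that("LDA effect size exceeds 2 for strong planted effects and stays low under the null", {
  g <- make_groups(10)
  set.seed(31)
  # 10x mean shift, tiny variance, on the per-million scale
  strong <- c(rnorm(10, 2e4, 500), rnorm(10, 2e5, 500))
  m <- rbind(strong = strong,
             matrix(runif(20 * 5, 1e5, 3e5), 5,
                    dimnames = list(paste0("r", 1:5), NULL)))
  colnames(m) <- names(g)
  res <- lda_effect_size(feature_table(m, "counts"), g, lefse_config(seed = 1))
  expect_gt(res$lda_score[res$feature_id == "strong"], 2)
  expect_equal(res$enriched_group[res$feature_id == "strong"], "b")
  # determinism per seed
  res2 <- lda_effect_size(feature_table(m, "counts"), g, lefse_config(seed = 1))
  expect_equal(res2$lda_score, res$lda_score)
  # global x10 rescaling raises every score (scale covariance)
  res10 <- lda_effect_size(feature_table(m * 10, "counts"), g,
                           lefse_config(seed = 1))
  expect_true(all(res10$lda_score > res$lda_score))
  # identical class distributions: signed bootstrap effects cancel and the
  # score stays below the threshold in >= 95% of seeds
  vals <- runif(10, 9e3, 1.1e4)
  nullm <- matrix(c(vals, vals), 1, dimnames = list("n1", names(g)))
  below <- vapply(1:40, function(s) {
    r <- lda_effect_size(feature_table(nullm, "counts"), g,
                         lefse_config(seed = s))
    r$lda_score[1] < 2
  }, logical(1))
  expect_gte(mean(below), 0.95)
})

test_that("covariate-adjusted models control confounding and recover planted shifts", {
  g <- make_groups(30)
  covars <- toy_covariates(names(g), seed = 2)
  # type-I calibration: abundance driven purely by age
  set.seed(32)
  rejections <- vapply(1:200, function(i) {
    y <- exp(0.2 * covars$age + rnorm(60, 0, 0.5))
    m <- matrix(y, 1, dimnames = list("f", names(g)))
    confounder_lm(feature_table(m, "counts"), g, covars)$lm_group_p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.05)
  # power: 2 SD group shift on the log scale, age balanced
  set.seed(33)
  hits <- vapply(1:100, function(i) {
    base <- rnorm(60, 0, 0.5)
    base[g == "b"] <- base[g == "b"] + 1  # 2 SD
    m <- matrix(exp(base), 1, dimnames = list("f", names(g)))
    confounder_lm(feature_table(m, "counts"), g, covars)$lm_group_p < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.8)
  # constant feature rejected with reason
  m0 <- matrix(1, 1, 60, dimnames = list("f", names(g)))
  r0 <- confounder_lm(feature_table(m0, "counts"), g, covars)
  expect_true(is.na(r0$lm_group_p))
  expect_equal(r0$reason, "constant_feature")
  # collinear covariates named in the error
  covars2 <- covars
  covars2$age2 <- covars2$age * 2
  expect_error(confounder_lm(feature_table(m0, "counts"), g, covars2),
               "collinear")
})

test_that("consensus is the intersection of the two arms and keeps single-method calls", {
  g <- make_groups(8)
  set.seed(34)
  covars <- toy_covariates(names(g), seed = 3)
  both <- c(rnorm(8, 0.02, 0.002), rnorm(8, 0.2, 0.002))
  none <- runif(16, 0.1, 0.12)
  m <- rbind(both = both, none = none)
  colnames(m) <- names(g)
  rep <- discover_biomarkers(feature_table(m, "counts"), g, covars)
  expect_s3_class(rep, "biomarker_report")
  expect_true(rep$consensus[rep$feature_id == "both"])
  expect_equal(rep$method[rep$feature_id == "both"], "both")
  expect_false(rep$consensus[rep$feature_id == "none"])
  # consensus set is a subset of each arm's pass set
  lefse_pass <- !is.na(rep$lda_score) & rep$lda_score > 2 & rep$kw_p < 0.05
  lm_pass <- !is.na(rep$lm_group_p) & rep$lm_group_p < 0.05
  expect_true(all(rep$consensus == (lefse_pass & lm_pass)))
  expect_true(all(c("kw_q", "lm_q") %in% names(rep)))
  # empty intersection is a valid run
  m2 <- matrix(runif(32, 0.1, 0.12), 2, dimnames = list(c("x", "y"), names(g)))
  rep2 <- discover_biomarkers(feature_table(m2, "counts"), g, covars)
  expect_false(any(rep2$consensus))
})

test_that("statistics are invariant to sample and feature permutation", {
  g <- make_groups(6)
  set.seed(35)
  m <- matrix(rgamma(8 * 12, 2, 1), 8,
              dimnames = list(paste0("f", 1:8), names(g)))
  covars <- toy_covariates(names(g), seed = 5)
  tab <- feature_table(m, "counts")
  r1 <- kruskal_screen(tab, g)
  sperm <- sample(colnames(m)); fperm <- sample(rownames(m))
  tab2 <- feature_table(m[fperm, sperm], "counts")
  r2 <- kruskal_screen(tab2, g)
  expect_equal(r2$kw_p[match(r1$feature_id, r2$feature_id)], r1$kw_p)
  l1 <- confounder_lm(tab, g, covars)
  l2 <- confounder_lm(tab2, g, covars)
  expect_equal(l2$lm_group_p[match(l1$feature_id, l2$feature_id)],
               l1$lm_group_p)
})

test_that("pathway differential detects a planted 2-fold shift and excludes zero rows", {
  g <- make_groups(20)
  set.seed(36)
  n <- length(g)
  base <- matrix(rpois(50 * n, 200), 50, dimnames = list(sprintf("K%02d", 1:50),
                                                         names(g)))
  base["K01", g == "b"] <- rpois(20, 400)  # 2-fold pathway shift
  base["K50", ] <- 0
  covars <- toy_covariates(names(g), seed = 6)
  rep <- pathway_differential(feature_table(base, "counts"), g, covars)
  expect_true(rep$consensus[rep$feature_id == "K01"])
  expect_false("K50" %in% rep$feature_id)
  expect_equal(attr(rep, "excluded"), "K50")
  # voom-weighted arm agrees on the strong hit
  repv <- pathway_differential(feature_table(base, "counts"), g, covars,
                               use_voom = TRUE)
  expect_lt(repv$lm_group_p[repv$feature_id == "K01"], 0.05)
  # label permutation keeps the false-discovery rate near alpha
  set.seed(37)
  fp <- vapply(1:20, function(i) {
    gp <- setNames(sample(g), names(g))
    r <- pathway_differential(feature_table(base[1:30, ], "counts"), gp,
                              covars, lefse_config(seed = i))
    sum(r$consensus)
  }, numeric(1))
  expect_lt(mean(fp) / 30, 0.06)
})
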