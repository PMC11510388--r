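test_that("alpha indices reproduce closed forms", {
  # uniform over 4 taxa
  u <- feature_table(matrix(25, 4, 1, dimnames = list(paste0("f", 1:4), "s")),
                     "counts")
  a <- alpha_diversity(u)
  expect_equal(a$shannon, log(4), tolerance = 1e-12)
  expect_equal(a$simpson, 0.75, tolerance = 1e-12)
  # single taxon
  one <- feature_table(matrix(c(9, 0), 2, 1,
                              dimnames = list(c("a", "b"), "s")), "counts")
  a1 <- alpha_diversity(one)
  expect_equal(a1$shannon, 0)
  expect_equal(a1$simpson, 0)
  # chao1 with S_obs = 10, F1 = 2, F2 = 1 -> 10 + 2*1/(2*2) = 10.5
  x <- c(1, 1, 2, rep(5, 7))
  tab <- feature_table(matrix(x, 10, 1,
                              dimnames = list(paste0("f", 1:10), "s")), "counts")
  expect_equal(alpha_diversity(tab)$chao1, 10.5)
  expect_gte(alpha_diversity(tab)$chao1, sum(x > 0))
  # chao1 refuses non-integer input
  ni <- feature_table(matrix(c(0.5, 0.5), 2, 1,
                             dimnames = list(c("a", "b"), "s")), "relative")
  expect_error(alpha_diversity(ni, "chao1"), "counts")
})

test_that("alpha indices are invariant to ordering and zero-count features", {
  set.seed(11)
  m <- matrix(rpois(40, 10), 8, 5,
              dimnames = list(paste0("f", 1:8), paste0("s", 1:5)))
  tab <- feature_table(m, "counts")
  a <- alpha_diversity(tab)
  perm <- feature_table(m[sample(8), sample(5)], "counts")
  ap <- alpha_diversity(perm)
  ap <- ap[match(a$sample_id, ap$sample_id), ]
  expect_equal(ap$shannon, a$shannon)
  expect_equal(ap$simpson, a$simpson)
  padded <- feature_table(rbind(m, zero = 0), "counts")
  z <- alpha_diversity(padded)
  expect_equal(z$shannon, a$shannon)
  expect_equal(z$simpson, a$simpson)
})

test_that("Kruskal-Wallis group test matches hand computation and the exact MW oracle", {
  vals <- setNames(1:9, paste0("s", 1:9))
  g <- setNames(factor(rep(c("a", "b", "c"), each = 3)), names(vals))
  res <- alpha_group_test(vals, g)
  expect_equal(res$H, 7.2, tolerance = 1e-12)
  expect_equal(nrow(res$pairwise), 3L)
  # identical groups -> H = 0
  same <- setNames(rep(c(1, 2, 3), 2), paste0("s", 1:6))
  gs <- setNames(factor(rep(c("a", "b"), each = 3)), names(same))
  expect_equal(alpha_group_test(same, gs)$H, 0)
  # two-group KW decision agrees with exact-enumeration Mann-Whitney at n <= 8
  # away from the decision boundary (the chi-square approximation and the
  # exact null can legitimately disagree right at alpha)
  set.seed(4)
  for (i in 1:25) {
    x <- sample(1:100, 8)  # distinct, no ties
    gg <- setNames(factor(rep(c("a", "b"), each = 4)), paste0("s", 1:8))
    names(x) <- names(gg)
    kw_p <- alpha_group_test(x, gg)$omnibus_p
    exact_p <- wilcox.test(x[1:4], x[5:8], exact = TRUE)$p.value
    if (exact_p < 0.03 || exact_p > 0.10)
      expect_equal(kw_p < 0.05, exact_p < 0.05)
  }
  # undersized group flagged, not computed
  u <- setNames(c(1, 2, 3, 4), paste0("s", 1:4))
  gu <- setNames(factor(c("a", "a", "a", "b")), names(u))
  pw <- alpha_group_test(u, gu)$pairwise
  expect_equal(pw$flag, "group_too_small")
  expect_true(is.na(pw$p))
})

test_that("Bray-Curtis matches its formula and bounds", {
  m <- cbind(x = c(1, 0), y = c(0.5, 0.5))
  rownames(m) <- c("f1", "f2")
  d <- bray_curtis(feature_table(m / rep(colSums(m), each = 2), "relative"))
  expect_equal(d["x", "y"], 0.5)
  expect_equal(unname(diag(d)), c(0, 0))
  # identical samples -> 0; disjoint -> 1
  id <- cbind(a = c(3, 7), b = c(3, 7)); rownames(id) <- c("f1", "f2")
  expect_equal(bray_curtis(feature_table(id, "counts"))["a", "b"], 0)
  dj <- cbind(a = c(5, 0), b = c(0, 9)); rownames(dj) <- c("f1", "f2")
  expect_equal(bray_curtis(feature_table(dj, "counts"))["a", "b"], 1)
})

test_that("PERMANOVA separates clusters, is invariant to relabeling, errors on one group", {
  set.seed(5)
  pts <- rbind(matrix(rnorm(20, 0, 0.05), 10),
               matrix(rnorm(20, 5, 0.05), 10))
  rownames(pts) <- paste0("s", 1:20)
  d <- as.matrix(dist(pts))
  g <- setNames(factor(rep(c("a", "b"), each = 10)), rownames(pts))
  res <- permanova(d, g, n_permutations = 199, seed = 2)
  expect_equal(res$p_value, 1 / 200)
  expect_gte(res$p_value, 1 / (res$n_permutations + 1))
  # permuting sample order together with labels leaves F unchanged
  perm <- sample(rownames(pts))
  res2 <- permanova(d[perm, perm], g[perm], n_permutations = 199, seed = 2)
  expect_equal(res2$pseudo_F, res$pseudo_F)
  expect_error(permanova(d, setNames(factor(rep("a", 20)), rownames(pts))),
               "two groups")
  expect_error(permanova(matrix(c(0, 1, 2, 0), 2), factor(c("a", "b"))),
               "symmetric")
})

test_that("PCoA reconstructs Euclidean-embeddable distances and reports eigenvalues", {
  set.seed(9)
  pts <- matrix(rnorm(18), 6, 3, dimnames = list(paste0("s", 1:6), NULL))
  d <- as.matrix(dist(pts))
  fit <- pcoa(d)
  rec <- as.matrix(dist(fit$coordinates))
  expect_lt(max(abs(rec - d)), 1e-9)
  expect_true(all(diff(fit$eigenvalues) <= 1e-8))  # sorted descending
  # three equidistant samples: two equal positive eigenvalues
  eq <- matrix(1, 3, 3) - diag(3)
  dimnames(eq) <- list(paste0("s", 1:3), paste0("s", 1:3))
  ev <- pcoa(eq)$eigenvalues
  expect_equal(ev[1], ev[2], tolerance = 1e-9)
  # points on a line: one dominant positive eigenvalue
  line <- as.matrix(dist(matrix(c(0, 1, 2, 3), 4)))
  dimnames(line) <- list(paste0("s", 1:4), paste0("s", 1:4))
  evl <- pcoa(line)$eigenvalues
  expect_gt(evl[1], 10 * abs(evl[2]))
})
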