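test_that("feature tables round-trip through dense TSV and reject bad input", {
  tab <- toy_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_equal(ft_values(back), ft_values(tab))

  sparse <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tsample_id\tvalue",
               "f1\ts1\t3", "f2\ts2\t4"), sparse)
  st <- read_feature_table(sparse)
  expect_equal(unname(ft_values(st)["f1", ]), c(3, 0))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1", "f1\toops"), bad)
  expect_error(read_feature_table(bad), "non-numeric")
  expect_error(feature_table(matrix(-1, 1, 1,
                                    dimnames = list("f", "s"))), "non-negative")
})

test_that("taxonomy reader strips rank prefixes and keeps suffixed names", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tlineage",
               "f1\td__Bacteria;p__Firmicutes_A;c__;o__X;f__Y;g__Bacteroides_H;s__",
               "f2\tBacteria;Bacteroidota"), path)
  tax <- read_taxonomy(path)
  expect_equal(tax$phylum, c("Firmicutes_A", "Bacteroidota"))
  expect_equal(tax$genus[1], "Bacteroides_H")
  expect_equal(tax$class[1], "unassigned")
  expect_equal(tax$species[2], "unassigned")
})

test_that("to_relative normalizes columns and flags zero-total samples", {
  m <- matrix(c(5, 5, 0, 10), 4, 1, dimnames = list(paste0("f", 1:4), "s1"))
  rel <- to_relative(feature_table(m, "counts"))
  expect_equal(unname(ft_values(rel)[, 1]), c(0.25, 0.25, 0, 0.5))
  expect_equal(table_mode(rel), "relative")
  z <- matrix(c(1, 0), 1, 2, dimnames = list("f1", c("a", "b")))
  expect_error(to_relative(feature_table(z, "counts")), "zero-total.*b")
})

test_that("filtering applies prevalence ceiling and abundance rules as an intersection", {
  # f_prev: nonzero in 1/5 samples (20% < 25%); f_keep: 2/5 (40%);
  # f_low: constant relative abundance 0.005 <= 0.01 in every sample
  m <- rbind(f_prev = c(300, 0, 0, 0, 0),
             f_keep = c(300, 300, 0, 0, 0),
             f_low  = c(  3,   3, 3, 3, 3),
             f_big  = c(297, 297, 597, 597, 597))
  colnames(m) <- paste0("s", 1:5)
  res <- filter_features(feature_table(m, "counts"))
  expect_setequal(rownames(res$table), c("f_keep", "f_big"))
  expect_equal(res$removed$rule[res$removed$feature_id == "f_prev"], "prevalence")
  expect_equal(res$removed$rule[res$removed$feature_id == "f_low"], "abundance")

  # boundary: 1 of 4 samples is exactly 25% -> retained
  m4 <- rbind(f1 = c(50, 0, 0, 0), f2 = c(50, 100, 100, 100))
  colnames(m4) <- paste0("s", 1:4)
  res4 <- filter_features(feature_table(m4, "counts"))
  expect_true("f1" %in% rownames(res4$table))

  # ceiling rule: enumerate n = 1..10 against independent arithmetic
  for (n in 1:10) {
    mm <- matrix(10, 2, n, dimnames = list(c("a", "b"), paste0("s", 1:n)))
    mm[1, ] <- 0; mm[1, 1] <- 10  # feature a nonzero in exactly 1 sample
    kept <- rownames(filter_features(feature_table(mm, "counts"))$table)
    expect_equal("a" %in% kept, 1 >= ceiling(0.25 * n))
  }
})

test_that("rarefaction conserves depth, is deterministic, and unbiased in expectation", {
  m <- rbind(a = c(10, 30), b = c(0, 20), c = c(90, 0))
  colnames(m) <- c("s1", "s2")
  tab <- feature_table(m, "counts")
  r <- rarefy(tab, depth = "min", seed = 3)
  expect_true(all(colSums(ft_values(r)) == 50))
  expect_equal(ft_values(rarefy(tab, depth = "min", seed = 3)), ft_values(r))
  # single support: [10, 0] to depth 5 -> [5, 0]
  one <- feature_table(matrix(c(10, 0), 2, 1,
                              dimnames = list(c("a", "b"), "s")), "counts")
  expect_equal(unname(ft_values(rarefy(one, depth = 5))[, 1]), c(5, 0))
  expect_error(rarefy(tab, depth = 0), "positive")
  # explicit depth drops shallow samples with a log entry
  r2 <- rarefy(tab, depth = 80, seed = 1)
  expect_equal(colnames(r2), "s1")
  expect_equal(attr(r2, "dropped_samples"), "s2")

  # expectation: mean rarefied count ~= depth * proportion, over 1000 seeds
  draws <- vapply(1:1000, function(s)
    ft_values(rarefy(tab, depth = 50, seed = s))["a", "s1"], numeric(1))
  p <- 10 / 100
  expected <- 50 * p
  se <- sqrt(50 * p * (1 - p) * (100 - 50) / (100 - 1)) / sqrt(1000)
  expect_lt(abs(mean(draws) - expected), 3 * se)
})

test_that("CSS normalization matches its quantile-sum definition and is scale invariant", {
  x <- c(f1 = 2, f2 = 8, f3 = 0, f4 = 40)
  tab <- feature_table(cbind(s1 = x, s2 = 2 * x), "counts")
  out <- ft_values(css_normalize(tab, percentile = 0.5, scale = 1000))
  # brute-force evaluation of the definition on the vector itself
  nz <- sort(x[x > 0])
  q <- stats::quantile(nz, 0.5, names = FALSE)
  s_manual <- sum(x[x <= q])
  expect_equal(unname(out[, "s1"]), unname(x / s_manual * 1000))
  # doubling a sample leaves its normalized column unchanged
  expect_equal(out[, "s1"], out[, "s2"])
  # single-feature samples normalize to the same value
  sf <- feature_table(matrix(c(4, 8), 1, 2,
                             dimnames = list("f", c("a", "b"))), "counts")
  o <- ft_values(css_normalize(sf))
  expect_equal(o[1, "a"], o[1, "b"])
})

test_that("rank aggregation is additive, conservative, and commutes with to_relative", {
  tab <- toy_table()
  tax <- toy_taxonomy(rownames(tab))
  gen <- aggregate_at_rank(tab, tax, "genus")
  # f1 and f4 share GenA in toy taxonomy (1,4 -> GenA by recycling of 3 genera)
  expect_equal(ft_values(gen)["GenA", "s1"],
               sum(ft_values(tab)[tax$genus == "GenA", "s1"]))
  expect_equal(colSums(ft_values(gen)), colSums(ft_values(tab)))
  # commutativity with relative-abundance conversion
  a <- ft_values(aggregate_at_rank(to_relative(tab), tax, "phylum"))
  b <- ft_values(to_relative(aggregate_at_rank(tab, tax, "phylum")))
  expect_equal(a, b)
  # unassigned pooling
  tax2 <- tax; tax2$species <- "unassigned"
  sp <- aggregate_at_rank(tab, tax2, "species")
  expect_equal(nrow(sp), 1L)
  expect_equal(rownames(sp), "unassigned")
  # missing lineage errors with offender names
  expect_error(aggregate_at_rank(tab, tax[-1, ], "genus"), "f1")
})
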