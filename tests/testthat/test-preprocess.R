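test_that("low-count filter keeps any gene with total count >= 1", {
  # rows: g1 = (0,0), g2 = (0,0), g3 = (1,0), g4 = (5,3)
  x <- toy_counts(c(0, 0, 1, 5, 0, 0, 0, 3), 4, 2)
  out <- suppressMessages(filter_low_count_genes(x))
  # all-zero rows removed; g3 with a single count of 1 retained (boundary)
  expect_identical(out$report$removed_ids, c("g1", "g2"))
  expect_identical(rownames(out$matrix), c("g3", "g4"))
  expect_equal(out$report$features_out,
               out$report$features_in - length(out$report$removed_ids))
  expect_error(filter_low_count_genes(retag(x, "normalized")), "counts")
})

test_that("low-count report matches an independent row-sum scan", {
  set.seed(42)
  vals <- rbinom(500 * 8, 2, 0.05)      # zero-inflated
  x <- toy_counts(vals, 500, 8)
  out <- suppressMessages(filter_low_count_genes(x))
  brute <- rownames(x)[rowSums(unclass(x)) < 1]
  expect_identical(out$report$removed_ids, brute)
})

test_that("normalization: size factors and transform behave as closed form", {
  # identical columns -> all size factors 1 -> output log2(count + 1)
  x <- toy_counts(rep(c(4, 10, 30), 3), 3, 3)
  nx <- normalize_counts(x)
  expect_equal(unname(attr(nx, "size_factors")), rep(1, 3))
  expect_equal(unclass(nx)[, 1], log2(c(4, 10, 30) + 1),
               ignore_attr = TRUE)
  expect_identical(layer_tag(nx), "normalized")

  # doubling one sample doubles its size factor (all genes nonzero)
  set.seed(7)
  y <- matrix(rpois(50 * 4, 100) + 1, 50, 4,
              dimnames = list(sprintf("g%d", 1:50), sprintf("s%d", 1:4)))
  y2 <- y; y2[, 2] <- 2 * y[, 2]
  sf1 <- attr(normalize_counts(omics_matrix(y, "counts")), "size_factors")
  sf2 <- attr(normalize_counts(omics_matrix(y2, "counts")), "size_factors")
  # size factors are relative: doubling sample 2 doubles its factor
  # relative to every other sample
  expect_equal(unname(sf2[2] / sf2[1]), unname(2 * sf1[2] / sf1[1]),
               tolerance = 1e-12)

  # monotone within a sample
  ord <- order(y[, 3])
  ny <- normalize_counts(omics_matrix(y, "counts"))
  expect_true(all(diff(unclass(ny)[ord, 3]) >= 0))

  # all-zero sample is an error naming the sample
  z <- y; z[, 4] <- 0
  expect_error(normalize_counts(omics_matrix(z, "counts")), "s4")
})

test_that("RSD filter uses sample sd over mean and is scale invariant", {
  x <- toy_counts(c(1, 1, 5, 6, 1, 1, 5, 4, 1, 1, 5, 5, 2, 1, 5, 5), 4, 4,
                  layer = "raw_abundance")
  # g1 = (1,1,1,2): mean 1.25, sd 0.5, RSD 0.4 -> retained
  out <- suppressMessages(rsd_filter(x, 0.15))
  expect_true("g1" %in% rownames(out$matrix))
  # g3 constant at 5 -> RSD 0 -> removed
  expect_true("g3" %in% out$report$removed_ids)
  expect_equal(sd(c(1, 1, 1, 2)) / mean(c(1, 1, 1, 2)), 0.4)

  # threshold 0 keeps all non-constant metabolites (g2, g3 are constant)
  out0 <- suppressMessages(rsd_filter(x, 0))
  expect_identical(out0$report$removed_ids, c("g2", "g3"))

  # positive scaling leaves the decision unchanged
  xs <- retag(unclass(x) * 37.5, "raw_abundance")
  outs <- suppressMessages(rsd_filter(xs, 0.15))
  expect_identical(rownames(outs$matrix), rownames(out$matrix))

  xz <- toy_counts(c(-1, 0, 1, 0), 2, 2, layer = "raw_abundance")
  expect_error(rsd_filter(xz), "RSD undefined")
})

test_that("log transform is exact and guarded", {
  x <- toy_counts(c(1, exp(1), 10, 100), 2, 2, layer = "raw_abundance")
  lx <- log_normalize_metabolites(x)
  expect_equal(unclass(lx)[1, 1], 0)
  expect_equal(unclass(lx)[2, 1], 1)
  expect_equal(exp(unclass(lx)), unclass(x), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(layer_tag(lx), "log_abundance")
  bad <- toy_counts(c(1, -2, 3, 4), 2, 2, layer = "raw_abundance")
  expect_error(log_normalize_metabolites(bad), "g2.*s1")
})

test_that("variance filter removes ceil(fraction * n), ties lexical", {
  set.seed(3)
  x <- toy_counts(rnorm(20 * 5), 20, 5, layer = "normalized")
  out <- suppressMessages(variance_filter(x, 0.05))
  expect_equal(out$report$features_out, 19L)      # ceil(1) = 1
  brute <- rownames(x)[which.min(apply(unclass(x), 1, var))]
  expect_identical(out$report$removed_ids, brute)

  # exact ties broken by feature-ID lexical order
  tied <- toy_counts(rep(1:5, times = 4), 5, 4, layer = "normalized",
                     genes = c("zz", "aa", "mm", "bb", "cc"))
  out2 <- suppressMessages(variance_filter(tied, 0.5))  # remove 3 of 5
  expect_identical(sort(out2$report$removed_ids), c("aa", "bb", "cc"))
  expect_error(variance_filter(x, 1), "fraction")
})

test_that("negative-value screen equals an elementwise scan", {
  set.seed(9)
  v <- matrix(rnorm(200, mean = 2), 50, 4,
              dimnames = list(sprintf("f%02d", 1:50), sprintf("s%d", 1:4)))
  x <- omics_matrix(v, "adjusted")
  out <- suppressMessages(nonneg_filter(x))
  brute <- rownames(v)[apply(v, 1, function(r) any(r < 0))]
  expect_identical(out$report$removed_ids, brute)
  # all-nonnegative matrix is untouched
  y <- omics_matrix(abs(v), "adjusted")
  expect_identical(suppressMessages(nonneg_filter(y))$report$removed_ids,
                   character())
  expect_error(nonneg_filter(omics_matrix(abs(v), "counts")),
               "normalized or adjusted")
})

test_that("filters are idempotent", {
  set.seed(21)
  counts <- toy_counts(rnbinom(300 * 6, mu = 3, size = 1), 300, 6)
  f1 <- suppressMessages(filter_low_count_genes(counts))
  f2 <- suppressMessages(filter_low_count_genes(f1$matrix))
  expect_length(f2$report$removed_ids, 0)

  ab <- toy_counts(rexp(100 * 6) + 0.5, 100, 6, layer = "raw_abundance")
  r1 <- suppressMessages(rsd_filter(ab))
  r2 <- suppressMessages(rsd_filter(r1$matrix))
  expect_length(r2$report$removed_ids, 0)

  adj <- omics_matrix(matrix(rnorm(100 * 6, 2), 100, 6,
                             dimnames = list(sprintf("f%d", 1:100),
                                             sprintf("s%d", 1:6))),
                      "adjusted")
  n1 <- suppressMessages(nonneg_filter(adj))
  n2 <- suppressMessages(nonneg_filter(n1$matrix))
  expect_length(n2$report$removed_ids, 0)
})

test_that("sd-based phenotype classification works within strata", {
  # worked example: (0,0,0,10) -> mean 2.5, sd 5 -> only 10 is 'high'
  lab <- classify_by_sd(c(0, 0, 0, 10))
  expect_identical(as.vector(lab), c("excluded", "excluded", "excluded",
                                     "high"))
  expect_identical(attr(lab, "fe_map"), c(low = "high", high = "low"))

  # symmetric values give equal low/high counts
  v <- c(-3, -2, 0, 2, 3)
  lab2 <- classify_by_sd(v)
  expect_equal(sum(lab2 == "low"), sum(lab2 == "high"))

  # k = 0: nothing non-mean is excluded
  lab3 <- classify_by_sd(c(1, 2, 3, 4), k = 0)
  expect_false(any(lab3 == "excluded"))

  # strata are independent
  vals <- c(0, 0, 0, 10, 5, 5, 5, 5)
  strat <- rep(c("a", "b"), each = 4)
  expect_warning(lab4 <- classify_by_sd(vals, strat), "zero variance")
  expect_identical(as.vector(lab4)[5:8], rep("excluded", 4))
  expect_error(classify_by_sd(c(1, 2), rep("a", 2)), "fewer than 3")
})
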