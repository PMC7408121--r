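test_that("fit_pair matches constructions with known answers", {
  set.seed(4)
  n <- 20
  p <- rep(c(0L, 1L), each = n / 2)
  g <- rnorm(n)

  # no interaction, zero noise: beta4 is numerically zero
  m <- 1 + 2 * g + 0.5 * p
  f <- fit_pair(g, m, p)
  expect_lt(abs(f$beta4), 1e-10)
  expect_equal(f$beta1, 1, tolerance = 1e-8)
  expect_equal(f$beta2, 2, tolerance = 1e-8)

  # pure interaction, zero noise: beta4 = 1 and p underflows to the cap
  f2 <- fit_pair(g, g * p, p)
  expect_equal(f2$beta4, 1, tolerance = 1e-8)
  expect_lte(f2$p_interaction, 1e-250)
  expect_gt(f2$p_interaction, 0)

  # constant gene: singular fit is flagged, not fatal
  f3 <- fit_pair(rep(1, n), rnorm(n), p)
  expect_true(f3$singular)
  expect_equal(f3$p_interaction, 1)

  expect_error(fit_pair(g[1:4], m[1:4], p[1:4]), "6 samples")
  expect_error(fit_pair(g, m, rep(c(0L, 1L), c(18, 2))), ">= 3")
})

test_that("fit_pair equals the naive normal-equations oracle", {
  set.seed(12)
  for (i in 1:30) {
    n <- sample(10:40, 1)
    n0 <- sample(3:(n - 3), 1)
    p <- sample(rep(c(0L, 1L), c(n0, n - n0)))
    g <- rnorm(n)
    m <- 0.3 + 0.7 * g - 0.2 * p + 0.9 * g * p + rnorm(n)
    f <- fit_pair(g, m, p)
    o <- naive_pair_fit(g, m, p)
    expect_equal(c(f$beta1, f$beta2, f$beta3, f$beta4), o$beta,
                 tolerance = 1e-10)
    expect_equal(f$se_beta4, o$se4, tolerance = 1e-10)
    expect_equal(f$p_interaction, o$p, tolerance = 1e-10)
  }
})

test_that("per-group Spearman handles signs, ties and degeneracy", {
  p <- rep(c(0L, 1L), each = 5)
  g <- c(1:5, 1:5)
  expect_equal(as.vector(spearman_by_group(g, g, p)), c(1, 1))
  m <- c(-(1:5), 1:5)
  expect_equal(as.vector(spearman_by_group(g, m, p)), c(-1, 1))

  # constant vector in one group -> 0 with a degeneracy flag
  s <- spearman_by_group(c(rep(2, 5), 1:5), m, p)
  expect_equal(as.vector(s)[1], 0)
  expect_true(attr(s, "degenerate")[1])

  # oracle equivalence on random vectors with ties
  set.seed(6)
  for (i in 1:20) {
    g <- sample(1:4, 14, replace = TRUE)    # heavy ties
    m <- rnorm(14)
    p <- rep(c(0L, 1L), each = 7)
    s <- spearman_by_group(g, m, p)
    expect_equal(as.vector(s),
                 c(naive_spearman(g[p == 0], m[p == 0]),
                   naive_spearman(g[p == 1], m[p == 1])),
                 tolerance = 1e-12)
  }

  # invariance under strictly monotone transforms
  set.seed(7)
  g <- rexp(16); m <- rnorm(16); p <- rep(c(0L, 1L), each = 8)
  expect_equal(as.vector(spearman_by_group(g, m, p)),
               as.vector(spearman_by_group(log(g), exp(m), p)),
               tolerance = 1e-12)
})

test_that("signed correlation difference follows the group convention", {
  expect_equal(round(correlation_difference(0.776224, -0.54242), 5),
               -1.31864)
  expect_equal(round(correlation_difference(0.66996, -0.73284), 4), -1.4028)
  expect_equal(correlation_difference(0.3, 0.3), 0)
})

test_that("BH adjustment matches the hand step-up and reference", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # order preserved; reference equivalence on random vectors
  set.seed(8)
  for (i in 1:50) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    p[p == 0] <- 1e-12
    expect_equal(bh_fdr(p), p.adjust(p, "BH"), tolerance = 1e-14)
  }
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("vectorized engine equals per-pair fits on a 50x20 instance", {
  inst <- random_instance(50, 20, n = 20, seed = 10)
  res <- suppressMessages(run_all_pairs(inst$genes, inst$metabolites,
                                        inst$meta, default_coding("breed"),
                                        block_size = 7L))
  expect_equal(attr(res, "model_count"), 1000L)
  G <- unclass(inst$genes); M <- unclass(inst$metabolites)
  idx <- sample(nrow(res), 120)
  for (i in idx) {
    f <- fit_pair(G[res$gene_id[i], ], M[res$metabolite_id[i], ], inst$p)
    expect_equal(res$beta4[i], f$beta4, tolerance = 1e-10)
    expect_equal(res$beta1[i], f$beta1, tolerance = 1e-10)
    expect_equal(res$beta2[i], f$beta2, tolerance = 1e-10)
    expect_equal(res$beta3[i], f$beta3, tolerance = 1e-10)
    expect_equal(res$se_beta4[i], f$se_beta4, tolerance = 1e-10)
    expect_equal(res$p_interaction[i], f$p_interaction, tolerance = 1e-10)
    expect_equal(res$cor_group0[i], f$cor_group0, tolerance = 1e-12)
    expect_equal(res$cor_group1[i], f$cor_group1, tolerance = 1e-12)
  }
})

test_that("blocked results do not depend on the block size", {
  inst <- random_instance(23, 9, n = 16, seed = 13)
  r1 <- suppressMessages(run_all_pairs(inst$genes, inst$metabolites,
                                       inst$meta, default_coding("breed"),
                                       block_size = 1L))
  r2 <- suppressMessages(run_all_pairs(inst$genes, inst$metabolites,
                                       inst$meta, default_coding("breed"),
                                       block_size = 1000L))
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("engine validates alignment and handles singular genes", {
  inst <- random_instance(5, 4, n = 12, seed = 14)
  shuffled <- inst$metabolites[, rev(colnames(inst$metabolites))]
  shuffled <- omics_matrix(shuffled, "adjusted")
  expect_error(suppressMessages(
    run_all_pairs(inst$genes, shuffled, inst$meta,
                  default_coding("breed"))), "differ")

  G <- unclass(inst$genes)
  G["G001", ] <- 3                       # constant gene
  res <- suppressMessages(run_all_pairs(omics_matrix(G, "adjusted"),
                                        inst$metabolites, inst$meta,
                                        default_coding("breed")))
  bad <- res[res$gene_id == "G001", ]
  expect_true(all(bad$singular))
  expect_true(all(bad$p_interaction == 1))
  expect_true(all(is.na(bad$beta4)))
  expect_true(all(bad$cor_group0 == 0))
})

test_that("swapping phenotype levels negates diff_corr, keeps p", {
  inst <- random_instance(10, 6, n = 18, seed = 15)
  cod <- phenotype_coding("breed", "duroc", "landrace")
  swapped <- phenotype_coding("breed", "landrace", "duroc")
  r1 <- suppressMessages(run_all_pairs(inst$genes, inst$metabolites,
                                       inst$meta, cod))
  r2 <- suppressMessages(run_all_pairs(inst$genes, inst$metabolites,
                                       inst$meta, swapped))
  expect_equal(r1$diff_corr, -r2$diff_corr, tolerance = 1e-12)
  expect_equal(r1$p_interaction, r2$p_interaction, tolerance = 1e-10)
})

test_that("significance filter applies all three screens", {
  df <- data.frame(fdr = c(0.05, 0.2, 0.05, 0.05),
                   diff_corr = c(0.5, 0.5, 0.05, -0.5),
                   p_interaction = c(1e-8, 1e-8, 1e-8, 1e-3))
  out <- suppressMessages(filter_significant(df))
  expect_equal(nrow(out), 2L)
  out2 <- suppressMessages(filter_significant(df, raw_p_max = 1e-7))
  expect_equal(nrow(out2), 1L)
  empty <- suppressMessages(filter_significant(df[0, , drop = FALSE]))
  expect_equal(nrow(empty), 0L)
})
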