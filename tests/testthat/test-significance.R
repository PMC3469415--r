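test_that("Gumbel maximum-likelihood fit recovers simulated parameters", {
  set.seed(31)
  x <- ginet:::qgumbel(runif(10000), loc = 2, scale = 0.5)
  par <- ginet:::fit_gumbel(x)
  expect_equal(unname(par["loc"]), 2, tolerance = 0.03)
  expect_equal(unname(par["scale"]), 0.5, tolerance = 0.03)
})

test_that("single-locus thresholds are monotone in alpha and stable across seeds", {
  set.seed(37)
  G <- matrix(rbinom(200 * 5, 1, 0.5), 200, 5)
  Y <- matrix(rnorm(400), 200, 2)
  th1 <- single_locus_threshold(G, Y, n_perm = 1000, alpha = 0.01, seed = 1)
  th2 <- single_locus_threshold(G, Y, n_perm = 1000, alpha = 0.01, seed = 2)
  expect_equal(th1$threshold, th2$threshold, tolerance = 0.05)
  # quantile monotonicity from the same fitted null
  loose <- ginet:::qgumbel(0.5, th1$loc, th1$scale)
  expect_lt(loose, th1$threshold)
  expect_error(single_locus_threshold(G, Y, n_perm = 10), "at least 100")
  # reproducibility under the same seed
  th1b <- single_locus_threshold(G, Y, n_perm = 500, alpha = 0.01, seed = 1)
  th1c <- single_locus_threshold(G, Y, n_perm = 500, alpha = 0.01, seed = 1)
  expect_identical(th1b$maxima, th1c$maxima)
})

test_that("empirical p-values follow the add-one counting rule", {
  null <- seq_len(999) / 1000
  expect_equal(empirical_pvalue(2, null), 1 / 1000)       # above all nulls
  expect_equal(empirical_pvalue(0, null), 1.0)            # below all nulls
  expect_equal(empirical_pvalue(median(null), null), 501 / 1000)
  expect_error(empirical_pvalue(1, rep(NA_real_, 5)), "empty")
  # NA entries (inestimable permutations) are dropped from the count
  expect_equal(empirical_pvalue(2, c(null, NA, NA)), 1 / 1000)
})

test_that("Holm adjustment matches the hand step-down", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(0.05, 0.05, 0.05)), c(0.15, 0.15, 0.15))
  set.seed(41)
  p <- runif(25)
  expect_equal(holm_adjust(p), hand_holm(p))
  expect_true(all(holm_adjust(p) >= p))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("compiled pairwise evaluation matches the reference R implementation", {
  set.seed(43)
  G <- matrix(rbinom(150 * 4, 1, 0.5), 150, 4)
  colnames(G) <- paste0("L", 1:4)
  Y <- cbind(ET1 = rnorm(150) + G[, 1] - G[, 2] + 0.8 * G[, 1] * G[, 2],
             ET2 = rnorm(150) + G[, 1] + G[, 2])
  covs <- list(ET1 = "L3", ET2 = c("L3", "L4"))
  fit <- pairwise_fit(G, Y, c("L1", "L2"), covs)
  ac <- solve_activity_changes(fit)
  ip <- influence_coefficients(ac)
  W <- diag(2)
  cpp <- ginet:::.pair_eval_cpp(G[, 1], G[, 2], Y,
                                list(G[, 3, drop = FALSE], G[, 3:4]), W)
  expect_true(cpp$valid)
  expect_equal(cpp$gamma, unname(ip$gamma), tolerance = 1e-10)
  expect_equal(cpp$gamma_se, unname(ip$se), tolerance = 1e-10)
  dec_id <- ginet:::identity_decomposition(Y)
  vp <- variant_phenotype_effects(fit, dec_id)
  expect_equal(as.vector(t(cpp$vp_coef)), vp$coef, tolerance = 1e-10)
  expect_equal(as.vector(t(cpp$vp_var)), vp$var, tolerance = 1e-10)
})

test_that("tandem permutation nulls are reproducible and EVD-free", {
  set.seed(47)
  G <- matrix(rbinom(100 * 3, 1, 0.5), 100, 3)
  colnames(G) <- paste0("L", 1:3)
  Y <- cbind(ET1 = rnorm(100), ET2 = rnorm(100))
  n1 <- pairwise_null(G, Y, c("L1", "L2"), n_perm = 200, seed = 7)
  n2 <- pairwise_null(G, Y, c("L1", "L2"), n_perm = 200, seed = 7)
  expect_identical(n1$gamma_stat, n2$gamma_stat)
  expect_identical(n1$vp_coef, n2$vp_coef)
  n3 <- pairwise_null(G, Y, c("L1", "L2"), n_perm = 200, seed = 8)
  expect_false(identical(n1$gamma_stat, n3$gamma_stat))
  # pairwise p-values come from the empirical distribution directly:
  # no extreme-value parameters anywhere in the pairwise-null object
  expect_false(any(c("loc", "scale", "threshold") %in% names(n1)))
  expect_s3_class(n1, "empirical_null")
})

test_that("pairwise null p-values are uniform under no association", {
  set.seed(53)
  pvals <- c()
  for (r in 1:60) {
    G <- matrix(rbinom(120 * 2, 1, 0.5), 120, 2)
    colnames(G) <- c("L1", "L2")
    Y <- cbind(ET1 = rnorm(120), ET2 = rnorm(120))
    fit <- pairwise_fit(G, Y, c("L1", "L2"))
    if (!fit$estimable) next
    ac <- solve_activity_changes(fit)
    if (!ac$valid) next
    ip <- influence_coefficients(ac)
    null <- pairwise_null(G, Y, c("L1", "L2"), n_perm = 400, seed = 500 + r)
    for (d in 1:2) {
      if (isTRUE(ip$defined[d]) && is.finite(ip$statistic[d])) {
        pvals <- c(pvals, empirical_pvalue(ip$statistic[d], null$gamma_stat[, d]))
      }
    }
  }
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
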