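test_that("single-locus scan solves simple designs exactly", {
  G <- cbind(L1 = c(0, 0, 1, 1), L2 = c(0, 1, 0, 1))
  Y <- cbind(ET1 = c(0, 0, 1, 1), ET2 = c(1, 1, -1, -1))
  fits <- single_locus_scan(G, Y)
  exact <- fits[fits$locus == "L1" & fits$eigentrait == "ET1", ]
  expect_equal(exact$intercept, 0)
  expect_equal(exact$effect, 1)
  orth <- fits[fits$locus == "L2" & fits$eigentrait == "ET2", ]
  expect_equal(orth$effect, 0)
})

test_that("single-locus estimates match the normal-equations oracle", {
  set.seed(61)
  n <- 200
  G <- matrix(rbinom(n * 3, 1, 0.5), n, 3)
  Y <- matrix(rnorm(n * 2) + G[, 1], n, 2)
  fits <- single_locus_scan(G, Y)
  for (l in 1:3) for (j in 1:2) {
    o <- ne_ols(cbind(1, G[, l]), Y[, j])
    row <- fits[fits$locus == paste0("L", l) & fits$eigentrait == paste0("ET", j), ]
    expect_equal(row$effect, o$beta[2], tolerance = 1e-10)
    expect_equal(row$se, sqrt(o$cov[2, 2]), tolerance = 1e-10)
    expect_equal(row$statistic, abs(o$beta[2]) / sqrt(o$cov[2, 2]),
                 tolerance = 1e-10)
  }
})

test_that("constant loci are skipped with a warning", {
  G <- cbind(L1 = c(1, 1, 1, 1), L2 = c(0, 1, 0, 1))
  Y <- cbind(ET1 = rnorm(4))
  expect_warning(fits <- single_locus_scan(G, Y), "constant")
  expect_equal(unique(fits$locus), "L2")
})

test_that("covariate selection applies the statistic threshold per eigentrait", {
  fits <- data.frame(locus = c("a", "b", "c"), eigentrait = "ET1",
                     statistic = c(4.0, 1.0, 3.6))
  expect_equal(select_covariates(fits, 3.55)$ET1, c("a", "c"))
  fits$statistic <- c(1, 2, 3)
  expect_equal(length(select_covariates(fits, 3.55)$ET1), 0L)
  # boundary: statistic exactly at threshold qualifies ("at least")
  fits$statistic <- c(3.55, 0, 0)
  expect_equal(select_covariates(fits, 3.55)$ET1, "a")
})

test_that("pairwise fit solves exact interaction and additive designs", {
  # balanced 2x2 design, two samples per cell
  x1 <- rep(c(0, 0, 1, 1), each = 2)
  x2 <- rep(c(0, 1, 0, 1), 4)[1:8]
  G <- cbind(L1 = x1, L2 = x2)
  fit <- pairwise_fit(G, cbind(ET1 = x1 * x2, ET2 = x1 + x2), c("L1", "L2"))
  expect_true(fit$estimable)
  expect_equal(unname(fit$beta12["ET1"]), 1, tolerance = 1e-10)
  expect_equal(unname(fit$beta1["ET1"]), 0, tolerance = 1e-10)
  expect_equal(unname(fit$beta2["ET1"]), 0, tolerance = 1e-10)
  expect_equal(unname(fit$beta12["ET2"]), 0, tolerance = 1e-10)
})

test_that("pairwise fit with a covariate matches brute-force least squares", {
  set.seed(71)
  n <- 8
  G <- cbind(L1 = c(0, 1, 0, 1, 0, 1, 0, 1),
             L2 = c(0, 0, 1, 1, 0, 0, 1, 1),
             L3 = c(0, 0, 0, 0, 1, 1, 1, 1))
  Y <- cbind(ET1 = rnorm(n), ET2 = rnorm(n))
  covs <- list(ET1 = "L3", ET2 = "L3")
  fit <- pairwise_fit(G, Y, c("L1", "L2"), covs)
  for (j in 1:2) {
    X <- cbind(1, G[, 1], G[, 2], G[, 1] * G[, 2], G[, 3])
    o <- ne_ols(X, Y[, j])
    expect_equal(unname(c(fit$beta1[j], fit$beta2[j], fit$beta12[j])),
                 o$beta[2:4], tolerance = 1e-10)
    # diagonal covariance block matches the per-equation OLS covariance
    idx <- 3 * (j - 1) + 1:3
    expect_equal(unname(diag(fit$theta_cov)[idx]), diag(o$cov)[2:4],
                 tolerance = 1e-10)
  }
})

test_that("interaction coefficient is invariant to covariate ordering", {
  set.seed(81)
  G <- matrix(rbinom(400, 1, 0.5), 100, 4)
  colnames(G) <- paste0("L", 1:4)
  Y <- cbind(ET1 = rnorm(100) + G[, 1] * G[, 2], ET2 = rnorm(100))
  f1 <- pairwise_fit(G, Y, c("L1", "L2"), list(ET1 = c("L3", "L4"), ET2 = c("L3", "L4")))
  f2 <- pairwise_fit(G, Y, c("L1", "L2"), list(ET1 = c("L4", "L3"), ET2 = c("L4", "L3")))
  expect_equal(f1$beta12, f2$beta12, tolerance = 1e-12)
})

test_that("degenerate designs are flagged, not fit", {
  x <- rbinom(40, 1, 0.5)
  G <- cbind(L1 = x, L2 = x)  # identical columns
  Y <- cbind(ET1 = rnorm(40), ET2 = rnorm(40))
  fit <- pairwise_fit(G, Y, c("L1", "L2"))
  expect_false(fit$estimable)
  expect_match(fit$reason, "identical")

  # no double-variant samples: x1*x2 == 0 always -> rank deficient
  G2 <- cbind(L1 = rep(c(1, 0), 20), L2 = rep(c(0, 1), 20))
  fit2 <- pairwise_fit(G2, Y, c("L1", "L2"))
  expect_false(fit2$estimable)
})

test_that("samples missing a genotype are excluded listwise for that fit only", {
  set.seed(91)
  G <- matrix(rbinom(300, 1, 0.5), 100, 3)
  colnames(G) <- paste0("L", 1:3)
  G[1:5, 1] <- NA
  Y <- cbind(ET1 = rnorm(100), ET2 = rnorm(100))
  fit12 <- pairwise_fit(G, Y, c("L1", "L2"))
  expect_equal(fit12$n_used, 95L)
  fit23 <- pairwise_fit(G, Y, c("L2", "L3"))
  expect_equal(fit23$n_used, 100L)
  # oracle on complete cases
  keep <- !is.na(G[, 1])
  o <- ne_ols(cbind(1, G[keep, 1], G[keep, 2], G[keep, 1] * G[keep, 2]), Y[keep, 1])
  expect_equal(unname(fit12$beta12["ET1"]), o$beta[4], tolerance = 1e-10)
})

test_that("null single-locus statistics follow the t distribution", {
  set.seed(101)
  n <- 50
  stats <- replicate(1000, {
    x <- rbinom(n, 1, 0.5)
    while (var(x) == 0) x <- rbinom(n, 1, 0.5)
    y <- rnorm(n)
    f <- single_locus_scan(cbind(L1 = x), cbind(ET1 = y))
    sign(f$effect) * f$statistic
  })
  ks <- ks.test(stats, function(q) pt(q, df = n - 2))
  expect_gt(ks$p.value, 0.01)
})
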