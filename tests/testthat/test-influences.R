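test_that("activity changes solve the 2-eigentrait system exactly", {
  # hand solve: B = [[1,1],[1,-1]], c = (0.5, 0.5) -> delta = (0.5, 0)
  fit <- fake_fit(beta1 = c(1, 1), beta2 = c(1, -1), beta12 = c(0.5, 0.5))
  ac <- solve_activity_changes(fit)
  expect_true(ac$valid)
  expect_equal(ac$delta, c(0.5, 0), tolerance = 1e-12)
  expect_equal(ac$solve_mode, "exact")

  # homogeneous system with nonsingular B
  ac0 <- solve_activity_changes(fake_fit(c(1, 1), c(1, -1), c(0, 0)))
  expect_equal(ac0$delta, c(0, 0), tolerance = 1e-14)

  # near-singular main-effect matrix flagged invalid, no large values returned
  bad <- solve_activity_changes(fake_fit(c(1, 1), c(1 + 1e-12, 1 + 1e-12), c(0.3, 0.3)))
  expect_false(bad$valid)
  expect_true(all(is.na(bad$delta)))
})

test_that("least-squares mode recovers planted activity changes for k > 2", {
  set.seed(13)
  for (rep in 1:20) {
    B <- matrix(rnorm(6), 3, 2)
    d_true <- runif(2, -0.6, 0.6)
    fit <- fake_fit(B[, 1], B[, 2], as.vector(B %*% d_true),
                    theta_cov = diag(9) * 1e-6)
    ac <- solve_activity_changes(fit)
    expect_equal(ac$solve_mode, "least-squares")
    expect_equal(ac$delta, d_true, tolerance = 1e-10)
    expect_lt(ac$residual_norm, 1e-10)
  }
})

test_that("influence coefficients follow the closed-form activity algebra", {
  fit <- fake_fit(c(1, 1), c(1, -1), c(0.5, 0.5))  # delta = (0.5, 0)
  ip <- influence_coefficients(solve_activity_changes(fit))
  expect_equal(unname(ip$gamma), c(0.5, 0), tolerance = 1e-12)
  expect_equal(names(ip$gamma), c("A<-B", "B<-A"))

  # no interaction, no influence
  ip0 <- influence_coefficients(solve_activity_changes(fake_fit(c(1, 1), c(1, -1), c(0, 0))))
  expect_equal(unname(ip0$gamma), c(0, 0))

  # degenerate denominator: delta_2 = -1 makes gamma_{1<-2} undefined
  ac <- solve_activity_changes(fake_fit(c(1, 1), c(1, -1), c(-1, 1)))
  expect_equal(ac$delta, c(0, -1), tolerance = 1e-12)
  ipd <- influence_coefficients(ac)
  expect_false(ipd$defined[1])
  expect_true(is.na(ipd$gamma[1]))
  expect_true(ipd$defined[2])
})

test_that("forward map and gamma/delta relations round-trip on random instances", {
  set.seed(17)
  for (rep in 1:100) {
    B <- matrix(runif(4, 0.3, 1.5) * sample(c(-1, 1), 4, TRUE), 2, 2)
    if (abs(det(B)) < 0.1) next
    b12 <- rnorm(2, sd = 0.5)
    fit <- fake_fit(B[, 1], B[, 2], b12)
    ac <- solve_activity_changes(fit)
    # Eq. 4 forward map reproduces the interaction coefficients
    expect_equal(as.vector(B %*% ac$delta), b12, tolerance = 1e-10)
    ip <- influence_coefficients(ac)
    if (!all(ip$defined)) next
    # substituting gamma back into the coupled relations reproduces delta
    g <- unname(ip$gamma); d <- ac$delta
    expect_equal(g[1] * (1 + d[2]), d[1], tolerance = 1e-10)
    expect_equal(g[2] * (1 + d[1]), d[2], tolerance = 1e-10)
  }
})

test_that("delta-method variance is exact for linear maps", {
  set.seed(19)
  A <- matrix(rnorm(36), 6, 6)
  Sigma <- crossprod(A) / 10
  fit <- fake_fit(c(1, 0.5), c(0.8, -1), c(0.2, 0.1), theta_cov = Sigma)
  a <- rnorm(6)
  v <- propagate_variance(fit, function(th) sum(a * th))
  expect_equal(v, as.numeric(t(a) %*% Sigma %*% a), tolerance = 1e-6)
  # scalar multiple: var(c * theta_1) = c^2 var(theta_1)
  v2 <- propagate_variance(fit, function(th) 3 * th[1])
  expect_equal(v2, 9 * Sigma[1, 1], tolerance = 1e-6)
})

test_that("delta-method gamma variances agree with a Monte-Carlo oracle", {
  set.seed(23)
  n_ok <- 0
  for (rep in 1:20) {
    # well-conditioned random fit with small coefficient noise
    B <- matrix(runif(4, 0.6, 1.4) * c(1, 1, 1, -1), 2, 2)
    b12 <- runif(2, -0.4, 0.4)
    A <- matrix(rnorm(36), 6, 6)
    Sigma <- crossprod(A); Sigma <- Sigma / max(diag(Sigma)) * 2e-3
    fit <- fake_fit(B[, 1], B[, 2], b12, theta_cov = Sigma)
    ip <- influence_coefficients(solve_activity_changes(fit))
    theta <- as.vector(rbind(fit$beta1, fit$beta2, fit$beta12))
    mc <- mc_gamma(theta, Sigma, 50000, seed = 1000 + rep)
    mc_se <- apply(mc, 2, sd)
    expect_equal(unname(ip$se), unname(mc_se), tolerance = 0.05)
    n_ok <- n_ok + 1
  }
  expect_equal(n_ok, 20)
})

test_that("suppression yields a negative influence on the suppressed variant", {
  fx <- suppression_fixture(n = 400, gamma_ab = -0.8, seed = 29)
  P <- standardize_phenotypes(fx$phenotypes)
  dec <- eigentrait_decompose(P)
  ip <- pair_influences(fx$genotypes, dec$U, c("L1", "L2"))
  expect_true(ip$valid)
  expect_lt(ip$gamma[["L1<-L2"]], 0)
  expect_gt(abs(ip$gamma[["L1<-L2"]]) / ip$se[1], 3)
  expect_lt(abs(ip$gamma[["L2<-L1"]]), 0.2)
})
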