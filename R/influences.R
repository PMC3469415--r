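#' Solve for activity changes from a pairwise fit
#'
#' The interaction coefficients of a pair are reparametrized in terms of two
#' activity changes `delta_1`, `delta_2`: the inferred change in activity of
#' one perturbed gene when the other perturbation is present, posited to be
#' shared across phenotypes. Per eigentrait `j` the governing relation is
#'
#'   `beta_12j = delta_1 * beta_1j + delta_2 * beta_2j`
#'
#' (the interaction weighted by each variant's main effect on that
#' phenotype). With 2 eigentraits this is solved exactly by inversion of the
#' main-effect matrix `B`; with more it is solved by least squares via the
#' pseudoinverse, and the residual norm is reported as a goodness-of-fit
#' diagnostic for the shared-delta assumption. Because inversions can
#' produce large, unstable values, a condition-number guard flags the pair
#' invalid rather than returning silently large estimates.
#'
#' The covariance of `(delta_1, delta_2)` is propagated analytically from
#' the regression coefficient covariance through the linear solve.
#'
#' @param fit an estimable [pairwise_fit()].
#' @param cond_bound maximum allowed condition number of `B`.
#' @return an `activity_change`: list with `delta` (length 2), `delta_cov`,
#'   `grad` (2 x 3k Jacobian wrt the fit coefficients), `solve_mode`
#'   (`"exact"` or `"least-squares"`), `residual_norm`, `valid`, `reason`.
#' @export
solve_activity_changes <- function(fit, cond_bound = 1e8) {
  stopifnot(inherits(fit, "pairwise_fit"), isTRUE(fit$estimable))
  B <- cbind(fit$beta1, fit$beta2)           # k x 2, rows = eigentraits
  cvec <- fit$beta12
  k <- nrow(B)
  sv <- svd(B, nu = 0, nv = 0)$d
  invalid <- function(reason) {
    structure(list(pair = fit$pair, delta = c(NA_real_, NA_real_),
                   valid = FALSE, reason = reason),
              class = "activity_change")
  }
  if (sv[2L] <= 0 || sv[1L] / sv[2L] > cond_bound) {
    return(invalid("near-singular main-effect matrix"))
  }
  M <- crossprod(B)
  Minv <- solve(M)
  delta <- as.vector(Minv %*% crossprod(B, cvec))
  r <- cvec - as.vector(B %*% delta)

  # Jacobian of delta wrt theta = (beta_1j, beta_2j, beta_12j) per eigentrait:
  #   d delta / d beta_mj  = Minv (e_m r_j - delta_m B[j,])   (m = 1, 2)
  #   d delta / d beta_12j = Minv B[j,]
  grad <- matrix(0, 2L, 3L * k)
  for (j in seq_len(k)) {
    Bj <- B[j, ]
    for (m in 1:2) {
      em <- c(0, 0); em[m] <- 1
      grad[, 3L * (j - 1L) + m] <- Minv %*% (em * r[j] - delta[m] * Bj)
    }
    grad[, 3L * (j - 1L) + 3L] <- Minv %*% Bj
  }
  delta_cov <- grad %*% fit$theta_cov %*% t(grad)

  structure(list(pair = fit$pair, delta = delta, delta_cov = delta_cov,
                 grad = grad, theta_cov = fit$theta_cov,
                 solve_mode = if (k == 2L) "exact" else "least-squares",
                 residual_norm = sqrt(sum(r^2)),
                 valid = TRUE, reason = NULL),
            class = "activity_change")
}

#' Directed influence coefficients from activity changes
#'
#' Each activity change is rewritten as an influence coefficient times the
#' partner variant's activity (baseline activity of a lone variant is 1):
#'
#'   `delta_1 = gamma_12 * (1 + delta_2)`,  `delta_2 = gamma_21 * (1 + delta_1)`
#'
#' giving `gamma_12 = delta_1 / (1 + delta_2)` (the influence of variant 2
#' on variant 1) and `gamma_21 = delta_2 / (1 + delta_1)`. Negative
#' influences correspond to suppression, positive to enhancement. Standard
#' errors come from the delta method chained through the activity-change
#' solve; a direction whose denominator `|1 + delta|` falls below `tol` is
#' flagged undefined.
#'
#' @param ac an [solve_activity_changes()] result.
#' @param tol denominator tolerance.
#' @return an `influence_pair`: list with `pair`, `gamma` (named: the first
#'   element is the influence of variant 2 on variant 1), `se`, `statistic`
#'   (`|gamma|/se`), `defined` (logical per direction), `valid`, `reason`.
#' @export
influence_coefficients <- function(ac, tol = 1e-8) {
  stopifnot(inherits(ac, "activity_change"))
  nm <- c(paste0(ac$pair[1L], "<-", ac$pair[2L]),
          paste0(ac$pair[2L], "<-", ac$pair[1L]))
  if (!isTRUE(ac$valid)) {
    return(structure(list(pair = ac$pair,
                          gamma = stats::setNames(c(NA_real_, NA_real_), nm),
                          se = c(NA_real_, NA_real_),
                          statistic = c(NA_real_, NA_real_),
                          defined = c(FALSE, FALSE),
                          valid = FALSE, reason = ac$reason),
                     class = "influence_pair"))
  }
  d <- ac$delta
  den <- c(1 + d[2L], 1 + d[1L])
  defined <- abs(den) >= tol
  gamma <- c(if (defined[1L]) d[1L] / den[1L] else NA_real_,
             if (defined[2L]) d[2L] / den[2L] else NA_real_)
  # Jacobian of gamma wrt delta
  J <- matrix(0, 2L, 2L)
  if (defined[1L]) J[1L, ] <- c(1 / den[1L], -d[1L] / den[1L]^2)
  if (defined[2L]) J[2L, ] <- c(-d[2L] / den[2L]^2, 1 / den[2L])
  Gg <- J %*% ac$grad
  gcov <- Gg %*% ac$theta_cov %*% t(Gg)
  v <- pmax(diag(gcov), 0)
  se <- sqrt(v)
  se[!defined] <- NA_real_
  structure(list(pair = ac$pair,
                 gamma = stats::setNames(gamma, nm),
                 se = se,
                 statistic = ifelse(defined & se > 0, abs(gamma) / se, NA_real_),
                 defined = defined,
                 valid = TRUE, reason = NULL),
            class = "influence_pair")
}

#' @export
print.influence_pair <- function(x, ...) {
  if (!isTRUE(x$valid)) {
    cat(sprintf("influence_pair %s -- %s: invalid (%s)\n",
                x$pair[1L], x$pair[2L], x$reason))
    return(invisible(x))
  }
  for (i in 1:2) {
    cat(sprintf("%s: gamma = %+.4f (SE %.4f, |stat| %.2f)%s\n",
                names(x$gamma)[i], x$gamma[i], x$se[i], x$statistic[i],
                if (x$defined[i]) "" else " [undefined]"))
  }
  invisible(x)
}

#' Delta-method variance of a function of pairwise-fit coefficients
#'
#' Propagates the full coefficient covariance of a pairwise fit through an
#' arbitrary scalar function of the coefficient vector
#' `theta = (beta_1j, beta_2j, beta_12j)` over eigentraits `j` (the order of
#' `fit$theta_cov`): `Var(f) = g' Sigma g + cross terms`, with the gradient
#' `g` supplied analytically or computed by central finite differences with
#' a relative step of 1e-6. For linear functions the result is exact.
#'
#' @param fit an estimable [pairwise_fit()].
#' @param f function taking the coefficient vector and returning a scalar.
#' @param grad optional analytic gradient function (same signature).
#' @return variance estimate (non-negative; numerically negative values are
#'   clamped to 0 with a warning).
#' @export
propagate_variance <- function(fit, f, grad = NULL) {
  stopifnot(inherits(fit, "pairwise_fit"), isTRUE(fit$estimable))
  k <- length(fit$beta1)
  theta <- as.vector(rbind(fit$beta1, fit$beta2, fit$beta12))
  g <- if (!is.null(grad)) grad(theta) else numeric_gradient(f, theta)
  v <- as.numeric(t(g) %*% fit$theta_cov %*% g)
  if (v < 0) {
    warning("negative variance estimate clamped to 0")
    v <- 0
  }
  v
}

numeric_gradient <- function(f, theta, rel_step = 1e-6) {
  g <- numeric(length(theta))
  for (i in seq_along(theta)) {
    h <- rel_step * max(abs(theta[i]), 1)
    up <- theta; up[i] <- up[i] + h
    dn <- theta; dn[i] <- dn[i] - h
    g[i] <- (f(up) - f(dn)) / (2 * h)
  }
  g
}

#' Influences for a pair in one call
#'
#' Convenience wrapper: [pairwise_fit()] then [solve_activity_changes()]
#' then [influence_coefficients()].
#'
#' @inheritParams pairwise_fit
#' @inheritParams solve_activity_changes
#' @inheritParams influence_coefficients
#' @return an `influence_pair` (carrying the `fit` and `activity` as
#'   attributes `"fit"` and `"activity"`).
#' @export
pair_influences <- function(G, Y, pair, covariates = NULL,
                            cond_bound = 1e8, tol = 1e-8) {
  fit <- pairwise_fit(G, Y, pair, covariates)
  if (!isTRUE(fit$estimable)) {
    ip <- structure(list(pair = fit$pair, gamma = c(NA_real_, NA_real_),
                         se = c(NA_real_, NA_real_),
                         statistic = c(NA_real_, NA_real_),
                         defined = c(FALSE, FALSE),
                         valid = FALSE, reason = fit$reason),
                    class = "influence_pair")
    attr(ip, "fit") <- fit
    return(ip)
  }
  ac <- solve_activity_changes(fit, cond_bound = cond_bound)
  ip <- influence_coefficients(ac, tol = tol)
  attr(ip, "fit") <- fit
  attr(ip, "activity") <- ac
  ip
}
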