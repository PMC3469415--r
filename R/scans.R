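#' Single-locus regression scan
#'
#' Fits, for every locus and every eigentrait, the one-locus model
#' `y = mu + beta * x + e` by ordinary least squares, where `x` is the
#' variant-allele probability at the locus. The test statistic is
#' `|beta| / SE(beta)`; strong-effect variants identified from it are used
#' as covariates in the pairwise scans.
#'
#' @param G a [genotype_matrix()] or numeric genotype matrix (samples x loci).
#' @param Y numeric response matrix (samples x eigentraits), e.g. `dec$U`.
#' @return data frame with one row per locus x eigentrait: `locus`,
#'   `eigentrait`, `intercept`, `effect`, `se`, `statistic`, `n_used`.
#' @export
single_locus_scan <- function(G, Y) {
  Gv <- if (inherits(G, "genotype_matrix")) G$values else as.matrix(G)
  Y <- as.matrix(Y)
  if (nrow(Gv) != nrow(Y)) stop("genotypes and responses have different sample counts")
  loci <- colnames(Gv); if (is.null(loci)) loci <- paste0("L", seq_len(ncol(Gv)))
  ets <- colnames(Y); if (is.null(ets)) ets <- paste0("ET", seq_len(ncol(Y)))
  rows <- vector("list", ncol(Gv) * ncol(Y))
  idx <- 0L
  for (l in seq_len(ncol(Gv))) {
    x <- Gv[, l]
    use <- !is.na(x)
    xs <- x[use]
    if (stats::var(xs) == 0) {
      warning(sprintf("locus '%s' is constant among used samples; fit skipped", loci[l]))
      next
    }
    for (j in seq_len(ncol(Y))) {
      fit <- simple_ols(xs, Y[use, j])
      idx <- idx + 1L
      rows[[idx]] <- data.frame(locus = loci[l], eigentrait = ets[j],
                                intercept = fit$mu, effect = fit$beta,
                                se = fit$se,
                                statistic = if (fit$se > 0) abs(fit$beta) / fit$se else Inf,
                                n_used = length(xs),
                                stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows[seq_len(idx)])
}

# OLS for y = mu + beta*x; closed form with n-2 residual df.
simple_ols <- function(x, y) {
  n <- length(x)
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2)
  beta <- sum(xc * yc) / sxx
  mu <- mean(y) - beta * mean(x)
  rss <- sum((yc - beta * xc)^2)
  sigma2 <- rss / (n - 2L)
  list(mu = mu, beta = beta, se = sqrt(sigma2 / sxx), sigma2 = sigma2)
}

#' Select strong-effect variants as covariates
#'
#' For each eigentrait, loci whose single-locus test statistic is at least
#' `threshold` standard errors from zero qualify as strong-effect variants
#' and are conditioned on in subsequent pairwise scans. The default 3.55
#' corresponds to p < 0.01 under a 10,000-permutation extreme-value
#' calibration at the original study's scale; [single_locus_threshold()]
#' recalibrates it for other designs.
#'
#' @param fits data frame from [single_locus_scan()].
#' @param threshold minimum `|effect|/SE` statistic.
#' @return named list (one element per eigentrait) of locus-id vectors.
#' @export
select_covariates <- function(fits, threshold = 3.55) {
  ets <- unique(fits$eigentrait)
  out <- lapply(ets, function(et) {
    sub <- fits[fits$eigentrait == et & fits$statistic >= threshold, ]
    sub$locus
  })
  names(out) <- ets
  out
}

#' Pairwise interaction regression on eigentraits
#'
#' For a pair of loci fits, per eigentrait `j`, the model
#' `y_j = mu_j + beta_1j x1 + beta_2j x2 + beta_12j x1 x2 + covariates + e`
#' by ordinary least squares, where the covariates are that eigentrait's
#' strong-effect variants excluding the pair itself. Statistical epistasis
#' is a significant interaction coefficient `beta_12j`.
#'
#' Because covariate sets differ between eigentraits, the full coefficient
#' covariance across eigentraits is assembled with the
#' seemingly-unrelated-regressions cross blocks
#' `Cov(theta_j, theta_l) = sigma_jl (Xj'Xj)^-1 Xj'Xl (Xl'Xl)^-1`,
#' with the residual covariance `sigma_jl = e_j'e_l / sqrt((n-p_j)(n-p_l))`
#' so the diagonal matches the per-equation OLS estimate. Samples missing a
#' genotype at the pair or any covariate locus are excluded listwise from
#' this fit only.
#'
#' @param G a [genotype_matrix()] or numeric genotype matrix.
#' @param Y numeric response matrix (samples x eigentraits).
#' @param pair length-2 vector of locus ids or column indices.
#' @param covariates named list of locus-id vectors per eigentrait (from
#'   [select_covariates()]), or `NULL` for none.
#' @return a `pairwise_fit` object; see Details. `estimable = FALSE` with a
#'   `reason` when the design is rank deficient (e.g. no double-variant
#'   samples or identical genotype columns).
#' @details Fields: `pair`; `coefficients` (list per eigentrait of named
#'   vectors); `beta1`, `beta2`, `beta12` (length-k vectors of the pair main
#'   and interaction effects); `theta_cov` (3k x 3k covariance of those, in
#'   the order beta1, beta2, beta12 within each eigentrait); `sigma_res`
#'   (k x k residual covariance); `n_used`; `df` per eigentrait.
#' @export
pairwise_fit <- function(G, Y, pair, covariates = NULL) {
  Gv <- if (inherits(G, "genotype_matrix")) G$values else as.matrix(G)
  Y <- as.matrix(Y)
  loci <- colnames(Gv); if (is.null(loci)) loci <- paste0("L", seq_len(ncol(Gv)))
  colnames(Gv) <- loci
  pair_ids <- if (is.numeric(pair)) loci[pair] else as.character(pair)
  if (!all(pair_ids %in% loci)) stop("pair loci not found in genotype matrix")
  k <- ncol(Y)
  ets <- colnames(Y); if (is.null(ets)) ets <- paste0("ET", seq_len(k))
  if (is.null(covariates)) covariates <- stats::setNames(rep(list(character()), k), ets)
  cov_sets <- lapply(seq_len(k), function(j) {
    cv <- covariates[[ets[j]]]
    if (is.null(cv)) cv <- character()
    setdiff(cv, pair_ids)
  })

  all_loci_used <- unique(c(pair_ids, unlist(cov_sets)))
  use <- stats::complete.cases(Gv[, all_loci_used, drop = FALSE])
  n <- sum(use)
  x1 <- Gv[use, pair_ids[1L]]; x2 <- Gv[use, pair_ids[2L]]
  Yu <- Y[use, , drop = FALSE]

  invalid <- function(reason) {
    structure(list(pair = pair_ids, estimable = FALSE, reason = reason,
                   n_used = n), class = "pairwise_fit")
  }
  if (stats::var(x1) == 0 || stats::var(x2) == 0) {
    return(invalid("constant locus among used samples"))
  }
  if (isTRUE(all.equal(x1, x2, tolerance = 0, check.attributes = FALSE))) {
    return(invalid("identical genotype columns"))
  }

  X <- vector("list", k); XtXinv <- vector("list", k)
  coefs <- vector("list", k); resid <- matrix(NA_real_, n, k)
  df <- integer(k)
  for (j in seq_len(k)) {
    Zc <- Gv[use, cov_sets[[j]], drop = FALSE]
    Xj <- cbind(`(Intercept)` = 1, x1 = x1, x2 = x2, `x1:x2` = x1 * x2, Zc)
    colnames(Xj)[2:3] <- pair_ids
    colnames(Xj)[4L] <- paste(pair_ids, collapse = ":")
    qrX <- qr(Xj)
    if (qrX$rank < ncol(Xj)) return(invalid("inestimable interaction: rank-deficient design"))
    b <- qr.coef(qrX, Yu[, j])
    coefs[[j]] <- b
    resid[, j] <- Yu[, j] - Xj %*% b
    X[[j]] <- Xj
    XtXinv[[j]] <- solve(crossprod(Xj))
    df[j] <- n - ncol(Xj)
    if (df[j] <= 0L) return(invalid("no residual degrees of freedom"))
  }
  sigma_res <- crossprod(resid) / sqrt(tcrossprod(as.numeric(n) - sapply(X, ncol)))
  dimnames(sigma_res) <- list(ets, ets)

  # covariance of (beta1, beta2, beta12) per eigentrait, across eigentraits
  sel <- 2:4
  theta_cov <- matrix(0, 3L * k, 3L * k)
  for (j in seq_len(k)) for (l in seq_len(k)) {
    block <- if (j == l) XtXinv[[j]] else XtXinv[[j]] %*% crossprod(X[[j]], X[[l]]) %*% XtXinv[[l]]
    theta_cov[(3L * (j - 1L) + 1L):(3L * j), (3L * (l - 1L) + 1L):(3L * l)] <-
      sigma_res[j, l] * block[sel, sel]
  }
  nm <- as.vector(vapply(ets, function(et)
    paste0(c("beta1.", "beta2.", "beta12."), et), character(3L)))
  dimnames(theta_cov) <- list(nm, nm)

  structure(list(pair = pair_ids, estimable = TRUE, reason = NULL,
                 eigentrait_ids = ets,
                 coefficients = stats::setNames(coefs, ets),
                 beta1 = stats::setNames(vapply(coefs, `[[`, 0, pair_ids[1L]), ets),
                 beta2 = stats::setNames(vapply(coefs, `[[`, 0, pair_ids[2L]), ets),
                 beta12 = stats::setNames(
                   vapply(coefs, `[[`, 0, paste(pair_ids, collapse = ":")), ets),
                 theta_cov = theta_cov,
                 sigma_res = sigma_res,
                 covariate_sets = stats::setNames(cov_sets, ets),
                 n_used = n, df = df),
            class = "pairwise_fit")
}

#' @export
print.pairwise_fit <- function(x, ...) {
  if (!isTRUE(x$estimable)) {
    cat(sprintf("pairwise_fit %s -- %s: not estimable (%s)\n",
                x$pair[1L], x$pair[2L], x$reason))
    return(invisible(x))
  }
  cat(sprintf("pairwise_fit %s -- %s (n = %d)\n", x$pair[1L], x$pair[2L], x$n_used))
  print(rbind(beta1 = x$beta1, beta2 = x$beta2, beta12 = x$beta12))
  invisible(x)
}

#' Extract recomposed variant-to-phenotype coefficients from a pairwise fit
#'
#' The pair's main-effect coefficients across eigentraits are multiplied by
#' `diag(S) Vt` to express them on the original phenotypes, with exact
#' (linear-map) delta-method variances from the coefficient covariance.
#'
#' @param fit an estimable `pairwise_fit`.
#' @param dec an `eigentrait_decomposition` (supplies `S` and `Vt`).
#' @return data frame: `variant`, `phenotype`, `coef`, `var`.
#' @export
variant_phenotype_effects <- function(fit, dec) {
  stopifnot(isTRUE(fit$estimable))
  k <- length(fit$beta1)
  W <- dec$S * dec$Vt  # k x T; column t holds weights S_j Vt[j, t]
  out <- list()
  for (v in 1:2) {
    a <- if (v == 1L) fit$beta1 else fit$beta2
    idx <- 3L * (seq_len(k) - 1L) + v   # positions of beta_v across eigentraits
    Sv <- fit$theta_cov[idx, idx, drop = FALSE]
    coef_t <- as.vector(a %*% W)
    var_t <- vapply(seq_len(ncol(W)), function(t) {
      w <- W[, t]
      as.numeric(t(w) %*% Sv %*% w)
    }, 0)
    out[[v]] <- data.frame(variant = fit$pair[v], phenotype = dec$phenotype_ids,
                           coef = coef_t, var = var_t, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
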