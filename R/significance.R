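# Gumbel (extreme value) distribution helpers and maximum-likelihood fit.
qgumbel <- function(p, loc, scale) loc - scale * log(-log(p))
pgumbel <- function(q, loc, scale) exp(-exp(-(q - loc) / scale))

fit_gumbel <- function(x) {
  stopifnot(length(x) >= 10L)
  nll <- function(par) {
    scale <- exp(par[2L])
    z <- (x - par[1L]) / scale
    sum(log(scale) + z + exp(-z))
  }
  # moment start: scale = sd*sqrt(6)/pi, loc = mean - Euler-gamma * scale
  s0 <- stats::sd(x) * sqrt(6) / pi
  start <- c(mean(x) - 0.5772156649 * s0, log(s0))
  opt <- stats::optim(start, nll, method = "BFGS")
  c(loc = opt$par[1L], scale = exp(opt$par[2L]))
}

#' Permutation-calibrated single-locus significance threshold
#'
#' Permutes the genotype rows jointly (responses fixed), takes the maximum
#' single-locus test statistic `|effect|/SE` over all loci and eigentraits
#' per permutation, fits a Gumbel extreme value distribution to the maxima
#' by maximum likelihood, and returns its `1 - alpha` quantile. Taking the
#' maximum over loci and eigentraits jointly accounts for the multiplicity
#' of tests.
#'
#' @param G a [genotype_matrix()] or numeric genotype matrix.
#' @param Y numeric response matrix (samples x eigentraits).
#' @param n_perm number of permutations (>= 100).
#' @param alpha target familywise error rate.
#' @param seed RNG seed.
#' @return a `permutation_threshold`: list with `threshold`, `loc`, `scale`,
#'   `n_perm`, `alpha`, `seed`, and the vector of permutation `maxima`.
#' @export
single_locus_threshold <- function(G, Y, n_perm = 10000L, alpha = 0.01,
                                   seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be at least 100")
  Gv <- if (inherits(G, "genotype_matrix")) G$values else as.matrix(G)
  Y <- as.matrix(Y)
  n <- nrow(Gv)
  if (anyNA(Gv)) {
    keep <- stats::complete.cases(Gv)
    Gv <- Gv[keep, , drop = FALSE]; Y <- Y[keep, , drop = FALSE]; n <- nrow(Gv)
  }
  rng <- local_rng(seed)
  maxima <- vapply(seq_len(n_perm), function(b) {
    perm <- rng$sample(n)
    max(single_locus_stats(Gv[perm, , drop = FALSE], Y))
  }, 0)
  par <- fit_gumbel(maxima)
  structure(list(threshold = qgumbel(1 - alpha, par["loc"], par["scale"]),
                 loc = unname(par["loc"]), scale = unname(par["scale"]),
                 n_perm = n_perm, alpha = alpha, seed = seed,
                 maxima = maxima),
            class = "permutation_threshold")
}

# Vectorized |beta|/SE statistics for all loci x eigentraits under the
# one-locus model with intercept.
single_locus_stats <- function(Gv, Y) {
  n <- nrow(Gv)
  Gc <- scale(Gv, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  sxx <- colSums(Gc^2)                       # per locus
  sxy <- crossprod(Gc, Yc)                   # loci x eigentraits
  beta <- sxy / sxx
  syy <- colSums(Yc^2)
  rss <- outer(sxx, syy, function(a, b) b) - sxy^2 / sxx
  se <- sqrt(rss / (n - 2) / sxx)
  abs(beta) / se
}

# Seed-scoped RNG: evaluates sampling under a private seed without
# disturbing the caller's RNG state.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- NULL
  list(sample = function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    if (is.null(env$state)) set.seed(seed) else assign(".Random.seed", env$state, globalenv())
    out <- sample.int(n)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    out
  })
}

#' Tandem-permutation empirical null for a locus pair
#'
#' Applies `n_perm` shared row shuffles to the two tested genotype columns
#' only -- retaining any linkage between the markers while breaking their
#' association with the responses -- and re-evaluates the full pipeline
#' (pairwise fit, activity-change solve, influence coefficients, test
#' statistics) per permutation. Covariates and responses stay fixed at
#' observed values. Pairwise p-values are taken from these empirical
#' distributions directly; no extreme value distribution is fitted in the
#' pairwise path.
#'
#' @inheritParams pairwise_fit
#' @param dec an `eigentrait_decomposition` supplying the recomposition
#'   weights for variant-to-phenotype nulls (or `NULL` to use identity
#'   weights, i.e. eigentrait-space effects).
#' @param n_perm number of permutations.
#' @param seed RNG seed for the permutation sequence. [influence_scan()]
#'   passes the same seed for every pair, so permutation index `b` applies
#'   the same row shuffle to every pair: this synchronization preserves the
#'   cross-model correlation of coefficients involving a shared variant,
#'   which the averaged variant-to-phenotype null requires.
#' @param cond_bound,tol guards passed through to the influence solve.
#' @return an `empirical_null`: list with `gamma_stat` (n_perm x 2 matrix,
#'   columns `1<-2` and `2<-1`), `gamma`, `vp_coef` and `vp_var`
#'   (n_perm x 2T, variant-major), `valid` (logical), `n_perm`, `seed`,
#'   `n_invalid`.
#' @export
pairwise_null <- function(G, Y, pair, covariates = NULL, dec = NULL,
                          n_perm = 1000L, seed = 1L,
                          cond_bound = 1e8, tol = 1e-8) {
  Gv <- if (inherits(G, "genotype_matrix")) G$values else as.matrix(G)
  Y <- as.matrix(Y)
  loci <- colnames(Gv); if (is.null(loci)) loci <- paste0("L", seq_len(ncol(Gv)))
  colnames(Gv) <- loci
  pair_ids <- if (is.numeric(pair)) loci[pair] else as.character(pair)
  k <- ncol(Y)
  ets <- colnames(Y); if (is.null(ets)) ets <- paste0("ET", seq_len(k))
  if (is.null(covariates)) covariates <- stats::setNames(rep(list(character()), k), ets)
  cov_sets <- lapply(ets, function(et) setdiff(covariates[[et]], pair_ids))

  all_used <- unique(c(pair_ids, unlist(cov_sets)))
  use <- stats::complete.cases(Gv[, all_used, drop = FALSE])
  x1 <- Gv[use, pair_ids[1L]]; x2 <- Gv[use, pair_ids[2L]]
  Yu <- Y[use, , drop = FALSE]
  Zlist <- lapply(cov_sets, function(cv) Gv[use, cv, drop = FALSE])
  W <- if (is.null(dec)) diag(k) else dec$S * dec$Vt

  res <- .tandem_perm_null_cpp(x1, x2, Yu, Zlist, W, as.integer(n_perm),
                               as.numeric(seed), cond_bound, tol)
  structure(list(pair = pair_ids,
                 gamma_stat = res$gamma_stat,
                 gamma = res$gamma,
                 vp_coef = res$vp_coef,
                 vp_var = res$vp_var,
                 valid = as.logical(res$valid),
                 n_perm = n_perm, seed = seed,
                 n_invalid = sum(!res$valid)),
            class = "empirical_null")
}

#' Empirical p-value from a permutation null
#'
#' `p = (count(null >= stat) + 1) / (n_valid + 1)`: the add-one estimator,
#' which is never exactly zero and is a valid p-value for any number of
#' permutations.
#'
#' @param stat observed non-negative test statistic.
#' @param null numeric vector of permuted statistics (`NA` entries, e.g.
#'   from inestimable permutations, are dropped and counted separately).
#' @return p-value in (0, 1\].
#' @export
empirical_pvalue <- function(stat, null) {
  null <- null[!is.na(null)]
  if (length(null) == 0L) stop("empirical null is empty (all permutations invalid)")
  (sum(null >= stat) + 1) / (length(null) + 1)
}

#' Holm step-down adjustment
#'
#' Familywise-error-controlling step-down adjustment: p-values are sorted
#' ascending, the i-th smallest is multiplied by `m - i + 1`, running maxima
#' enforce monotonicity, values are capped at 1, and the result is returned
#' in the original order.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
holm_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "holm")
}
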