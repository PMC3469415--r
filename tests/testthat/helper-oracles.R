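# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# brute-force ordinary least squares via the normal equations
ne_ols <- function(X, y) {
  XtXinv <- solve(t(X) %*% X)
  beta <- XtXinv %*% t(X) %*% y
  res <- y - X %*% beta
  sigma2 <- sum(res^2) / (nrow(X) - ncol(X))
  list(beta = as.vector(beta), cov = sigma2 * XtXinv, sigma2 = sigma2)
}

# hand-executed Holm step-down
hand_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# brute-force one-sided hypergeometric tail by enumeration of 2x2 outcomes
enum_hyper_tail <- function(overlap, term_size, set_size, universe_size) {
  ks <- overlap:min(term_size, set_size)
  sum(choose(term_size, ks) * choose(universe_size - term_size, set_size - ks)) /
    choose(universe_size, set_size)
}

# vectorized Monte-Carlo gamma draws for a 2-eigentrait pairwise fit:
# theta draws ~ MVN(theta_hat, Sigma), exact 2x2 solve per draw
mc_gamma <- function(theta_hat, Sigma, n_draw, seed) {
  set.seed(seed)
  L <- chol(Sigma)
  TH <- matrix(rnorm(n_draw * 6), n_draw, 6) %*% L
  TH <- sweep(TH, 2, theta_hat, "+")
  b11 <- TH[, 1]; b21 <- TH[, 2]; c1 <- TH[, 3]
  b12 <- TH[, 4]; b22 <- TH[, 5]; c2 <- TH[, 6]
  det <- b11 * b22 - b12 * b21
  d1 <- (b22 * c1 - b21 * c2) / det
  d2 <- (-b12 * c1 + b11 * c2) / det
  cbind(d1 / (1 + d2), d2 / (1 + d1))
}

# minimal hand-built pairwise_fit-like object for the influence algebra
fake_fit <- function(beta1, beta2, beta12, theta_cov = diag(3 * length(beta1)) * 1e-4) {
  structure(list(pair = c("A", "B"), estimable = TRUE,
                 eigentrait_ids = paste0("ET", seq_along(beta1)),
                 beta1 = beta1, beta2 = beta2, beta12 = beta12,
                 theta_cov = theta_cov,
                 n_used = 100L, df = rep(96L, length(beta1))),
            class = "pairwise_fit")
}

write_tsv_fixture <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
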