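#' Parameter-recovery benchmark on synthetic populations
#'
#' Generates replicate populations with known ground-truth influence
#' networks, runs the full inference pipeline on each, and scores directed
#' influence recovery: a true influence counts as recovered when its edge is
#' significant (adjusted p below `alpha`) with the correct sign. False
#' positives are significant influence edges absent from the truth, reported
#' both per possible false edge (1 - specificity) and per discovered edge.
#'
#' @param n_datasets number of replicate populations.
#' @param n samples per population.
#' @param loci,n_influences,noise_sd,effect_range truth dimensions passed to
#'   [simulate_truth()] / [simulate_genotypes()].
#' @param n_perm tandem permutations per pair.
#' @param alpha adjusted-p cutoff.
#' @param seed master seed; per-dataset seeds derive from it.
#' @return list with `recovery_rate`, `false_positive_rate`,
#'   `false_discovery_rate`, `n_true`, `n_recovered`, `n_false`,
#'   `n_discovered`, `n_datasets`.
#' @export
recovery_benchmark <- function(n_datasets = 50L, n = 500L, loci = 6L,
                               n_influences = 4L, noise_sd = 0.25,
                               effect_range = c(0.3, 1), n_perm = 1000L,
                               alpha = 0.05, seed = 1L) {
  recovered <- 0L; total <- 0L; fp <- 0L; possible_fp <- 0L; discovered <- 0L
  for (r in seq_len(n_datasets)) {
    s <- (as.numeric(seed) * 1009 + 7 * r) %% 2147483647
    G <- simulate_genotypes(n, loci, seed = s + 1)
    tr <- simulate_truth(loci, 2L, n_influences, effect_range = effect_range,
                         noise_sd = noise_sd, seed = s + 2)
    ph <- simulate_phenotypes(G, tr, seed = s + 3)
    res <- run_influence_analysis(G, ph, n_perm = n_perm, alpha = alpha,
                                  seed = s + 4)
    inf <- res$influences
    te <- which(tr$gamma != 0, arr.ind = TRUE)
    for (e in seq_len(nrow(te))) {
      a <- tr$locus_ids[te[e, 1L]]; b <- tr$locus_ids[te[e, 2L]]
      row <- inf[inf$from == b & inf$to == a, ]
      total <- total + 1L
      if (nrow(row) == 1L && !is.na(row$p_adj) && row$p_adj < alpha &&
          sign(row$coef) == sign(tr$gamma[a, b])) {
        recovered <- recovered + 1L
      }
    }
    sig <- inf[!is.na(inf$p_adj) & inf$p_adj < alpha, ]
    discovered <- discovered + nrow(sig)
    possible_fp <- possible_fp + loci * (loci - 1L) - nrow(te)
    for (i in seq_len(nrow(sig))) {
      if (tr$gamma[sig$to[i], sig$from[i]] == 0) fp <- fp + 1L
    }
  }
  list(recovery_rate = recovered / total,
       false_positive_rate = fp / possible_fp,
       false_discovery_rate = if (discovered > 0L) fp / discovered else 0,
       n_true = total, n_recovered = recovered, n_false = fp,
       n_discovered = discovered, n_datasets = n_datasets)
}

#' Null calibration of the influence network pipeline
#'
#' Runs the full pipeline on populations whose phenotypes are pure Gaussian
#' noise (no genetic effects of any kind) and reports the familywise
#' false-edge rate (fraction of datasets yielding any network edge at the
#' `alpha` cutoff) together with the pooled raw permutation p-values of the
#' influence coefficients, which should be uniform under this global null.
#'
#' @param n_datasets number of all-null populations.
#' @param n samples per population.
#' @param loci loci per population.
#' @param n_perm tandem permutations per pair.
#' @param alpha adjusted-p cutoff defining an edge.
#' @param seed master seed.
#' @return list with `fwer` (any-edge fraction), `fwer_influences`
#'   (variant-to-variant edges only), `pvalues` (raw influence p-values),
#'   `n_datasets`.
#' @export
null_calibration <- function(n_datasets = 200L, n = 500L, loci = 5L,
                             n_perm = 1000L, alpha = 0.05, seed = 1L) {
  any_edge <- 0L; any_vv <- 0L
  pvals <- vector("list", n_datasets)
  for (r in seq_len(n_datasets)) {
    s <- (as.numeric(seed) * 1013 + 11 * r) %% 2147483647
    G <- simulate_genotypes(n, loci, seed = s + 1)
    Y <- with_seed(s + 2, matrix(stats::rnorm(2 * n), n, 2,
                                 dimnames = list(G$sample_ids, c("P1", "P2"))))
    ph <- phenotype_table(Y)
    res <- run_influence_analysis(G, ph, n_perm = n_perm, alpha = alpha,
                                  seed = s + 3)
    if (nrow(res$network$edges) > 0L) any_edge <- any_edge + 1L
    if (any(res$network$edges$type == "variant-variant")) any_vv <- any_vv + 1L
    pvals[[r]] <- res$influences$p[!is.na(res$influences$p)]
  }
  list(fwer = any_edge / n_datasets, fwer_influences = any_vv / n_datasets,
       pvalues = unlist(pvals), n_datasets = n_datasets)
}
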