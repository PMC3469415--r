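#' Simulate a genotyped population
#'
#' Generates biallelic, randomly assorting loci as independent Bernoulli
#' draws at the given variant-allele frequencies, emulating a haploid cross
#' with balanced (about 50%) allele frequencies in which one allele may be
#' underrepresented. An optional `linkage` parameter induces a common
#' pairwise genotype correlation through a Gaussian copula, for stressing
#' the tandem-permutation procedure.
#'
#' @param n number of samples (the original study used 218 strains).
#' @param loci number of loci (ignored when `freqs` is given).
#' @param freqs vector of variant-allele frequencies in (0, 1); recycled to
#'   `loci`. Default 0.5 everywhere.
#' @param linkage common pairwise latent correlation in \[0, 1).
#' @param seed RNG seed.
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes <- function(n, loci = 5L, freqs = rep(0.5, loci),
                               linkage = 0, seed = 1L) {
  freqs <- rep_len(freqs, loci)
  if (any(freqs <= 0 | freqs >= 1)) stop("allele frequencies must lie in (0, 1)")
  vals <- with_seed(seed, {
    if (linkage > 0) {
      z <- matrix(stats::rnorm(n * loci), n, loci)
      shared <- stats::rnorm(n)
      z <- sqrt(1 - linkage) * z + sqrt(linkage) * shared
      sweep(z, 2L, stats::qnorm(1 - freqs), `>`) * 1
    } else {
      matrix(stats::rbinom(n * loci, 1L, rep(freqs, each = n)), n, loci)
    }
  })
  dimnames(vals) <- list(paste0("S", seq_len(n)), paste0("L", seq_len(loci)))
  genotype_matrix(vals)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a ground-truth influence network
#'
#' Draws a sparse set of directed influence coefficients gamma, derives the
#' activity changes delta per pair from the coupled relations
#' `delta_1 = gamma_12 (1 + delta_2)`, `delta_2 = gamma_21 (1 + delta_1)`
#' (closed form `delta_1 = gamma_12 (1 + gamma_21) / (1 - gamma_12 gamma_21)`),
#' and builds the implied interaction coefficients
#' `beta_12j = delta_1 beta_1j + delta_2 beta_2j` per phenotype. Draws whose
#' activity algebra degenerates (`|1 - gamma_12 gamma_21|` or `|1 + delta|`
#' below tolerance) are resampled and logged. Main effects are drawn
#' uniformly from `main_range` with random sign so the main-effect matrix of
#' a pair is generically well conditioned.
#'
#' @param loci,phenotypes dimensions of the truth.
#' @param n_influences number of directed nonzero influences (at most
#'   `loci * (loci - 1)`).
#' @param effect_range range of |gamma| for the nonzero influences.
#' @param main_range range of |main effect| per locus x phenotype.
#' @param seed RNG seed.
#' @param tol degeneracy tolerance for the activity algebra.
#' @return a `synthetic_truth`: list with `beta` (loci x phenotypes),
#'   `gamma` (loci x loci, `gamma[a, b]` = influence of variant b on variant
#'   a), `delta` (named list per pair key "i:j" of length-2 vectors),
#'   `beta12` (list per pair key of per-phenotype interaction coefficients),
#'   `noise_sd`, `seed`, `n_resampled`.
#' @export
simulate_truth <- function(loci, phenotypes = 2L, n_influences = 4L,
                           effect_range = c(0.3, 1), main_range = c(0.5, 1.5),
                           noise_sd = 0.25, seed = 1L, tol = 0.05) {
  if (n_influences > loci * (loci - 1L)) stop("too many influences requested")
  with_seed(seed, {
    locus_ids <- paste0("L", seq_len(loci))
    pheno_ids <- paste0("P", seq_len(phenotypes))
    beta <- matrix(stats::runif(loci * phenotypes, main_range[1L], main_range[2L]) *
                     sample(c(-1, 1), loci * phenotypes, replace = TRUE),
                   loci, phenotypes, dimnames = list(locus_ids, pheno_ids))
    directed <- which(diag(loci) == 0, arr.ind = TRUE)  # all ordered pairs
    gamma <- matrix(0, loci, loci, dimnames = list(locus_ids, locus_ids))
    n_resampled <- 0L
    repeat {
      sel <- directed[sample.int(nrow(directed), n_influences), , drop = FALSE]
      g <- stats::runif(n_influences, effect_range[1L], effect_range[2L]) *
        sample(c(-1, 1), n_influences, replace = TRUE)
      gamma[] <- 0
      gamma[sel] <- g
      ok <- TRUE
      for (i in seq_len(loci - 1L)) for (j in (i + 1L):loci) {
        g12 <- gamma[i, j]; g21 <- gamma[j, i]
        if (abs(1 - g12 * g21) < tol) { ok <- FALSE; break }
        d1 <- g12 * (1 + g21) / (1 - g12 * g21)
        d2 <- g21 * (1 + g12) / (1 - g12 * g21)
        if (abs(1 + d1) < tol || abs(1 + d2) < tol) { ok <- FALSE; break }
      }
      if (ok) break
      n_resampled <- n_resampled + 1L
      if (n_resampled > 1000L) stop("could not draw a non-degenerate influence set")
    }
    delta <- list(); beta12 <- list()
    for (i in seq_len(loci - 1L)) for (j in (i + 1L):loci) {
      g12 <- gamma[i, j]; g21 <- gamma[j, i]
      d1 <- g12 * (1 + g21) / (1 - g12 * g21)
      d2 <- g21 * (1 + g12) / (1 - g12 * g21)
      key <- paste(locus_ids[i], locus_ids[j], sep = ":")
      delta[[key]] <- c(d1, d2)
      beta12[[key]] <- d1 * beta[i, ] + d2 * beta[j, ]
    }
    structure(list(locus_ids = locus_ids, phenotype_ids = pheno_ids,
                   beta = beta, gamma = gamma, delta = delta, beta12 = beta12,
                   noise_sd = noise_sd, seed = seed, n_resampled = n_resampled),
              class = "synthetic_truth")
  })
}

#' Simulate phenotypes from a ground truth
#'
#' Generative model is the pairwise regression model itself:
#' `y_ij = sum_v x_iv beta_vj + sum_pairs x_iu x_iv beta_uv,j + e`,
#' `e ~ Normal(0, noise_sd)`. This matches what the inference machinery can
#' identify, so noise-free data are recovered exactly.
#'
#' @param G a [genotype_matrix()] with loci matching `truth`.
#' @param truth a [simulate_truth()] result.
#' @param seed RNG seed for the noise.
#' @return a [phenotype_table()].
#' @export
simulate_phenotypes <- function(G, truth, seed = 1L) {
  Gv <- if (inherits(G, "genotype_matrix")) G$values else as.matrix(G)
  loci <- length(truth$locus_ids)
  stopifnot(ncol(Gv) == loci)
  Y <- Gv %*% truth$beta
  for (i in seq_len(loci - 1L)) for (j in (i + 1L):loci) {
    key <- paste(truth$locus_ids[i], truth$locus_ids[j], sep = ":")
    b12 <- truth$beta12[[key]]
    if (any(b12 != 0)) Y <- Y + outer(Gv[, i] * Gv[, j], b12)
  }
  noise <- with_seed(seed,
    matrix(stats::rnorm(length(Y), sd = truth$noise_sd), nrow(Y), ncol(Y)))
  vals <- Y + noise
  dimnames(vals) <- list(rownames(Gv), truth$phenotype_ids)
  phenotype_table(vals)
}

#' Two-variant suppression fixture
#'
#' A minimal worked example mirroring a constitutively activating allele
#' whose effect on both composite phenotypes is abolished by a downstream
#' kinase deletion: variant B carries a negative influence on variant A
#' (`gamma_A<-B < 0`), so double mutants lose most of A's effect. Used to
#' check that the pipeline infers suppression with the correct sign.
#'
#' @param n number of samples.
#' @param gamma_ab influence of variant B on variant A (negative =
#'   suppression).
#' @param noise_sd phenotype noise standard deviation.
#' @param seed RNG seed.
#' @return list with `genotypes`, `phenotypes`, and the `truth` object.
#' @export
suppression_fixture <- function(n = 300L, gamma_ab = -0.8, noise_sd = 0.25,
                                seed = 1L) {
  truth <- simulate_truth(loci = 2L, phenotypes = 2L, n_influences = 0L,
                          noise_sd = noise_sd, seed = seed)
  # A has same-sign effects on the two phenotypes, B opposite-sign: the two
  # composite phenotypes then carry complementary information about the pair
  truth$beta <- matrix(c(1, 1, 1, -1), 2L, 2L,
                       dimnames = list(truth$locus_ids, truth$phenotype_ids))
  truth$gamma["L1", "L2"] <- gamma_ab
  d1 <- gamma_ab          # gamma_BA = 0 so delta_A = gamma_AB, delta_B = 0
  truth$delta[["L1:L2"]] <- c(d1, 0)
  truth$beta12[["L1:L2"]] <- d1 * truth$beta[1L, ]
  G <- simulate_genotypes(n, loci = 2L, seed = seed + 1L)
  pheno <- simulate_phenotypes(G, truth, seed = seed + 2L)
  list(genotypes = G, phenotypes = pheno, truth = truth)
}

#' Simulate expression data driven by two phenotypes
#'
#' Generates a genes x samples log2-ratio-style expression matrix whose
#' global patterns are driven by the two phenotypes: one gene group loads on
#' the shared component of the phenotypes (their normalized sum) and a
#' second group on the component unique to the first phenotype (its residual
#' after projecting out the shared component). An SVD of the result yields
#' one mode tracking the shared biology (both phenotypes load on it) and one
#' tracking the first-phenotype-specific biology (only the first phenotype
#' loads on it), the correspondence structure that partially pleiotropic
#' phenotypes produce in real expression data.
#'
#' @param pheno a [phenotype_table()] with at least 2 phenotypes.
#' @param n_genes total genes; split between the two groups by `share`.
#' @param share fraction of genes in the shared-component group.
#' @param strength multiplicative loading scale for the two groups.
#' @param noise_sd per-gene Gaussian noise SD.
#' @param seed RNG seed.
#' @param drivers optional samples x 2 matrix of expression programs to use
#'   directly (e.g. latent shared/unique components of the phenotypes);
#'   defaults to the normalized phenotype sum and the first phenotype's
#'   residual from it.
#' @return an [expression_matrix()] over `pheno`'s samples.
#' @export
simulate_expression <- function(pheno, n_genes = 2000L, share = 0.5,
                                strength = c(1.5, 1), noise_sd = 0.5,
                                seed = 1L, drivers = NULL) {
  P <- standardize_phenotypes(pheno)
  if (is.null(drivers)) {
    shared <- P[, 1L] + P[, 2L]
    uniq <- P[, 1L] - sum(P[, 1L] * shared) / sum(shared^2) * shared
  } else {
    stopifnot(nrow(drivers) == nrow(P), ncol(drivers) == 2L)
    shared <- drivers[, 1L]; uniq <- drivers[, 2L]
  }
  shared <- shared / sqrt(sum(shared^2))
  uniq <- uniq / sqrt(sum(uniq^2))
  n1 <- round(n_genes * share); n2 <- n_genes - n1
  with_seed(seed, {
    load1 <- stats::runif(n1, 0.5, 1.5) * strength[1L] *
      sample(c(-1, 1), n1, replace = TRUE)
    load2 <- stats::runif(n2, 0.5, 1.5) * strength[2L] *
      sample(c(-1, 1), n2, replace = TRUE)
    vals <- rbind(outer(load1, shared), outer(load2, uniq)) * sqrt(nrow(P)) +
      matrix(stats::rnorm(n_genes * nrow(P), sd = noise_sd), n_genes, nrow(P))
    dimnames(vals) <- list(paste0("g", seq_len(n_genes)), rownames(P))
    expression_matrix(vals)
  })
}
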