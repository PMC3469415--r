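#' Pairwise influence scan on a response matrix
#'
#' Core engine shared by the phenotype and expression-mode analyses: given
#' aligned genotypes and an orthogonal response matrix (eigentraits or
#' expression-mode sample patterns), runs the single-locus scan, selects
#' strong-effect covariates, fits all locus pairs, reparametrizes into
#' directed influences, generates tandem-permutation nulls per pair, and
#' computes empirical p-values with Holm step-down adjustment in two
#' families: all variant-to-variant influences across pairs, and the
#' averaged variant-to-phenotype coefficients.
#'
#' Permutations are synchronized across pairs: permutation index `b` applies
#' the same row shuffle to every pair's genotype columns (derived only from
#' the master seed), so results do not depend on the order in which pairs
#' are processed, and -- critically -- the null of the averaged
#' variant-to-phenotype statistic preserves the correlation between pairwise
#' models that share a variant, which independent per-pair permutations
#' would destroy.
#'
#' @param G a [genotype_matrix()] or numeric genotype matrix.
#' @param Y response matrix (samples x k), columns orthogonal composites.
#' @param dec optional [eigentrait_decompose()] result; when supplied,
#'   variant-to-phenotype effects are recomposed onto the original
#'   phenotypes, otherwise they are reported on the response columns.
#' @param covariate_threshold single-locus statistic cutoff for covariate
#'   selection (default 3.55, i.e. p < 0.01 under a 10,000-permutation
#'   extreme-value calibration).
#' @param n_perm number of tandem permutations per pair.
#' @param alpha adjusted-p significance cutoff for network edges.
#' @param seed master RNG seed.
#' @param cond_bound,tol numerical guards for the influence solve.
#' @return an `influence_scan` list: `scan` (single-locus fits),
#'   `covariates`, `pairs` (per-pair fit/influence/null summaries),
#'   `influences` (data frame of directed influences with p-values),
#'   `effects` (averaged variant-to-phenotype effects with p-values),
#'   `network` (significance-filtered [build_network()] result), `seed`,
#'   `n_perm`, `alpha`.
#' @export
influence_scan <- function(G, Y, dec = NULL, covariate_threshold = 3.55,
                           n_perm = 1000L, alpha = 0.05, seed = 1L,
                           cond_bound = 1e8, tol = 1e-8) {
  Gv <- if (inherits(G, "genotype_matrix")) G$values else as.matrix(G)
  Y <- as.matrix(Y)
  if (ncol(Y) < 2L) stop("influence inference needs at least 2 response columns")
  loci <- colnames(Gv); if (is.null(loci)) loci <- paste0("L", seq_len(ncol(Gv)))
  colnames(Gv) <- loci
  L <- length(loci)
  if (is.null(dec)) dec <- identity_decomposition(Y)

  scan <- single_locus_scan(Gv, Y)
  covs <- select_covariates(scan, threshold = covariate_threshold)

  pair_idx <- utils::combn(L, 2L)
  pairs <- vector("list", ncol(pair_idx))
  infl_rows <- list(); vp_list <- list()
  vp_nulls <- list()  # per pair: list(pair_ids, vp_coef, vp_var)
  for (p in seq_len(ncol(pair_idx))) {
    i <- pair_idx[1L, p]; j <- pair_idx[2L, p]
    pair_ids <- loci[c(i, j)]
    fit <- pairwise_fit(Gv, Y, pair_ids, covs)
    if (!isTRUE(fit$estimable)) {
      pairs[[p]] <- list(pair = pair_ids, estimable = FALSE, reason = fit$reason)
      next
    }
    ac <- solve_activity_changes(fit, cond_bound = cond_bound)
    ip <- influence_coefficients(ac, tol = tol)
    vp <- variant_phenotype_effects(fit, dec)
    null <- pairwise_null(Gv, Y, pair_ids, covs, dec = dec, n_perm = n_perm,
                          seed = seed, cond_bound = cond_bound, tol = tol)
    p_gamma <- c(NA_real_, NA_real_)
    for (d in 1:2) {
      if (isTRUE(ip$defined[d]) && is.finite(ip$statistic[d])) {
        p_gamma[d] <- empirical_pvalue(ip$statistic[d], null$gamma_stat[, d])
      }
    }
    # direction d = 1 is the influence of variant 2 on variant 1
    infl_rows[[p]] <- data.frame(
      from = c(pair_ids[2L], pair_ids[1L]),
      to = c(pair_ids[1L], pair_ids[2L]),
      coef = unname(ip$gamma), se = ip$se, statistic = ip$statistic,
      p = p_gamma, defined = ip$defined, n_perm_valid = sum(null$valid),
      stringsAsFactors = FALSE)
    vp_list[[p]] <- vp
    vp_nulls[[p]] <- list(pair = pair_ids, vp_coef = null$vp_coef,
                          vp_var = null$vp_var)
    pairs[[p]] <- list(pair = pair_ids, estimable = TRUE, fit = fit,
                       activity = ac, influence = ip,
                       n_perm_invalid = null$n_invalid)
  }

  influences <- if (length(infl_rows) > 0L) do.call(rbind, Filter(Negate(is.null), infl_rows)) else NULL
  if (!is.null(influences)) rownames(influences) <- NULL

  effects <- NULL
  if (length(Filter(Negate(is.null), vp_list)) > 0L) {
    effects <- average_effects(vp_list)
    effects <- averaged_effect_pvalues(effects, vp_nulls, dec$phenotype_ids)
  }

  # one Holm family over every coefficient that can become a network edge,
  # so the network-wide familywise error rate is controlled at alpha
  n_inf <- if (is.null(influences)) 0L else nrow(influences)
  pool <- c(if (n_inf > 0L) influences$p, if (!is.null(effects)) effects$p)
  if (length(pool) > 0L) {
    adj <- rep(NA_real_, length(pool))
    ok <- !is.na(pool)
    if (any(ok)) adj[ok] <- holm_adjust(pool[ok])
    if (n_inf > 0L) influences$p_adj <- adj[seq_len(n_inf)]
    if (!is.null(effects)) effects$p_adj <- adj[n_inf + seq_len(nrow(effects))]
  }

  net <- build_network(influences, effects, alpha = alpha)
  structure(list(scan = scan, covariates = covs, pairs = pairs,
                 influences = influences, effects = effects, network = net,
                 dec = dec, seed = seed, n_perm = n_perm, alpha = alpha,
                 covariate_threshold = covariate_threshold),
            class = "influence_scan")
}

# Identity decomposition: report effects on the response columns themselves.
identity_decomposition <- function(Y) {
  k <- ncol(Y)
  ids <- colnames(Y); if (is.null(ids)) ids <- paste0("ET", seq_len(k))
  structure(list(U = Y, S = rep(1, k), Vt = diag(k), phenotype_ids = ids),
            class = "eigentrait_decomposition")
}

# Significance of averaged variant-to-phenotype effects: the null of the
# averaged statistic is computed per permutation from the same per-pair
# nulls (mean of null coefficients over contributing models, RMS of their
# variances), not from a normal approximation.
averaged_effect_pvalues <- function(effects, vp_nulls, phenotype_ids) {
  T <- length(phenotype_ids)
  effects$p <- NA_real_
  for (r in seq_len(nrow(effects))) {
    v <- effects$variant[r]
    t_idx <- match(effects$phenotype[r], phenotype_ids)
    coef_cols <- list(); var_cols <- list()
    for (pn in vp_nulls) {
      pos <- match(v, pn$pair)
      if (is.na(pos)) next
      col <- (pos - 1L) * T + t_idx
      coef_cols[[length(coef_cols) + 1L]] <- pn$vp_coef[, col]
      var_cols[[length(var_cols) + 1L]] <- pn$vp_var[, col]
    }
    if (length(coef_cols) == 0L) next
    cm <- do.call(cbind, coef_cols); vm <- do.call(cbind, var_cols)
    mean_b <- rowMeans(cm, na.rm = TRUE)
    n_b <- rowSums(!is.na(cm))
    rms_b <- sqrt(rowMeans(vm, na.rm = TRUE) / n_b)
    stat_b <- ifelse(n_b > 0L & rms_b > 0, abs(mean_b) / rms_b, NA_real_)
    effects$p[r] <- empirical_pvalue(effects$statistic[r], stat_b)
  }
  effects
}

#' @export
print.influence_scan <- function(x, ...) {
  cat(sprintf("influence_scan: %d loci, %d pairs, %d permutations/pair (seed %s)\n",
              length(unique(x$scan$locus)), length(x$pairs), x$n_perm,
              format(x$seed)))
  print(x$network)
  invisible(x)
}

#' Run the full influence-network analysis
#'
#' End-to-end orchestration: align samples, standardize phenotypes,
#' decompose into eigentraits, single-locus scan and covariate selection,
#' all pairwise interaction fits, activity-change and influence
#' reparametrization, tandem-permutation significance with Holm adjustment,
#' averaging of recomposed variant-to-phenotype effects, and network
#' assembly. Optionally writes a results bundle of fixed-name artifacts.
#'
#' @param genotypes a [genotype_matrix()] or path to a genotype table.
#' @param phenotypes a [phenotype_table()] or path to a phenotype table.
#' @param covariate_threshold single-locus covariate cutoff (default 3.55).
#' @param n_perm tandem permutations per pair (default 100,000, the original
#'   study's count; desk-scale runs use >= 1,000).
#' @param alpha adjusted-p significance cutoff (default 0.05).
#' @param seed master RNG seed.
#' @param out_dir optional directory for the results bundle:
#'   `eigentraits.tsv`, `single_locus.tsv`, `pairwise.tsv`,
#'   `influences.tsv`, `effects.tsv`, `network.tsv`, `network.graphml`,
#'   `run.json`.
#' @param cond_bound,tol numerical guards for the influence solve.
#' @return an `influence_scan` result (with the decomposition in `$dec`).
#' @export
run_influence_analysis <- function(genotypes, phenotypes,
                                   covariate_threshold = 3.55,
                                   n_perm = 100000L, alpha = 0.05, seed = 1L,
                                   out_dir = NULL,
                                   cond_bound = 1e8, tol = 1e-8) {
  if (is.character(genotypes)) genotypes <- read_genotypes(genotypes)
  if (is.character(phenotypes)) phenotypes <- read_phenotypes(phenotypes)
  if (!isTRUE(phenotypes$pleiotropy_available)) {
    stop("influence inference requires at least 2 phenotypes")
  }
  aligned <- align_samples(genotypes, phenotypes)
  P <- standardize_phenotypes(aligned$phenotypes)
  dec <- eigentrait_decompose(P)
  res <- influence_scan(aligned$genotypes, dec$U, dec = dec,
                        covariate_threshold = covariate_threshold,
                        n_perm = n_perm, alpha = alpha, seed = seed,
                        cond_bound = cond_bound, tol = tol)
  if (!is.null(out_dir)) write_results_bundle(res, out_dir)
  res
}

write_results_bundle <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)
  dec <- res$dec
  utils::write.table(
    data.frame(sample = rownames(dec$U), dec$U, check.names = FALSE),
    path("eigentraits.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$scan, path("single_locus.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pw <- do.call(rbind, lapply(res$pairs, function(p) {
    if (!isTRUE(p$estimable)) {
      return(data.frame(locus1 = p$pair[1L], locus2 = p$pair[2L],
                        eigentrait = NA, beta1 = NA, beta2 = NA, beta12 = NA,
                        n_used = NA, estimable = FALSE,
                        reason = p$reason, stringsAsFactors = FALSE))
    }
    data.frame(locus1 = p$pair[1L], locus2 = p$pair[2L],
               eigentrait = p$fit$eigentrait_ids,
               beta1 = p$fit$beta1, beta2 = p$fit$beta2,
               beta12 = p$fit$beta12, n_used = p$fit$n_used,
               estimable = TRUE, reason = "", stringsAsFactors = FALSE)
  }))
  utils::write.table(pw, path("pairwise.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(res$influences)) {
    utils::write.table(res$influences, path("influences.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$effects)) {
    utils::write.table(res$effects, path("effects.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_network(res$network, path("network.tsv"), "tsv")
  write_network(res$network, path("network.graphml"), "graphml")
  run_meta <- list(seed = res$seed, n_perm = res$n_perm, alpha = res$alpha,
                   covariate_threshold = res$covariate_threshold,
                   covariates = res$covariates,
                   package_version = as.character(utils::packageVersion("ginet")),
                   timestamp = format(Sys.time(), tz = "UTC"))
  writeLines(jsonlite::toJSON(run_meta, auto_unbox = TRUE, pretty = TRUE),
             path("run.json"))
  invisible(out_dir)
}
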