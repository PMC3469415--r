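make_expr_fixture <- function(n_genes = 200, n_samples = 30, seed = 63) {
  set.seed(seed)
  ph <- phenotype_table(matrix(rnorm(n_samples * 2), n_samples, 2,
                               dimnames = list(paste0("S", 1:n_samples),
                                               c("ME", "PR"))))
  ex <- expression_matrix(matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
                                 dimnames = list(paste0("g", 1:n_genes),
                                                 paste0("S", 1:n_samples))))
  list(expr = ex, pheno = ph)
}

test_that("phenotype rows are appended at the target scale without touching genes", {
  fx <- make_expr_fixture()
  aug <- augment_with_phenotypes(fx$expr, fx$pheno, target_sd = 2)
  expect_equal(nrow(aug), 200 + 2)
  expect_equal(sd(aug["ME", ]), 2, tolerance = 1e-12)
  expect_equal(sd(aug["PR", ]), 2, tolerance = 1e-12)
  expect_identical(aug[1:200, ], fx$expr$values)
  expect_equal(attr(aug, "phenotype_rows"), c("ME", "PR"))

  ph_bad <- phenotype_table(fx$pheno$values[1:10, ])
  expect_error(augment_with_phenotypes(fx$expr, ph_bad), "missing")
})

test_that("expression decomposition partitions variance and honors the sign convention", {
  # rank-1 matrix: first mode carries all variance
  u <- rnorm(50); v <- rnorm(12)
  m1 <- decompose_expression(outer(u, v))
  expect_equal(m1$variance_fraction[1], 1, tolerance = 1e-12)

  fx <- make_expr_fixture()
  modes <- decompose_expression(fx$expr$values)
  expect_equal(sum(modes$variance_fraction), 1, tolerance = 1e-10)
  # largest-magnitude gene weight positive per mode
  for (j in 1:5) {
    w <- modes$weights[modes$gene_ids, j]
    expect_gt(w[which.max(abs(w))], 0)
  }
})

test_that("mode gene sets flag the expected two-sided tail at 2 SD", {
  set.seed(67)
  n <- 10000
  w <- matrix(rnorm(n), n, 1, dimnames = list(paste0("g", 1:n), "Mode1"))
  fake_modes <- structure(list(weights = w, gene_ids = rownames(w),
                               patterns = matrix(0, 1, 2)),
                          class = "expression_modes")
  sets <- mode_gene_sets(fake_modes, k_sd = 2, n_modes = 1)
  frac <- nrow(sets) / n
  expect_equal(frac, 2 * pnorm(-2), tolerance = 0.005 / (2 * pnorm(-2)))
  s <- attr(sets, "sets")
  expect_true(all(w[s$Mode1.positive, 1] > mean(w)))
  expect_true(all(w[s$Mode1.negative, 1] < mean(w)))

  # all weights within 2 SD -> both sets empty
  w2 <- matrix(seq(-1, 1, length.out = 50), 50, 1,
               dimnames = list(paste0("g", 1:50), "Mode1"))
  fake2 <- structure(list(weights = w2, gene_ids = rownames(w2),
                          patterns = matrix(0, 1, 2)),
                     class = "expression_modes")
  expect_equal(nrow(mode_gene_sets(fake2, k_sd = 2, n_modes = 1)), 0L)
})

test_that("enrichment p-values equal brute-force hypergeometric enumeration", {
  universe <- paste0("g", 1:20)
  ann <- annotation_sets(list(T1 = paste0("g", 1:5),
                              T2 = paste0("g", 6:12),
                              Tdisjoint = paste0("x", 1:4)),
                         category = "TF-target")
  expect_warning(
    res <- enrichment(paste0("g", 1:5), universe, ann, correction = "bonferroni"),
    "disjoint")
  # set identical to term T1
  p1 <- res$p[res$term == "T1"]
  expect_equal(p1, enum_hyper_tail(5, 5, 5, 20), tolerance = 1e-12)
  p2 <- res$p[res$term == "T2"]
  expect_equal(p2, enum_hyper_tail(0, 7, 5, 20), tolerance = 1e-12)
  expect_equal(res$p_bonferroni, pmin(res$p * 2, 1))
  # empty set -> empty result
  expect_equal(nrow(enrichment(character(), universe, ann, "bonferroni")), 0L)
})

test_that("permutation FDR machinery estimates the random-set hit rate", {
  set.seed(71)
  universe <- paste0("g", 1:1000)
  terms <- lapply(1:60, function(i) sample(universe, 40))
  names(terms) <- paste0("T", 1:60)
  ann <- annotation_sets(terms)
  cutoff <- 0.01
  # independent estimate of the null hit rate for size-80 random sets
  obs_hits <- replicate(150, {
    sum(enrichment(sample(universe, 80), universe, ann, "bonferroni")$p < cutoff)
  })
  # a set enriched for T1 so at least one genuine hit anchors the FDR
  query <- c(terms$T1, sample(setdiff(universe, terms$T1), 40))
  res <- enrichment(query, universe, ann,
                    correction = "permutation-fdr", p_cutoff = cutoff,
                    n_perm = 300, seed = 5)
  expect_gte(sum(res$p < cutoff), 1)
  null_rate <- attr(res, "fdr") * sum(res$p < cutoff)
  # internal permutation null-hit rate matches the independently simulated
  # rate within a factor of 2 (with slack for near-zero rates)
  expect_lt(abs(null_rate - mean(obs_hits)), max(mean(obs_hits), 0.5))
})

test_that("mode patterns feed the pair scan as orthogonal composite phenotypes", {
  fx <- make_expr_fixture()
  modes <- decompose_expression(fx$expr$values)
  Y <- modes_as_phenotypes(modes, 2)
  expect_equal(dim(Y), c(30L, 2L))
  expect_lt(abs(sum(Y[, 1] * Y[, 2])), 1e-10)
  expect_false(attr(Y, "standardized"))
  expect_error(modes_as_phenotypes(modes, 40), "exceeds")
})

test_that("appended phenotype rows perturb mode sample patterns negligibly", {
  set.seed(73)
  n <- 60
  ph <- phenotype_table(matrix(rnorm(2 * n), n, 2,
                               dimnames = list(paste0("S", 1:n), c("ME", "PR"))))
  expr <- simulate_expression(ph, n_genes = 5000, noise_sd = 0.5, seed = 74)
  plain <- decompose_expression(expr$values)
  aug <- decompose_expression(augment_with_phenotypes(expr, ph))
  for (j in 1:3) {
    d <- min(max(abs(plain$patterns[j, ] - aug$patterns[j, ])),
             max(abs(plain$patterns[j, ] + aug$patterns[j, ])))
    expect_lt(d, 1e-3)
  }
})

test_that("phenotype mode weights reflect shared and unique expression programs", {
  # latent structure: ME = shared + unique, PR = shared + independent noise;
  # genes are driven by the shared and the ME-unique programs, so ME should
  # load on both leading modes while PR loads on the shared mode only
  set.seed(79)
  n <- 80
  shared <- rnorm(n); uniq <- rnorm(n)
  ph <- phenotype_table(cbind(ME = shared + uniq, PR = shared + rnorm(n)))
  expr <- simulate_expression(ph, n_genes = 3000, share = 0.55,
                              strength = c(1.5, 1), noise_sd = 0.4, seed = 80,
                              drivers = cbind(shared, uniq))
  aug <- augment_with_phenotypes(expr, ph)
  modes <- decompose_expression(aug)
  w <- abs(modes$phenotype_weights[, 1:2])
  # the first phenotype drives both leading modes; the second is
  # predominantly captured by the shared mode only
  shared_mode <- which.max(w["PR", ])
  unique_mode <- setdiff(1:2, shared_mode)
  expect_gt(w["ME", unique_mode], 3 * w["PR", unique_mode])
  expect_gt(w["ME", shared_mode], 0.5 * w["PR", shared_mode])
})
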