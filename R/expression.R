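#' Append phenotypes to an expression matrix as scaled rows
#'
#' To locate expression patterns that correspond to the organismal
#' phenotypes, the phenotypes are appended to the genes x samples matrix as
#' extra rows, re-centered on the reference (e.g. wild-type) strain value
#' and scaled to a standard deviation of `target_sd` (default 2) to match
#' the origin and scale of log2-ratio expression data. Because a couple of
#' rows are added to thousands of gene rows, their contribution to the SVD
#' patterns is negligible; they act as markers for reading mode weights.
#'
#' @param expr an [expression_matrix()].
#' @param pheno a [phenotype_table()] covering the expression samples.
#' @param reference_value named numeric vector (per phenotype) of the
#'   reference-strain phenotype value; defaults to the mean over the
#'   expression samples.
#' @param target_sd standard deviation of the appended rows.
#' @return numeric matrix of `genes + phenotypes` rows x samples, with an
#'   attribute `"phenotype_rows"` naming the appended rows.
#' @export
augment_with_phenotypes <- function(expr, pheno, reference_value = NULL,
                                    target_sd = 2) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(pheno, "phenotype_table"))
  missing <- setdiff(expr$sample_ids, pheno$sample_ids)
  if (length(missing) > 0L) {
    stop("phenotypes missing for expression sample(s): ",
         paste(missing, collapse = ", "))
  }
  ph <- t(pheno$values[expr$sample_ids, , drop = FALSE])  # phenotypes x samples
  for (i in seq_len(nrow(ph))) {
    ref <- if (!is.null(reference_value)) reference_value[[rownames(ph)[i]]]
           else mean(ph[i, ])
    centered <- ph[i, ] - ref
    s <- stats::sd(centered)
    if (s == 0) stop("zero-variance phenotype: ", rownames(ph)[i])
    ph[i, ] <- centered / s * target_sd
  }
  out <- rbind(expr$values, ph)
  attr(out, "phenotype_rows") <- rownames(ph)
  out
}

#' Decompose an expression matrix into modes
#'
#' Singular value decomposition of the (optionally phenotype-augmented)
#' genes x samples matrix into global expression patterns ("modes"). Each
#' mode has a sample pattern (right singular vector), per-gene weights
#' (left singular vector scaled by the singular value is not used here;
#' weights are the raw left singular vector entries), and a variance
#' fraction (squared singular value over the total). The sign convention
#' matches [eigentrait_decompose()]: each mode's largest-magnitude gene
#' weight is positive.
#'
#' @param mat numeric matrix, genes (+ appended phenotype rows) x samples.
#' @return an `expression_modes`: list with `patterns` (modes x samples),
#'   `weights` (rows x modes, including any phenotype rows),
#'   `phenotype_weights` (subset of `weights` for appended rows),
#'   `variance_fraction` (per mode), `gene_ids`, `phenotype_rows`.
#' @export
decompose_expression <- function(mat) {
  mat <- as.matrix(mat)
  if (any(!is.finite(mat))) stop("expression matrix must be finite")
  if (is.null(rownames(mat))) rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  pheno_rows <- attr(mat, "phenotype_rows")
  if (is.null(pheno_rows)) pheno_rows <- character()
  k <- min(dim(mat))
  sv <- svd(mat, nu = k, nv = k)
  weights <- sv$u
  patterns <- t(sv$v)
  gene_rows <- setdiff(rownames(mat), pheno_rows)
  gi <- match(gene_rows, rownames(mat))
  for (j in seq_len(k)) {
    lead <- which.max(abs(weights[gi, j]))
    if (weights[gi[lead], j] < 0) {
      weights[, j] <- -weights[, j]
      patterns[j, ] <- -patterns[j, ]
    }
  }
  rownames(weights) <- rownames(mat)
  colnames(weights) <- paste0("Mode", seq_len(k))
  rownames(patterns) <- colnames(weights)
  colnames(patterns) <- colnames(mat)
  structure(list(patterns = patterns,
                 weights = weights,
                 phenotype_weights = weights[pheno_rows, , drop = FALSE],
                 singular_values = sv$d[seq_len(k)],
                 variance_fraction = sv$d[seq_len(k)]^2 / sum(sv$d^2),
                 gene_ids = gene_rows,
                 phenotype_rows = pheno_rows),
            class = "expression_modes")
}

#' @export
print.expression_modes <- function(x, ...) {
  cat(sprintf("expression_modes: %d genes, %d samples, %d modes\n",
              length(x$gene_ids), ncol(x$patterns), nrow(x$patterns)))
  cat("variance fractions:",
      paste(sprintf("%.3f", utils::head(x$variance_fraction, 5L)), collapse = " "),
      if (length(x$variance_fraction) > 5L) "..." else "", "\n")
  invisible(x)
}

#' Mode gene sets at a weight threshold
#'
#' For each mode, genes whose weight lies `k_sd` or more standard deviations
#' from the mean weight form two sets: positive-weight and negative-weight
#' members. Mean and SD are computed over gene weights only; appended
#' phenotype rows are markers, not genes, and are excluded.
#'
#' @param modes an [decompose_expression()] result.
#' @param k_sd threshold in standard deviations (default 2).
#' @param n_modes number of leading modes to process (default all).
#' @return data frame: `mode`, `direction` (`"positive"`/`"negative"`),
#'   `gene`; plus attribute `"sets"`, a named list of gene vectors keyed
#'   `"Mode<i>.<direction>"`.
#' @export
mode_gene_sets <- function(modes, k_sd = 2, n_modes = nrow(modes$patterns)) {
  sets <- list(); rows <- list()
  for (j in seq_len(n_modes)) {
    w <- modes$weights[modes$gene_ids, j]
    mu <- mean(w); s <- stats::sd(w)
    hi <- names(w)[w >= mu + k_sd * s]
    lo <- names(w)[w <= mu - k_sd * s]
    sets[[paste0("Mode", j, ".positive")]] <- hi
    sets[[paste0("Mode", j, ".negative")]] <- lo
    if (length(hi) > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(mode = j, direction = "positive",
                                              gene = hi, stringsAsFactors = FALSE)
    }
    if (length(lo) > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(mode = j, direction = "negative",
                                              gene = lo, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(mode = integer(), direction = character(), gene = character(),
               stringsAsFactors = FALSE)
  attr(out, "sets") <- sets
  out
}

#' Annotation-term enrichment of a gene set
#'
#' One-sided Fisher exact test of overlap between a gene set and each
#' annotation term, restricted to a gene universe. For GO-style categories
#' with interdependent terms, a gene-name permutation (set-size-matched
#' random draws from the universe) estimates the false discovery rate at a
#' p-value cutoff; for transcription-factor target sets a Bonferroni factor
#' equal to the number of factors tested is applied.
#'
#' @param genes character vector, the gene set (must be within `universe`).
#' @param universe character vector of all assayed genes.
#' @param annotations an [annotation_sets()] object.
#' @param correction `"permutation-fdr"` or `"bonferroni"`.
#' @param p_cutoff p-value cutoff at which the permutation FDR is estimated.
#' @param n_perm gene-name permutations for the FDR estimate.
#' @param seed RNG seed for the permutations.
#' @return data frame: `term`, `overlap`, `set_size`, `term_size`,
#'   `universe_size`, `p`, and `p_bonferroni` or attribute `"fdr"` depending
#'   on `correction`. Terms disjoint from the universe are skipped with a
#'   warning.
#' @export
enrichment <- function(genes, universe, annotations,
                       correction = c("permutation-fdr", "bonferroni"),
                       p_cutoff = 1e-4, n_perm = 1000L, seed = 1L) {
  correction <- match.arg(correction)
  genes <- intersect(genes, universe)
  if (length(genes) == 0L) {
    return(data.frame(term = character(), overlap = integer(),
                      set_size = integer(), term_size = integer(),
                      universe_size = integer(), p = numeric(),
                      stringsAsFactors = FALSE))
  }
  terms <- annotations$sets
  term_in_universe <- lapply(terms, intersect, universe)
  empty <- lengths(term_in_universe) == 0L
  if (any(empty)) {
    warning("term(s) disjoint from universe skipped: ",
            paste(names(terms)[empty], collapse = ", "))
    term_in_universe <- term_in_universe[!empty]
  }
  N <- length(universe); n_set <- length(genes)
  fisher_p <- function(set) {
    vapply(term_in_universe, function(tg) {
      ov <- length(intersect(set, tg))
      # one-sided (enrichment) hypergeometric tail
      stats::phyper(ov - 1L, length(tg), N - length(tg), length(set),
                    lower.tail = FALSE)
    }, 0)
  }
  p <- fisher_p(genes)
  out <- data.frame(term = names(term_in_universe),
                    overlap = vapply(term_in_universe, function(tg)
                      length(intersect(genes, tg)), 0L),
                    set_size = n_set,
                    term_size = lengths(term_in_universe) + 0L,
                    universe_size = N,
                    p = unname(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (correction == "bonferroni") {
    out$p_bonferroni <- pmin(out$p * length(term_in_universe), 1)
  } else {
    n_hits <- sum(out$p < p_cutoff)
    null_hits <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
      sum(fisher_p(sample(universe, n_set)) < p_cutoff)
    }, 0))
    attr(out, "fdr") <- if (n_hits > 0L) min(mean(null_hits) / n_hits, 1) else NA_real_
    attr(out, "p_cutoff") <- p_cutoff
  }
  out[order(out$p), , drop = FALSE]
}

#' Expression modes as composite phenotypes for the pair scan
#'
#' Returns the first `k` mode sample patterns as a samples x k response
#' matrix consumable by [influence_scan()]. The patterns are already
#' orthonormal, so phenotype standardization is skipped (flagged in an
#' attribute). Modeling more modes than samples support is rejected.
#'
#' @param modes an [decompose_expression()] result.
#' @param k number of leading modes.
#' @return samples x k matrix with attribute `"standardized"` = `FALSE`.
#' @export
modes_as_phenotypes <- function(modes, k) {
  n_modes <- nrow(modes$patterns)
  if (k > n_modes) stop("k exceeds the number of modes")
  if (k > ncol(modes$patterns)) stop("k exceeds the sample count")
  Y <- t(modes$patterns[seq_len(k), , drop = FALSE])
  attr(Y, "standardized") <- FALSE
  Y
}
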