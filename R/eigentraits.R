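#' Mean-center and standard-deviation normalize phenotypes
#'
#' Each phenotype column is centered to mean 0 and scaled to sample standard
#' deviation 1 (n-1 denominator), removing arbitrary scale differences
#' between assays before the singular value decomposition.
#'
#' @param pheno a [phenotype_table()] or a numeric matrix (samples x
#'   phenotypes) with no missing values.
#' @return numeric matrix of standardized phenotypes.
#' @export
standardize_phenotypes <- function(pheno) {
  mat <- if (inherits(pheno, "phenotype_table")) pheno$values else as.matrix(pheno)
  if (any(is.na(mat))) stop("missing phenotype values: impute or drop samples first")
  sds <- apply(mat, 2L, stats::sd)
  zero <- which(sds == 0 | !is.finite(sds))
  if (length(zero) > 0L) {
    stop("zero-variance phenotype(s): ", paste(colnames(mat)[zero], collapse = ", "))
  }
  scale(mat, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Factor standardized phenotypes into eigentraits
#'
#' Computes the full singular value decomposition `P = U diag(S) Vt` of the
#' standardized phenotype matrix. The columns of `U` are the eigentraits:
#' orthogonal composite phenotypes, each a normalized linear combination of
#' the originals. With two positively correlated phenotypes the eigentraits
#' are the normalized sum and difference. No truncation is performed, so
#' results on eigentraits can be recomposed to the original phenotypes
#' without loss (see [recompose_effects()]).
#'
#' Sign convention: each right singular vector is flipped, together with its
#' left singular vector, so that its largest-magnitude loading is positive.
#' This removes the SVD sign ambiguity and makes output reproducible.
#'
#' @param P standardized phenotype matrix (samples x phenotypes), e.g. from
#'   [standardize_phenotypes()].
#' @return an `eigentrait_decomposition`: list with `U` (samples x k), `S`
#'   (k singular values, descending), `Vt` (k x phenotypes), and
#'   `phenotype_ids`.
#' @export
eigentrait_decompose <- function(P) {
  P <- as.matrix(P)
  n <- nrow(P); k <- ncol(P)
  if (n <= k) stop("need more samples than phenotypes")
  sv <- svd(P, nu = k, nv = k)
  U <- sv$u; S <- sv$d; Vt <- t(sv$v)
  for (j in seq_len(k)) {
    lead <- which.max(abs(Vt[j, ]))
    if (Vt[j, lead] < 0) {
      Vt[j, ] <- -Vt[j, ]
      U[, j] <- -U[, j]
    }
  }
  ids <- colnames(P)
  if (is.null(ids)) ids <- paste0("P", seq_len(k))
  colnames(U) <- rownames(Vt) <- paste0("ET", seq_len(k))
  colnames(Vt) <- ids
  rownames(U) <- rownames(P)
  structure(list(U = U, S = S, Vt = Vt, phenotype_ids = ids),
            class = "eigentrait_decomposition")
}

#' @export
print.eigentrait_decomposition <- function(x, ...) {
  cat(sprintf("eigentrait_decomposition: %d samples, %d eigentraits\n",
              nrow(x$U), length(x$S)))
  frac <- x$S^2 / sum(x$S^2)
  cat("variance fractions:", paste(sprintf("%.3f", frac), collapse = " "), "\n")
  invisible(x)
}

#' Map eigentrait-space effect estimates back to the original phenotypes
#'
#' Regression coefficients estimated against the eigentraits (columns of
#' `U`) are multiplied by `diag(S) Vt` to express them on the original
#' standardized phenotypes. Because ordinary least squares is linear in the
#' response and the decomposition is full rank, this recomposition equals
#' fitting the same model directly on each standardized phenotype.
#'
#' @param coeffs numeric matrix of coefficients, terms x k eigentraits.
#' @param dec an `eigentrait_decomposition`.
#' @return matrix of coefficients, terms x phenotypes.
#' @export
recompose_effects <- function(coeffs, dec) {
  coeffs <- as.matrix(coeffs)
  k <- length(dec$S)
  if (ncol(coeffs) != k) {
    stop(sprintf("coefficient matrix has %d columns; decomposition has %d eigentraits",
                 ncol(coeffs), k))
  }
  out <- coeffs %*% (dec$S * dec$Vt)
  colnames(out) <- dec$phenotype_ids
  out
}
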