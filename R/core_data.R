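#' Construct a genotype matrix
#'
#' A `genotype_matrix` holds variant-allele probabilities for a population:
#' rows are samples, columns are variant loci. Values lie in \[0, 1\] (binary
#' 0/1 for fully genotyped crosses), where 0 codes the reference allele
#' (e.g. wild type) and 1 the variant. Missing genotypes are `NA` and are
#' excluded listwise only from fits that use the affected locus.
#'
#' @param values numeric matrix, samples x loci, values in \[0, 1\] or `NA`.
#' @param sample_ids,locus_ids optional identifier vectors; taken from
#'   `dimnames(values)` when omitted.
#' @param reference_note free-text note naming the reference allele.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(values, sample_ids = rownames(values),
                            locus_ids = colnames(values),
                            reference_note = "0 = reference allele, 1 = variant") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(locus_ids)) locus_ids <- paste0("L", seq_len(ncol(values)))
  if (nrow(values) < 2L) stop("genotype matrix needs at least 2 samples")
  if (ncol(values) < 1L) stop("genotype matrix needs at least 1 locus")
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(locus_ids)) {
    stop("duplicate locus id(s): ",
         paste(unique(locus_ids[duplicated(locus_ids)]), collapse = ", "))
  }
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("genotype value outside [0,1] at sample '%s', locus '%s'",
                 sample_ids[bad[1L, 1L]], locus_ids[bad[1L, 2L]]))
  }
  dimnames(values) <- list(sample_ids, locus_ids)
  structure(list(values = values,
                 sample_ids = sample_ids,
                 locus_ids = locus_ids,
                 reference_note = reference_note),
            class = "genotype_matrix")
}

#' Construct a phenotype table
#'
#' Quantitative phenotype measurements prior to standardization: rows are
#' samples, columns are phenotypes. At least two phenotypes are required for
#' influence inference (a single phenotype cannot disambiguate interaction
#' direction); a one-column table loads with `pleiotropy_available = FALSE`.
#'
#' @param values numeric matrix, samples x phenotypes.
#' @param sample_ids,phenotype_ids optional identifier vectors.
#' @return an object of class `phenotype_table`.
#' @export
phenotype_table <- function(values, sample_ids = rownames(values),
                            phenotype_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(phenotype_ids)) phenotype_ids <- paste0("P", seq_len(ncol(values)))
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(phenotype_ids)) stop("duplicate phenotype id(s)")
  dimnames(values) <- list(sample_ids, phenotype_ids)
  pleio <- ncol(values) >= 2L
  if (!pleio) {
    warning("single phenotype: pleiotropy unavailable, influence inference disabled")
  }
  structure(list(values = values,
                 sample_ids = sample_ids,
                 phenotype_ids = phenotype_ids,
                 pleiotropy_available = pleio,
                 n_missing = sum(is.na(values))),
            class = "phenotype_table")
}

#' Construct an expression matrix
#'
#' Gene-expression values as log2 ratios relative to a reference strain:
#' rows are genes, columns are samples.
#'
#' @param values numeric matrix, genes x samples.
#' @param gene_ids,sample_ids optional identifier vectors.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(ncol(values)))
  if (any(!is.finite(values))) stop("expression matrix contains non-finite values")
  if (anyDuplicated(sample_ids)) stop("duplicate sample id(s) in expression matrix")
  if (anyDuplicated(gene_ids)) {
    # average duplicate gene rows on the log2 scale
    values <- rowsum(values, group = gene_ids, reorder = FALSE) /
      as.vector(table(factor(gene_ids, levels = unique(gene_ids))))
    gene_ids <- unique(gene_ids)
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, gene_ids = gene_ids, sample_ids = sample_ids),
            class = "expression_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci (%d missing)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("phenotype_table: %d samples x %d phenotypes\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

# Shared delimited-table reader: TSV by default, comma autodetected from the
# header line; decimal point only.
read_table_guess <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t"
         else if (grepl(",", header, fixed = TRUE)) ","
         else "\t"
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    row.names = NULL, colClasses = "character",
                    stringsAsFactors = FALSE, comment.char = "")
}

parse_numeric_cells <- function(df, path, na_tokens = c("NA", "NaN", "")) {
  ids <- df[[1L]]
  cols <- names(df)[-1L]
  mat <- matrix(NA_real_, nrow = nrow(df), ncol = length(cols),
                dimnames = list(ids, cols))
  for (j in seq_along(cols)) {
    cell <- trimws(df[[j + 1L]])
    missing <- is.na(cell) | cell %in% na_tokens
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!missing & is.na(num))
    if (length(bad) > 0L) {
      stop(sprintf("malformed numeric cell '%s' in %s (row '%s', column '%s')",
                   cell[bad[1L]], basename(path), ids[bad[1L]], cols[j]))
    }
    num[missing] <- NA_real_
    mat[, j] <- num
  }
  mat
}

#' Read a genotype table from a delimited text file
#'
#' Expects a header row of locus identifiers and a first column of sample
#' identifiers; cells are numeric variant-allele probabilities in \[0, 1\]
#' or an `NA` token. Tab-separated by default; comma autodetected.
#'
#' @param path path to the file.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path) {
  mat <- parse_numeric_cells(read_table_guess(path), path)
  genotype_matrix(mat)
}

#' Read a phenotype table from a delimited text file
#'
#' Samples in rows (first column holds sample identifiers), phenotypes in
#' columns, in the declared order.
#'
#' @param path path to the file.
#' @return a [phenotype_table()].
#' @export
read_phenotypes <- function(path) {
  mat <- parse_numeric_cells(read_table_guess(path), path)
  phenotype_table(mat)
}

#' Read an expression matrix from a delimited text file
#'
#' Genes in rows, samples in columns. Rows sharing a gene identifier (e.g.
#' duplicated probes) are averaged on the log2 scale.
#'
#' @param path path to the file.
#' @param population_samples optional character vector of known population
#'   sample ids; expression samples must be a subset.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, population_samples = NULL) {
  mat <- parse_numeric_cells(read_table_guess(path), path)
  if (any(is.na(mat))) stop("expression matrix contains non-numeric or missing cells")
  if (!is.null(population_samples)) {
    unmatched <- setdiff(colnames(mat), population_samples)
    if (length(unmatched) > 0L) {
      stop("expression sample ids not in population: ",
           paste(unmatched, collapse = ", "))
    }
  }
  expression_matrix(mat)
}

#' Write a genotype or phenotype table to TSV
#'
#' Values are written with 12 significant digits so a write/read round trip
#' reproduces them to text precision.
#'
#' @param x a `genotype_matrix` or `phenotype_table`.
#' @param path output path.
#' @param id_column header for the identifier column.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path, id_column = "sample") {
  vals <- x$values
  df <- data.frame(id = rownames(vals),
                   signif(vals, 12L),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotation sets from a GMT file
#'
#' Standard GMT: one term per line, tab-separated `term<TAB>description<TAB>
#' gene1<TAB>gene2...`. Duplicate term identifiers are merged by union with
#' a warning.
#'
#' @param path path to the GMT file.
#' @param category label attached to every term (e.g. `"GO-process"` or
#'   `"TF-target"`).
#' @return an `annotation_sets` object: list with `sets` (named list of
#'   character vectors) and `meta` (data frame of term, description, category).
#' @export
read_annotations <- function(path, category = "GO-process") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty GMT file: no annotation sets")
    return(annotation_sets(list(), category = category))
  }
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT line %d has %d field(s); expected term, description, genes",
                   i, length(fields)))
    }
    term <- fields[1L]
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (term %in% names(sets)) {
      warning(sprintf("duplicate term '%s': sets merged by union", term))
      sets[[term]] <- union(sets[[term]], genes)
    } else {
      sets[[term]] <- genes
      desc[term] <- fields[2L]
    }
  }
  annotation_sets(sets, descriptions = desc, category = category)
}

#' @rdname read_annotations
#' @param sets named list of gene-identifier character vectors.
#' @param descriptions optional named character vector of term descriptions.
#' @export
annotation_sets <- function(sets, descriptions = NULL, category = "GO-process") {
  if (length(sets) == 0L) {
    meta <- data.frame(term = character(), description = character(),
                       category = character(), size = integer(),
                       stringsAsFactors = FALSE)
    return(structure(list(sets = sets, meta = meta), class = "annotation_sets"))
  }
  if (any(lengths(sets) == 0L)) stop("empty annotation set")
  meta <- data.frame(term = names(sets),
                     description = if (is.null(descriptions)) names(sets)
                                   else unname(descriptions[names(sets)]),
                     category = rep_len(category, length(sets)),
                     size = lengths(sets) + 0L,
                     stringsAsFactors = FALSE, row.names = NULL)
  structure(list(sets = sets, meta = meta), class = "annotation_sets")
}

#' Align a genotype matrix and a phenotype table on shared samples
#'
#' @param geno a `genotype_matrix`.
#' @param pheno a `phenotype_table`.
#' @return list with the two objects restricted to shared samples in the
#'   genotype table's order.
#' @export
align_samples <- function(geno, pheno) {
  shared <- intersect(geno$sample_ids, pheno$sample_ids)
  if (length(shared) < 2L) stop("fewer than 2 shared samples between tables")
  list(genotypes = genotype_matrix(geno$values[shared, , drop = FALSE],
                                   reference_note = geno$reference_note),
       phenotypes = phenotype_table(pheno$values[shared, , drop = FALSE]))
}
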