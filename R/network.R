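#' Average variant-to-phenotype effects over pairwise models
#'
#' Every pairwise model containing a variant yields recomposed
#' variant-to-phenotype coefficients for it ([variant_phenotype_effects()]).
#' These are averaged arithmetically per (variant, phenotype) over all
#' contributing models, and the per-model delta-method variances are
#' combined as a root-mean-square error of the mean,
#' `sqrt(mean(var) / n_models)` (an independence approximation: the models
#' share data, so correlation between them is understated).
#'
#' @param vp_list list of data frames from [variant_phenotype_effects()],
#'   one per estimable pair model.
#' @return data frame: `variant`, `phenotype`, `coef` (mean), `rms_se`,
#'   `n_models`, `statistic` (`|coef|/rms_se`).
#' @export
average_effects <- function(vp_list) {
  vp_list <- Filter(Negate(is.null), vp_list)
  if (length(vp_list) == 0L) stop("no estimable pair models to average")
  all_vp <- do.call(rbind, vp_list)
  key <- interaction(all_vp$variant, all_vp$phenotype, drop = TRUE, sep = "\r")
  agg <- lapply(split(all_vp, key), function(d) {
    m <- mean(d$coef)
    rms <- sqrt(mean(d$var) / nrow(d))
    data.frame(variant = d$variant[1L], phenotype = d$phenotype[1L],
               coef = m, rms_se = rms, n_models = nrow(d),
               statistic = if (rms > 0) abs(m) / rms else Inf,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$variant, out$phenotype), , drop = FALSE]
}

#' Assemble the significance-filtered directed influence network
#'
#' Nodes are the variants and phenotypes; edges are (i) variant-to-variant
#' influences, taken directly from each pair's influence coefficients (they
#' are uniquely determined per pair and are not averaged), and (ii) averaged
#' variant-to-phenotype effects. An edge is retained iff its adjusted
#' p-value is below `alpha`; its sign is the sign of the coefficient
#' (negative = suppression, positive = enhancement) and its weight the
#' absolute coefficient.
#'
#' @param influences data frame with columns `from`, `to`, `coef`, `se`,
#'   `p`, `p_adj` for variant-to-variant influences.
#' @param effects data frame with columns `variant`, `phenotype`, `coef`,
#'   `rms_se`, `p`, `p_adj` for averaged variant-to-phenotype effects (may
#'   be `NULL`).
#' @param alpha significance cutoff on adjusted p-values.
#' @return an `influence_network`: list with `nodes` (data frame: `id`,
#'   `type`) and `edges` (data frame: `from`, `to`, `type`, `coef`, `sign`,
#'   `weight`, `se`, `p`, `p_adj`).
#' @export
build_network <- function(influences, effects = NULL, alpha = 0.05) {
  edges <- list()
  if (!is.null(influences) && nrow(influences) > 0L) {
    keep <- !is.na(influences$p_adj) & influences$p_adj < alpha
    if (any(keep)) {
      d <- influences[keep, , drop = FALSE]
      edges[[1L]] <- data.frame(from = d$from, to = d$to,
                                type = "variant-variant",
                                coef = d$coef, sign = sign(d$coef),
                                weight = abs(d$coef), se = d$se,
                                p = d$p, p_adj = d$p_adj,
                                stringsAsFactors = FALSE)
    }
  }
  if (!is.null(effects) && nrow(effects) > 0L) {
    keep <- !is.na(effects$p_adj) & effects$p_adj < alpha
    if (any(keep)) {
      d <- effects[keep, , drop = FALSE]
      edges[[2L]] <- data.frame(from = d$variant, to = d$phenotype,
                                type = "variant-phenotype",
                                coef = d$coef, sign = sign(d$coef),
                                weight = abs(d$coef), se = d$rms_se,
                                p = d$p, p_adj = d$p_adj,
                                stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges) > 0L) do.call(rbind, edges) else
    data.frame(from = character(), to = character(), type = character(),
               coef = numeric(), sign = numeric(), weight = numeric(),
               se = numeric(), p = numeric(), p_adj = numeric(),
               stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  variants <- unique(c(if (!is.null(influences)) c(influences$from, influences$to),
                       if (!is.null(effects)) effects$variant))
  phenos <- if (!is.null(effects)) unique(effects$phenotype) else character()
  nodes <- data.frame(id = c(variants, phenos),
                      type = c(rep("variant", length(variants)),
                               rep("phenotype", length(phenos))),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, alpha = alpha),
            class = "influence_network")
}

#' @export
print.influence_network <- function(x, ...) {
  cat(sprintf("influence_network: %d nodes, %d edges (adjusted p < %g)\n",
              nrow(x$nodes), nrow(x$edges), x$alpha))
  if (nrow(x$edges) > 0L) print(x$edges[, c("from", "to", "type", "coef", "p_adj")])
  invisible(x)
}

#' Write an influence network to file
#'
#' Formats: `"tsv"` (canonical machine-readable edge list plus a node
#' table), `"sif"` (Cytoscape simple-interaction format with labels
#' `activates`/`suppresses`; isolated nodes written as bare lines), and
#' `"graphml"` (via igraph, carrying coefficient, weight, SE and p-values
#' as edge attributes).
#'
#' @param net an [build_network()] result.
#' @param path output file path.
#' @param format one of `"tsv"`, `"sif"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("tsv", "sif", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "sif") {
    lines <- character()
    if (nrow(net$edges) > 0L) {
      lab <- ifelse(net$edges$sign < 0, "suppresses", "activates")
      lines <- paste(net$edges$from, lab, net$edges$to, sep = "\t")
    }
    isolated <- setdiff(net$nodes$id, c(net$edges$from, net$edges$to))
    writeLines(c(lines, isolated), path)
  } else {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Convert an influence network to an igraph graph
#'
#' @param net an [build_network()] result.
#' @return a directed `igraph` graph with node attribute `type` and edge
#'   attributes `type`, `coef`, `sign`, `weight`, `se`, `p`, `p_adj`.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                vertices = net$nodes)
}

#' Read a GraphML influence network back as edge/node tables
#'
#' @param path a GraphML file written by [write_network()].
#' @return list with `nodes` and `edges` data frames.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  edges <- igraph::as_data_frame(g, what = "edges")
  nodes <- igraph::as_data_frame(g, what = "vertices")
  list(nodes = nodes, edges = edges)
}
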