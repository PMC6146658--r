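# Bipartite process-gene network: one-mode projection onto genes with shared
# GO biological-process term counts as weights, family link density, and
# hypergeometric term enrichment with Bonferroni control.

#' One-mode projection of a gene-to-term annotation table
#'
#' Two genes are connected iff they share at least one term; the edge weight
#' is the number of shared terms. Genes with empty term sets stay isolated.
#'
#' @param annotations data.frame with columns `gene_id`, `term` (one row per
#'   annotation); rows for genes outside `genes` are ignored.
#' @param genes character vector of genes to project (nodes of the result).
#' @return undirected weighted igraph over `genes`.
#' @export
go_projection <- function(annotations, genes) {
  ann <- annotations[annotations$gene_id %in% genes, , drop = FALSE]
  terms <- sort(unique(ann$term))
  inc <- matrix(0L, nrow = length(genes), ncol = length(terms),
                dimnames = list(genes, terms))
  if (nrow(ann) > 0)
    inc[cbind(match(ann$gene_id, genes), match(ann$term, terms))] <- 1L
  w <- inc %*% t(inc)
  diag(w) <- 0
  up <- which(upper.tri(w) & w >= 1, arr.ind = TRUE)
  edges <- data.frame(from = genes[up[, 1]], to = genes[up[, 2]],
                      weight = w[up], stringsAsFactors = FALSE)
  graph_from_edges(edges, directed = FALSE, nodes = genes)
}

#' Link density within one family's node set
#'
#' Edges among the family's nodes divided by C(n, 2).
#'
#' @param graph undirected igraph.
#' @param families named character vector (node -> family).
#' @param family family whose density to compute (>= 2 nodes required).
#' @return numeric density in \[0, 1\].
#' @export
family_link_density <- function(graph, families, family) {
  members <- names(families)[families == family]
  members <- intersect(members, igraph::V(graph)$name)
  n <- length(members)
  if (n < 2) stop("family ", family, " has fewer than 2 nodes")
  sub <- igraph::induced_subgraph(graph, members)
  igraph::ecount(sub) / choose(n, 2)
}

#' Hypergeometric GO term enrichment with Bonferroni control
#'
#' One-sided upper-tail hypergeometric p-value per term (successes = genes in
#' the foreground carrying the term), Bonferroni-adjusted by the number of
#' tested terms (terms with at least one foreground gene, by default).
#' A term is enriched iff its adjusted value is <= alpha (inclusive).
#'
#' @param foreground gene set of interest (must be within the universe).
#' @param annotations data.frame with `gene_id`, `term` and optionally `name`.
#' @param alpha adjusted-significance level (default 0.05).
#' @param universe background gene universe; default all annotated genes.
#' @param test_all_terms Bonferroni over all annotated terms instead of only
#'   terms observed in the foreground.
#' @return data.frame: term, n_universe, n_foreground, p_value, p_adjusted,
#'   enriched.
#' @export
go_enrich <- function(foreground, annotations, alpha = 0.05, universe = NULL,
                      test_all_terms = FALSE) {
  if (length(foreground) == 0) stop("empty foreground")
  if (is.null(universe)) universe <- unique(annotations$gene_id)
  if (!all(foreground %in% universe)) stop("foreground outside the universe")
  ann <- unique(annotations[annotations$gene_id %in% universe,
                            c("gene_id", "term"), drop = FALSE])
  N <- length(universe)
  n <- length(unique(foreground))
  by_term <- split(ann$gene_id, ann$term)
  k_fg <- vapply(by_term, function(g) length(intersect(g, foreground)), 0L)
  tested <- if (test_all_terms) names(by_term) else names(by_term)[k_fg > 0]
  if (length(tested) == 0)
    return(data.frame(term = character(0), n_universe = integer(0),
                      n_foreground = integer(0), p_value = numeric(0),
                      p_adjusted = numeric(0), enriched = logical(0)))
  K <- vapply(by_term[tested], length, 0L)
  k <- k_fg[tested]
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  padj <- pmin(1, p * length(tested))
  out <- data.frame(term = tested, n_universe = K, n_foreground = k,
                    p_value = p, p_adjusted = padj,
                    enriched = padj <= alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p_value, out$term), , drop = FALSE]
}
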