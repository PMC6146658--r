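#' @importFrom stats setNames
NULL

#' Build a graph from an edge table
#'
#' Thin constructor around [igraph::graph_from_data_frame()] shared by the
#' three network stages. Self-loops are dropped and duplicate edges collapsed
#' (keeping the maximum weight); the numbers removed are recorded as graph
#' attributes `self_loops_dropped` and `duplicates_collapsed`.
#'
#' @param edges data.frame with columns `from`, `to` and optionally `weight`.
#' @param directed logical; build a directed graph.
#' @param nodes optional character vector of node names (isolated nodes are
#'   kept even if they carry no edge).
#' @return an `igraph` graph.
#' @export
graph_from_edges <- function(edges, directed = FALSE, nodes = NULL) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) > 0 && ncol(edges) < 2)
    stop("edge table needs at least two columns (from, to)")
  if (nrow(edges) == 0) {
    g <- igraph::make_empty_graph(n = 0, directed = directed)
    if (!is.null(nodes)) g <- igraph::add_vertices(g, length(nodes), name = as.character(nodes))
    g <- igraph::set_graph_attr(g, "self_loops_dropped", 0L)
    g <- igraph::set_graph_attr(g, "duplicates_collapsed", 0L)
    return(g)
  }
  from <- as.character(edges[[1]])
  to <- as.character(edges[[2]])
  w <- if (ncol(edges) >= 3) as.numeric(edges[[3]]) else rep(1, length(from))

  loops <- from == to
  n_loops <- sum(loops)
  from <- from[!loops]; to <- to[!loops]; w <- w[!loops]

  if (!directed) {
    swap <- from > to
    tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  }
  key <- paste(from, to, sep = "\r")
  n_dup <- sum(duplicated(key))
  if (n_dup > 0) {
    w <- tapply(w, key, max)
    parts <- strsplit(names(w), "\r", fixed = TRUE)
    from <- vapply(parts, `[`, "", 1L)
    to <- vapply(parts, `[`, "", 2L)
    w <- as.numeric(w)
  }
  verts <- unique(c(from, to, as.character(nodes)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = w, stringsAsFactors = FALSE),
    directed = directed, vertices = data.frame(name = verts, stringsAsFactors = FALSE)
  )
  g <- igraph::set_graph_attr(g, "self_loops_dropped", as.integer(n_loops))
  g <- igraph::set_graph_attr(g, "duplicates_collapsed", as.integer(n_dup))
  g
}

#' Average degree of a graph
#'
#' For an undirected graph returns the scalar 2E/N. For a directed graph the
#' mean in-degree and mean out-degree are both E/N; a named list with both is
#' returned.
#'
#' @param graph an `igraph` graph with at least one node.
#' @return numeric scalar (undirected) or list with `in_degree` and
#'   `out_degree` (directed).
#' @export
average_degree <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0) stop("average degree is undefined for an empty node set")
  e <- igraph::ecount(graph)
  if (igraph::is_directed(graph)) {
    list(in_degree = e / n, out_degree = e / n)
  } else {
    2 * e / n
  }
}

#' Connected components
#'
#' Partition of the node set into connected components (weak connectivity for
#' directed graphs), with the largest component reported.
#'
#' @param graph an `igraph` graph.
#' @return list with `membership` (named integer vector), `sizes`,
#'   `n_components` and `largest_size`.
#' @export
graph_components <- function(graph) {
  comp <- igraph::components(graph, mode = "weak")
  list(
    membership = comp$membership,
    sizes = as.integer(comp$csize),
    n_components = comp$no,
    largest_size = if (comp$no > 0) max(comp$csize) else 0L
  )
}

#' Top-k hub nodes by degree
#'
#' Degrees are unweighted. Ordering is deterministic: degree descending, then
#' node label ascending.
#'
#' @param graph an `igraph` graph.
#' @param k number of hubs to report (k >= 1; truncated at the node count).
#' @param mode degree mode: "all" (default), "in" or "out" (directed graphs).
#' @return data.frame with columns `node` and `degree`.
#' @export
hub_report <- function(graph, k, mode = c("all", "in", "out")) {
  mode <- match.arg(mode)
  stopifnot(k >= 1)
  deg <- igraph::degree(graph, mode = mode)
  labels <- names(deg)
  ord <- order(-deg, labels)
  top <- utils::head(ord, k)
  data.frame(node = labels[top], degree = as.integer(deg[top]),
             row.names = NULL, stringsAsFactors = FALSE)
}
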