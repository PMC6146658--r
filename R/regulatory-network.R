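# Directed regulatory-graph analysis: homolog-based DEG label transfer,
# focal subnetwork extraction, triangle-motif counting, network intersection
# and downstream-response summaries.

#' Transfer DEG labels across a homology map
#'
#' A node is labelled DEG-for-treatment iff at least one of its homology
#' partners is a DEG under that treatment (OR over partners; many-to-many
#' maps are allowed). Unmapped nodes stay unlabelled.
#'
#' @param graph igraph over the target species' genes.
#' @param map data.frame with columns `node` (target-species gene) and
#'   `partner` (source-species gene).
#' @param calls DEG-call data.frame (gene_id, treatment, is_deg) for the
#'   source species.
#' @return data.frame of labels: node, treatment.
#' @export
transfer_deg_labels <- function(graph, map, calls) {
  deg <- calls[calls$is_deg, c("gene_id", "treatment"), drop = FALSE]
  merged <- merge(map, deg, by.x = "partner", by.y = "gene_id")
  merged <- merged[merged$node %in% igraph::V(graph)$name, , drop = FALSE]
  out <- unique(merged[, c("node", "treatment"), drop = FALSE])
  out <- out[order(out$node, out$treatment), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Induced subgraph on a focal gene set, with its one-step shell
#'
#' @param graph igraph.
#' @param focal character vector of focal genes; members missing from the
#'   graph are dropped with a message.
#' @return list: `induced` (subgraph on focal), `shell` (subgraph on focal
#'   plus direct neighbors), `degrees` (per focal node; in/out for directed
#'   graphs).
#' @export
focal_subnetwork <- function(graph, focal) {
  if (length(focal) == 0) stop("empty focal set")
  present <- intersect(focal, igraph::V(graph)$name)
  missing <- setdiff(focal, present)
  if (length(missing) > 0)
    message(length(missing), " focal gene(s) absent from the graph")
  if (length(present) == 0) stop("no focal gene present in the graph")
  induced <- igraph::induced_subgraph(graph, present)
  nbrs <- unique(unlist(lapply(
    igraph::adjacent_vertices(graph, present, mode = "all"),
    function(v) v$name)))
  shell <- igraph::induced_subgraph(graph, union(present, nbrs))
  degrees <- if (igraph::is_directed(graph)) {
    data.frame(node = present,
               in_degree = as.integer(igraph::degree(graph, present, mode = "in")),
               out_degree = as.integer(igraph::degree(graph, present, mode = "out")),
               stringsAsFactors = FALSE)
  } else {
    data.frame(node = present,
               degree = as.integer(igraph::degree(graph, present)),
               stringsAsFactors = FALSE)
  }
  list(induced = induced, shell = shell, degrees = degrees)
}

#' Count triangle motifs
#'
#' Triangles are counted on the underlying undirected skeleton (a node triple
#' counts iff all three pairs are connected in at least one direction). For
#' directed graphs each triangle is also classified by orientation: `cyclic`
#' (a directed 3-cycle of single edges), `feed_forward` (single edges, not
#' cyclic), or `with_mutual` (at least one mutually regulated pair).
#'
#' @param graph igraph.
#' @return list: `count`, `triples` (3-column matrix of node names), and
#'   `orientation` (named counts, directed graphs only).
#' @export
count_triangles_motifs <- function(graph) {
  skel <- igraph::as_undirected(graph, mode = "collapse")
  tri <- igraph::triangles(skel)
  n_tri <- length(tri) / 3
  if (n_tri == 0)
    return(list(count = 0L,
                triples = matrix(character(0), ncol = 3),
                orientation = NULL))
  triples <- matrix(tri$name, ncol = 3, byrow = TRUE)
  orientation <- NULL
  if (igraph::is_directed(graph)) {
    cls <- apply(triples, 1, function(v) {
      has <- function(a, b) igraph::are_adjacent(graph, a, b)
      mut <- sum(has(v[1], v[2]) && has(v[2], v[1]),
                 has(v[2], v[3]) && has(v[3], v[2]),
                 has(v[1], v[3]) && has(v[3], v[1]))
      if (mut > 0) return("with_mutual")
      cyc <- (has(v[1], v[2]) && has(v[2], v[3]) && has(v[3], v[1])) ||
             (has(v[2], v[1]) && has(v[3], v[2]) && has(v[1], v[3]))
      if (cyc) "cyclic" else "feed_forward"
    })
    orientation <- table(factor(cls, levels = c("cyclic", "feed_forward", "with_mutual")))
  }
  list(count = as.integer(n_tri), triples = triples, orientation = orientation)
}

#' Intersection of two undirected networks
#'
#' Edge set = intersection of the two edge sets; directed inputs are
#' symmetrized first (with a message). Reports the shared-edge count and the
#' induced node set.
#'
#' @param g1,g2 igraph graphs.
#' @return list: `graph` (edges common to both, over the union of node sets),
#'   `n_edges`, `nodes` (nodes incident to a shared edge), `n_nodes`.
#' @export
intersect_networks <- function(g1, g2) {
  sym <- function(g) {
    if (igraph::is_directed(g)) {
      message("symmetrizing a directed input for edge intersection")
      g <- igraph::as_undirected(g, mode = "collapse")
    }
    g
  }
  g1 <- sym(g1); g2 <- sym(g2)
  keyset <- function(g) {
    df <- igraph::as_data_frame(g, what = "edges")
    paste(pmin(df$from, df$to), pmax(df$from, df$to), sep = "\r")
  }
  common <- intersect(keyset(g1), keyset(g2))
  parts <- strsplit(common, "\r", fixed = TRUE)
  edges <- data.frame(from = vapply(parts, `[`, "", 1L),
                      to = vapply(parts, `[`, "", 2L),
                      stringsAsFactors = FALSE)
  nodes <- union(igraph::V(g1)$name, igraph::V(g2)$name)
  g <- graph_from_edges(edges, directed = FALSE, nodes = nodes)
  inc <- unique(c(edges$from, edges$to))
  list(graph = g, n_edges = nrow(edges), nodes = sort(inc), n_nodes = length(inc))
}

#' Downstream DEG-target summary per regulator family
#'
#' For each family, the number of distinct out-neighbors of its member
#' regulators that carry a transferred DEG label, overall and per treatment
#' (a target regulated by two same-family regulators counts once).
#'
#' @param graph directed igraph.
#' @param labels label data.frame from [transfer_deg_labels()].
#' @param regulators data.frame with columns `gene_id`, `family`.
#' @return list: `overall` (named counts per family) and `per_treatment`
#'   (family x treatment counts with per-family fractions).
#' @export
downstream_response_summary <- function(graph, labels, regulators) {
  stopifnot(igraph::is_directed(graph))
  fams <- sort(unique(regulators$family))
  trts <- sort(unique(labels$treatment))
  deg_nodes <- unique(labels$node)
  overall <- setNames(integer(length(fams)), fams)
  per_trt <- matrix(0L, length(fams), length(trts), dimnames = list(fams, trts))
  for (f in fams) {
    regs <- intersect(regulators$gene_id[regulators$family == f],
                      igraph::V(graph)$name)
    if (length(regs) == 0) next
    targets <- unique(unlist(lapply(
      igraph::adjacent_vertices(graph, regs, mode = "out"),
      function(v) v$name)))
    hit <- intersect(targets, deg_nodes)
    overall[f] <- length(hit)
    for (t in trts)
      per_trt[f, t] <- length(intersect(targets, labels$node[labels$treatment == t]))
  }
  fractions <- per_trt / pmax(1L, overall)
  list(overall = overall, per_treatment = per_trt, fractions = fractions)
}
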