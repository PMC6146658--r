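# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive double/triple loops and stay independent of
# the code paths they verify.

oracle_gcc_matrix <- function(m, rho = 0.5) {
  ng <- nrow(m)
  nk <- ncol(m)
  r <- matrix(1, ng, ng, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(ng)) {
    others <- setdiff(seq_len(ng), i)
    diffs <- numeric(0)
    for (j in others)
      for (k in seq_len(nk)) diffs <- c(diffs, abs(m[i, k] - m[j, k]))
    gmin <- min(diffs)
    gmax <- max(diffs)
    for (j in others) {
      xi <- numeric(nk)
      for (k in seq_len(nk)) {
        d <- abs(m[i, k] - m[j, k])
        xi[k] <- if (gmax == 0) 1 else (gmin + rho * gmax) / (d + rho * gmax)
      }
      r[i, j] <- mean(xi)
    }
  }
  r
}

oracle_triangle_count <- function(graph) {
  skel <- igraph::as_undirected(graph, mode = "collapse")
  nodes <- igraph::V(skel)$name
  if (length(nodes) < 3) return(0L)
  count <- 0L
  trip <- utils::combn(nodes, 3)
  for (c_i in seq_len(ncol(trip))) {
    v <- trip[, c_i]
    if (igraph::are_adjacent(skel, v[1], v[2]) &&
        igraph::are_adjacent(skel, v[2], v[3]) &&
        igraph::are_adjacent(skel, v[1], v[3]))
      count <- count + 1L
  }
  count
}

oracle_projection_weights <- function(annotations, genes) {
  term_sets <- lapply(genes, function(g)
    unique(annotations$term[annotations$gene_id == g]))
  names(term_sets) <- genes
  out <- list()
  for (i in seq_along(genes)) {
    for (j in seq_along(genes)) {
      if (j <= i) next
      w <- length(intersect(term_sets[[i]], term_sets[[j]]))
      if (w >= 1)
        out[[length(out) + 1L]] <- data.frame(
          from = min(genes[i], genes[j]), to = max(genes[i], genes[j]),
          weight = w, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(from = character(0), to = character(0), weight = numeric(0)))
  df <- do.call(rbind, out)
  df[order(df$from, df$to), , drop = FALSE]
}

# small random fixtures
random_rel_matrix <- function(ng, nt = 5) {
  m <- matrix(stats::rnorm(ng * nt, 0, 2), ng, nt)
  rownames(m) <- sprintf("g%02d", seq_len(ng))
  colnames(m) <- paste0("t", seq_len(nt))
  m
}

random_digraph <- function(n, n_edges) {
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  idx <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
  graph_from_edges(pairs[idx, ], directed = TRUE, nodes = nodes)
}

edge_key_set <- function(graph) {
  df <- igraph::as_data_frame(graph, what = "edges")
  sort(paste(pmin(df$from, df$to), pmax(df$from, df$to)))
}

reported_counts <- function() {
  path <- system.file("extdata", "reported_family_counts.tsv",
                      package = "tfstressnet")
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
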