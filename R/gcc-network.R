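# Grey relational analysis: the grey correlation coefficient (GCC) between
# short expression profiles, the asymmetric pairwise GCC matrix, and the
# thresholded co-expression network.
#
# For a reference profile x0 and comparison profile xi of length n, the
# pointwise coefficient is
#   xi_i(k) = (gmin + rho * gmax) / (|x0(k) - xi(k)| + rho * gmax)
# where gmin and gmax are the global extrema of |x0(k) - xi(k)| over the whole
# comparison set for that reference, and rho is the resolution ratio (0.5 by
# default). The overall GCC r_0i is the mean of xi_i(k) over k. The matrix is
# generally asymmetric because the extrema are recomputed per reference row.

#' Pointwise grey correlation coefficients
#'
#' @param x0 reference profile.
#' @param xi comparison profile (same length).
#' @param global_min,global_max extrema of |x0(k) - xi(k)| over the full
#'   comparison set for this reference (global_max >= global_min >= 0).
#' @param rho resolution ratio, > 0 (default 0.5).
#' @return numeric vector of pointwise coefficients. When `global_max` is 0
#'   (all profiles identical to the reference) the coefficient is 1 by
#'   convention.
#' @export
gcc_pointwise <- function(x0, xi, global_min, global_max, rho = 0.5) {
  if (length(x0) != length(xi)) stop("profiles differ in length")
  if (rho < 0) stop("rho must be non-negative")
  if (global_max < global_min || global_min < 0)
    stop("need global_max >= global_min >= 0")
  if (global_max == 0) return(rep(1, length(x0)))
  d <- abs(x0 - xi)
  (global_min + rho * global_max) / (d + rho * global_max)
}

#' Overall grey correlation coefficient
#'
#' Arithmetic mean of the pointwise coefficients.
#'
#' @param xi_values nonempty vector of pointwise coefficients.
#' @return scalar in (0, 1].
#' @export
gcc_overall <- function(xi_values) {
  if (length(xi_values) == 0) stop("empty coefficient vector")
  mean(xi_values)
}

#' Pairwise grey correlation matrix
#'
#' Each gene serves in turn as the reference; the global extrema are
#' recomputed per reference row over all other genes (the reference itself is
#' excluded from the comparison set). The diagonal is 1 by definition.
#'
#' @param rel gene x condition matrix of relative expression (log2FC); any
#'   numeric matrix with >= 2 rows works.
#' @param rho resolution ratio.
#' @return list of class `grey_matrix`: `r` (square, generally asymmetric),
#'   `rho`, `n` (profile length).
#' @export
gcc_matrix <- function(rel, rho = 0.5) {
  m <- unclass(rel)
  if (!is.matrix(m) || nrow(m) < 2) stop("need a matrix with >= 2 genes")
  if (any(!is.finite(m))) stop("non-finite relative expression")
  ng <- nrow(m)
  r <- matrix(1, ng, ng, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(ng)) {
    d <- abs(sweep(m[-i, , drop = FALSE], 2, m[i, ]))  # |x_0(k) - x_j(k)|
    gmin <- min(d); gmax <- max(d)
    if (gmax == 0) {
      r[i, -i] <- 1
    } else {
      xi <- (gmin + rho * gmax) / (d + rho * gmax)
      r[i, -i] <- rowMeans(xi)
    }
  }
  structure(list(r = r, rho = rho, n = ncol(m)), class = "grey_matrix")
}

#' Build the thresholded co-expression network
#'
#' An undirected edge \{i, j\} is set iff r_ij >= tau OR r_ji >= tau, with
#' weight max\{r_ij, r_ji\} and a `reciprocal` flag when both directions pass.
#' Reported metrics include the number of ordered (directed-qualifying) pairs,
#' since one undirected edge corresponds to one or two qualifying directions.
#'
#' @param grey a `grey_matrix` from [gcc_matrix()] (or a plain square matrix).
#' @param tau edge threshold in (0, 1] (default 0.94).
#' @return list: `graph` (undirected weighted igraph with edge attribute
#'   `reciprocal`) and `metrics` (n_nodes, n_edges, n_directed_qualifying,
#'   n_reciprocal, average_degree, n_components, largest_component).
#' @export
build_coexpression <- function(grey, tau = 0.94) {
  r <- if (inherits(grey, "grey_matrix")) grey$r else grey
  stopifnot(is.matrix(r), nrow(r) == ncol(r))
  if (tau <= 0) stop("tau must be in (0, 1]")
  ng <- nrow(r)
  labels <- rownames(r)
  if (is.null(labels)) labels <- as.character(seq_len(ng))
  qual <- r >= tau; diag(qual) <- FALSE
  n_directed <- sum(qual)
  up <- which(upper.tri(r) & (qual | t(qual)), arr.ind = TRUE)
  edges <- data.frame(
    from = labels[up[, 1]], to = labels[up[, 2]],
    weight = pmax(r[up], t(r)[up]),
    stringsAsFactors = FALSE
  )
  recip <- qual[up] & t(qual)[up]
  g <- graph_from_edges(edges, directed = FALSE, nodes = labels)
  if (igraph::ecount(g) > 0) {
    # graph_from_edges may reorder; align the reciprocal flag by edge key
    key_in <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    gdf <- igraph::as_data_frame(g, what = "edges")
    key_g <- paste(pmin(gdf$from, gdf$to), pmax(gdf$from, gdf$to))
    g <- igraph::set_edge_attr(g, "reciprocal", value = recip[match(key_g, key_in)])
  }
  comp <- graph_components(g)
  list(graph = g, metrics = list(
    n_nodes = ng,
    n_edges = igraph::ecount(g),
    n_directed_qualifying = n_directed,
    n_reciprocal = sum(recip),
    average_degree = average_degree(g),
    n_components = comp$n_components,
    largest_component = comp$largest_size
  ))
}

#' Within- vs between-family relative edge density
#'
#' (within-family edges / within-family possible pairs) divided by
#' (between-family edges / between-family possible pairs). A zero
#' between-density with positive within-density is reported as `Inf`;
#' undefined denominators give `NA` with a `reason` attribute.
#'
#' @param graph undirected igraph whose nodes are all labelled in `families`.
#' @param families named character vector (node -> family).
#' @return numeric ratio (possibly Inf/NA) with attributes `within_density`
#'   and `between_density`.
#' @export
family_density_ratio <- function(graph, families) {
  nodes <- igraph::V(graph)$name
  if (!all(nodes %in% names(families))) stop("every node must be labelled")
  fam <- families[nodes]
  if (length(unique(fam)) < 2)
    stop("between-family density undefined with a single family")
  n_by <- table(fam)
  within_pairs <- sum(choose(n_by, 2))
  total_pairs <- choose(length(nodes), 2)
  between_pairs <- total_pairs - within_pairs
  ee <- igraph::as_data_frame(graph, what = "edges")
  w_edges <- sum(fam[ee$from] == fam[ee$to])
  b_edges <- nrow(ee) - w_edges
  if (within_pairs == 0 || between_pairs == 0) {
    out <- NA_real_
    attr(out, "reason") <- "no within- or between-family pairs"
    return(out)
  }
  wd <- w_edges / within_pairs
  bd <- b_edges / between_pairs
  ratio <- if (bd == 0 && wd > 0) Inf else if (bd == 0) NA_real_ else wd / bd
  attr(ratio, "within_density") <- wd
  attr(ratio, "between_density") <- bd
  ratio
}

#' Spearman correlation between node degree and expression magnitude
#'
#' Per treatment, the Spearman rank correlation between the degree of each
#' network node and its |log2 relative expression|, with ties mid-ranked.
#' A constant degree sequence is reported as NA with a flag.
#'
#' @param graph igraph whose node names appear in `rel`.
#' @param rel relative-expression matrix.
#' @return data.frame: treatment, spearman_rho, defined.
#' @export
degree_expression_correlation <- function(graph, rel) {
  nodes <- igraph::V(graph)$name
  if (!all(nodes %in% rownames(rel))) stop("graph nodes missing from expression")
  deg <- igraph::degree(graph)
  out <- lapply(colnames(rel), function(t) {
    x <- abs(rel[nodes, t])
    if (length(unique(deg)) < 2 || length(unique(x)) < 2)
      return(data.frame(treatment = t, spearman_rho = NA_real_, defined = FALSE))
    data.frame(treatment = t,
               spearman_rho = suppressWarnings(
                 stats::cor(deg, x, method = "spearman")),
               defined = TRUE, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
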