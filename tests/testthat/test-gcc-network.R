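test_that("gcc_pointwise matches the hand-evaluated formula", {
  # reference (1,2,3); comparison set {(2,2,2), (1,2,3)}: global_min = 0,
  # global_max = 1; for (2,2,2) deviations are (1,0,1) so xi = (1/3, 1, 1/3)
  xi <- gcc_pointwise(c(1, 2, 3), c(2, 2, 2), global_min = 0, global_max = 1,
                      rho = 0.5)
  expect_equal(xi, c(1/3, 1, 1/3))
  expect_equal(gcc_overall(xi), 5/9)
  # identical profiles with zero global min: all coefficients 1
  expect_equal(gcc_pointwise(c(1, 2), c(1, 2), 0, 1), c(1, 1))
  # all-identical comparison set (global_max = 0): xi == 1 by convention
  expect_equal(gcc_pointwise(c(1, 2), c(1, 2), 0, 0), c(1, 1))
  expect_error(gcc_pointwise(1:3, 1:2, 0, 1), "length")
  expect_error(gcc_overall(numeric(0)), "empty")
})

test_that("gcc_matrix equals the naive direct-formula oracle", {
  withr::with_seed(101, {
    for (rep in 1:10) {
      m <- random_rel_matrix(sample(3:15, 1))
      got <- gcc_matrix(m, rho = 0.5)$r
      expect_equal(got, oracle_gcc_matrix(m, rho = 0.5), tolerance = 1e-12)
    }
  })
})

test_that("gcc_matrix basic properties: identical genes, asymmetry, bounds, translation invariance", {
  m <- rbind(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5), c = c(9, 1, 4, 0, 2))
  colnames(m) <- paste0("t", 1:5)
  r <- gcc_matrix(m)$r
  expect_equal(unname(r["a", "b"]), 1)
  expect_equal(unname(r["b", "a"]), 1)
  expect_equal(unname(diag(r)), rep(1, 3))
  # entries in (0, 1]; rows with a zero-attaining global min stay >= 1/3
  expect_true(all(r > 0 & r <= 1))
  expect_true(all(r[c("a", "b"), ] >= 1/3))
  # asymmetry on a random fixture
  withr::with_seed(55, {
    m2 <- random_rel_matrix(8)
    r2 <- gcc_matrix(m2)$r
    expect_gt(max(abs(r2 - t(r2))), 1e-6)
    # translation invariance
    r3 <- gcc_matrix(m2 + 7)$r
    expect_equal(r3, r2, tolerance = 1e-12)
  })
  expect_error(gcc_matrix(rbind(a = c(1, NA), b = c(2, 3))), "non-finite")
})

test_that("build_coexpression applies the OR/max edge rule", {
  r <- matrix(c(1, 0.95, 0.90, 1), 2, 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("g1", "g2")))
  net <- build_coexpression(r, tau = 0.94)
  expect_equal(igraph::ecount(net$graph), 1)
  df <- igraph::as_data_frame(net$graph)
  expect_equal(df$weight, 0.95)
  expect_false(df$reciprocal)
  expect_equal(net$metrics$n_directed_qualifying, 1)
  # reciprocal edge counted once undirected, twice directed
  r2 <- matrix(c(1, 0.95, 0.96, 1), 2, 2, byrow = TRUE,
               dimnames = list(c("g1", "g2"), c("g1", "g2")))
  net2 <- build_coexpression(r2, tau = 0.94)
  expect_true(igraph::as_data_frame(net2$graph)$reciprocal)
  expect_equal(net2$metrics$n_directed_qualifying, 2)
  # impossible threshold: empty edge set, degree 0
  net3 <- build_coexpression(r2, tau = 1)
  expect_equal(net3$metrics$n_edges, 0)
  expect_equal(net3$metrics$average_degree, 0)
})

test_that("edge count is monotone nonincreasing in tau", {
  withr::with_seed(77, {
    m <- random_rel_matrix(12)
    grey <- gcc_matrix(m)
    taus <- c(0.5, 0.7, 0.9, 0.94, 0.99)
    edges <- vapply(taus, function(t) build_coexpression(grey, t)$metrics$n_edges, 0)
    expect_true(all(diff(edges) <= 0))
  })
})

test_that("family_density_ratio matches brute-force pair counting", {
  # complete graph: ratio 1
  nodes <- c("a1", "a2", "b1", "b2")
  fams <- stats::setNames(c("A", "A", "B", "B"), nodes)
  cmb <- utils::combn(nodes, 2)
  complete <- graph_from_edges(data.frame(from = cmb[1, ], to = cmb[2, ]))
  expect_equal(as.numeric(family_density_ratio(complete, fams)), 1)
  # two cliques, no cross edges: infinite ratio
  cliques <- graph_from_edges(data.frame(from = c("a1", "b1"), to = c("a2", "b2")))
  expect_equal(as.numeric(family_density_ratio(cliques, fams)), Inf)
  expect_error(family_density_ratio(cliques, stats::setNames(rep("A", 4), nodes)),
               "single family")
  # random fixture vs enumeration
  withr::with_seed(3, {
    g <- igraph::as_undirected(random_digraph(10, 18), mode = "collapse")
    fam <- stats::setNames(sample(c("X", "Y"), 10, TRUE), igraph::V(g)$name)
    while (length(unique(fam)) < 2)
      fam <- stats::setNames(sample(c("X", "Y"), 10, TRUE), igraph::V(g)$name)
    ratio <- family_density_ratio(g, fam)
    prs <- utils::combn(igraph::V(g)$name, 2)
    w_e <- w_p <- b_e <- b_p <- 0
    for (i in seq_len(ncol(prs))) {
      same <- fam[prs[1, i]] == fam[prs[2, i]]
      adj <- igraph::are_adjacent(g, prs[1, i], prs[2, i])
      if (same) { w_p <- w_p + 1; w_e <- w_e + adj }
      else { b_p <- b_p + 1; b_e <- b_e + adj }
    }
    expect_equal(as.numeric(ratio), (w_e / w_p) / (b_e / b_p))
  })
})

test_that("degree_expression_correlation ranks with ties mid-ranked", {
  # 6-node path-ish fixture with hand-computable ranks
  g <- graph_from_edges(data.frame(from = c("a", "a", "a", "b", "c"),
                                   to = c("b", "c", "d", "c", "e")))
  g <- igraph::add_vertices(g, 1, name = "f")
  rel <- matrix(c(3, 2.5, 2, 1.5, 1, 0.5), 6, 1,
                dimnames = list(c("a", "b", "c", "d", "e", "f"), "cold"))
  out <- degree_expression_correlation(g, rel)
  # degrees: a=3 b=2 c=3 d=1 e=1 f=0; |rel| strictly decreasing
  deg <- c(3, 2, 3, 1, 1, 0)
  expect_equal(out$spearman_rho,
               stats::cor(rank(deg), rank(c(3, 2.5, 2, 1.5, 1, 0.5)),
                          method = "pearson"))
  # perfectly monotone planted relation (rank-identical, ties mid-ranked) -> rho 1
  star <- graph_from_edges(data.frame(from = rep("h", 3), to = c("x", "y", "z")))
  rel2 <- matrix(c(9, 1, 1, 1), 4, 1, dimnames = list(c("h", "x", "y", "z"), "t"))
  expect_equal(degree_expression_correlation(star, rel2)$spearman_rho, 1)
  # constant degree flagged as undefined
  pair <- graph_from_edges(data.frame(from = "u", to = "v"))
  rel4 <- matrix(c(1, 2), 2, 1, dimnames = list(c("u", "v"), "t"))
  out4 <- degree_expression_correlation(pair, rel4)
  expect_false(out4$defined)
  expect_true(is.na(out4$spearman_rho))
})

test_that("planted co-expression clusters are recovered at zero noise (ARI = 1)", {
  cfg <- synth_config(n_genes_per_family = 12, noise_sd = 0, seed = 23)
  inv <- generate_inventory(cfg)
  ex <- generate_expression(cfg, inv)
  net <- build_coexpression(gcc_matrix(relative_expression(ex$em)), tau = 0.94)
  comp <- graph_components(net$graph)
  ari <- adjusted_rand_index(comp$membership[names(ex$truth$cluster)],
                             ex$truth$cluster)
  expect_equal(ari, 1)
})
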