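test_that("transfer_deg_labels ORs over homology partners", {
  g <- graph_from_edges(data.frame(from = "AT1", to = "AT2"), directed = TRUE,
                        nodes = c("AT1", "AT2", "AT3"))
  map <- data.frame(node = c("AT1", "AT2", "AT2"),
                    partner = c("Bn1", "Bn2", "Bn3"), stringsAsFactors = FALSE)
  calls <- data.frame(gene_id = c("Bn1", "Bn2", "Bn3"),
                      treatment = c("cold", "salt", "heat"),
                      is_deg = c(TRUE, FALSE, TRUE), stringsAsFactors = FALSE)
  labels <- transfer_deg_labels(g, map, calls)
  expect_equal(labels$treatment[labels$node == "AT1"], "cold")
  # two partners, one heat DEG -> heat label via OR
  expect_equal(labels$treatment[labels$node == "AT2"], "heat")
  # unmapped node gets nothing
  expect_false("AT3" %in% labels$node)
  # monotone: adding pairs never removes labels
  map2 <- rbind(map, data.frame(node = "AT3", partner = "Bn1"))
  labels2 <- transfer_deg_labels(g, map2, calls)
  expect_true(all(paste(labels$node, labels$treatment) %in%
                  paste(labels2$node, labels2$treatment)))
})

test_that("focal_subnetwork induces the right edge sets and degrees", {
  g <- graph_from_edges(data.frame(from = c("hub", "hub", "hub", "x"),
                                   to = c("a", "b", "c", "hub")),
                        directed = TRUE)
  # focal = all nodes: subgraph == graph
  all_sub <- focal_subnetwork(g, igraph::V(g)$name)
  expect_equal(igraph::ecount(all_sub$induced), igraph::ecount(g))
  # star leaves: no induced edges, shell pulls the hub back in
  leaves <- focal_subnetwork(g, c("a", "b", "c"))
  expect_equal(igraph::ecount(leaves$induced), 0)
  expect_setequal(igraph::V(leaves$shell)$name, c("a", "b", "c", "hub"))
  expect_equal(leaves$degrees$in_degree, c(1L, 1L, 1L))
  expect_message(focal_subnetwork(g, c("a", "ghost")), "absent")
  expect_error(focal_subnetwork(g, character(0)), "empty")
  # brute-force edge filter agreement on a random fixture
  withr::with_seed(61, {
    rg <- random_digraph(12, 30)
    focal <- sample(igraph::V(rg)$name, 6)
    sub <- focal_subnetwork(rg, focal)$induced
    df <- igraph::as_data_frame(rg)
    keep <- df$from %in% focal & df$to %in% focal
    expect_setequal(paste(igraph::as_data_frame(sub)$from,
                          igraph::as_data_frame(sub)$to),
                    paste(df$from[keep], df$to[keep]))
  })
})

test_that("count_triangles_motifs counts skeleton triangles with orientation classes", {
  empty <- graph_from_edges(data.frame(from = character(0), to = character(0)),
                            directed = TRUE, nodes = c("a", "b"))
  expect_equal(count_triangles_motifs(empty)$count, 0L)
  # complete graph on 4 nodes: C(4,3) = 4 triangles
  cmb <- utils::combn(letters[1:4], 2)
  k4 <- graph_from_edges(data.frame(from = cmb[1, ], to = cmb[2, ]))
  expect_equal(count_triangles_motifs(k4)$count, 4L)
  # orientation classes: cycle, feed-forward, mutual pair
  cyc <- graph_from_edges(data.frame(from = c("a", "b", "c"),
                                     to = c("b", "c", "a")), directed = TRUE)
  expect_equal(unname(count_triangles_motifs(cyc)$orientation["cyclic"]), 1L)
  ffl <- graph_from_edges(data.frame(from = c("a", "a", "b"),
                                     to = c("b", "c", "c")), directed = TRUE)
  expect_equal(unname(count_triangles_motifs(ffl)$orientation["feed_forward"]), 1L)
  mut <- graph_from_edges(data.frame(from = c("a", "b", "b", "c"),
                                     to = c("b", "a", "c", "a")), directed = TRUE)
  expect_equal(unname(count_triangles_motifs(mut)$orientation["with_mutual"]), 1L)
})

test_that("triangle counter agrees with cubic brute force on random digraphs", {
  withr::with_seed(71, {
    for (rep in 1:5) {
      g <- random_digraph(sample(8:20, 1), sample(15:60, 1))
      expect_equal(count_triangles_motifs(g)$count, oracle_triangle_count(g))
    }
  })
})

test_that("planted triangles are recovered exactly from the synthetic regulatory graph", {
  cfg <- synth_config(n_genes_per_family = 15, n_triangles = 6, seed = 37)
  inv <- generate_inventory(cfg)
  gr <- generate_go_and_regulatory(cfg, inv)
  out <- count_triangles_motifs(gr$regulatory)
  expect_equal(out$count, gr$truth$n_triangles)
  expect_equal(out$count, oracle_triangle_count(gr$regulatory))
})

test_that("intersect_networks is commutative, idempotent and matches set algebra", {
  g1 <- graph_from_edges(data.frame(from = c("a", "b", "c"), to = c("b", "c", "d")))
  same <- intersect_networks(g1, g1)
  expect_equal(same$n_edges, 3)
  disjoint <- graph_from_edges(data.frame(from = "x", to = "y"))
  expect_equal(intersect_networks(g1, disjoint)$n_edges, 0)
  withr::with_seed(83, {
    a <- igraph::as_undirected(random_digraph(10, 20), mode = "collapse")
    b <- igraph::as_undirected(random_digraph(10, 20), mode = "collapse")
    ab <- intersect_networks(a, b)
    ba <- intersect_networks(b, a)
    expect_setequal(edge_key_set(ab$graph), edge_key_set(ba$graph))
    expect_setequal(edge_key_set(ab$graph),
                    intersect(edge_key_set(a), edge_key_set(b)))
    # idempotent
    expect_setequal(edge_key_set(intersect_networks(ab$graph, ab$graph)$graph),
                    edge_key_set(ab$graph))
  })
  # directed inputs symmetrized with a message
  dg <- graph_from_edges(data.frame(from = "a", to = "b"), directed = TRUE)
  expect_message(out <- intersect_networks(dg, g1), "symmetrizing")
  expect_equal(out$n_edges, 1)
})

test_that("downstream_response_summary counts distinct DEG targets per family", {
  g <- graph_from_edges(data.frame(
    from = c("tf1", "tf2", "tf1", "tf3"),
    to = c("x", "x", "y", "z")), directed = TRUE)
  regulators <- data.frame(gene_id = c("tf1", "tf2", "tf3"),
                           family = c("MYB", "MYB", "WRKY"),
                           stringsAsFactors = FALSE)
  labels <- data.frame(node = c("x", "y"), treatment = c("cold", "cold"),
                       stringsAsFactors = FALSE)
  out <- downstream_response_summary(g, labels, regulators)
  # x regulated by two MYBs counts once; z is not DEG-labeled
  expect_equal(unname(out$overall["MYB"]), 2L)
  expect_equal(unname(out$overall["WRKY"]), 0L)
  expect_equal(out$per_treatment["MYB", "cold"], 2L)
  # regulator with no out-edges contributes 0
  reg2 <- rbind(regulators, data.frame(gene_id = "z", family = "NAC"))
  out2 <- downstream_response_summary(g, labels, reg2)
  expect_equal(unname(out2$overall["NAC"]), 0L)
})
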