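toy_em <- function(fpkm, conds, reps) {
  samples <- data.frame(
    sample = colnames(fpkm),
    condition = rep(conds, times = reps),
    replicate = unlist(lapply(reps, seq_len)), stringsAsFactors = FALSE)
  expression_matrix(fpkm, samples)
}

test_that("relative_expression computes log2 mean ratios with pseudocount", {
  m <- rbind(flat = c(10, 10, 10, 10), up4 = c(1000, 1000, 4000, 4000))
  colnames(m) <- c("control_r1", "control_r2", "cold_r1", "cold_r2")
  em <- toy_em(m, c("control", "cold"), c(2, 2))
  rel <- relative_expression(em, pseudocount = 1)
  expect_equal(unname(rel["flat", "cold"]), 0)
  expect_equal(unname(rel["up4", "cold"]), 2, tolerance = 1e-3)
  expect_error(relative_expression(em, pseudocount = 0))
})

test_that("noise_probability is 0 at no change, 1 at full dominance, and matches hand enumeration", {
  # 3 genes, control/treat with 2 replicates each -> noise pool has
  # 3 genes x 2 conditions x 1 pair = 6 points
  m <- rbind(g1 = c(10, 10, 10, 10),      # M=D=0 -> probability 0
             g2 = c(10, 12, 1000, 1200),  # dominates everything -> 1
             g3 = c(20, 10, 40, 20))
  colnames(m) <- c("control_r1", "control_r2", "t_r1", "t_r2")
  em <- toy_em(m, c("control", "t"), c(2, 2))
  p <- noise_probability(em, "t", pseudocount = 1)
  expect_equal(unname(p["g1"]), 0)
  expect_equal(unname(p["g2"]), 1)
  # hand enumeration for g3: signal M = log2(31/16), D = 15.
  # noise (M, D) points: g1 pairs (0,0), (0,0); g2: |log2(11/13)|, 2 and
  # |log2(1001/1201)|, 200; g3: log2(21/11), 10 and log2(41/21), 20.
  # strictly dominated: both g1 points and g3's (log2(21/11), 10)?
  # M3 = log2(31/16) = 0.954; log2(21/11) = 0.933 < M3 and 10 < 15 -> yes.
  # g2's (0.241, 2) also dominated. total 4/6
  expect_equal(unname(p["g3"]), 4 / 6)
  # monotone in (M, D): probabilities never decrease if a gene's change grows
  expect_true(p["g2"] >= p["g3"] && p["g3"] >= p["g1"])
})

test_that("noise_probability needs replicated conditions", {
  m <- rbind(g1 = c(10, 20), g2 = c(5, 1))
  colnames(m) <- c("control_r1", "t_r1")
  em <- toy_em(m, c("control", "t"), c(1, 1))
  expect_error(noise_probability(em, "t"), "replicates")
})

test_that("call_degs applies inclusive boundaries and direction rules", {
  rel <- matrix(c(3, -1.2, 0), nrow = 3,
                dimnames = list(c("a", "b", "c"), "cold"))
  probs <- matrix(c(0.59, 0.6, 0.99), nrow = 3,
                  dimnames = list(c("a", "b", "c"), "cold"))
  calls <- call_degs(rel, probs)
  expect_false(calls$is_deg[calls$gene_id == "a"])  # prob below threshold
  expect_true(calls$is_deg[calls$gene_id == "b"])   # 0.6 is inclusive
  expect_equal(calls$direction[calls$gene_id == "b"], "down")
  expect_true(is.na(calls$direction[calls$gene_id == "c"]))
  expect_false(calls$is_deg[calls$gene_id == "c"])
  # strict fold-change switch
  rel2 <- matrix(1, dimnames = list("a", "cold"))
  pr2 <- matrix(1, dimnames = list("a", "cold"))
  expect_true(call_degs(rel2, pr2)$is_deg)
  expect_false(call_degs(rel2, pr2, inclusive_fc = FALSE)$is_deg)
})

test_that("DEG counts are monotone nonincreasing in both thresholds", {
  withr::with_seed(21, {
    rel <- matrix(rnorm(200, 0, 1.5), 40, 5,
                  dimnames = list(sprintf("g%d", 1:40), paste0("t", 1:5)))
    probs <- matrix(runif(200), 40, 5, dimnames = dimnames(rel))
    sweep <- deg_threshold_sweep(rel, probs, prob_grid = seq(0.2, 0.9, 0.1))
    for (t in unique(sweep$treatment)) {
      n <- sweep$n_deg[sweep$treatment == t][order(sweep$threshold[sweep$treatment == t])]
      expect_true(all(diff(n) <= 0))
    }
    n1 <- sum(call_degs(rel, probs, 0.5, 1)$is_deg)
    n2 <- sum(call_degs(rel, probs, 0.5, 2)$is_deg)
    expect_true(n2 <= n1)
  })
})

test_that("venn_summary class counts sum to the distinct DEG total", {
  calls <- data.frame(
    gene_id = c("a", "a", "b", "c", "d"),
    treatment = c("cold", "heat", "cold", "salt", "heat"),
    is_deg = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    family = c("MYB", "MYB", "MYB", "WRKY", "NAC"), stringsAsFactors = FALSE)
  v <- venn_summary(calls)
  expect_equal(v$n_deg_genes, 3)  # d is excluded
  expect_equal(sum(v$classes$count), v$n_deg_genes)
  expect_equal(v$classes$count[v$classes$members == "cold+heat"], 1)
  expect_equal(v$n_multi, 1)
  expect_equal(unname(as.vector(v$per_family_unique[c("MYB", "WRKY")])), c(2, 1))
  # brute-force set enumeration on a seeded 10-gene fixture
  withr::with_seed(31, {
    genes <- sprintf("g%d", 1:10)
    trts <- c("cold", "heat", "salt")
    grid <- expand.grid(gene_id = genes, treatment = trts, stringsAsFactors = FALSE)
    grid$is_deg <- runif(nrow(grid)) < 0.5
    v2 <- venn_summary(grid)
    member_sets <- lapply(genes, function(g)
      sort(grid$treatment[grid$gene_id == g & grid$is_deg]))
    names(member_sets) <- genes
    member_sets <- member_sets[lengths(member_sets) > 0]
    expect_equal(v2$n_deg_genes, length(member_sets))
    brute <- table(vapply(member_sets, paste, "", collapse = "+"))
    got <- stats::setNames(v2$classes$count, v2$classes$members)
    expect_equal(got[names(brute)], stats::setNames(as.integer(brute), names(brute)))
  })
})

test_that("select_crucial requires annotation evidence and a nonempty term list", {
  calls <- data.frame(gene_id = c("a", "b"), treatment = "cold",
                      is_deg = c(TRUE, TRUE), stringsAsFactors = FALSE)
  go <- data.frame(gene_id = "a", term = "GO:0009409",
                   name = "response to cold", stringsAsFactors = FALSE)
  out <- select_crucial(calls, go, c("response to cold"))
  expect_true(out$is_crucial[out$gene_id == "a"])
  expect_false(out$is_crucial[out$gene_id == "b"])  # DEG without annotation
  expect_error(select_crucial(calls, go, character(0)), "empty")
  # id-based matching too
  out2 <- select_crucial(calls, go, c("GO:0009409"))
  expect_true(out2$is_crucial[out2$gene_id == "a"])
})

test_that("ddct computes 2^-dCt", {
  expect_equal(ddct(0), 1)
  expect_equal(ddct(1), 0.5)
  expect_equal(ddct(-2), 4)
  expect_error(ddct(Inf), "finite")
})

test_that("cluster_expression uses Euclidean/Kendall average linkage deterministically", {
  rel <- rbind(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5),
               c = c(5, 4, 3, 2, 1), d = c(0, 0, 0, 0, 0))
  colnames(rel) <- paste0("t", 1:5)
  cl <- cluster_expression(rel)
  expect_equal(min(cl$genes$height), 0)  # identical rows merge at 0
  # tau of a column with itself -> distance 0: identical columns merge at 0
  rel2 <- cbind(rel, t6 = rel[, 1])
  expect_equal(min(cluster_expression(rel2)$arrays$height), 0)
  # constant column flagged
  rel3 <- rbind(a = c(1, 1), b = c(2, 1), c = c(0, 1))
  colnames(rel3) <- c("t1", "t2")
  expect_message(cluster_expression(rel3), "constant")
  # planted archetypes recovered by the 2-cluster cut
  withr::with_seed(17, {
    arch <- rbind(matrix(rep(c(2, 2, 0, 0, 0), 5), 5, byrow = TRUE),
                  matrix(rep(c(0, 0, 0, 2, 2), 5), 5, byrow = TRUE)) +
            matrix(rnorm(50, 0, 0.05), 10, 5)
    rownames(arch) <- sprintf("g%d", 1:10)
    colnames(arch) <- paste0("t", 1:5)
    cut <- stats::cutree(cluster_expression(arch)$genes, k = 2)
    expect_equal(length(unique(cut[1:5])), 1)
    expect_equal(length(unique(cut[6:10])), 1)
    expect_false(cut[1] == cut[6])
  })
})

test_that("planted DE genes are recovered from the synthetic matrix", {
  cfg <- synth_config(n_genes_per_family = 20, de_effect_log2fc = 2,
                      noise_sd = 0.1, seed = 19)
  inv <- generate_inventory(cfg)
  ex <- generate_expression(cfg, inv)
  rel <- relative_expression(ex$em)
  # planted log2FC = 2 recovered within noise tolerance
  de_idx <- which(ex$truth$is_de, arr.ind = TRUE)
  expect_true(mean(abs(abs(rel[de_idx]) - 2) < 0.4) > 0.95)
  probs <- noise_probability_matrix(ex$em)
  calls <- call_degs(rel, probs)
  got <- calls$is_deg[match(paste(rownames(rel)[de_idx[, 1]], colnames(rel)[de_idx[, 2]]),
                            paste(calls$gene_id, calls$treatment))]
  expect_true(mean(got) >= 0.9)
})
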