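test_that("modularity reproduces closed-form values", {
  g <- clique_edges(paste0("a", 1:5))
  memb <- setNames(rep(1, 5), paste0("a", 1:5))
  expect_equal(spikesync::modularity(g, memb), 0)

  # k equal disjoint cliques split by component: Q = 1 - 1/k
  tri2 <- dplyr::bind_rows(clique_edges(paste0("x", 1:3)),
                           clique_edges(paste0("y", 1:3)))
  memb2 <- setNames(c(1, 1, 1, 2, 2, 2), c(paste0("x", 1:3), paste0("y", 1:3)))
  expect_equal(spikesync::modularity(tri2, memb2), 0.5)

  empty <- tibble::tibble(from = character(), to = character(),
                          weight = double())
  expect_error(spikesync::modularity(empty, memb2),
               class = "spikesync_analysis_error")
})

test_that("modularity equals a double-loop evaluation of the definition", {
  set.seed(31)
  for (i in 1:25) {
    W <- random_weight_graph(8)
    memb <- sample(1:3, 8, replace = TRUE)
    names(memb) <- rownames(W)
    gamma <- sample(c(0.5, 1, 1.7), 1)
    expect_equal(spikesync::modularity(W, memb, gamma),
                 brute_modularity(W, memb, gamma))
  }
})

test_that("louvain separates disjoint cliques for every seed", {
  g <- dplyr::bind_rows(clique_edges(paste0("a", 1:4)),
                        clique_edges(paste0("b", 1:4)))
  for (s in 0:19) {
    p <- louvain(g, seed = s)
    labs <- setNames(p$community, p$node)
    expect_equal(length(unique(labs[paste0("a", 1:4)])), 1)
    expect_equal(length(unique(labs[paste0("b", 1:4)])), 1)
    expect_false(labs[["a1"]] == labs[["b1"]])
    expect_equal(attr(p, "modularity"), 0.5)
  }

  tri <- clique_edges(c("u", "v", "w"))
  p <- louvain(tri, seed = 1)
  expect_equal(length(unique(p$community)), 1)
})

test_that("modularity never decreases across passes and Q is recomputable", {
  set.seed(77)
  for (i in 1:15) {
    W <- random_weight_graph(sample(5:10, 1))
    p <- louvain(W, seed = i)
    trace <- attr(p, "q_trace")
    expect_true(all(diff(trace) >= -1e-9))
    labs <- setNames(p$community, p$node)
    expect_equal(attr(p, "modularity"), spikesync::modularity(W, labs))
    expect_true(attr(p, "modularity") >= -1 &&
                  attr(p, "modularity") <= 1)
    # labels form a contiguous 1..K set renumbered by first appearance
    expect_equal(sort(unique(p$community)),
                 seq_len(length(unique(p$community))))
  }
})

test_that("edgeless graphs are rejected with an analysis error", {
  g <- tibble::tibble(from = character(), to = character(),
                      weight = double())
  attr(g, "nodes") <- c("a", "b")
  expect_error(louvain(g), class = "spikesync_analysis_error")
})

test_that("louvain attains the enumerated modularity optimum on small graphs", {
  set.seed(55)
  n_trials <- 30
  hits <- 0
  parts_cache <- list()
  for (i in seq_len(n_trials)) {
    n <- sample(5:7, 1)
    W <- random_weight_graph(n, p_edge = 0.6)
    key <- as.character(n)
    if (is.null(parts_cache[[key]])) parts_cache[[key]] <- set_partitions(n)
    best <- max(vapply(parts_cache[[key]], function(m) {
      brute_modularity(W, m)
    }, numeric(1)))
    p <- louvain(W, seed = i)
    if (attr(p, "modularity") >= best - 1e-9) hits <- hits + 1
  }
  # Louvain is a greedy heuristic; it may miss the optimum occasionally
  expect_gte(hits / n_trials, 0.95)
})

test_that("results agree with an independent community-detection library", {
  skip_if_not_installed("igraph")
  set.seed(99)
  for (i in 1:10) {
    W <- random_weight_graph(10, p_edge = 0.4)
    ig <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                              weighted = TRUE)
    p <- louvain(W, seed = i)
    labs <- setNames(p$community, p$node)
    q_ig <- igraph::modularity(ig, labs[igraph::V(ig)$name],
                               weights = igraph::E(ig)$weight)
    expect_equal(attr(p, "modularity"), q_ig, tolerance = 1e-10)
    # our greedy optimum is at least as good as igraph's Louvain run
    cl <- igraph::cluster_louvain(ig)
    expect_gte(attr(p, "modularity"),
               igraph::modularity(ig, igraph::membership(cl),
                                  weights = igraph::E(ig)$weight) - 0.05)
  }
})

test_that("planted synthetic communities are recovered", {
  gt <- generate_ground_truth()
  ok <- 0
  n_runs <- 10
  for (s in seq_len(n_runs)) {
    rec <- simulate_trial(gt, seed = 7000 + s)
    g <- functional_edges(synchrony_matrix(rec), 0.3)
    p <- louvain(g, seed = s)
    labs <- setNames(p$community, p$node)
    truth <- gt$community_of[p$node]
    if (ari(labs, truth) >= 0.9) ok <- ok + 1
  }
  expect_gte(ok / n_runs, 0.9)
})
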