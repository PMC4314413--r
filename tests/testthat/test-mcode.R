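test_that("core decomposition: triangle, complete graph, oracle sweep", {
  expect_equal(unname(core_decomposition(complete_graph(c("a", "b", "c")))),
               rep(2L, 3))
  expect_equal(unname(core_decomposition(complete_graph(sprintf("v%d", 1:5)))),
               rep(4L, 5))
  for (seed in 1:25) {
    g <- rand_connected_graph(sample(8:25, 1), runif(1, 0.12, 0.3), seed + 100)
    core <- core_decomposition(g)
    or <- oracle_core_numbers(g)
    expect_equal(core[names(or)], or)
  }
})

test_that("vertex weight follows the core-clustering definition", {
  k5 <- complete_graph(sprintf("v%d", 1:5))
  expect_equal(unname(vertex_weight(k5, "v1")), 4)
  edge <- build_network(data.frame(a = "A", b = "B"))
  expect_equal(unname(vertex_weight(edge, "A")), 1)
  lonely <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices("Z")
  expect_equal(unname(vertex_weight(lonely, "Z")), 0)
  for (seed in 1:10) {
    g <- rand_connected_graph(12, 0.25, seed + 300)
    w <- vertex_weight(g)
    ow <- vapply(igraph::V(g)$name, function(v) oracle_vertex_weight(g, v),
                 numeric(1))
    expect_equal(w, ow)
  }
})

test_that("complex score is density times node count", {
  expect_equal(round(complex_score(56, 1437), 3), 52.255)
  expect_equal(round(complex_score(7, 14), 3), 4.667)
  expect_equal(complex_score(10, 45), 10)   # K10
  expect_equal(complex_score(1, 0), 0)
})

test_that("haircut trims to the 2-core; fluff grows monotonically", {
  tri_pendant <- build_network(data.frame(a = c("a", "b", "c", "c"),
                                          b = c("b", "c", "a", "d")))
  expect_equal(haircut(c("a", "b", "c", "d"), tri_pendant), c("a", "b", "c"))
  tree <- path_graph(c("a", "b", "c", "d"))
  expect_equal(haircut(c("a", "b", "c", "d"), tree), character(0))
  for (seed in 1:5) {
    g <- rand_connected_graph(15, 0.2, seed + 400)
    members <- haircut(igraph::V(g)$name, g)
    if (length(members) > 0) {
      sub <- igraph::induced_subgraph(g, members)
      expect_gte(min(igraph::degree(sub)), 2)
    }
  }
  # fluff: a neighbour embedded in a clique is dense enough to join
  g <- igraph::union(complete_graph(c("k1", "k2", "k3", "k4")),
                     path_graph(c("k1", "out", "far")))
  grown <- fluff(c("k1", "k2", "k3", "k4"), g, 0.5)
  expect_true(all(c("k1", "k2", "k3", "k4") %in% grown))
  expect_equal(fluff(c("k1", "k2", "k3", "k4"), g, 1),
               c("k1", "k2", "k3", "k4"))  # density <= 1, strict >
})

test_that("an isolated clique is predicted whole with its complete-graph score", {
  g <- igraph::union(complete_graph(sprintf("c%d", 1:8)),
                     path_graph(c("c1", "p1", "p2", "p3")))
  cx <- predict_complexes(g, mcode_params())
  expect_equal(nrow(cx), 1)
  expect_equal(cx$score, 8)
  expect_equal(attr(cx, "member_sets")[[1]], sort(sprintf("c%d", 1:8)))
})

test_that("prediction respects depth bound, visited bookkeeping, k-core filter", {
  # two cliques joined by a path: complexes never overlap pre-fluff
  g <- igraph::union(complete_graph(sprintf("a%d", 1:6)),
                     complete_graph(sprintf("b%d", 1:5)),
                     path_graph(c("a1", "x", "b1")))
  cx <- predict_complexes(g, mcode_params(k_core = 4))
  sets <- attr(cx, "member_sets")
  expect_equal(length(sets), 2)
  expect_length(intersect(sets[[1]], sets[[2]]), 0)
  expect_equal(sets[[1]], sort(sprintf("a%d", 1:6)))
  # k_core filter discards the smaller clique when raised
  cx5 <- predict_complexes(g, mcode_params(k_core = 5))
  expect_equal(length(attr(cx5, "member_sets")), 1)
  # max_depth = 1 keeps every complex inside the seed's closed neighbourhood
  for (seed in 1:5) {
    rg <- rand_connected_graph(18, 0.3, seed + 500)
    cx1 <- predict_complexes(rg, mcode_params(k_core = 2, max_depth = 1))
    for (i in seq_len(nrow(cx1))) {
      members <- attr(cx1, "member_sets")[[i]]
      seedv <- cx1$seed[i]
      closed <- c(seedv, igraph::V(rg)$name[igraph::neighbors(rg, seedv)])
      expect_true(all(members %in% closed))
    }
  }
})

test_that("node_score_cutoff boundary: 0 admits nothing beyond the seed", {
  # two-tier toy: a 5-clique (weight 4) with a pendant triangle (weight 2)
  g <- igraph::union(complete_graph(sprintf("k%d", 1:5)),
                     complete_graph(c("k1", "t1", "t2")))
  w <- vertex_weight(g)
  expect_equal(unname(w[sprintf("k%d", 1:5)]), rep(4, 5))
  expect_equal(unname(w["t1"]), 2)
  # strict >: at cutoff 0 no neighbour beats the (maximal) seed weight,
  # so every candidate stays a singleton and is discarded
  cx0 <- predict_complexes(g, mcode_params(k_core = 2, node_score_cutoff = 0,
                                           haircut = FALSE))
  expect_equal(nrow(cx0), 0)
  # a small positive cutoff admits the equal-weight clique, nothing else
  cx <- predict_complexes(g, mcode_params(k_core = 2, node_score_cutoff = 0.1,
                                          haircut = FALSE))
  expect_equal(attr(cx, "member_sets")[[1]], sort(sprintf("k%d", 1:5)))
})

test_that("prediction is deterministic and sorted by score", {
  g <- rand_connected_graph(40, 0.12, 600)
  p <- mcode_params(k_core = 2)
  a <- predict_complexes(g, p)
  b <- predict_complexes(g, p)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(a$score, sort(a$score, decreasing = TRUE))
  # every emitted complex is connected; haircut guarantees min degree 2
  for (members in attr(a, "member_sets")) {
    sub <- igraph::induced_subgraph(g, members)
    expect_true(igraph::is_connected(sub))
    expect_gte(min(igraph::degree(sub)), 2)
  }
})

test_that("a planted clique in the synthetic background tops the ranking", {
  hits <- 0L
  for (seed in 1:10) {
    cfg <- sim_config(m_genes = 150, n_de_genes = 8, clique_sizes = 8L,
                      background_edge_param = 1, seed = seed)
    net <- generate_network(cfg)
    cx <- predict_complexes(net$network, mcode_params())
    if (nrow(cx) >= 1 &&
        setequal(attr(cx, "member_sets")[[1]],
                 net$truth$clique_members[[1]])) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
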