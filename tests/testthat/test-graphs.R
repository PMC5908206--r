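test_that("random graph generator draws exactly m edges and is reproducible", {
  g <- generate_random(60, 800, seed = 1)
  expect_valid_graph(g)
  expect_equal(edge_count(g), 800)
  expect_equal(edge_count(g) / choose(60, 2), 0.452, tolerance = 0.001)
  g2 <- generate_random(60, 800, seed = 1)
  expect_identical(adjacency(g), adjacency(g2))
  expect_false(identical(adjacency(g), adjacency(generate_random(60, 800, seed = 2))))
  # degenerate sizes
  expect_identical(adjacency(generate_random(3, 3, seed = 5)), adjacency(k3()))
  expect_equal(edge_count(generate_random(10, 0, seed = 1)), 0)
  expect_error(generate_random(10, 46, seed = 1), "must lie in")
})

test_that("scale-free generator hits the m(n-m) edge budget with a heavy tail", {
  g <- generate_scale_free(60, 16, seed = 1)
  expect_valid_graph(g)
  expect_equal(edge_count(g), 16 * (60 - 16))
  d <- node_stats(g)$degree
  expect_gt(max(d), 2 * stats::median(d))
  # different seed: different wiring, same edge count
  g2 <- generate_scale_free(60, 16, seed = 2)
  expect_equal(edge_count(g2), 704)
  expect_false(identical(adjacency(g), adjacency(g2)))
  # a single newcomer attaches to all m_attach seed nodes
  g5 <- generate_scale_free(5, 4, seed = 1)
  expect_equal(edge_count(g5), 4)
  expect_equal(node_stats(g5)$degree[5], 4L)
  expect_error(generate_scale_free(10, 0, seed = 1), "m_attach")
})

test_that("modular generator builds equal blocks with few bridges", {
  g <- generate_modular(60, 4, intra_p = 0.9, inter_edges = 8, seed = 1)
  expect_valid_graph(g)
  expect_equal(as.integer(table(g$membership)), rep(15L, 4))
  A <- adjacency(g)
  same <- outer(g$membership, g$membership, "==")
  ut <- upper.tri(A)
  expect_equal(sum(A[ut & !same]), 8)
  dens_within <- mean(A[ut & same])
  dens_between <- mean(A[ut & !same])
  expect_gt(dens_within, 10 * dens_between)
  # Newman modularity of the block partition beats a scrambled partition
  ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  q_blocks <- igraph::modularity(ig, g$membership)
  q_random <- igraph::modularity(ig, sample(g$membership))
  expect_gt(q_blocks, q_random)
  # complete blocks of size 2 with no bridges: 4 disjoint edges
  g2 <- generate_modular(8, 4, intra_p = 1, inter_edges = 0, seed = 1)
  expect_equal(edge_count(g2), 4)
  expect_equal(node_stats(g2)$degree, rep(1L, 8))
  expect_error(generate_modular(10, 4, 0.5, 2, seed = 1), "divide")
})

test_that("benchmark suite has the expected sizes", {
  for (topo in c("random", "scale_free", "modular")) {
    g <- benchmark_graph(topo, seed = 1)
    expect_valid_graph(g)
    expect_equal(n_nodes(g), 60)
    expect_true(abs(edge_count(g) - 400) < 40)
  }
})

test_that("connectivity retry yields connected realizations", {
  expect_false(is_connected(edgeless(4)))
  expect_true(is_connected(k3()))
  # sparse modular graphs are often disconnected without the retry
  g <- generate_modular(24, 4, intra_p = 0.6, inter_edges = 3, seed = 1,
                        require_connected = TRUE)
  expect_true(is_connected(g))
  g2 <- generate_random(30, 35, seed = 2, require_connected = TRUE)
  expect_true(is_connected(g2))
})

test_that("node statistics match hand counts on canonical graphs", {
  s3 <- node_stats(k3())
  expect_equal(s3$degree, rep(2L, 3))
  expect_equal(s3$clustering, rep(1, 3))
  s4 <- node_stats(k4())
  expect_equal(s4$degree, rep(3L, 4))
  expect_equal(s4$clustering, rep(1, 4))
  expect_equal(s4$triangles, rep(3L, 4))
  ss <- node_stats(star5())
  expect_equal(ss$degree, c(4L, 1L, 1L, 1L, 1L))
  expect_equal(ss$clustering, rep(0, 5))
})

test_that("generator invariants hold across seeds and degree sums match edges", {
  for (seed in 1:5) {
    for (g in list(generate_random(30, 100, seed = seed),
                   generate_scale_free(30, 4, seed = seed),
                   generate_modular(30, 3, 0.7, 5, seed = seed))) {
      expect_valid_graph(g)
      expect_equal(sum(node_stats(g)$degree), 2 * edge_count(g))
    }
  }
})

test_that("motif fixtures carry the requested class around the focal pair", {
  for (cls in c("t0", "t00", "t01", "t02", "t11", "t12", "t13")) {
    fx <- generate_motif_fixture(cls, n = 30, n_common = 6, seed = 3)
    expect_valid_graph(fx$graph)
    inv <- motif_inventory(fx$graph, fx$pair[1], fx$pair[2])
    count <- switch(cls,
      t0 = inv$t0, t00 = inv$t00_i + inv$t00_j,
      t01 = sum(inv$t01_i) + sum(inv$t01_j),
      t02 = inv$t02, t11 = sum(inv$t11), t12 = sum(inv$t12), t13 = inv$t13)
    expect_gte(count, 1)
    if (cls %in% c("t01", "t02", "t11", "t12")) {
      expect_length(inv$common_neighbors, 6)
    }
    if (cls != "t0") expect_equal(inv$t0, 0)
  }
  # minimal t0 fixture on three nodes is the triangle
  fx3 <- generate_motif_fixture("t0", n = 3, n_common = 1, seed = 1)
  expect_identical(adjacency(fx3$graph), adjacency(k3()))
  expect_error(generate_motif_fixture("t11", n = 5, n_common = 6, seed = 1),
               "too small")
})
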