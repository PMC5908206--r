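test_that("common neighbors and topological overlap match hand counts", {
  expect_equal(common_neighbors(k3(), 1, 2), 3)
  expect_equal(common_neighbors(path3(), 1, 3), 2)
  expect_equal(length(common_neighbors(edgeless(4), 1, 2)), 0)
  expect_error(common_neighbors(k3(), 2, 2), "distinct")
  TO <- topological_overlap(k3())
  expect_equal(TO[upper.tri(TO)], rep(1, 3))
  expect_equal(diag(TO), rep(0, 3))
  expect_equal(topological_overlap(cycle4())[1, 3], 2)
  # TO is bounded by the smaller degree
  g <- generate_random(20, 60, seed = 1)
  TOg <- topological_overlap(g)
  d <- node_stats(g)$degree
  expect_true(all(TOg <= outer(d, d, pmin)))
})

test_that("per-neighbor triangle counts agree between count and formula", {
  expect_equal(triangles_per_common_neighbor(k4(), 1, 2, 3), 2)
  expect_equal(triangles_per_common_neighbor(k3(), 1, 2, 3), 0)
  expect_equal(triangles_per_common_neighbor(path3(), 1, 3, 2), 0)
  expect_error(triangles_per_common_neighbor(k3(), 1, 2, 1), "not a common neighbor")
  g <- generate_random(15, 40, seed = 2)
  for (i in 1:5) for (j in 6:10) {
    for (k in common_neighbors(g, i, j)) {
      expect_equal(triangles_per_common_neighbor(g, i, j, k, "exact"),
                   triangles_per_common_neighbor(g, i, j, k, "formula"))
    }
  }
})

test_that("motif inventories of canonical graphs match hand classification", {
  inv3 <- motif_inventory(k3(), 1, 2)
  expect_equal(inv3$t0, 1)
  expect_equal(inv3$t00_i + inv3$t00_j + sum(inv3$t01_i) + sum(inv3$t01_j) +
                 inv3$t02 + sum(inv3$t11) + sum(inv3$t12) + inv3$t13, 0)
  # K4 around a pair: 2 triangles through the pair, and the opposite triangle
  # (3,4,x=i or j) touches one focal node and both common neighbors: t02
  inv4 <- motif_inventory(k4(), 1, 2)
  expect_equal(inv4$t0, 2)
  expect_equal(inv4$t02, 1)
  expect_equal(inv4$t00_i + inv4$t00_j + sum(inv4$t01_i) + sum(inv4$t01_j) +
                 sum(inv4$t11) + sum(inv4$t12) + inv4$t13, 0)
  # t0 equals TO masked by adjacency
  g <- generate_random(12, 30, seed = 3)
  TOg <- topological_overlap(g)
  A <- adjacency(g)
  for (i in 1:3) for (j in 4:6) {
    expect_equal(motif_inventory(g, i, j)$t0, A[i, j] * TOg[i, j])
  }
})

test_that("the classification partitions all triangles near the pair", {
  for (seed in 1:4) {
    g <- generate_random(14, 35, seed = seed)
    tris <- brute_triangles(g)
    A <- adjacency(g)
    for (pair in list(c(1, 2), c(3, 9), c(5, 14))) {
      i <- pair[1]; j <- pair[2]
      N <- common_neighbors(g, i, j)
      inv <- motif_inventory(g, i, j)
      # independent classification of each brute-force triangle
      expected <- c(t0 = 0, t00 = 0, t01 = 0, t02 = 0, t11 = 0, t12 = 0, t13 = 0)
      for (tri in tris) {
        has_i <- i %in% tri; has_j <- j %in% tri
        m <- sum(setdiff(tri, c(i, j)) %in% N)
        cls <- if (has_i && has_j) "t0"
          else if (has_i || has_j) c("t00", "t01", "t02")[m + 1]
          else if (m > 0) c("t11", "t12", "t13")[m]
          else NA
        if (!is.na(cls)) expected[cls] <- expected[cls] + 1
      }
      got <- c(t0 = inv$t0, t00 = inv$t00_i + inv$t00_j,
               t01 = sum(inv$t01_i) + sum(inv$t01_j),
               t02 = 2 * inv$t02,  # one copy at each focal node
               t11 = sum(inv$t11), t12 = sum(inv$t12), t13 = inv$t13)
      expect_equal(got, expected)
    }
  }
})

test_that("inventories are symmetric in the pair and match the matrix totals", {
  g <- generate_random(16, 45, seed = 6)
  mt <- serfc:::motif_totals(g)
  for (pair in list(c(1, 2), c(2, 7), c(4, 16), c(10, 11))) {
    i <- pair[1]; j <- pair[2]
    a <- motif_inventory(g, i, j)
    b <- motif_inventory(g, j, i)
    expect_equal(a$t0, b$t0)
    expect_equal(a$t00_i, b$t00_j)
    expect_equal(a$t01_i, b$t01_j)
    expect_equal(a$t02, b$t02)
    expect_equal(sum(a$t11), sum(b$t11))
    expect_equal(a$t13, b$t13)
    # algebraic whole-graph totals agree with the per-pair enumeration
    expect_equal(mt$t0[i, j], a$t0)
    expect_equal(mt$t00_i[i, j], a$t00_i)
    expect_equal(mt$t00_i[j, i], a$t00_j)
    expect_equal(mt$t01_i[i, j], sum(a$t01_i))
    expect_equal(mt$t01_i[j, i], sum(a$t01_j))
    expect_equal(mt$t02[i, j], a$t02)
    expect_equal(mt$t11[i, j], sum(a$t11))
    expect_equal(mt$t12[i, j], sum(a$t12))
    expect_equal(mt$t13[i, j], a$t13)
  }
})

test_that("tidy() flattens an inventory to the long export form", {
  tl <- tidy(motif_inventory(k4(), 1, 2))
  expect_true(all(c("i", "j", "class", "k", "l", "count") %in% names(tl)))
  expect_equal(tl$count[tl$class == "t0"], 2L)
  expect_equal(sum(tl$count), 3L)  # t0 = 2 plus t02 = 1
})
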