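# Small named graphs used across the suite, built in code.

graph_from_edges <- function(n, edges) {
  A <- matrix(0L, n, n)
  if (length(edges)) {
    e <- matrix(unlist(edges), ncol = 2, byrow = TRUE)
    A[e] <- 1L
    A[e[, 2:1]] <- 1L
  }
  ser_graph(A)
}

k3 <- function() ser_graph(1 - diag(3))
k4 <- function() ser_graph(1 - diag(4))
k5 <- function() ser_graph(1 - diag(5))
path3 <- function() graph_from_edges(3, list(c(1, 2), c(2, 3)))
star5 <- function() graph_from_edges(5, list(c(1, 2), c(1, 3), c(1, 4), c(1, 5)))
cycle4 <- function() graph_from_edges(4, list(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
edgeless <- function(n) ser_graph(matrix(0L, n, n))

# Brute-force triangle list for cross-checks, independent of the package's
# enumeration: all index triples tested directly against the adjacency.
brute_triangles <- function(g) {
  A <- adjacency(g)
  n <- nrow(A)
  out <- list()
  if (n >= 3) {
    for (u in 1:(n - 2)) for (v in (u + 1):(n - 1)) for (w in (v + 1):n) {
      if (A[u, v] == 1 && A[u, w] == 1 && A[v, w] == 1) {
        out[[length(out) + 1]] <- c(u, v, w)
      }
    }
  }
  out
}

expect_valid_graph <- function(g) {
  A <- adjacency(g)
  expect_true(all(A %in% c(0L, 1L)))
  expect_identical(A, t(A))
  expect_true(all(diag(A) == 0L))
}
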