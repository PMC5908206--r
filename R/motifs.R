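#' Common neighbors of a node pair
#'
#' @param graph A [ser_graph].
#' @param i,j Distinct node indices (1-based).
#' @return Sorted integer vector of nodes adjacent to both `i` and `j`.
#' @examples
#' common_neighbors(ser_graph(1 - diag(3)), 1, 2)
#' @export
common_neighbors <- function(graph, i, j) {
  g <- as_ser_graph(graph)
  if (i == j) stop("i and j must be distinct nodes", call. = FALSE)
  which(g$adjacency[i, ] == 1L & g$adjacency[j, ] == 1L)
}

#' Topological overlap (matching index) matrix
#'
#' `TO[i, j]` is the number of common neighbors of the pair, the unnormalized
#' matching index. Symmetric with zero diagonal by convention.
#'
#' @param graph A [ser_graph].
#' @return Integer matrix `n x n`.
#' @examples
#' topological_overlap(ser_graph(1 - diag(3)))
#' @export
topological_overlap <- function(graph) {
  g <- as_ser_graph(graph)
  TO <- g$adjacency %*% g$adjacency
  diag(TO) <- 0L
  TO
}

# Triangle count through each node: diag(A^3) / 2.
triangles_per_node <- function(A) {
  as.integer(round(diag((A %*% A) %*% A) / 2))
}

#' Triangles around a common neighbor
#'
#' `c_ijk` is the number of triangles through the k-th common neighbor of the
#' pair `(i, j)`, not counting the triangle that `k` forms with `i` and `j`
#' when those are connected. This is the quantity entering the
#' neighbor-silence probability of the pacemaker-based prediction.
#'
#' @param graph A [ser_graph].
#' @param i,j The focal pair.
#' @param k A common neighbor of `i` and `j`.
#' @param method `"exact"` counts the edges among the neighbors of `k`
#'   directly; `"formula"` evaluates `C_k d_k (d_k - 1) / 2 - A_ij` from the
#'   clustering coefficient (the two agree up to rounding).
#' @return Nonnegative integer.
#' @examples
#' k4 <- ser_graph(1 - diag(4))
#' triangles_per_common_neighbor(k4, 1, 2, 3)  # 3 triangles at k, minus the (i,j) edge
#' @export
triangles_per_common_neighbor <- function(graph, i, j, k,
                                          method = c("exact", "formula")) {
  g <- as_ser_graph(graph)
  method <- match.arg(method)
  if (!(k %in% common_neighbors(g, i, j))) {
    stop("k = ", k, " is not a common neighbor of (", i, ", ", j, ")",
         call. = FALSE)
  }
  A <- g$adjacency
  if (method == "exact") {
    nb <- which(A[k, ] == 1L)
    tri_k <- sum(A[nb, nb]) / 2
  } else {
    d <- sum(A[k, ])
    ck <- if (d < 2) 0 else (sum(A[which(A[k, ] == 1L), which(A[k, ] == 1L)]) / 2) /
      (d * (d - 1) / 2)
    tri_k <- ck * d * (d - 1) / 2
  }
  max(0L, as.integer(round(tri_k)) - A[i, j])
}

# All triangles of the graph as a 3-column matrix of node triples (u < v < w).
enumerate_triangles <- function(A) {
  n <- nrow(A)
  out <- list()
  idx <- 0L
  for (u in seq_len(n - 1L)) {
    nb_u <- which(A[u, ] == 1L)
    nb_u <- nb_u[nb_u > u]
    for (v in nb_u) {
      w <- which(A[u, ] == 1L & A[v, ] == 1L)
      w <- w[w > v]
      if (length(w)) {
        idx <- idx + 1L
        out[[idx]] <- cbind(u, v, w)
      }
    }
  }
  if (idx == 0L) matrix(integer(0), 0L, 3L) else do.call(rbind, out)
}

#' Triangle-motif inventory around a node pair
#'
#' Classifies every triangle within graph distance 1 of the pair `(i, j)` into
#' the motif hierarchy: `t0` (triangle through both `i` and `j`), `t00`
#' (through exactly one of them and no common neighbor), `t01` (one of them
#' and one common neighbor), `t02` (one of them and two common neighbors),
#' and, one step out, `t11`/`t12`/`t13` (through no focal node and one/two/
#' three common neighbors). A triangle touching both focal nodes is always
#' `t0`; otherwise the class with the most common neighbors wins, so the
#' classes partition the triangles. `t02` is reported once per triangle; its
#' `i`-side and `j`-side copies are equinumerous because any two connected
#' common neighbors close a triangle with each focal node.
#'
#' @param graph A [ser_graph].
#' @param i,j Distinct focal nodes.
#' @param include_outside Also count triangles entirely outside the
#'   1-neighborhood of the pair (third level and beyond; reported in
#'   `$t_outside`, never used by the predictors).
#' @return A list of class `ser_motif_inventory` with the focal pair, the
#'   sorted common-neighbor list, per-class counts (`t01_i`, `t01_j` and `t11`
#'   resolved per common neighbor; `t12` per unordered common-neighbor pair),
#'   and `c` (the [triangles_per_common_neighbor()] count per common
#'   neighbor).
#' @examples
#' motif_inventory(ser_graph(1 - diag(4)), 1, 2)
#' @export
motif_inventory <- function(graph, i, j, include_outside = FALSE) {
  g <- as_ser_graph(graph)
  if (i == j) stop("i and j must be distinct nodes", call. = FALSE)
  A <- g$adjacency
  N <- common_neighbors(g, i, j)
  nc <- length(N)
  tris <- enumerate_triangles(A)
  t0 <- 0L
  t00_i <- 0L; t00_j <- 0L
  t01_i <- stats::setNames(rep(0L, nc), N)
  t01_j <- stats::setNames(rep(0L, nc), N)
  t02 <- 0L
  t11 <- stats::setNames(rep(0L, nc), N)
  t12 <- if (nc >= 2L) {
    pr <- utils::combn(N, 2L)
    stats::setNames(rep(0L, ncol(pr)), paste(pr[1, ], pr[2, ], sep = "-"))
  } else stats::setNames(integer(0), character(0))
  t13 <- 0L
  t_outside <- 0L
  nb_i <- which(A[i, ] == 1L)
  nb_j <- which(A[j, ] == 1L)
  hood <- union(c(i, j), union(nb_i, nb_j))
  for (r in seq_len(nrow(tris))) {
    tri <- tris[r, ]
    has_i <- i %in% tri
    has_j <- j %in% tri
    in_N <- tri[tri %in% N]
    if (has_i && has_j) {
      t0 <- t0 + 1L
    } else if (has_i || has_j) {
      others <- setdiff(tri, c(i, j))
      m <- sum(others %in% N)
      if (m == 0L) {
        if (has_i) t00_i <- t00_i + 1L else t00_j <- t00_j + 1L
      } else if (m == 1L) {
        k <- as.character(others[others %in% N])
        if (has_i) t01_i[k] <- t01_i[k] + 1L else t01_j[k] <- t01_j[k] + 1L
      } else {
        # counted once per triangle; the mirror copy at the other focal node
        # is a distinct triangle and increments the same counter
        t02 <- t02 + 1L
      }
    } else {
      m <- length(in_N)
      if (m == 1L) {
        k <- as.character(in_N)
        t11[k] <- t11[k] + 1L
      } else if (m == 2L) {
        key <- paste(sort(in_N), collapse = "-")
        t12[key] <- t12[key] + 1L
      } else if (m == 3L) {
        t13 <- t13 + 1L
      } else if (include_outside && any(tri %in% hood)) {
        t_outside <- t_outside + 1L
      }
    }
  }
  t02 <- t02 %/% 2L  # the i-side and j-side copies were both enumerated
  cvec <- vapply(N, function(k) triangles_per_common_neighbor(g, i, j, k),
                 integer(1))
  structure(
    list(pair = c(i = i, j = j), common_neighbors = N,
         t0 = t0, t00_i = t00_i, t00_j = t00_j,
         t01_i = t01_i, t01_j = t01_j, t02 = t02,
         t11 = t11, t12 = t12, t13 = t13,
         t_outside = if (include_outside) t_outside else NA_integer_,
         c = stats::setNames(cvec, N)),
    class = "ser_motif_inventory"
  )
}

#' @export
print.ser_motif_inventory <- function(x, ...) {
  cat("<ser_motif_inventory> pair (", x$pair[1], ", ", x$pair[2], "), ",
      length(x$common_neighbors), " common neighbors\n", sep = "")
  cat("  t0 = ", x$t0, ", t00 = (", x$t00_i, ", ", x$t00_j, "), t01 = (",
      sum(x$t01_i), ", ", sum(x$t01_j), "), t02 = ", x$t02,
      ", t11 = ", sum(x$t11), ", t12 = ", sum(x$t12), ", t13 = ", x$t13,
      "\n", sep = "")
  invisible(x)
}

# Per-pair motif totals for the whole graph, computed algebraically.
# Returns a list of n x n matrices: t0, t00_i (counts on the row-node side),
# t01_i (row-side total over common neighbors), t02, t11, t12, t13 (numbers),
# plus TO. Row-side means "the side of the first index": t00_i[i, j] counts
# triangles at i. Used by the pacemaker predictor; cross-checked against
# motif_inventory() in the tests.
motif_totals <- function(graph) {
  g <- as_ser_graph(graph)
  A <- g$adjacency
  n <- nrow(A)
  storage.mode(A) <- "double"
  TO <- A %*% A
  diag(TO) <- 0
  B <- A * TO                    # triangles through each edge
  tri <- triangles_per_node(g$adjacency)
  BA <- B %*% A
  t02 <- matrix(0, n, n)
  t11 <- matrix(0, n, n)
  t12 <- matrix(0, n, n)
  t13 <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      cn <- which(A[i, ] == 1 & A[j, ] == 1)
      m <- length(cn)
      if (m == 0L) next
      A_N <- A[cn, cn, drop = FALSE]
      t02[i, j] <- sum(A_N) / 2
      if (m >= 2L) {
        TO_N <- TO[cn, cn, drop = FALSE]
        AN2 <- A_N %*% A_N
        # per connected pair of common neighbors: apexes outside {i, j} and N
        tt12 <- A_N * (TO_N - 2 - AN2)
        t12[i, j] <- sum(tt12) / 2
        t13[i, j] <- sum(diag(AN2 %*% A_N)) / 6
      }
      # triangles at each common neighbor avoiding i and j
      gk <- tri[cn] - B[i, cn] - B[j, cn] + A[i, j]
      t11[i, j] <- sum(gk) - 2 * t12[i, j] - 3 * t13[i, j]
    }
  }
  sym <- function(m) m + t(m)
  t02 <- sym(t02); t11 <- sym(t11); t12 <- sym(t12); t13 <- sym(t13)
  t0 <- A * TO
  # row-side t01 totals: sum over common neighbors k of the triangles through
  # the edge (i, k), minus the (i, j, k) triangle and the two-common-neighbor
  # triangles (those are t02)
  t01_i <- pmax(BA - t0 - 2 * t02, 0)
  diag(t01_i) <- 0
  # triangles at the row node avoiding j and all common neighbors
  t00_i <- pmax(matrix(tri, n, n) - t0 - t01_i - t02, 0)
  diag(t00_i) <- 0
  list(TO = TO, t0 = t0, t00_i = t00_i, t01_i = t01_i,
       t02 = t02, t11 = t11, t12 = t12, t13 = t13)
}
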