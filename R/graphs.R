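#' Construct an undirected binary graph
#'
#' The structural connectivity object used throughout the package: a simple,
#' undirected, unweighted graph stored as a dense binary adjacency matrix.
#'
#' @param adjacency Square numeric matrix with entries in \{0, 1\}, symmetric,
#'   zero diagonal.
#' @param membership Optional integer vector of length `n` assigning each node
#'   to a module (kept by the modular generator).
#' @return An object of class `ser_graph` with elements `adjacency`
#'   (integer matrix), `n_nodes`, and optionally `membership`.
#' @examples
#' g <- ser_graph(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3))
#' n_nodes(g)
#' edge_count(g)
#' @export
ser_graph <- function(adjacency, membership = NULL) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency)) {
    stop("adjacency must be a square matrix", call. = FALSE)
  }
  if (anyNA(adjacency) || !all(adjacency %in% c(0, 1))) {
    stop("adjacency entries must all be 0 or 1", call. = FALSE)
  }
  if (!isTRUE(all.equal(adjacency, t(adjacency), check.attributes = FALSE))) {
    stop("adjacency must be symmetric (undirected graph)", call. = FALSE)
  }
  if (any(diag(adjacency) != 0)) {
    stop("adjacency must have a zero diagonal (no self-loops)", call. = FALSE)
  }
  storage.mode(adjacency) <- "integer"
  dimnames(adjacency) <- NULL
  n <- nrow(adjacency)
  if (!is.null(membership)) {
    stopifnot(length(membership) == n)
    membership <- as.integer(membership)
  }
  structure(
    list(adjacency = adjacency, n_nodes = n, membership = membership),
    class = "ser_graph"
  )
}

#' @export
print.ser_graph <- function(x, ...) {
  cat("<ser_graph> ", x$n_nodes, " nodes, ", edge_count(x), " edges",
      if (!is.null(x$membership)) paste0(", ", length(unique(x$membership)), " modules"),
      "\n", sep = "")
  invisible(x)
}

#' @rdname ser_graph
#' @param g A `ser_graph`.
#' @export
n_nodes <- function(g) g$n_nodes

#' @rdname ser_graph
#' @export
edge_count <- function(g) sum(g$adjacency) %/% 2L

#' @rdname ser_graph
#' @export
adjacency <- function(g) g$adjacency

as_ser_graph <- function(x) {
  if (inherits(x, "ser_graph")) x else ser_graph(x)
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

edges_to_adjacency <- function(n, from, to) {
  A <- matrix(0L, n, n)
  A[cbind(from, to)] <- 1L
  A[cbind(to, from)] <- 1L
  A
}

#' Is a graph connected?
#' @param graph A [ser_graph].
#' @return Logical.
#' @export
is_connected <- function(graph) {
  A <- as_ser_graph(graph)$adjacency
  n <- nrow(A)
  if (n <= 1L) return(TRUE)
  reached <- c(TRUE, rep(FALSE, n - 1L))
  repeat {
    nxt <- reached | (A %*% reached > 0)
    if (all(nxt == reached)) break
    reached <- nxt
  }
  all(reached)
}

# Retry a seeded generator until its output is connected (max 100 attempts).
retry_connected <- function(seed, gen) {
  for (attempt in 0:99) {
    g <- gen(if (is.null(seed)) NULL else seed + attempt)
    if (is_connected(g)) return(g)
  }
  stop("no connected realization found in 100 attempts", call. = FALSE)
}

#' Erdos-Renyi random graph with a fixed number of edges
#'
#' Draws exactly `m` edges uniformly at random among the `choose(n, 2)` node
#' pairs (the G(n, m) model).
#'
#' @param n Number of nodes.
#' @param m Number of edges, `0 <= m <= choose(n, 2)`.
#' @param seed Optional integer seed; the draw is reproducible for a fixed seed.
#' @param require_connected Retry (with incremented seeds, at most 100 times)
#'   until the realization is connected.
#' @return A [ser_graph].
#' @examples
#' g <- generate_random(60, 800, seed = 1)
#' edge_count(g)
#' @export
generate_random <- function(n, m, seed = NULL, require_connected = FALSE) {
  if (require_connected) {
    return(retry_connected(seed, function(s) generate_random(n, m, seed = s)))
  }
  n <- as.integer(n)
  m <- as.integer(m)
  m_max <- n * (n - 1L) %/% 2L
  if (m < 0L || m > m_max) {
    stop("m must lie in [0, ", m_max, "] for n = ", n, call. = FALSE)
  }
  idx <- with_seed_if(seed, sample.int(m_max, m))
  ut <- which(upper.tri(matrix(0L, n, n)))
  A <- matrix(0L, n, n)
  A[ut[idx]] <- 1L
  A <- A + t(A)
  ser_graph(A)
}

# Sample `size` distinct values from a multiset `pool` (repeated entries give
# preferential weighting), the way the classical BA construction does it.
sample_distinct <- function(pool, size) {
  out <- integer(0)
  while (length(out) < size) {
    cand <- pool[sample.int(length(pool), 1L)]
    if (!cand %in% out) out <- c(out, cand)
  }
  out
}

#' Barabasi-Albert scale-free graph
#'
#' Preferential attachment starting from `m_attach` isolated seed nodes; each
#' newcomer attaches to `m_attach` distinct existing nodes sampled with
#' probability proportional to their current degree (uniformly for the first
#' newcomer). The construction yields exactly `m_attach * (n - m_attach)` edges
#' and a heavy-tailed degree sequence.
#'
#' @param n Number of nodes.
#' @param m_attach Edges added per new node, `1 <= m_attach < n`.
#' @param seed Optional integer seed.
#' @return A [ser_graph].
#' @examples
#' g <- generate_scale_free(60, 16, seed = 1)
#' edge_count(g)  # 16 * (60 - 16) = 704
#' @export
generate_scale_free <- function(n, m_attach, seed = NULL) {
  n <- as.integer(n)
  m <- as.integer(m_attach)
  if (m < 1L || m >= n) stop("m_attach must satisfy 1 <= m_attach < n", call. = FALSE)
  with_seed_if(seed, {
    A <- matrix(0L, n, n)
    targets <- seq_len(m)
    repeated <- integer(0)
    for (v in (m + 1L):n) {
      A[v, targets] <- 1L
      A[targets, v] <- 1L
      repeated <- c(repeated, targets, rep.int(v, m))
      targets <- sample_distinct(repeated, m)
    }
    ser_graph(A)
  })
}

#' Modular benchmark graph
#'
#' A union of `module_count` equal-size Erdos-Renyi blocks (edge probability
#' `intra_p` within each block) plus `inter_edges` bridges drawn uniformly from
#' the between-module node pairs. Block membership is kept on the returned
#' graph (`$membership`).
#'
#' @param n Number of nodes; must be divisible by `module_count`.
#' @param module_count Number of equal-size modules.
#' @param intra_p Within-module edge probability.
#' @param inter_edges Number of between-module edges.
#' @param seed Optional integer seed.
#' @return A [ser_graph] with a `membership` vector.
#' @examples
#' g <- generate_modular(60, 4, intra_p = 0.9, inter_edges = 8, seed = 1)
#' table(g$membership)
#' @inheritParams generate_random
#' @export
generate_modular <- function(n, module_count, intra_p, inter_edges, seed = NULL,
                             require_connected = FALSE) {
  if (require_connected) {
    return(retry_connected(seed, function(s) {
      generate_modular(n, module_count, intra_p, inter_edges, seed = s)
    }))
  }
  n <- as.integer(n)
  mc <- as.integer(module_count)
  if (n %% mc != 0L) stop("module_count must divide n", call. = FALSE)
  if (intra_p < 0 || intra_p > 1) stop("intra_p must lie in [0, 1]", call. = FALSE)
  if (inter_edges < 0L) stop("inter_edges must be >= 0", call. = FALSE)
  membership <- rep(seq_len(mc), each = n %/% mc)
  with_seed_if(seed, {
    A <- matrix(0L, n, n)
    same <- outer(membership, membership, "==")
    ut <- upper.tri(A)
    within <- which(ut & same)
    A[within] <- as.integer(stats::runif(length(within)) < intra_p)
    between <- which(ut & !same)
    if (inter_edges > length(between)) {
      stop("inter_edges exceeds the number of between-module pairs", call. = FALSE)
    }
    A[sample(between, inter_edges)] <- 1L
    A <- A + t(A)
    ser_graph(A, membership = membership)
  })
}

motif_classes <- c("t0", "t00", "t01", "t02", "t11", "t12", "t13")

#' Toy graph with a prescribed triangle motif around a focal pair
#'
#' Builds a random graph in which a designated pair of nodes carries at least
#' one triangle of the requested class of the motif hierarchy (see
#' [motif_inventory()]), with the rest of the graph filled in randomly. Used to
#' validate the pacemaker-based coactivation prediction motif by motif.
#'
#' The focal pair is nodes 1 and 2. Classes `t01`, `t02`, `t11` and `t12` get
#' `n_common` common neighbors; `t0` gets `n_common` triangles through the
#' pair; `t13` needs three mutually connected common neighbors; `t00` has no
#' common neighbors at all. Random filler edges are placed only among nodes
#' outside the focal structure so the focal pair's motif inventory is exactly
#' the constructed one.
#'
#' @param motif_class One of `"t0"`, `"t00"`, `"t01"`, `"t02"`, `"t11"`,
#'   `"t12"`, `"t13"`.
#' @param n Number of nodes (default 30).
#' @param n_common Number of common neighbors of the focal pair where the class
#'   uses them (default 6).
#' @param seed Optional integer seed.
#' @param filler_p Edge probability among filler nodes (background randomness).
#' @return A list with elements `graph` (a [ser_graph]) and `pair` (the focal
#'   pair, `c(1L, 2L)`).
#' @examples
#' fx <- generate_motif_fixture("t01", seed = 1)
#' motif_inventory(fx$graph, fx$pair[1], fx$pair[2])$t01_i
#' @export
generate_motif_fixture <- function(motif_class, n = 30, n_common = 6, seed = NULL,
                                   filler_p = 0.2) {
  motif_class <- match.arg(motif_class, motif_classes)
  n <- as.integer(n)
  i <- 1L; j <- 2L
  nc <- switch(motif_class, t00 = 0L, t13 = 3L, as.integer(n_common))
  # nodes 3 .. 2+nc are the common neighbors; extras are allocated after them
  need_extra <- switch(motif_class,
    t0 = 0L, t00 = 4L, t01 = 2L, t02 = 0L, t11 = 2L, t12 = 1L, t13 = 0L)
  if (2L + nc + need_extra > n) {
    stop("n too small to host motif class ", motif_class, call. = FALSE)
  }
  cn <- if (nc > 0L) 2L + seq_len(nc) else integer(0)
  extra <- if (need_extra > 0L) 2L + nc + seq_len(need_extra) else integer(0)
  from <- integer(0); to <- integer(0)
  add_edge <- function(u, v) {
    from <<- c(from, u); to <<- c(to, v)
  }
  for (k in cn) { add_edge(i, k); add_edge(j, k) }
  switch(motif_class,
    t0 = add_edge(i, j),
    t00 = { # one triangle hanging off each focal node, no common neighbors
      add_edge(i, extra[1]); add_edge(i, extra[2]); add_edge(extra[1], extra[2])
      add_edge(j, extra[3]); add_edge(j, extra[4]); add_edge(extra[3], extra[4])
    },
    t01 = { # a triangle at i through common neighbor 1, and at j through 2
      add_edge(i, extra[1]); add_edge(cn[1], extra[1])
      add_edge(j, extra[2]); add_edge(cn[2], extra[2])
    },
    t02 = add_edge(cn[1], cn[2]),
    t11 = { # triangle at common neighbor 1 away from the pair
      add_edge(cn[1], extra[1]); add_edge(cn[1], extra[2]); add_edge(extra[1], extra[2])
    },
    t12 = { # triangle through two connected common neighbors and a filler
      add_edge(cn[1], cn[2]); add_edge(cn[1], extra[1]); add_edge(cn[2], extra[1])
    },
    t13 = { add_edge(cn[1], cn[2]); add_edge(cn[2], cn[3]); add_edge(cn[1], cn[3]) }
  )
  A <- edges_to_adjacency(n, from, to)
  # "everything else random": background edges anywhere, except the (i, j)
  # edge itself and any edge that would change the pair's common-neighbor set
  with_seed_if(seed, {
    cand <- which(upper.tri(A) & A == 0L, arr.ind = TRUE)
    cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
    take <- stats::runif(nrow(cand)) < filler_p
    for (r in which(take)) {
      u <- cand[r, 1]; v <- cand[r, 2]
      if ((u == i && v == j)) next
      if (u %in% c(i, j) && A[setdiff(c(i, j), u), v] == 1L) next
      if (v %in% c(i, j) && A[setdiff(c(i, j), v), u] == 1L) next
      A[u, v] <- 1L; A[v, u] <- 1L
    }
  })
  list(graph = ser_graph(A), pair = c(i, j))
}

#' Canonical benchmark graphs
#'
#' The three 60-node benchmark topologies used throughout the evaluation
#' protocol, at roughly 400 undirected edges (~800 nonzero adjacency entries)
#' each: an Erdos-Renyi graph with 400 edges, a Barabasi-Albert graph with 8
#' attachments per node (416 edges), and four dense 15-node modules
#' (`intra_p = 0.9`) joined by 8 bridges (~390 edges).
#'
#' @param topology `"random"`, `"scale_free"`, or `"modular"`.
#' @param seed Optional integer seed.
#' @param n Number of nodes (default 60).
#' @return A [ser_graph].
#' @examples
#' edge_count(benchmark_graph("scale_free", seed = 1))
#' @export
benchmark_graph <- function(topology = c("random", "scale_free", "modular"),
                            seed = NULL, n = 60) {
  switch(match.arg(topology),
    random = generate_random(n, round(n * (n - 1) / 2 * 400 / 1770), seed = seed),
    scale_free = generate_scale_free(n, max(1L, round(8 * n / 60)), seed = seed),
    modular = generate_modular(n, 4, intra_p = 0.9,
                               inter_edges = max(1L, round(8 * n / 60)),
                               seed = seed)
  )
}

#' Per-node degree and clustering statistics
#'
#' @param graph A [ser_graph] (or adjacency matrix).
#' @return A tibble with one row per node: `node`, `degree`, `triangles`
#'   (number of triangles through the node), and `clustering` (local clustering
#'   coefficient, defined as 0 for degree < 2).
#' @examples
#' node_stats(generate_random(10, 20, seed = 1))
#' @export
node_stats <- function(graph) {
  g <- as_ser_graph(graph)
  A <- g$adjacency
  d <- rowSums(A)
  A2 <- A %*% A
  tri <- diag(A2 %*% A) / 2
  denom <- d * (d - 1) / 2
  clustering <- ifelse(d < 2, 0, tri / denom)
  tibble::tibble(
    node = seq_len(g$n_nodes),
    degree = as.integer(d),
    triangles = as.integer(round(tri)),
    clustering = clustering
  )
}
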