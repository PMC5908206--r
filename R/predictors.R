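#' State probability triple
#'
#' Validates a probability triple `(S, E, R)` on the initial-condition simplex.
#' Accepts a numeric vector of length 3 (ordered S, E, R), possibly named, or
#' a probability-mode [ic_probs()] object.
#'
#' @param probs Numeric length-3 vector or `ser_ic`.
#' @return Named numeric vector `c(S, E, R)`.
#' @export
state_probs <- function(probs) {
  if (inherits(probs, "ser_ic")) {
    if (probs$mode != "probability") {
      stop("exact-count initial conditions carry no probability triple; use ic_probs()",
           call. = FALSE)
    }
    probs <- probs$p
  }
  stopifnot(is.numeric(probs), length(probs) == 3)
  if (!is.null(names(probs))) probs <- probs[c("S", "E", "R")]
  if (any(probs < -1e-12) || abs(sum(probs) - 1) > 1e-12) {
    stop("state probabilities must be nonnegative and sum to 1", call. = FALSE)
  }
  stats::setNames(pmin(pmax(as.numeric(probs), 0), 1), c("S", "E", "R"))
}

new_prediction <- function(values, predictor, probs = NULL) {
  structure(list(values = values, predictor = predictor, probs = probs,
                 scaled_to_third = TRUE),
            class = "ser_prediction")
}

#' @export
print.ser_prediction <- function(x, ...) {
  cat("<ser_prediction> ", x$predictor, ", ", nrow(x$values), " nodes",
      if (!is.null(x$probs))
        paste0(", probs (S, E, R) = (", paste(signif(x$probs, 3), collapse = ", "), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Scale a topological matrix to the coactivation range
#'
#' Divides a nonnegative symmetric matrix by three times its maximum so that
#' its entries lie in `[0, 1/3]`, the range of the normalized coactivation
#' (1/3 being the maximum excitation frequency of a node in the SER
#' dynamics). Used to put the purely topological predictors (SC and TO) on
#' the same scale as simulated functional connectivity.
#'
#' @param matrix Nonnegative symmetric matrix with at least one positive entry.
#' @param predictor Label stored on the result.
#' @return A `ser_prediction` object.
#' @examples
#' normalize_topological(topological_overlap(generate_random(10, 20, seed = 1)), "TO")
#' @export
normalize_topological <- function(matrix, predictor = "topological") {
  m <- if (inherits(matrix, "ser_graph")) matrix$adjacency else as.matrix(matrix)
  mx <- max(m)
  if (mx <= 0) {
    stop("cannot normalize an all-zero matrix (no scale)", call. = FALSE)
  }
  new_prediction(m / (3 * mx), predictor)
}

#' Structural-connectivity predictor (normalized adjacency)
#' @param graph A [ser_graph].
#' @return A `ser_prediction` with entries in `[0, 1/3]`.
#' @export
predict_sc <- function(graph) {
  p <- normalize_topological(as_ser_graph(graph)$adjacency, "SC")
  p
}

#' Topological-overlap predictor (normalized matching index)
#' @param graph A [ser_graph].
#' @return A `ser_prediction` with entries in `[0, 1/3]`.
#' @export
predict_to <- function(graph) {
  normalize_topological(topological_overlap(graph), "TO")
}

#' Probability that a pair forms an active pacemaker with a common neighbor
#'
#' For a connected pair `(i, j)`, an isolated triangle through the pair and a
#' common neighbor oscillates indefinitely when initialized with a permutation
#' of (S, E, R). Under mean-field independence of initial states, the
#' probability that the pair and at least one of its common neighbors form
#' such an active pacemaker is
#' `2 A_ij [SR(1-(1-E)^m) + SE(1-(1-R)^m) + RE(1-(1-S)^m)]` with `m` the
#' number of common neighbors.
#'
#' @param graph A [ser_graph].
#' @param i,j Distinct nodes.
#' @param probs State probabilities (see [state_probs()]).
#' @return Probability in `[0, 1]`; 0 whenever `A_ij = 0`.
#' @export
pair_pacemaker_probability <- function(graph, i, j, probs) {
  g <- as_ser_graph(graph)
  p <- state_probs(probs)
  m <- length(common_neighbors(g, i, j))
  pair_pacemaker_value(g$adjacency[i, j], m, p)
}

pair_pacemaker_value <- function(a_ij, m, p) {
  2 * a_ij * (p[["S"]] * p[["R"]] * (1 - (1 - p[["E"]])^m) +
              p[["S"]] * p[["E"]] * (1 - (1 - p[["R"]])^m) +
              p[["R"]] * p[["E"]] * (1 - (1 - p[["S"]])^m))
}

#' Probability that a common neighbor is not part of an active pacemaker
#'
#' Given `c_ijk` triangles around a common neighbor (excluding the one through
#' the focal pair), the probability that none of them is initialized as a
#' pacemaker is `S(1-2RE)^c + E(1-2SR)^c + R(1-2SE)^c`: conditional on the
#' neighbor's own state, each surrounding triangle becomes a pacemaker exactly
#' when its remaining two nodes carry the two missing states.
#'
#' @param c_ijk Nonnegative triangle count (see
#'   [triangles_per_common_neighbor()]).
#' @param probs State probabilities.
#' @return Probability in `[0, 1]`; equals 1 when `c_ijk = 0`.
#' @export
neighbor_silence_probability <- function(c_ijk, probs) {
  p <- state_probs(probs)
  stopifnot(all(c_ijk >= 0))
  p[["S"]] * (1 - 2 * p[["R"]] * p[["E"]])^c_ijk +
    p[["E"]] * (1 - 2 * p[["S"]] * p[["R"]])^c_ijk +
    p[["R"]] * (1 - 2 * p[["S"]] * p[["E"]])^c_ijk
}

#' First pacemaker-based coactivation prediction (FC1)
#'
#' Composes the pair-pacemaker probability and the neighbor-silence
#' probabilities under mean-field independence: a pair coactivates when it is
#' not itself locked into a pacemaker and at least one of its common
#' neighbors is driven by one,
#' `FC1_ij = (1 - pair_pm_ij) (1 - prod_k silence_ijk) / 3`.
#' The empty product over common neighbors is 1, so pairs without common
#' neighbors predict 0.
#'
#' @param graph A [ser_graph].
#' @param probs State probabilities.
#' @param c_method Source of the per-neighbor triangle counts; see
#'   [triangles_per_common_neighbor()].
#' @return A `ser_prediction` with symmetric values in `[0, 1/3]`.
#' @examples
#' predict_fc1(generate_random(20, 60, seed = 1), ic_probs(E = 0.2))
#' @export
predict_fc1 <- function(graph, probs, c_method = c("exact", "formula")) {
  g <- as_ser_graph(graph)
  c_method <- match.arg(c_method)
  p <- state_probs(probs)
  A <- g$adjacency
  n <- nrow(A)
  TO <- topological_overlap(g)
  tri <- triangles_per_node(A)
  # silence probability depends only on c; tabulate over 0..max
  cmax <- max(tri)
  sil <- vapply(0:(cmax + 1), function(cc) neighbor_silence_probability(cc, p),
                numeric(1))
  vals <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      cn <- which(A[i, ] == 1L & A[j, ] == 1L)
      if (!length(cn)) next
      cvec <- pmax(tri[cn] - A[i, j], 0L)
      prod_sil <- prod(sil[cvec + 1L])
      delta <- pair_pacemaker_value(A[i, j], length(cn), p)
      vals[i, j] <- (1 - delta) * (1 - prod_sil) / 3
    }
  }
  vals <- vals + t(vals)
  new_prediction(vals, "FC1", p)
}

# Successor map of the excitation cycle S -> E -> R -> S (indices 1, 2, 3).
SUCC <- c(2L, 3L, 1L)

#' Pacemaker building-block probabilities
#'
#' The elementary probabilities from which the pacemaker-based predictions are
#' composed, for a given initial-state triple: the probability that a free
#' triangle is initialized as a pacemaker (`6 S E R`); the conditional
#' probability that a triangle through a node of known state is a pacemaker
#' (`2ER` given S, `2SR` given E, `2SE` given R), and its directional halves
#' (the orientation of excitation propagation within the triangle); and the
#' conditional probabilities given two vertex states (the third state's
#' probability when the two differ, 0 when equal).
#'
#' @param probs State probabilities.
#' @return A list with elements `free`, `given_one` (named vector),
#'   `half` (named vector, one propagation orientation), and `given_two`
#'   (3 x 3 matrix indexed by the two known states).
#' @examples
#' triangle_activation_terms(c(1, 1, 1) / 3)
#' @export
triangle_activation_terms <- function(probs) {
  p <- state_probs(probs)
  states <- names(p)
  half <- vapply(1:3, function(a) prod(p[-a]), numeric(1))
  names(half) <- states
  given_two <- matrix(0, 3, 3, dimnames = list(states, states))
  for (a in 1:3) for (b in 1:3) {
    if (a != b) given_two[a, b] <- p[[setdiff(1:3, c(a, b))]]
  }
  list(free = 6 * prod(p), given_one = 2 * half, half = half,
       given_two = given_two)
}

# The 8 initializations of a 4-cycle (i, k, j, k') that sustain a traveling
# wave (a "pacemaker of length 4"): the rotations of (S, E, R, S) around the
# cycle and of its mirror image. Rows are state indices for (i, k, j, k').
wave4_patterns <- local({
  base <- c(1L, 2L, 3L, 1L)  # S E R S
  rot <- function(v, s) v[((seq_along(v) - 1L + s) %% 4L) + 1L]
  pats <- lapply(0:3, function(s) rot(base, s))
  mirror <- base[c(1L, 4L, 3L, 2L)]
  pats <- c(pats, lapply(0:3, function(s) rot(mirror, s)))
  do.call(rbind, pats)
})

# P(two given common neighbors complete a length-4 pacemaker with the pair),
# for pair states (a, b); zero when a == b (no wave has equal opposite states).
wave4_prob <- function(a, b, p) {
  rows <- wave4_patterns[wave4_patterns[, 1] == a & wave4_patterns[, 3] == b, ,
                         drop = FALSE]
  if (!nrow(rows)) return(0)
  sum(p[rows[, 2]] * p[rows[, 4]])
}

# Systematic coactivation probability for one pair, given its motif totals and
# the initial-state triple. `cnt` carries t0, t00_i, t00_j, t01_i, t01_j, t02,
# t11, t12, nc. See the methods vignette for the derivation.
fc2_pair_probability <- function(cnt, p) {
  q <- 2 * vapply(1:3, function(a) prod(p[-a]), numeric(1))  # pacemaker | one state
  h <- q / 2                                                  # one orientation
  p6 <- 6 * prod(p)                                           # free triangle
  t01_tot <- cnt$t01_i + cnt$t01_j
  t1x <- cnt$t11 + cnt$t12
  total <- 0
  for (a in 1:3) {
    if (p[a] == 0) next
    # same-state pair (a, a): any of the guaranteed synchronizing pacemakers
    # (t01 with the excitation entering from the common neighbor, any t02,
    # any t11/t12 driving both nodes at one step), or an adjacent pacemaker
    # locking each node in its common phase
    PG <- 1 - (1 - h[a])^t01_tot * (1 - q[a])^(2 * cnt$t02) * (1 - p6)^t1x
    PLi <- 1 - (1 - q[a])^cnt$t00_i * (1 - h[a])^cnt$t01_i
    PLj <- 1 - (1 - q[a])^cnt$t00_j * (1 - h[a])^cnt$t01_j
    total <- total + p[a]^2 * (1 - (1 - PG) * (1 - PLi * PLj))
    for (b in 1:3) {
      if (b == a || p[b] == 0) next
      cc <- setdiff(1:3, c(a, b))
      # no pacemaker through the pair itself
      no_t0 <- (1 - p[cc])^cnt$t0
      # lock probabilities: any adjacent pacemaker fixes a node's phase
      Li <- 1 - (1 - q[a])^(cnt$t00_i + cnt$t01_i + cnt$t02)
      Lj <- 1 - (1 - q[b])^(cnt$t00_j + cnt$t01_j + cnt$t02)
      X4 <- (1 - wave4_prob(a, b, p))^max(cnt$nc - 1, 0)
      # i locked by a t01 pacemaker whose common neighbor re-excites both
      # nodes in i's phase; j must be free and not enslaved by a
      # wrong-direction t01 or a t02 pacemaker at i
      PA <- (1 - (1 - h[a])^cnt$t01_i) * (1 - h[a])^cnt$t01_i *
        (1 - q[a])^cnt$t02 * (1 - Lj) * X4
      PB <- (1 - (1 - h[b])^cnt$t01_j) * (1 - h[b])^cnt$t01_j *
        (1 - q[b])^cnt$t02 * (1 - Li) * X4
      # neither node locked, both driven at one step by a t11 pacemaker
      PC11 <- (1 - Li) * (1 - Lj) * (1 - (1 - p6)^cnt$t11) * X4
      # a t12 pacemaker drives both nodes through two common neighbors, i.e.
      # on two of the three phase slots at once; unlike t11, a pacemaker
      # adjacent to one node of the pair is tolerated: the drive set still
      # contains the locked phase when the pacemaker's outer vertex differs
      # from it (probability 2/3), while an unlocked pair faces a two-phase
      # ambiguity (probability 1/2); two locked nodes can never be re-phased
      PC12 <- (Li * (1 - Lj) + Lj * (1 - Li)) *
                (1 - (1 - p6 * 2 / 3)^cnt$t12) * X4 +
              (1 - Li) * (1 - Lj) * (1 - (1 - p6 / 2)^cnt$t12) * X4
      U <- 1 - (1 - pmin(PA + PB + PC11, 1)) * (1 - PC12)
      total <- total + p[a] * p[b] * no_t0 * U
    }
  }
  total
}

#' Second pacemaker-based coactivation prediction (FC2)
#'
#' Predicts pairwise coactivation by enumerating the full triangle-motif
#' hierarchy around each pair and composing, per initial pair-state
#' configuration, the probabilities that surrounding pacemakers
#' systematically synchronize (or desynchronize) the pair. Decomposed over
#' the nine pair-state configurations weighted by their joint initial
#' probability:
#' \itemize{
#'   \item a triangle through both nodes (`t0`) used as a pacemaker locks the
#'     pair in distinct phases and cancels all coactivation;
#'   \item for same-state pairs, coactivation is guaranteed by any `t02`
#'     pacemaker, a `t01` pacemaker whose excitation propagates from the
#'     common neighbor into the pair, or any `t11`/`t12` pacemaker (which
#'     reaches both nodes at one step), and otherwise requires an adjacent
#'     pacemaker locking each node;
#'   \item for different-state pairs, the pair synchronizes through a
#'     correctly oriented `t01` pacemaker (with the other node unlocked and
#'     not enslaved by a wrong-direction `t01` or `t02` pacemaker) or, with
#'     both nodes unlocked, through a `t11`/`t12` pacemaker; configurations
#'     in which both nodes are locked by adjacent pacemakers are excluded, as
#'     are initializations in which two common neighbors close a sustained
#'     length-4 wave with the pair;
#'   \item `t13` triangles never contribute directly.
#' }
#' Per-triangle pacemaker events are treated as independent (mean-field), as
#' in [predict_fc1()]. The factor 1/3 converts the synchronization
#' probability into a coactivation rate (the maximum excitation frequency).
#'
#' @param graph A [ser_graph].
#' @param probs State probabilities.
#' @return A `ser_prediction` with symmetric values in `[0, 1/3]`.
#' @examples
#' predict_fc2(generate_random(20, 60, seed = 1), ic_probs(E = 0.2))
#' @export
predict_fc2 <- function(graph, probs) {
  g <- as_ser_graph(graph)
  p <- state_probs(probs)
  mt <- motif_totals(g)
  n <- g$n_nodes
  A <- g$adjacency
  vals <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      cnt <- list(
        t0 = mt$t0[i, j], t00_i = mt$t00_i[i, j], t00_j = mt$t00_i[j, i],
        t01_i = mt$t01_i[i, j], t01_j = mt$t01_i[j, i],
        t02 = mt$t02[i, j], t11 = mt$t11[i, j], t12 = mt$t12[i, j],
        nc = mt$TO[i, j]
      )
      vals[i, j] <- fc2_pair_probability(cnt, p) / 3
    }
  }
  vals <- vals + t(vals)
  clip_hi <- vals > 1 / 3 + 1e-9
  if (any(clip_hi)) {
    warning("FC2 values above 1/3 clipped (max excess ",
            signif(max(vals - 1 / 3), 3), ")")
  }
  vals <- pmin(pmax(vals, 0), 1 / 3)
  new_prediction(vals, "FC2", p)
}

#' Compute one of the four analytical predictors by name
#'
#' @param graph A [ser_graph].
#' @param predictor One of `"SC"`, `"TO"`, `"FC1"`, `"FC2"`.
#' @param probs State probabilities (ignored by SC and TO).
#' @return A `ser_prediction`.
#' @export
predict_fc <- function(graph, predictor = c("SC", "TO", "FC1", "FC2"),
                       probs = NULL) {
  predictor <- match.arg(predictor)
  switch(predictor,
    SC = predict_sc(graph),
    TO = predict_to(graph),
    FC1 = predict_fc1(graph, probs),
    FC2 = predict_fc2(graph, probs)
  )
}
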