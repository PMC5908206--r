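# Internal state coding: S = 0L, E = 1L, R = 2L.
STATE_LEVELS <- c("S", "E", "R")

state_to_int <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  m <- match(as.character(x), STATE_LEVELS) - 1L
  if (anyNA(m)) stop("states must be among S, E, R", call. = FALSE)
  m
}

int_to_state <- function(x) STATE_LEVELS[x + 1L]

#' Initial-condition specifications
#'
#' An initial condition is either a probability triple over the three node
#' states (independent per-node draws) or exact state counts (a uniformly
#' random assignment with those counts).
#'
#' `ic_probs()` builds a probability-mode specification; `S + E + R` must equal
#' 1 (tolerance 1e-12). `ic_counts()` builds an exact-count specification; when
#' `n_S`/`n_R` are left `NULL` the non-excited nodes are equipartitioned into S
#' and R at draw time (an odd remainder goes to S or R with equal probability).
#'
#' @param S,E,R State probabilities in `[0, 1]`.
#' @param n_E,n_S,n_R Exact state counts.
#' @return An object of class `ser_ic`.
#' @examples
#' ic_probs(E = 0.2)
#' ic_counts(n_E = 12)
#' @export
ic_probs <- function(E, S = (1 - E) / 2, R = (1 - E) / 2) {
  p <- c(S = S, E = E, R = R)
  if (any(p < -1e-12) || any(p > 1 + 1e-12)) {
    stop("state probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-12) {
    stop("state probabilities must sum to 1 (got ", sum(p), ")", call. = FALSE)
  }
  structure(list(mode = "probability", p = pmin(pmax(p, 0), 1)), class = "ser_ic")
}

#' @rdname ic_probs
#' @export
ic_counts <- function(n_E, n_S = NULL, n_R = NULL) {
  if (is.null(n_S) != is.null(n_R)) {
    stop("give both n_S and n_R, or neither", call. = FALSE)
  }
  structure(
    list(mode = "exact_count", n_E = as.integer(n_E),
         n_S = if (!is.null(n_S)) as.integer(n_S),
         n_R = if (!is.null(n_R)) as.integer(n_R)),
    class = "ser_ic"
  )
}

#' @export
print.ser_ic <- function(x, ...) {
  if (x$mode == "probability") {
    cat("<ser_ic> probabilities S =", x$p[["S"]], "E =", x$p[["E"]],
        "R =", x$p[["R"]], "\n")
  } else {
    cat("<ser_ic> exact counts n_E =", x$n_E,
        if (is.null(x$n_S)) "(S/R equipartitioned)" else
          paste("n_S =", x$n_S, "n_R =", x$n_R), "\n")
  }
  invisible(x)
}

# Probability triple implied by an IC for a graph of n nodes (used to feed the
# analytical predictors at the matching point of the initial-condition simplex).
ic_to_probs <- function(ic, n) {
  if (ic$mode == "probability") return(ic$p)
  rem <- n - ic$n_E
  n_S <- if (is.null(ic$n_S)) rem / 2 else ic$n_S
  n_R <- if (is.null(ic$n_R)) rem / 2 else ic$n_R
  c(S = n_S / n, E = ic$n_E / n, R = n_R / n)
}

# Draw `runs` initial state vectors as an n x runs integer matrix.
draw_initial_matrix <- function(n, ic, runs) {
  if (ic$mode == "probability") {
    matrix(sample.int(3L, n * runs, replace = TRUE, prob = ic$p) - 1L, n, runs)
  } else {
    rem <- n - ic$n_E
    n_S <- if (is.null(ic$n_S)) rem %/% 2L else ic$n_S
    n_R <- if (is.null(ic$n_R)) rem %/% 2L else ic$n_R
    leftover <- n - ic$n_E - n_S - n_R
    if (leftover < 0L || leftover > 1L) {
      stop("state counts must sum to the number of nodes", call. = FALSE)
    }
    base <- c(rep(0L, n_S), rep(1L, ic$n_E), rep(2L, n_R))
    vapply(seq_len(runs), function(r) {
      v <- base
      if (leftover == 1L) v <- c(v, sample(c(0L, 2L), 1L))
      v[sample.int(n)]
    }, integer(n))
  }
}

#' Draw a random initial state
#'
#' @param graph A [ser_graph] (only its node count is used).
#' @param ic An initial condition from [ic_probs()] or [ic_counts()].
#' @param seed Optional integer seed.
#' @return A character vector of per-node states among `"S"`, `"E"`, `"R"`.
#' @examples
#' draw_initial_state(generate_random(10, 15, seed = 1), ic_counts(n_E = 2), seed = 1)
#' @export
draw_initial_state <- function(graph, ic, seed = NULL) {
  g <- as_ser_graph(graph)
  int_to_state(with_seed_if(seed, draw_initial_matrix(g$n_nodes, ic, 1L))[, 1])
}

# One synchronous update on integer-coded state columns (n x runs matrix).
step_matrix <- function(A, states) {
  excited <- states == 1L
  fired <- (states == 0L) & ((A %*% excited) > 0)
  out <- matrix(0L, nrow(states), ncol(states))
  out[states == 1L] <- 2L
  out[fired] <- 1L
  out
}

#' One synchronous SER update
#'
#' Applies the deterministic update rules to every node at once: a susceptible
#' node becomes excited if at least one neighbor is excited, an excited node
#' becomes refractory, a refractory node becomes susceptible.
#'
#' @param graph A [ser_graph].
#' @param state Character (or integer-coded) state vector of length `n_nodes`.
#' @return The updated state vector (character).
#' @examples
#' ser_step(ser_graph(1 - diag(3)), c("S", "S", "E"))
#' @export
ser_step <- function(graph, state) {
  g <- as_ser_graph(graph)
  s <- state_to_int(state)
  stopifnot(length(s) == g$n_nodes)
  int_to_state(step_matrix(g$adjacency, matrix(s, ncol = 1L))[, 1])
}

#' Simulate one deterministic SER trajectory
#'
#' @param graph A [ser_graph].
#' @param init Initial state vector (characters among S/E/R).
#' @param steps Number of update steps.
#' @return An object of class `ser_trajectory`: an `n_nodes x (steps + 1)`
#'   character matrix whose first column is the initial condition.
#' @examples
#' ser_run(ser_graph(1 - diag(3)), c("S", "E", "R"), steps = 6)
#' @export
ser_run <- function(graph, init, steps) {
  g <- as_ser_graph(graph)
  steps <- as.integer(steps)
  stopifnot(steps >= 1L)
  s <- state_to_int(init)
  stopifnot(length(s) == g$n_nodes)
  out <- matrix(NA_integer_, g$n_nodes, steps + 1L)
  out[, 1L] <- s
  cur <- matrix(s, ncol = 1L)
  for (t in seq_len(steps)) {
    cur <- step_matrix(g$adjacency, cur)
    out[, t + 1L] <- cur[, 1L]
  }
  structure(int_to_state(out), dim = dim(out),
            dimnames = list(NULL, paste0("t", 0:steps)),
            class = c("ser_trajectory", "matrix"))
}

#' Per-node excitation frequency of a trajectory
#'
#' @param traj A `ser_trajectory`.
#' @param include_initial_state Count the initial column as a time point?
#' @return Numeric vector: fraction of counted time points each node spends
#'   excited.
#' @export
excitation_frequency <- function(traj, include_initial_state = FALSE) {
  m <- unclass(traj)
  if (!include_initial_state) m <- m[, -1L, drop = FALSE]
  rowMeans(m == "E")
}

#' Simulation configuration
#'
#' @param runs Number of independent runs (default 5000).
#' @param steps Time steps per run (default 50).
#' @param include_initial_state Count the initial condition (t = 0) in the
#'   coactivation sum? Default `FALSE`: initial-state coincidences reflect the
#'   statistics of the initial condition, not the dynamics.
#' @param seed Optional integer master seed.
#' @return A list of class `ser_sim_config`.
#' @export
sim_config <- function(runs = 5000, steps = 50, include_initial_state = FALSE,
                       seed = NULL) {
  stopifnot(runs >= 1, steps >= 1)
  structure(list(runs = as.integer(runs), steps = as.integer(steps),
                 include_initial_state = isTRUE(include_initial_state),
                 seed = seed),
            class = "ser_sim_config")
}

new_coactivation <- function(values, runs, steps, normalized = TRUE, se = NULL) {
  structure(list(values = values, runs = runs, steps = steps,
                 normalized = normalized, se = se),
            class = "ser_coactivation")
}

#' @export
print.ser_coactivation <- function(x, ...) {
  cat("<ser_coactivation> ", nrow(x$values), " nodes, runs = ", x$runs,
      ", steps = ", x$steps,
      ", max off-diagonal = ", signif(max(offdiag(x$values)), 4), "\n", sep = "")
  invisible(x)
}

offdiag <- function(m) m[row(m) != col(m)]

#' Simulated coactivation (functional connectivity) matrix
#'
#' Runs the deterministic SER model from many random initial conditions and
#' counts, for every pair of nodes, the time steps at which both are excited
#' simultaneously. The count is summed over time steps `1..steps` (optionally
#' including t = 0) and over runs, then normalized by runs x counted steps, so
#' entries lie in approximately `[0, 1/3]` (1/3 is the maximum excitation
#' frequency of a node in the SER dynamics).
#'
#' @param graph A [ser_graph].
#' @param ic An initial condition ([ic_probs()] / [ic_counts()]).
#' @param config A [sim_config()].
#' @param detail Also estimate entrywise Monte-Carlo standard errors from the
#'   per-run spread (costs O(pairs x runs); intended for small graphs).
#' @return A `ser_coactivation` object; `$values` is the normalized symmetric
#'   matrix (the diagonal holds each node's excitation frequency and is
#'   excluded from all downstream comparisons), `$se` the standard errors when
#'   `detail = TRUE`.
#' @examples
#' g <- generate_random(20, 60, seed = 1)
#' fc <- accumulate_coactivation(g, ic_counts(n_E = 4), sim_config(200, 30, seed = 1))
#' max(fc$values[upper.tri(fc$values)])
#' @export
accumulate_coactivation <- function(graph, ic, config = sim_config(),
                                    detail = FALSE) {
  g <- as_ser_graph(graph)
  A <- g$adjacency
  n <- g$n_nodes
  runs <- config$runs
  steps <- config$steps
  with_seed_if(config$seed, {
    states <- draw_initial_matrix(n, ic, runs)
    C <- matrix(0, n, n)
    if (detail) {
      pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
      per_run <- matrix(0L, nrow(pairs), runs)
    }
    add_counts <- function(st) {
      Em <- st == 1L
      storage.mode(Em) <- "double"
      C <<- C + tcrossprod(Em)
      if (detail) {
        per_run <<- per_run + (st[pairs[, 1], , drop = FALSE] == 1L) *
                              (st[pairs[, 2], , drop = FALSE] == 1L)
      }
    }
    if (config$include_initial_state) add_counts(states)
    for (t in seq_len(steps)) {
      states <- step_matrix(A, states)
      add_counts(states)
    }
    denom_t <- steps + as.integer(config$include_initial_state)
    se <- NULL
    if (detail) {
      x <- per_run / denom_t
      v <- apply(x, 1L, stats::var)
      se <- matrix(0, n, n)
      se[pairs] <- sqrt(v / runs)
      se <- se + t(se)
    }
    new_coactivation(C / (runs * denom_t), runs, steps, se = se)
  })
}

#' Attractor period of a trajectory
#'
#' Finds the smallest lag `p >= 1` such that the global state vector repeats
#' with lag `p` at every time point beyond a transient.
#'
#' @param traj A `ser_trajectory`.
#' @param max_transient Number of initial steps allowed as transient
#'   (default 20).
#' @return The period (typically 1 for a frozen all-susceptible state or 3 for
#'   the generic oscillation), or 0 if no repeat is found in the trajectory.
#' @examples
#' detect_period(ser_run(ser_graph(1 - diag(3)), c("S", "E", "R"), 12), 2)
#' @export
detect_period <- function(traj, max_transient = 20) {
  m <- unclass(traj)
  T_idx <- ncol(m) - 1L                 # time indices 0..T_idx
  t0 <- min(max_transient, T_idx)
  keys <- apply(m, 2L, paste, collapse = "")
  for (p in seq_len(max(T_idx - t0, 0L))) {
    span <- (t0 + 1L):(T_idx + 1L - p)  # column indices (1-based) of t in [t0, T-p]
    if (length(span) < 1L) break
    if (all(keys[span] == keys[span + p])) return(p)
  }
  0L
}

#' Exact expected coactivation by full state-space enumeration
#'
#' For small graphs the deterministic SER model admits an exact functional
#' connectivity: every one of the `3^n` initial states is enumerated, its
#' trajectory simulated, and its normalized coactivation weighted by the
#' product of per-node initial-state probabilities. Serves as the independent
#' oracle for the Monte-Carlo simulator.
#'
#' @param graph A [ser_graph] with at most `cap` nodes.
#' @param probs Probability triple `c(S, E, R)` summing to 1 (or a [ic_probs()]
#'   object).
#' @param steps Time steps.
#' @param include_initial_state Count t = 0 in the coactivation sum?
#' @param cap Refuse graphs larger than this (default 12; the enumeration is
#'   exponential in `n`).
#' @return A `ser_coactivation` object with `runs = NA` (exact expectation).
#' @examples
#' k3 <- ser_graph(1 - diag(3))
#' exact_expected_coactivation(k3, c(1, 1, 1) / 3, steps = 50)$values[1, 2]  # 1/1350
#' @export
exact_expected_coactivation <- function(graph, probs, steps,
                                        include_initial_state = FALSE,
                                        cap = 12) {
  g <- as_ser_graph(graph)
  n <- g$n_nodes
  if (n > cap) {
    stop("graph has ", n, " nodes; the 3^n enumeration is capped at ", cap,
         call. = FALSE)
  }
  if (inherits(probs, "ser_ic")) {
    stopifnot(probs$mode == "probability")
    probs <- probs$p
  }
  stopifnot(length(probs) == 3, abs(sum(probs) - 1) < 1e-12)
  steps <- as.integer(steps)
  n_states <- 3L^n
  codes <- 0:(n_states - 1L)
  states <- matrix(0L, n, n_states)
  rem <- codes
  for (k in seq_len(n)) {
    states[k, ] <- rem %% 3L
    rem <- rem %/% 3L
  }
  w <- apply(states, 2L, function(s) prod(probs[s + 1L]))
  keep <- w > 0
  states <- states[, keep, drop = FALSE]
  w <- w[keep]
  C <- matrix(0, n, n)
  add <- function(st) {
    Em <- st == 1L
    storage.mode(Em) <- "double"
    Ew <- sweep(Em, 2L, w, "*")
    C <<- C + Ew %*% t(Em)
  }
  if (include_initial_state) add(states)
  for (t in seq_len(steps)) {
    states <- step_matrix(g$adjacency, states)
    add(states)
  }
  denom_t <- steps + as.integer(include_initial_state)
  new_coactivation(C / denom_t, runs = NA_integer_, steps = steps)
}
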