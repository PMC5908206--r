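values_of <- function(x) {
  if (inherits(x, c("ser_coactivation", "ser_prediction"))) x$values else as.matrix(x)
}

#' Compare a simulated coactivation matrix with a prediction
#'
#' Pearson correlation and mean signed difference (simulated minus predicted)
#' over the off-diagonal upper-triangle entries — each unordered pair counted
#' once, the diagonal excluded. A negative mean signed difference therefore
#' indicates over-prediction. When either matrix has zero variance over the
#' compared pairs the correlation is undefined and flagged rather than
#' reported as NaN; the mean difference is still computed.
#'
#' @param sim Simulated coactivation (a `ser_coactivation` or matrix).
#' @param pred Prediction (a `ser_prediction` or matrix).
#' @return A one-row tibble: `pearson`, `msd`, `n_pairs`, `degenerate`.
#' @examples
#' g <- generate_random(20, 60, seed = 1)
#' fc <- accumulate_coactivation(g, ic_counts(4), sim_config(200, 30, seed = 1))
#' compare_fc(fc, predict_to(g))
#' @export
compare_fc <- function(sim, pred) {
  s <- values_of(sim)
  q <- values_of(pred)
  stopifnot(all(dim(s) == dim(q)))
  ut <- upper.tri(s)
  sv <- s[ut]
  qv <- q[ut]
  degenerate <- stats::sd(sv) == 0 || stats::sd(qv) == 0
  tibble::tibble(
    pearson = if (degenerate) NA_real_ else stats::cor(sv, qv),
    msd = mean(sv - qv),
    n_pairs = length(sv),
    degenerate = degenerate
  )
}

predictor_matrices <- function(graph, predictors, probs) {
  stats::setNames(
    lapply(predictors, function(nm) predict_fc(graph, nm, probs)),
    predictors
  )
}

compare_many <- function(sim, preds) {
  purrr::imap_dfr(preds, function(pr, nm) {
    dplyr::mutate(compare_fc(sim, pr), predictor = nm, .before = 1)
  })
}

new_sweep <- function(tbl, axis) {
  structure(tbl, class = c("ser_sweep", class(tbl)), axis = axis)
}

#' Sweep initial conditions along the excited-fraction axis
#'
#' For each requested number of initially excited nodes, simulates the
#' coactivation matrix (non-excited nodes equipartitioned into S and R),
#' evaluates the requested predictors at the matching point of the
#' probability simplex, and compares them with the simulation.
#'
#' @param graph A [ser_graph].
#' @param predictors Character vector among `"SC"`, `"TO"`, `"FC1"`, `"FC2"`.
#' @param config A [sim_config()]; its seed drives all randomness.
#' @param E_counts Integer counts of initially excited nodes (default: every
#'   integer from 0 to `n_nodes`).
#' @return A tibble of class `ser_sweep`: one row per E count x predictor with
#'   `pearson`, `msd`, `n_pairs`, `degenerate`.
#' @examples
#' g <- generate_modular(24, 4, 0.9, 6, seed = 1)
#' sweep_E_line(g, "SC", sim_config(100, 30, seed = 1), E_counts = c(4, 8))
#' @export
sweep_E_line <- function(graph, predictors = c("SC", "TO", "FC1", "FC2"),
                         config = sim_config(), E_counts = NULL) {
  g <- as_ser_graph(graph)
  n <- g$n_nodes
  if (is.null(E_counts)) E_counts <- 0:n
  stopifnot(all(E_counts >= 0), all(E_counts <= n))
  seeds <- derive_seeds(config$seed, length(E_counts))
  rows <- purrr::map2_dfr(E_counts, seeds, function(ne, sd_i) {
    ic <- ic_counts(n_E = ne)
    cfg <- sim_config(config$runs, config$steps, config$include_initial_state,
                      seed = sd_i)
    sim <- accumulate_coactivation(g, ic, cfg)
    preds <- predictor_matrices(g, predictors, ic_to_probs(ic, n))
    dplyr::mutate(compare_many(sim, preds), E_count = ne, .before = 1)
  })
  new_sweep(rows, axis = "E_line")
}

# Independent per-task seeds derived from a master seed (NULL stays NULL).
derive_seeds <- function(seed, k) {
  if (is.null(seed)) return(vector("list", k))
  withr::with_seed(as.integer(seed), as.list(sample.int(.Machine$integer.max, k)))
}

#' Lattice of the initial-condition simplex
#' @param step Lattice spacing (must divide 1).
#' @return Tibble of `(S, E, R)` triples summing to 1.
#' @export
simplex_grid <- function(step = 0.1) {
  m <- round(1 / step)
  stopifnot(abs(m * step - 1) < 1e-9)
  pts <- expand.grid(iE = 0:m, iS = 0:m)
  pts <- pts[pts$iE + pts$iS <= m, ]
  tibble::tibble(S = pts$iS / m, E = pts$iE / m, R = (m - pts$iE - pts$iS) / m)
}

#' Sweep the full initial-condition simplex
#'
#' Simulates the coactivation matrix at every point of a triangular lattice
#' over the state-probability simplex (independent per-node draws) and
#' compares each requested predictor at the same point.
#'
#' @inheritParams sweep_E_line
#' @param grid_step Lattice spacing of the simplex grid.
#' @return A tibble of class `ser_sweep` with columns `S`, `E`, `R`,
#'   `predictor`, `pearson`, `msd`, `n_pairs`, `degenerate`.
#' @export
sweep_simplex <- function(graph, predictors = c("SC", "TO", "FC1", "FC2"),
                          config = sim_config(), grid_step = 0.1) {
  g <- as_ser_graph(graph)
  grid <- simplex_grid(grid_step)
  seeds <- derive_seeds(config$seed, nrow(grid))
  rows <- purrr::map_dfr(seq_len(nrow(grid)), function(r) {
    p <- c(S = grid$S[r], E = grid$E[r], R = grid$R[r])
    ic <- ic_probs(E = p[["E"]], S = p[["S"]], R = p[["R"]])
    cfg <- sim_config(config$runs, config$steps, config$include_initial_state,
                      seed = seeds[[r]])
    sim <- accumulate_coactivation(g, ic, cfg)
    preds <- predictor_matrices(g, predictors, p)
    dplyr::mutate(compare_many(sim, preds),
                  S = p[["S"]], E = p[["E"]], R = p[["R"]], .before = 1)
  })
  new_sweep(rows, axis = "simplex")
}

#' Robustness of the predictions across density and realizations
#'
#' Generates `n_graphs` Erdos-Renyi graphs at each density, simulates the
#' coactivation matrix at the given excited count, and summarizes each
#' predictor's correlation and mean signed difference across realizations.
#'
#' @param densities Edge densities in `(0, 1]`.
#' @param n_graphs Realizations per density.
#' @param n Nodes per graph.
#' @param config A [sim_config()].
#' @param predictors Predictors to evaluate.
#' @param E_count Number of initially excited nodes.
#' @return A tibble: one row per density x predictor with means and standard
#'   deviations of `pearson` and `msd` across realizations.
#' @export
density_robustness <- function(densities = seq(0.1, 0.6, by = 0.1),
                               n_graphs = 50, n = 60,
                               config = sim_config(),
                               predictors = c("SC", "TO", "FC1", "FC2"),
                               E_count = 12) {
  stopifnot(all(densities > 0), all(densities <= 1))
  m_max <- n * (n - 1) / 2
  seeds <- derive_seeds(config$seed, length(densities) * n_graphs)
  k <- 0L
  per_real <- purrr::map_dfr(densities, function(d) {
    purrr::map_dfr(seq_len(n_graphs), function(r) {
      k <<- k + 1L
      sd_i <- seeds[[k]]
      g <- generate_random(n, round(d * m_max), seed = sd_i)
      cfg <- sim_config(config$runs, config$steps, config$include_initial_state,
                        seed = sd_i)
      sim <- accumulate_coactivation(g, ic_counts(E_count), cfg)
      preds <- predictor_matrices(g, predictors, ic_to_probs(ic_counts(E_count), n))
      dplyr::mutate(compare_many(sim, preds),
                    density = d, realization = r, .before = 1)
    })
  })
  out <- dplyr::summarise(
    dplyr::group_by(per_real, .data$density, .data$predictor),
    mean_pearson = mean(.data$pearson, na.rm = TRUE),
    sd_pearson = stats::sd(.data$pearson, na.rm = TRUE),
    mean_msd = mean(.data$msd),
    sd_msd = stats::sd(.data$msd),
    n_graphs = dplyr::n(),
    .groups = "drop"
  )
  out$flagged <- out$n_graphs < 2
  out
}

#' Validate the pacemaker prediction motif class by motif class
#'
#' Rebuilds, for each triangle-motif class, a toy fixture graph around a focal
#' pair, sweeps the number of initially excited nodes, and records the
#' simulated and predicted coactivation of the focal pair. The pacemaker-based
#' prediction should track the simulated curve more closely than the simpler
#' predictors.
#'
#' @param motif_classes Character vector among the seven motif classes.
#' @param config A [sim_config()].
#' @param n,n_common Fixture size parameters (30 nodes, 6 common neighbors).
#' @param E_counts Excited counts to sweep (default `1:(n - 1)`).
#' @param predictors Predictors to evaluate on the focal pair.
#' @return A tibble: one row per class x E count x predictor with `simulated`,
#'   `predicted`, and `abs_dev` for the focal pair.
#' @export
motif_fixture_validation <- function(motif_classes = c("t0", "t00", "t01", "t02",
                                                       "t11", "t12", "t13"),
                                     config = sim_config(),
                                     n = 30, n_common = 6, E_counts = NULL,
                                     predictors = c("SC", "TO", "FC1", "FC2")) {
  motif_classes <- match.arg(motif_classes, several.ok = TRUE)
  if (is.null(E_counts)) E_counts <- seq_len(n - 1)
  seeds <- derive_seeds(config$seed, length(motif_classes))
  purrr::map2_dfr(motif_classes, seeds, function(cls, sd_c) {
    fx <- generate_motif_fixture(cls, n = n, n_common = n_common, seed = sd_c)
    i <- fx$pair[1]; j <- fx$pair[2]
    inner <- derive_seeds(sd_c, length(E_counts))
    purrr::map2_dfr(E_counts, inner, function(ne, sd_i) {
      ic <- ic_counts(n_E = ne)
      cfg <- sim_config(config$runs, config$steps, config$include_initial_state,
                        seed = sd_i)
      sim <- accumulate_coactivation(fx$graph, ic, cfg)
      preds <- predictor_matrices(fx$graph, predictors, ic_to_probs(ic, n))
      purrr::imap_dfr(preds, function(pr, nm) {
        tibble::tibble(
          motif_class = cls, E_count = ne, predictor = nm,
          simulated = sim$values[i, j], predicted = pr$values[i, j],
          abs_dev = abs(sim$values[i, j] - pr$values[i, j])
        )
      })
    })
  })
}
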