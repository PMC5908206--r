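test_that("the synchronous update follows the three SER rules", {
  expect_identical(ser_step(k3(), c("S", "E", "R")), c("E", "R", "S"))
  expect_identical(ser_step(k3(), c("S", "S", "E")), c("E", "E", "R"))
  # all-susceptible is a fixed point: no excitation source
  expect_identical(ser_step(k3(), c("S", "S", "S")), c("S", "S", "S"))
  # no neighbor: excitation dies after one cycle
  tr <- ser_run(edgeless(3), c("E", "E", "E"), 3)
  expect_identical(unname(tr[, 2]), c("R", "R", "R"))
  expect_identical(unname(tr[, 3]), c("S", "S", "S"))
  expect_identical(unname(tr[, 4]), c("S", "S", "S"))
})

test_that("a triangle not initialized as a pacemaker dies within 3 steps", {
  tr <- ser_run(k3(), c("S", "S", "E"), 3)
  expect_identical(unname(tr[, 2]), c("E", "E", "R"))
  expect_identical(unname(tr[, 4]), c("S", "S", "S"))
  tr2 <- ser_run(k3(), c("E", "E", "E"), 3)
  expect_identical(unname(tr2[, 2]), c("R", "R", "R"))
  expect_identical(unname(tr2[, 3]), c("S", "S", "S"))
})

test_that("trajectories are deterministic, refractory-disciplined and causal", {
  for (seed in 1:5) {
    g <- generate_random(20, 50, seed = seed)
    init <- draw_initial_state(g, ic_probs(E = 0.3), seed = seed)
    tr <- ser_run(g, init, 30)
    expect_identical(unclass(tr), unclass(ser_run(g, init, 30)))
    A <- adjacency(g)
    m <- unclass(tr)
    for (t in 1:30) {
      prev_e <- m[, t] == "E"
      now_e <- m[, t + 1] == "E"
      # no node is excited at two consecutive steps
      expect_false(any(prev_e & now_e))
      # every excitation had an excited neighbor and a susceptible node
      if (any(now_e)) {
        expect_true(all(m[now_e, t] == "S"))
        expect_true(all((A %*% prev_e)[now_e] > 0))
      }
    }
  }
})

test_that("initial-condition draws honor exact counts and probabilities", {
  g <- generate_random(60, 400, seed = 1)
  s <- draw_initial_state(g, ic_counts(n_E = 12, n_S = 24, n_R = 24), seed = 1)
  expect_equal(as.integer(table(factor(s, c("S", "E", "R")))), c(24L, 12L, 24L))
  # equipartition default
  s2 <- draw_initial_state(g, ic_counts(n_E = 12), seed = 2)
  expect_equal(sum(s2 == "E"), 12)
  expect_equal(sum(s2 == "S"), 24)
  # odd remainder goes to S or R
  s3 <- draw_initial_state(edgeless(9), ic_counts(n_E = 2), seed = 3)
  expect_equal(sum(s3 == "E"), 2)
  expect_true(sum(s3 == "S") %in% 3:4)
  expect_identical(draw_initial_state(k3(), ic_probs(E = 1), seed = 1),
                   c("E", "E", "E"))
  # binomial concentration of probability draws
  big <- edgeless(3000)
  s4 <- draw_initial_state(big, ic_probs(E = 1/3, S = 1/3, R = 1/3), seed = 4)
  sigma <- sqrt((2 / 9) / 3000)
  for (st in c("S", "E", "R")) {
    expect_lt(abs(mean(s4 == st) - 1 / 3), 3 * sigma)
  }
  expect_error(ic_probs(E = 0.5, S = 0.4, R = 0.4), "sum to 1")
  expect_error(draw_initial_state(k3(), ic_counts(n_E = 1, n_S = 3, n_R = 3)),
               "sum to the number of nodes")
})

test_that("period detection identifies fixed points and period-3 orbits", {
  expect_equal(detect_period(ser_run(k3(), c("S", "E", "R"), 12), 2), 3)
  expect_equal(detect_period(ser_run(k3(), c("S", "S", "S"), 10), 2), 1)
  # dense benchmark with mixed initial conditions settles into period 3
  g <- generate_random(60, 800, seed = 1)
  tr <- ser_run(g, draw_initial_state(g, ic_counts(n_E = 12), seed = 2), 50)
  expect_equal(detect_period(tr, 20), 3)
  # an all-E flash dies: fixed point, period 1
  tr2 <- ser_run(g, rep("E", 60), 20)
  expect_equal(detect_period(tr2, 5), 1)
})

test_that("period is 1 or 3 on benchmarks across many random draws", {
  hits <- integer(0)
  for (seed in 1:20) {
    g <- benchmark_graph(c("random", "scale_free", "modular")[(seed %% 3) + 1],
                         seed = seed)
    for (ne in c(6, 20, 40)) {
      tr <- ser_run(g, draw_initial_state(g, ic_counts(ne), seed = seed + ne), 60)
      hits <- c(hits, detect_period(tr, 30))
    }
  }
  expect_true(all(hits %in% c(1L, 3L)))
})

test_that("coactivation accumulation matches its definition and bounds", {
  # an isolated pacemaker triangle never has two nodes excited together
  fc <- accumulate_coactivation(k3(), ic_counts(n_E = 1, n_S = 1, n_R = 1),
                                sim_config(50, 30, seed = 1))
  expect_equal(max(fc$values[upper.tri(fc$values)]), 0)
  # no excitations at all
  fc0 <- accumulate_coactivation(k3(), ic_probs(E = 0),
                                 sim_config(50, 30, seed = 1))
  expect_equal(max(fc0$values), 0)
  # symmetric, nonnegative, bounded by ceil(steps/3)/steps
  g <- generate_random(30, 120, seed = 2)
  fc2 <- accumulate_coactivation(g, ic_counts(6), sim_config(200, 48, seed = 3))
  v <- fc2$values
  expect_identical(v, t(v))
  expect_true(all(v >= 0))
  expect_true(all(v <= 1 / 3 + 1e-12))
})

test_that("exact enumeration oracle reproduces the K3 closed form", {
  ex <- exact_expected_coactivation(k3(), c(1, 1, 1) / 3, steps = 50)
  off <- ex$values[upper.tri(ex$values)]
  expect_equal(off, rep(1 / 1350, 3), tolerance = 1e-12)
  # degenerate corners of the simplex give identically zero coactivation
  expect_equal(max(exact_expected_coactivation(k3(), c(0.5, 0, 0.5), 20)$values), 0)
  expect_equal(max(exact_expected_coactivation(k3(), c(0, 1, 0), 20)$values), 0)
  expect_error(exact_expected_coactivation(edgeless(15), c(1, 1, 1) / 3, 10),
               "capped")
})

test_that("exactly 6 of the 27 triangle initializations sustain activity", {
  sustained <- 0L
  states <- c("S", "E", "R")
  for (code in 0:26) {
    init <- states[c(code %% 3, code %/% 3 %% 3, code %/% 9) + 1]
    tr <- ser_run(k3(), init, 9)
    if (any(tr[, 5:10] == "E")) {
      sustained <- sustained + 1L
      expect_setequal(init, states)  # sustained iff a permutation of S, E, R
    } else {
      # dies to all-susceptible within 3 steps
      expect_identical(unname(tr[, 4]), c("S", "S", "S"))
    }
  }
  expect_equal(sustained, 6L)
})

test_that("Monte-Carlo coactivation converges to the exact oracle", {
  graphs <- list(K3 = k3(), C4 = cycle4(), ER8 = generate_random(8, 14, seed = 4))
  for (nm in names(graphs)) {
    g <- graphs[[nm]]
    probs <- c(1, 1, 1) / 3
    ex <- exact_expected_coactivation(g, probs, steps = 30)
    mc <- accumulate_coactivation(g, ic_probs(E = 1/3, S = 1/3, R = 1/3),
                                  sim_config(50000, 30, seed = 5), detail = TRUE)
    ut <- upper.tri(ex$values)
    tol <- pmax(4 * mc$se[ut], 1e-4)
    expect_true(all(abs(mc$values[ut] - ex$values[ut]) <= tol),
                label = paste("oracle agreement on", nm))
  }
})

test_that("excitation frequency of a pacemaker node is exactly one third", {
  tr <- ser_run(k3(), c("S", "E", "R"), 48)
  expect_equal(excitation_frequency(tr), rep(16 / 48, 3))
})
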