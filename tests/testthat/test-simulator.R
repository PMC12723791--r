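test_that("sim_config validates its arguments", {
  cfg <- sim_config(dt = 0.2, T = 10)
  expect_identical(cfg$n_steps, 50L)
  expect_error(sim_config(dt = 0), "positive")
  expect_error(sim_config(dt = 0.2, T = 0.01), "positive integer")
  expect_error(sim_config(record_every = 0), "record_every")
  expect_error(sim_config(convergence_tol = -1), "nonnegative")
})

test_that("overlap is the mean pattern-weighted activation", {
  xi <- c(1, -1, 1, -1)
  x <- c(2, -2, 0.5, 3)
  expect_equal(overlap(xi, x), mean(xi * tanh(x)))
  expect_error(overlap(xi, x[-1]), "equal length")
})

test_that("construct_cued_state hits the target overlap", {
  xi <- sample_patterns(400, 1, seed = 10)$patterns[1, ]
  st <- construct_cued_state(xi, 0.7, seed = 11)
  expect_equal(overlap(xi, st$x), 0.7, tolerance = 1e-3)
  expect_equal(attr(st, "realized_m0"), overlap(xi, st$x), tolerance = 1e-12)
  expect_gt(attr(st, "c1"), 0)
  # z0 override is honored exactly
  z0 <- rnorm(400)
  st2 <- construct_cued_state(xi, 0.7, seed = 11, z0 = z0)
  expect_identical(st2$z, z0)
  expect_identical(st2$x, st$x)   # same eta stream regardless of z0 source
  expect_error(construct_cued_state(xi, 0.9999, seed = 11), "unreachable")
})

test_that("compiled trajectory reproduces the R-level Euler reference", {
  spec <- network_spec(N = 40, P = 8, gamma = Inf, seed = 12)
  init <- construct_cued_state(spec$patterns$patterns[1, ], 0.5, seed = 13)
  cfg <- sim_config(dt = 0.2, T = 4, record_every = 1L)
  traj <- run_trajectory(spec, init, cfg, tracked = c(1L, 2L))
  st <- init
  for (s in seq_len(cfg$n_steps)) st <- euler_step(st, spec, cfg$dt)
  expect_equal(traj$state$x, st$x, tolerance = 1e-12)
  expect_equal(traj$state$z, st$z, tolerance = 1e-12)
  expect_equal(unname(traj$m_ss[1]), overlap(spec$patterns$patterns[1, ], st$x),
               tolerance = 1e-12)
  # record bookkeeping: t = 0 plus one record per step
  expect_length(traj$times, cfg$n_steps + 1L)
  expect_equal(traj$times, seq(0, 4, by = 0.2))
  expect_identical(colnames(traj$m), c("m1", "m2"))
})

test_that("ungated runs integrate without any modulator couplings", {
  spec <- network_spec(N = 60, P = 3, gamma = 0, seed = 14)
  expect_null(spec$W)
  init <- construct_cued_state(spec$patterns$patterns[1, ], 0.6, seed = 15)
  traj <- run_trajectory(spec, init, sim_config(dt = 0.2, T = 50))
  # z never updates when it cannot feed back
  expect_identical(traj$state$z, init$z)
  expect_gt(unname(traj$m_ss[1]), 0.9)   # retrieval at low load
  # gamma > 0 without W must refuse rather than silently gate on garbage
  spec_bad <- spec
  spec_bad$gamma <- 2
  expect_error(run_trajectory(spec_bad, init, sim_config(T = 1)), "no W matrix")
})

test_that("early stopping halts at a fixed point and flags convergence", {
  spec <- network_spec(N = 60, P = 3, gamma = 0, seed = 16)
  init <- construct_cued_state(spec$patterns$patterns[1, ], 0.6, seed = 17)
  traj <- run_trajectory(spec, init, sim_config(dt = 0.2, T = 2000,
                                                convergence_tol = 1e-9))
  expect_true(traj$converged)
  expect_lt(traj$steps, sim_config()$n_steps)
  # the stopped state is stationary: one more Euler step moves it by at
  # most dt * tol (the drift re-evaluated at the stopped state can sit
  # marginally above the last checked value)
  st2 <- euler_step(traj$state, spec, 0.2)
  expect_lt(max(abs(st2$x - traj$state$x)), 0.2 * 1e-9)
  # and the endpoint agrees with the full fixed-horizon run
  full <- run_trajectory(spec, init, sim_config(dt = 0.2, T = 2000))
  expect_equal(unname(traj$m_ss[1]), unname(full$m_ss[1]), tolerance = 1e-6)
})

test_that("subpopulation overlaps decompose the total exactly", {
  x <- rnorm(200); z <- rnorm(200)
  xi <- sample(c(-1, 1), 200, replace = TRUE)
  sp <- subpopulation_overlaps(x, z, xi)
  expect_equal(sp$rhoF + sp$rhoA, 1)
  expect_equal(sp$rhoF * sp$mF + sp$rhoA * sp$mA, overlap(xi, x),
               tolerance = 1e-14)
  expect_error(subpopulation_overlaps(x, z, xi, gamma = 5), "binary gate")
})

test_that("gate_population_trace counts membership flips and then stills", {
  spec <- network_spec(N = 80, P = 8, gamma = Inf, seed = 18)
  init <- construct_cued_state(spec$patterns$patterns[1, ], 0.55, seed = 19)
  traj <- run_trajectory(spec, init, sim_config(dt = 0.2, T = 200,
                                                record_every = 10L),
                         record_gate = TRUE)
  tr <- gate_population_trace(traj)
  expect_identical(nrow(tr), length(traj$times) - 1L)
  expect_true(all(tr$flips >= 0))
  expect_gt(sum(tr$flips[1:3]), 0)            # exchange during the transient
  no_gate <- run_trajectory(spec, init, sim_config(dt = 0.2, T = 2))
  expect_error(gate_population_trace(no_gate), "record_gate")
})
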