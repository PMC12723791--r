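test_that("sample_gaussian_paths realizes the prescribed covariance", {
  tgrid <- seq(0, 2, by = 0.25)
  cov <- exp(-abs(outer(tgrid, tgrid, "-")))
  X <- sample_gaussian_paths(cov, M = 6000, seed = 21)
  expect_identical(dim(X), c(6000L, length(tgrid)))
  emp <- crossprod(X) / nrow(X)
  expect_lt(max(abs(emp - cov)), 0.12)   # ~6 sigma of the M = 6000 MC error
  expect_identical(sample_gaussian_paths(cov * 0, 5), matrix(0, 5, 9))
  expect_error(sample_gaussian_paths(matrix(c(1, 2, 0, 1), 2), 5), "symmetric")
  # common random numbers: same Z, same paths
  Z <- matrix(rnorm(3 * 9), 3)
  expect_identical(sample_gaussian_paths(cov, 3, Z = Z),
                   sample_gaussian_paths(cov, 3, Z = Z))
})

test_that("update_propagator reproduces the step and exponential oracles", {
  L <- 60; dt <- 0.1
  # R = 0: dG/dt = delta, so G(t, t') = Theta(t - t')
  G0 <- update_propagator(matrix(0, L, L), dt)
  expect_equal(G0[lower.tri(G0)], rep(1, sum(lower.tri(G0))), tolerance = 1e-12)
  expect_true(all(G0[upper.tri(G0, diag = TRUE)] == 0))
  # memoryless kernel R(t,u) = -lambda delta(t-u): G = exp(-lambda (t - t'))
  toy <- make_fixture("linear_kernel_toy")
  Ge <- update_propagator(toy$R, toy$dt)
  tg <- (seq_len(toy$L) - 1) * toy$dt
  exact <- outer(tg, tg, function(t, tp) exp(-toy$lambda * (t - tp)))
  exact[upper.tri(exact, diag = TRUE)] <- 0
  # explicit Euler error is O(dt) with constant lambda (the first
  # sub-diagonal carries 1 versus exp(-lambda dt))
  expect_lt(max(abs(Ge - exact)), 1.5 * toy$lambda * toy$dt)
})

test_that("resolvent_kernel solves G = c (delta + R o G) on the grid", {
  L <- 30; dt <- 0.2; cpl <- 1.7
  R <- matrix(0, L, L)
  R[lower.tri(R)] <- rnorm(sum(lower.tri(R)), sd = 0.3)
  G <- resolvent_kernel(R, cpl, dt)
  # defining equation with the delta as 1/dt on the diagonal and the
  # composition (R o G)(t,t') = int R(t,u) G(u,t') du = dt * R %*% G
  lhs <- G
  rhs <- cpl * (diag(1 / dt, L) + dt * (R %*% G))
  expect_equal(lhs, rhs, tolerance = 1e-10)
  expect_equal(resolvent_kernel(matrix(0, L, L), cpl, dt), diag(cpl / dt, L))
})

test_that("single_site_integrate matches closed-form Euler recursions", {
  L <- 40L; dt <- 0.1; alpha <- 0.2; g <- 1.5
  kappa <- g / sqrt(alpha)
  m <- rep(0.6, L)
  zeros <- matrix(0, 1, L)
  x0 <- 0.3; z0 <- 1
  # no noise, no memory kernel, gamma = 0: x' = (1/2)(-x + kappa m), whose
  # Euler iterates are exactly x_k = kappa m + (x0 - kappa m)(1 - dt/2)^k
  p <- single_site_integrate(zeros, zeros, x0, z0, m, matrix(0, L, L),
                             alpha, g, gamma = 0, dt = dt)
  k <- seq_len(L) - 1
  expect_equal(drop(p$x), kappa * 0.6 + (x0 - kappa * 0.6) * (1 - dt / 2)^k,
               tolerance = 1e-12)
  expect_equal(drop(p$phi), tanh(drop(p$x)), tolerance = 1e-14)
  expect_true(all(p$sig == 0.5))
  # diagonal kernel G = (kappa/dt) I: retarded term alpha*kappa*phi(x_k),
  # pinned against the same recursion written in plain R
  G <- diag(kappa / dt, L)
  p2 <- single_site_integrate(zeros, zeros, x0, z0, m, G,
                              alpha, g, gamma = 0, dt = dt)
  x_ref <- numeric(L); x_ref[1] <- x0
  for (j in seq_len(L - 1))
    x_ref[j + 1] <- x_ref[j] + dt * 0.5 *
      (-x_ref[j] + kappa * 0.6 + alpha * kappa * tanh(x_ref[j]))
  expect_equal(drop(p2$x), x_ref, tolerance = 1e-12)
  # binary gate freezes paths with z < 0 exactly (z relaxes toward 0 from
  # z0 = -1, never crossing it)
  p3 <- single_site_integrate(zeros, zeros, x0, -1, m, matrix(0, L, L),
                              alpha, g, gamma = Inf, dt = dt)
  expect_true(all(p3$x == x0))
})

test_that("estimate_response is causal and matches the one-step derivative", {
  L <- 25L; dt <- 0.2; alpha <- 0.3; g <- 1.5
  m <- rep(0.5, L)
  zeros <- matrix(0, 1, L)
  G <- matrix(0, L, L)
  p <- single_site_integrate(zeros, zeros, 0.2, 0, m, G, alpha, g,
                             gamma = 0, dt = dt)
  eps <- 1e-6
  R <- estimate_response(p, zeros, m, G, alpha, g, dt, eps = eps, m_resp = 1L)
  expect_true(all(R[upper.tri(R, diag = TRUE)] == 0))
  # first sub-diagonal: d phi(x_{j+1}) / d(impulse) = phi'(x_{j+1}) sigma_j
  x <- drop(p$x)
  expect_equal(R[cbind(2:L, 1:(L - 1))],
               (1 - tanh(x[2:L])^2) * 0.5, tolerance = 1e-4)
  expect_error(estimate_response(p, zeros, m, G, alpha, g, dt, eps = 0),
               "nonzero")
})

test_that("solve_dmft converges, respects bounds, and is seed-reproducible", {
  sol <- solve_dmft(alpha = 0.1, gamma = 0, m0 = 0.8, T = 10, dt = 0.2,
                    M = 400, m_resp = 100, seed = 31)
  expect_s3_class(sol, "dmft_solution")
  expect_true(sol$converged)
  expect_true(all(abs(sol$m) <= 1))
  expect_equal(sol$m[1], 0.8, tolerance = 2e-3)
  expect_gt(tail(sol$m, 1), 0.8)     # below capacity the overlap grows
  sol2 <- solve_dmft(alpha = 0.1, gamma = 0, m0 = 0.8, T = 10, dt = 0.2,
                     M = 400, m_resp = 100, seed = 31)
  expect_identical(sol$m, sol2$m)
})

test_that("asymptotic_fixed_point honors limits and the low-load root", {
  # a fully frozen population pins the overlap at its frozen value
  fp1 <- asymptotic_fixed_point(0.4, mF_ss = 0.7, rhoF_ss = 1)
  expect_identical(fp1$m_ss, 0.7)
  expect_true(fp1$converged)
  # ungated low load: crosstalk is weak, the static overlap approaches the
  # noise-free scalar self-consistency root
  fp2 <- asymptotic_fixed_point(0.05, mF_ss = 0, rhoF_ss = 0, m_init = 0.9)
  expect_true(fp2$converged)
  expect_equal(fp2$m_ss, oracle_scalar_root(0.05, 1.5), tolerance = 0.02)
  expect_error(asymptotic_fixed_point(0.4, 0, -0.1), "rhoF_ss")
})

test_that("mss_band returns ordered finite band edges", {
  band <- mss_band(0.4, N = 200, cfg = sim_config(dt = 0.2, T = 200,
                                                  convergence_tol = 1e-8),
                   n_reps = 2, seed_base = 41)
  expect_identical(nrow(band), 1L)
  expect_true(all(is.finite(c(band$mss_lo, band$mss_hi))))
  expect_lte(band$mss_lo, band$mss_hi)
  expect_true(band$rhoF_hi > 0 && band$rhoF_hi < 1)
})
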