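# Reference implementations used as oracles. Each one is deliberately naive
# (dense matrices, double loops, plain R) so that agreement with the package
# code is evidence of correctness, not of shared bugs.

# Dense double-loop Hebbian drive: (g / sqrt(PN)) * J %*% phi with
# J = sum_mu xi^mu (xi^mu)^T built element by element.
oracle_dense_drive <- function(Xi, phi, g) {
  P <- nrow(Xi); N <- ncol(Xi)
  J <- matrix(0, N, N)
  for (mu in seq_len(P)) J <- J + outer(Xi[mu, ], Xi[mu, ])
  drive <- numeric(N)
  for (i in seq_len(N)) drive[i] <- sum(J[i, ] * phi)
  drive * g / sqrt(P * N)
}

# Plain-R Euler integrator for the classical (ungated) associative network
# dx/dt = -x + (g/sqrt(PN)) J phi(x).  Returns the x iterates after each of
# n_steps steps (a matrix with one row per step).
oracle_hopfield_euler <- function(Xi, x0, g, dt, n_steps) {
  pre <- g / sqrt(nrow(Xi) * ncol(Xi))
  x <- x0
  out <- matrix(NA_real_, n_steps, length(x0))
  for (s in seq_len(n_steps)) {
    phi <- tanh(x)
    drive <- pre * drop(crossprod(Xi, Xi %*% phi))
    x <- x + dt * (-x + drive)
    out[s, ] <- x
  }
  out
}

# Noise-free scalar self-consistency for the condensed overlap:
# m = tanh((g / sqrt(alpha)) m), the alpha -> 0 limit of the mean-field
# steady state.  Returns the positive root.
oracle_scalar_root <- function(alpha, g) {
  kappa <- g / sqrt(alpha)
  if (kappa <= 1) return(0)
  uniroot(function(m) m - tanh(kappa * m), c(1e-8, 1),
          f.lower = -tanh(kappa * 1e-8) + 1e-8, tol = 1e-12)$root
}

# Disorder-averaged many-body overlap trajectory on the DMFT comparison grid.
oracle_manybody_mean_m <- function(alpha, gamma, m0, N, T, dt, n_reps,
                                   seed_base) {
  cfg <- sim_config(dt = dt, T = T, record_every = 1L)
  seeds <- spawn_seeds(seed_base, 2L * n_reps)
  ms <- vapply(seq_len(n_reps), function(r) {
    spec <- network_spec(N = N, alpha = alpha, gamma = gamma,
                         seed = seeds[2 * r - 1])
    init <- construct_cued_state(spec$patterns$patterns[1, ], m0,
                                 seed = seeds[2 * r])
    run_trajectory(spec, init, cfg, tracked = 1L)$m[, 1]
  }, numeric(round(T / dt) + 1L))
  rowMeans(ms)
}

# First-passage time of the overlap below `level` (censored at the horizon).
oracle_lifetime <- function(times, m, level = 0.3) {
  below <- which(m < level)
  if (!length(below)) max(times) else times[min(below)]
}
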