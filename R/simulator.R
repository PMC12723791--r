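#' Simulation configuration
#'
#' Euler integration settings. The defaults (`dt = 0.2`, `T = 2000`) are the
#' protocol used for all phase-diagram and capacity experiments; flow-map
#' experiments use `dt = 0.25`. `convergence_tol > 0` enables early stopping
#' when the largest drift magnitude `max_i |dx_i/dt|` falls below the
#' tolerance; it is off by default so fixed-horizon runs are exactly
#' reproducible.
#'
#' @param dt Euler time step (must be positive; <= 0.25 in standard use).
#' @param T time horizon; `T/dt` must round to a positive integer.
#' @param record_every record observables every this many steps.
#' @param convergence_tol nonnegative early-stop tolerance on `max|dx|/dt`
#'   (0 disables early stopping).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.2, T = 2000, record_every = 10L,
                       convergence_tol = 0) {
  if (dt <= 0) stop("dt must be positive")
  n_steps <- round(T / dt)
  if (n_steps < 1) stop("T/dt must be a positive integer step count")
  if (record_every < 1) stop("record_every must be >= 1")
  if (convergence_tol < 0) stop("convergence_tol must be nonnegative")
  structure(list(dt = dt, T = T, n_steps = as.integer(n_steps),
                 record_every = as.integer(record_every),
                 convergence_tol = convergence_tol),
            class = "sim_config")
}

#' Mattis overlap of an activity vector with a pattern
#'
#' m = (1/N) sum_i xi_i * tanh(x_i), the order parameter for retrieval;
#' bounded in (-1, 1).
#'
#' @param pattern length-N pattern vector.
#' @param x length-N activity vector.
#' @return scalar overlap.
#' @export
overlap <- function(pattern, x) {
  if (length(pattern) != length(x)) stop("pattern and x must have equal length")
  mean(pattern * activation(x))
}

#' Construct a cued initial state with a target overlap
#'
#' Builds x(0) = c1 * xi + eta with eta iid standard normal, where c1 is
#' found by root-finding (bisection on the monotone map c1 -> realized
#' overlap, for the same eta draw) so that the realized Mattis overlap
#' matches `target_m0` within `tol`. The modulator layer starts at iid
#' standard normal z(0).
#'
#' @param pattern length-N (+/-1) pattern to cue.
#' @param target_m0 target initial overlap, in `[0, m_max)` where `m_max` is
#'   the saturation overlap achievable for the drawn eta.
#' @param seed optional seed controlling eta and z(0).
#' @param z0 optional fixed modulator initial state (overrides the draw).
#' @param tol overlap tolerance for the root-find (default 1e-3).
#' @param c_max upper bracket for the cue coefficient.
#' @return a `network_state` at t = 0, with attributes `c1` and
#'   `realized_m0`.
#' @export
construct_cued_state <- function(pattern, target_m0, seed = NULL, z0 = NULL,
                                 tol = 1e-3, c_max = 20) {
  N <- length(pattern)
  seeds <- spawn_seeds(if (is.null(seed)) sample.int(2^31 - 2, 1) else seed,
                       c("eta", "z0"))
  eta <- with_seed(seeds[["eta"]], rnorm(N))
  if (is.null(z0)) z0 <- with_seed(seeds[["z0"]], rnorm(N))
  realized <- function(c1) mean(pattern * tanh(c1 * pattern + eta))
  m_max <- realized(c_max)
  if (target_m0 >= m_max - tol)
    stop(sprintf("target overlap %.4f unreachable; max achievable for this noise draw is %.4f",
                 target_m0, m_max))
  c1 <- if (realized(0) >= target_m0) 0 else {
    uniroot(function(c1) realized(c1) - target_m0,
            lower = 0, upper = c_max, tol = 1e-10,
            f.lower = realized(0) - target_m0,
            f.upper = m_max - target_m0)$root
  }
  st <- network_state(c1 * pattern + eta, z0, t = 0)
  attr(st, "c1") <- c1
  attr(st, "realized_m0") <- realized(c1)
  st
}

#' One explicit Euler step of the gated dynamics (reference implementation)
#'
#' x <- x + dt * sigma(z) * (-x + drive), z <- z + (dt/tau_z) * (-z +
#' W phi / sqrt(N)). The gate multiplies the entire x-drift, so sigma = 0
#' freezes the neuron exactly. When the spec carries no W matrix (ungated
#' runs), z is left untouched since it never feeds back on x.
#'
#' The compiled loop in [run_trajectory()] performs the identical update;
#' this R-level step is the readable reference and is tested against it.
#'
#' @param state a `network_state`.
#' @param spec a `network_spec`.
#' @param dt Euler step.
#' @return the advanced `network_state`.
#' @export
euler_step <- function(state, spec, dt) {
  phi <- activation(state$x)
  sig <- gate(state$z, spec$gamma)
  x_new <- state$x + dt * sig * (-state$x + recurrent_drive(spec, phi))
  z_new <- if (!is.null(spec$W)) {
    state$z + (dt / spec$tau_z) * (-state$z + drop(spec$W %*% phi) / sqrt(spec$N))
  } else state$z
  if (!all(is.finite(x_new)) || !all(is.finite(z_new)))
    stop(sprintf("non-finite state after Euler step at t = %g", state$t + dt))
  network_state(x_new, z_new, state$t + dt)
}

#' Integrate a trajectory and record retrieval observables
#'
#' Repeats the Euler update for `cfg$n_steps` steps (compiled loop with the
#' low-rank Hebbian drive), recording the Mattis overlaps with the tracked
#' patterns every `record_every` steps. In the binary-gate limit the
#' frozen/active sub-population overlaps (mF, mA) and fractions (rhoF, rhoA)
#' relative to the first tracked pattern are recorded as well.
#'
#' @param spec a `network_spec`.
#' @param init a `network_state` (e.g. from [construct_cued_state()]).
#' @param cfg a [sim_config()].
#' @param tracked integer indices of patterns whose overlaps are recorded.
#' @param record_gate record per-neuron gate values at each record time.
#' @param record_x record activity snapshots at each record time.
#' @return object of class `trajectory`: list with `times`, `m` (matrix,
#'   one column per tracked pattern), `m_ss` (final overlaps), sub-population
#'   series when the gate is binary, optional `gate_trace` / `x_snapshots`,
#'   final state, step count and convergence flag.
#' @export
run_trajectory <- function(spec, init, cfg = sim_config(), tracked = 1L,
                           record_gate = FALSE, record_x = FALSE) {
  stopifnot(inherits(spec, "network_spec"), inherits(init, "network_state"),
            inherits(cfg, "sim_config"))
  if (length(init$x) != spec$N) stop("initial state does not match spec N")
  Xi <- as_pattern_matrix(spec$patterns)
  tracked <- as.integer(tracked)
  if (any(tracked < 1 | tracked > spec$P)) stop("tracked indices out of range")
  gamma_inf <- is.infinite(spec$gamma)
  has_W <- !is.null(spec$W)
  if (spec$gamma > 0 && !has_W)
    stop("spec has gamma > 0 but no W matrix; rebuild with network_spec(..., make_W = TRUE)")
  W <- if (has_W) spec$W else matrix(0, 0, 0)
  res <- cpp_integrate(Xi, W, init$x, init$z, spec$g,
                       if (gamma_inf) 0 else spec$gamma, gamma_inf, has_W,
                       spec$tau_z, cfg$dt, cfg$n_steps, cfg$record_every,
                       cfg$convergence_tol, record_gate, record_x,
                       Xi[tracked, , drop = FALSE])
  m <- res$m
  colnames(m) <- paste0("m", tracked)
  out <- list(times = drop(res$times), m = m,
              m_ss = setNames(m[nrow(m), ], colnames(m)),
              mF = res$mF, mA = res$mA, rhoF = res$rhoF, rhoA = res$rhoA,
              gate_trace = res$gate_trace, x_snapshots = res$x_snapshots,
              state = network_state(res$x_final, res$z_final,
                                    t = res$steps * cfg$dt),
              steps = res$steps, converged = res$converged,
              dt = cfg$dt, tracked = tracked, gamma = spec$gamma)
  class(out) <- "trajectory"
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d records to t=%g; m_ss = %s%s\n",
              length(x$times), max(x$times),
              paste(sprintf("%.4f", x$m_ss), collapse = ", "),
              if (x$converged) " (early-stopped)" else ""))
  invisible(x)
}

#' Frozen/active sub-population overlap decomposition
#'
#' In the binary-gate limit the population splits into closed neurons
#' (sigma(z_i) = 0) and active neurons (sigma(z_i) > 0). This returns the
#' sub-population overlaps mF, mA (means of xi_i phi(x_i) over each group)
#' and the fractions rhoF, rhoA, which satisfy the exact decomposition
#' m = rhoF * mF + rhoA * mA.
#'
#' @param x activity vector.
#' @param z modulator vector.
#' @param pattern pattern vector.
#' @param gamma gate steepness (must be `Inf`; the split needs a binary gate).
#' @return named list `mF`, `mA`, `rhoF`, `rhoA` (empty group: overlap `NA`
#'   with weight 0).
#' @export
subpopulation_overlaps <- function(x, z, pattern, gamma = Inf) {
  if (!is.infinite(gamma))
    stop("sub-population split is defined in the binary gate limit (gamma = Inf)")
  v <- pattern * activation(x)
  closed <- gate(z, gamma) == 0
  nF <- sum(closed)
  nA <- length(x) - nF
  list(mF = if (nF) mean(v[closed]) else NA_real_,
       mA = if (nA) mean(v[!closed]) else NA_real_,
       rhoF = nF / length(x), rhoA = nA / length(x))
}

#' Gate membership-change counts along a trajectory
#'
#' Counts, between consecutive recorded times, how many neurons flipped
#' their binary gate state (the Hamming distance of consecutive binarized
#' gate vectors). Positive counts during the transient and zeros at the tail
#' signal the dynamical exchange between frozen and active populations
#' followed by stationarity.
#'
#' @param traj a `trajectory` run with `record_gate = TRUE` under a binary
#'   gate.
#' @return data.frame with `time` (end of each interval) and `flips`.
#' @export
gate_population_trace <- function(traj) {
  if (is.null(traj$gate_trace))
    stop("trajectory has no gate_trace; rerun with record_gate = TRUE")
  if (!is.infinite(traj$gamma))
    stop("gate flips are defined for the binary gate (gamma = Inf)")
  gt <- traj$gate_trace > 0.5
  n <- nrow(gt)
  if (n < 2) return(data.frame(time = numeric(0), flips = integer(0)))
  flips <- rowSums(gt[-1, , drop = FALSE] != gt[-n, , drop = FALSE])
  data.frame(time = traj$times[-1], flips = as.integer(flips))
}
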