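#' Steady-state overlap statistics over disorder realizations
#'
#' Runs `n_reps` independent realizations of the quenched disorder
#' (patterns, modulator couplings, cue noise, initial modulator state) at a
#' given memory load, initial overlap and gate steepness, and returns the
#' mean and standard deviation of the final overlap m(T). Per-realization
#' seeds are derived deterministically from `seed_base` so every cell of a
#' sweep is independently reproducible.
#'
#' @param alpha memory load P/N.
#' @param m0 target initial overlap of the cue.
#' @param gamma gate steepness (0, finite, or `Inf`).
#' @param n_reps number of disorder realizations (>= 1).
#' @param cfg a [sim_config()].
#' @param seed_base root seed for this cell.
#' @param N network size.
#' @param g gain.
#' @param tau_z modulator time-constant.
#' @return list with `mean`, `sd`, `values`, `n`.
#' @export
steady_state_overlap_stat <- function(alpha, m0, gamma, n_reps,
                                      cfg = sim_config(), seed_base = 1L,
                                      N = 1000, g = 1.5, tau_z = 1) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  seeds <- spawn_seeds(seed_base, 2L * n_reps)
  vals <- vapply(seq_len(n_reps), function(r) {
    spec <- network_spec(N = N, alpha = alpha, gamma = gamma, g = g,
                         tau_z = tau_z, seed = seeds[2 * r - 1])
    init <- construct_cued_state(as_pattern_matrix(spec$patterns)[1, ], m0,
                                 seed = seeds[2 * r])
    traj <- run_trajectory(spec, init, cfg, tracked = 1L)
    unname(traj$m_ss[1])
  }, numeric(1))
  list(mean = mean(vals), sd = if (n_reps > 1) sd(vals) else 0,
       values = vals, n = as.integer(n_reps))
}

#' Phase diagram of steady-state overlaps over an (alpha, m0) grid
#'
#' Computes [steady_state_overlap_stat()] for every grid cell, with
#' deterministic per-cell seeding, to map the retrieval phase: the region of
#' order-one steady-state overlap as a function of memory load and cue
#' quality.
#'
#' @param alphas sorted vector of memory loads.
#' @param m0s sorted vector of initial overlaps.
#' @param gamma gate steepness.
#' @param n_reps realizations per cell.
#' @param cfg a [sim_config()].
#' @param seed_base root seed; cell `(i, j)` uses a child seed of it.
#' @inheritParams steady_state_overlap_stat
#' @return object of class `phase_grid`: list with `alphas`, `m0s`, `gamma`,
#'   `mss_mean` and `mss_sd` (|alphas| x |m0s| matrices), `n_reps`,
#'   `seed_base`, `N`.
#' @export
phase_diagram <- function(alphas, m0s, gamma, n_reps = 10,
                          cfg = sim_config(), seed_base = 1L,
                          N = 1000, g = 1.5, tau_z = 1) {
  if (!length(alphas) || !length(m0s)) stop("alphas and m0s must be nonempty")
  cell_seeds <- matrix(spawn_seeds(seed_base, length(alphas) * length(m0s)),
                       nrow = length(alphas))
  mm <- ms <- matrix(NA_real_, length(alphas), length(m0s),
                     dimnames = list(alpha = signif(alphas, 6),
                                     m0 = signif(m0s, 6)))
  for (i in seq_along(alphas)) for (j in seq_along(m0s)) {
    st <- steady_state_overlap_stat(alphas[i], m0s[j], gamma, n_reps, cfg,
                                    seed_base = cell_seeds[i, j],
                                    N = N, g = g, tau_z = tau_z)
    mm[i, j] <- st$mean
    ms[i, j] <- st$sd
  }
  structure(list(alphas = alphas, m0s = m0s, gamma = gamma,
                 mss_mean = mm, mss_sd = ms, n_reps = n_reps,
                 seed_base = seed_base, N = N, g = g),
            class = "phase_grid")
}

#' @export
print.phase_grid <- function(x, ...) {
  cat(sprintf("<phase_grid> gamma=%s, %d x %d cells, %d reps, N=%d\n",
              format(x$gamma), length(x$alphas), length(x$m0s), x$n_reps, x$N))
  invisible(x)
}

#' Gated-minus-ungated difference map of steady-state overlaps
#'
#' delta m_ss = m_ss(gated) - m_ss(ungated), cellwise over two phase grids on
#' identical (alpha, m0) axes. Below the ungated critical capacity the map is
#' predominantly near zero to slightly negative (gating mildly degrades
#' retrieval fidelity); above it, strongly positive values mark the region
#' where gating rescues retrieval entirely.
#'
#' @param gated `phase_grid` for the gated network.
#' @param ungated `phase_grid` for the ungated benchmark.
#' @return matrix of differences on the shared grid.
#' @export
delta_map <- function(gated, ungated) {
  if (!isTRUE(all.equal(gated$alphas, ungated$alphas)) ||
      !isTRUE(all.equal(gated$m0s, ungated$m0s)))
    stop("phase grids must share identical (alphas, m0s) axes")
  gated$mss_mean - ungated$mss_mean
}

#' Estimate the critical storage capacity from a capacity sweep
#'
#' Sweeps the memory load at a fixed high-quality cue and reports the
#' largest load whose mean steady-state overlap still exceeds
#' `threshold` times the retrieval-plateau value (the maximum mean over the
#' sweep). Near a sharp transition the estimate is insensitive to the exact
#' threshold; the half-maximum default is reported alongside the sweep.
#'
#' @param alphas sorted loads straddling the transition.
#' @param gamma gate steepness (0 for the classical estimate).
#' @param m0 cue overlap (default 0.95, deep in the basin).
#' @param n_reps realizations per load.
#' @param threshold fraction of the plateau defining retrieval (default 0.5).
#' @param cfg a [sim_config()].
#' @inheritParams steady_state_overlap_stat
#' @return list with `alpha_c`, the `sweep` data.frame (alpha, mean, sd), the
#'   `threshold` used and the plateau value. Errors if no crossing lies in
#'   range.
#' @export
estimate_critical_capacity <- function(alphas, gamma = 0, m0 = 0.95,
                                       n_reps = 20, threshold = 0.5,
                                       cfg = sim_config(), seed_base = 1L,
                                       N = 1000, g = 1.5, tau_z = 1) {
  alphas <- sort(alphas)
  seeds <- spawn_seeds(seed_base, length(alphas))
  stats <- lapply(seq_along(alphas), function(i)
    steady_state_overlap_stat(alphas[i], m0, gamma, n_reps, cfg,
                              seed_base = seeds[i], N = N, g = g,
                              tau_z = tau_z))
  mu <- vapply(stats, `[[`, numeric(1), "mean")
  sweep <- data.frame(alpha = alphas, mean = mu,
                      sd = vapply(stats, `[[`, numeric(1), "sd"))
  plateau <- max(mu)
  above <- mu > threshold * plateau
  if (all(above))
    stop("no retrieval collapse detected in the given alpha range")
  if (!above[1])
    stop("retrieval fails already at the smallest alpha; extend the range down")
  alpha_c <- max(alphas[above])
  list(alpha_c = alpha_c, sweep = sweep, threshold = threshold,
       plateau = plateau)
}

#' Retrieval boundary m_c(alpha) from a phase grid
#'
#' For each memory load, the smallest initial overlap whose mean steady-state
#' overlap exceeds `level`, linearly interpolated between grid cells; `NA`
#' where retrieval never occurs in the scanned m0 range.
#'
#' @param grid a `phase_grid`.
#' @param level overlap level defining retrieval (default 0.5).
#' @return data.frame with `alpha` and `m_c`.
#' @export
estimate_retrieval_boundary <- function(grid, level = 0.5) {
  m_c <- vapply(seq_along(grid$alphas), function(i) {
    mu <- grid$mss_mean[i, ]
    m0 <- grid$m0s
    idx <- which(mu > level)
    if (!length(idx)) return(NA_real_)
    j <- min(idx)
    if (j == 1) return(m0[1])
    # linear interpolation between the first cell above and the one below
    m0[j - 1] + (level - mu[j - 1]) * (m0[j] - m0[j - 1]) / (mu[j] - mu[j - 1])
  }, numeric(1))
  data.frame(alpha = grid$alphas, m_c = m_c)
}
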