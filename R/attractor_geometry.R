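#' Construct an initial state with target overlaps on two patterns
#'
#' Builds x(0) = c1 xi1 + c2 xi2 + eta with eta standard normal and (c1, c2)
#' found by damped Newton iteration (with the exact 2 x 2 Jacobian
#' d m_a / d c_b = mean(xi_a xi_b sech^2(x))) so the realized overlaps match
#' the targets within `tol` each. The modulator initialisation z(0) can be
#' supplied so that it stays fixed across a grid of initial conditions, as
#' the flow-map protocol requires.
#'
#' @param xi1,xi2 the two pattern vectors (ideally exactly orthogonal, from
#'   [make_orthogonal_pair()]).
#' @param target length-2 target overlaps (m1_0, m2_0), inside the feasible
#'   region |m1| + |m2| < 1.
#' @param seed optional seed for eta (and z(0) when not supplied).
#' @param z0 optional fixed modulator initial state.
#' @param tol per-component overlap tolerance.
#' @return a `network_state` with attributes `coef` (c1, c2) and
#'   `realized_m` (m1_0, m2_0).
#' @export
construct_two_pattern_init <- function(xi1, xi2, target, seed = NULL,
                                       z0 = NULL, tol = 1e-3) {
  N <- length(xi1)
  stopifnot(length(xi2) == N, length(target) == 2)
  if (sum(abs(target)) >= 0.98)
    stop("target overlaps outside the feasible region |m1| + |m2| < 1")
  seeds <- spawn_seeds(if (is.null(seed)) sample.int(2^31 - 2, 1) else seed,
                       c("eta", "z0"))
  eta <- with_seed(seeds[["eta"]], rnorm(N))
  if (is.null(z0)) z0 <- with_seed(seeds[["z0"]], rnorm(N))
  cc <- c(0, 0)
  for (it in 1:100) {
    x <- cc[1] * xi1 + cc[2] * xi2 + eta
    phi <- tanh(x)
    m <- c(mean(xi1 * phi), mean(xi2 * phi))
    err <- m - target
    if (max(abs(err)) < tol) break
    d <- 1 - phi^2
    J <- matrix(c(mean(xi1 * xi1 * d), mean(xi1 * xi2 * d),
                  mean(xi2 * xi1 * d), mean(xi2 * xi2 * d)), 2, 2)
    step <- tryCatch(solve(J, err), error = function(e) NULL)
    if (is.null(step)) stop("singular Jacobian in two-pattern cue solve")
    cc <- cc - pmin(pmax(step, -2), 2)  # damped step
  }
  if (max(abs(err)) >= tol)
    stop(sprintf("two-pattern cue solve did not reach targets (%.3f, %.3f); residual %.2e",
                 target[1], target[2], max(abs(err))))
  st <- network_state(cc[1] * xi1 + cc[2] * xi2 + eta, z0, t = 0)
  attr(st, "coef") <- cc
  attr(st, "realized_m") <- m
  st
}

#' Grid of feasible initial overlap pairs
#'
#' Regular grid over the (m1, m2) diamond `|m1| + |m2| <= max_radius`.
#'
#' @param spacing grid spacing.
#' @param max_radius bound on |m1| + |m2| (must stay below 1).
#' @return data.frame with columns m1 and m2.
#' @export
overlap_grid <- function(spacing = 0.1, max_radius = 0.85) {
  v <- seq(-max_radius, max_radius, by = spacing)
  g <- expand.grid(m1 = v, m2 = v)
  g[abs(g$m1) + abs(g$m2) <= max_radius + 1e-12, , drop = FALSE]
}

#' Flow map of the two-pattern overlap dynamics
#'
#' Runs one trajectory per grid point of initial overlaps (m1_0, m2_0),
#' keeping the quenched disorder (patterns, W) and the modulator
#' initialisation z(0) fixed while only the initial neural state varies.
#' Records the realized initial overlaps, the endpoint overlaps, and the
#' displacement magnitude ||m(T) - m(0)|| (Euclidean in the (m1, m2) plane),
#' which serves as a proxy for the attractor landscape.
#'
#' @param spec a `network_spec` with P = 2 (orthogonal pattern pair).
#' @param grid data.frame of initial overlap targets (columns m1, m2), e.g.
#'   from [overlap_grid()].
#' @param cfg a [sim_config()] (flow maps use dt = 0.25, T = 2000).
#' @param seed root seed: one child fixes z(0) for the whole grid, further
#'   children draw the per-point cue noise eta.
#' @return object of class `flow_field`: the results data.frame plus the
#'   quenched seed and parameters.
#' @export
flow_map <- function(spec, grid = overlap_grid(), cfg = sim_config(dt = 0.25),
                     seed = 1L) {
  stopifnot(inherits(spec, "network_spec"), spec$P == 2)
  Xi <- as_pattern_matrix(spec$patterns)
  xi1 <- Xi[1, ]; xi2 <- Xi[2, ]
  seeds <- spawn_seeds(seed, nrow(grid) + 1L)
  z0 <- with_seed(seeds[1], rnorm(spec$N))
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    init <- construct_two_pattern_init(xi1, xi2,
                                       c(grid$m1[k], grid$m2[k]),
                                       seed = seeds[k + 1], z0 = z0)
    m0 <- attr(init, "realized_m")
    traj <- run_trajectory(spec, init, cfg, tracked = c(1L, 2L))
    mT <- unname(traj$m_ss)
    data.frame(m1_0 = m0[1], m2_0 = m0[2], m1_T = mT[1], m2_T = mT[2],
               displacement = sqrt(sum((mT - m0)^2)))
  })
  structure(list(results = do.call(rbind, rows), quenched_seed = spec$seed,
                 grid_seed = seed, gamma = spec$gamma, N = spec$N,
                 dt = cfg$dt, T = cfg$T),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("<flow_field> gamma=%s, %d initial conditions, N=%d\n",
              format(x$gamma), nrow(x$results), x$N))
  invisible(x)
}

#' Cluster trajectory endpoints into distinct attractors
#'
#' Single-linkage clustering of endpoint overlap coordinates at the given
#' merge radius: endpoints closer than `radius` (chainwise) are assigned to
#' the same attractor. The ungated network yields exactly four clusters near
#' (+-1, 0) and (0, +-1); the gated network yields many more (a continuum of
#' fixed points sampled at grid resolution).
#'
#' @param endpoints two-column matrix or data.frame of (m1_T, m2_T) pairs,
#'   or a `flow_field`.
#' @param radius merge radius in overlap units (default 0.1).
#' @return list with `count`, `centers` (cluster centroids), and
#'   `memberships`.
#' @export
cluster_attractors <- function(endpoints, radius = 0.1) {
  if (inherits(endpoints, "flow_field"))
    endpoints <- endpoints$results[, c("m1_T", "m2_T")]
  ep <- as.matrix(endpoints)
  if (!nrow(ep)) stop("no endpoints to cluster")
  if (nrow(ep) == 1) {
    return(list(count = 1L, centers = ep, memberships = 1L))
  }
  hc <- stats::hclust(stats::dist(ep), method = "single")
  mem <- stats::cutree(hc, h = radius)
  centers <- do.call(rbind, lapply(sort(unique(mem)), function(k)
    colMeans(ep[mem == k, , drop = FALSE])))
  list(count = length(unique(mem)), centers = centers, memberships = mem)
}

#' Convert (m1, m2) overlap coordinates to (m+, m-) reporting coordinates
#'
#' m+ = m1 + m2, m- = m1 - m2; the axes used when visualising two-pattern
#' flow maps.
#'
#' @param m two-column matrix or data.frame of (m1, m2) pairs.
#' @return matrix with columns `m_plus`, `m_minus`.
#' @export
to_sum_diff <- function(m) {
  m <- as.matrix(m)
  cbind(m_plus = m[, 1] + m[, 2], m_minus = m[, 1] - m[, 2])
}
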