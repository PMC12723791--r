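#' Cholesky-type factor of a covariance with PSD enforcement
#'
#' Symmetrizes, adds a diagonal jitter of `1e-10 * mean(diag)`, and attempts
#' a Cholesky factorization; on failure falls back to an eigenvalue-clipped
#' square root. Returns a factor `U` with `cov = t(U) %*% U`.
#' @keywords internal
safe_chol <- function(cov, jitter_scale = 1e-10) {
  s <- (cov + t(cov)) / 2
  jit <- jitter_scale * mean(diag(s))
  U <- tryCatch(chol(s + diag(jit, nrow(s))), error = function(e) NULL)
  if (is.null(U)) {
    e <- eigen(s, symmetric = TRUE)
    U <- diag(sqrt(pmax(e$values, 0))) %*% t(e$vectors)
  }
  U
}

#' Sample Gaussian paths with a prescribed two-time covariance
#'
#' Draws `M` discretized sample paths of a zero-mean Gaussian process whose
#' covariance matrix on the time grid is `cov` (positive semidefiniteness is
#' enforced by a small diagonal jitter, with an eigenvalue-clipping
#' fallback). Used for the colored noises eta_x and eta_z of the single-site
#' process.
#'
#' @param cov T x T symmetric covariance matrix.
#' @param M number of paths (>= 1).
#' @param seed optional seed.
#' @param Z optional M x T matrix of standard normals (common random
#'   numbers); drawn internally when `NULL`.
#' @return M x T matrix of paths.
#' @export
sample_gaussian_paths <- function(cov, M, seed = NULL, Z = NULL) {
  if (!is.matrix(cov) || nrow(cov) != ncol(cov))
    stop("cov must be a square matrix")
  if (max(abs(cov - t(cov))) > 1e-8 * (1 + max(abs(cov))))
    stop("cov must be symmetric")
  if (M < 1) stop("M must be >= 1")
  if (all(cov == 0)) return(matrix(0, M, nrow(cov)))
  U <- safe_chol(cov)
  if (is.null(Z)) Z <- with_seed(seed, matrix(rnorm(M * nrow(cov)), M))
  Z %*% U
}

#' Propagator from the response function by forward Volterra stepping
#'
#' Solves d/dt G(t, t') = delta(t - t') + int du R(t, u) G(u, t') on the
#' time grid by explicit forward stepping, with the delta represented as
#' 1/dt on the diagonal time step. With R = 0 this yields the unit step
#' kernel Theta(t - t'); a memoryless kernel R(t, u) = -lambda delta(t - u)
#' gives exponential decay exp(-lambda (t - t')).
#'
#' @param R causal (lower-triangular) response matrix on the grid.
#' @param dt grid spacing.
#' @return causal propagator matrix of the same dimension.
#' @export
update_propagator <- function(R, dt) {
  L <- nrow(R)
  G <- matrix(0, L, L)
  if (L < 2) return(G)
  for (k in seq_len(L - 1)) {
    G[k + 1, ] <- G[k, ] + dt^2 * (R[k, seq_len(k), drop = FALSE] %*%
                                     G[seq_len(k), , drop = FALSE])
    G[k + 1, k] <- G[k + 1, k] + 1
  }
  G
}

#' Resolvent memory kernel of the retarded self-interaction
#'
#' Solves the operator equation G = c * (delta + R o G), i.e.
#' G = c (I - c R)^{-1} with the identity as a Dirac delta, on the
#' discretized grid (the delta carries a 1/dt diagonal weight). This is the
#' resummed kernel entering the retarded term alpha * int G(t,u) phi(u) du
#' and the noise covariance alpha * G C G^T of the single-site process; the
#' coupling is c = g / sqrt(alpha).
#'
#' @param R causal response matrix with zero diagonal.
#' @param coupling scalar coupling constant c.
#' @param dt grid spacing.
#' @return causal kernel matrix with diagonal `coupling/dt`.
#' @export
resolvent_kernel <- function(R, coupling, dt) {
  L <- nrow(R)
  A <- diag(L) - coupling * dt * R
  forwardsolve(A, diag(L)) * (coupling / dt)
}

#' Integrate the single-site effective process for an ensemble of paths
#'
#' Euler-integrates M sample paths of the DMFT single-site equations in the
#' condensed-pattern frame (xi = +1, legitimate by the sign symmetry of the
#' dynamics): the neuronal variable is driven by the condensed field
#' (g/sqrt(alpha)) m(t), the colored noise eta_x and the retarded
#' self-interaction alpha * int G(t,u) phi(u) du, all gated multiplicatively
#' by sigma(z); the modulator variable relaxes toward its colored noise
#' eta_z.
#'
#' @param eta_x,eta_z M x L noise path matrices.
#' @param x0,z0 length-M initial conditions.
#' @param m length-L overlap trajectory (current iterate).
#' @param G L x L causal resolvent kernel from [resolvent_kernel()].
#' @param alpha,g,gamma,tau_z model parameters.
#' @param dt grid spacing.
#' @return list with M x L matrices `x`, `phi`, `sig`.
#' @export
single_site_integrate <- function(eta_x, eta_z, x0, z0, m, G,
                                  alpha, g = 1.5, gamma = 0, tau_z = 1, dt) {
  L <- ncol(eta_x)
  stopifnot(ncol(eta_z) == L, length(m) == L, nrow(G) == L,
            length(x0) == nrow(eta_x), length(z0) == nrow(eta_x))
  gamma_inf <- is.infinite(gamma)
  cpp_dmft_paths(eta_x, eta_z, x0, z0, m, G, g / sqrt(alpha), alpha,
                 if (gamma_inf) 0 else gamma, gamma_inf, tau_z, dt)
}

#' Impulse-response estimate of R(t, t')
#'
#' For every grid time t', reruns the single-site ensemble with an impulse
#' of area `eps` injected into the gated x-drift at t', using common random
#' numbers (identical noise paths), and estimates
#' R(t, t') = (<phi(t)>_pert - <phi(t)>) / eps for t > t'; entries on and
#' above the diagonal are exactly zero.
#'
#' @param paths result of [single_site_integrate()].
#' @param eta_x the noise paths used for `paths`.
#' @param m,G the overlap iterate and kernel used for `paths`.
#' @param alpha,g,dt model and grid parameters.
#' @param eps impulse area (nonzero).
#' @param m_resp number of paths used for the estimate (default: all).
#' @return L x L causal response matrix.
#' @export
estimate_response <- function(paths, eta_x, m, G, alpha, g = 1.5, dt,
                              eps = 0.05, m_resp = nrow(eta_x)) {
  if (!is.numeric(eps) || eps == 0) stop("eps must be nonzero")
  cpp_dmft_response(paths$x, paths$phi, paths$sig, eta_x, m, G,
                    g / sqrt(alpha), alpha, dt, eps, as.integer(m_resp))
}

#' Solve the self-consistent DMFT equations on a time grid
#'
#' Damped fixed-point iteration over the order parameters of the single-site
#' process: the overlap m(t), the two-time activation correlation
#' C_phi(t,t'), the impulse response R(t,t') and the resolvent kernel G.
#' Each iteration (i) builds the noise covariances cov_z = C_phi and
#' cov_x = alpha G C_phi G^T, (ii) samples colored noises with common random
#' numbers across iterations, (iii) integrates the M-path ensemble, and
#' (iv) re-estimates m, C_phi and R. Iteration stops when the sup-norm
#' change of m(t) falls below `tol`, floored at the Monte-Carlo standard
#' error of the ensemble-mean overlap (changes below that level are
#' unresolvable at finite M).
#'
#' The initial condition mirrors the many-body cue protocol: x(0) = c1 + eta
#' with c1 root-found so the ensemble overlap at t = 0 equals `m0`, and
#' z(0) standard normal.
#'
#' @param alpha memory load.
#' @param gamma gate steepness (0, finite, or `Inf`).
#' @param m0 initial overlap.
#' @param g gain.
#' @param tau_z modulator time-constant.
#' @param T time horizon.
#' @param dt grid spacing.
#' @param M number of sample paths.
#' @param tol sup-norm tolerance on m(t).
#' @param damping damping factor in (0, 1] applied to all updates
#'   (new = (1 - damping) old + damping estimate).
#' @param max_iter iteration cap; non-convergence is flagged, with the
#'   residual history attached.
#' @param eps impulse area for the response estimate.
#' @param m_resp paths used in the response estimate (default M/4, at least
#'   200).
#' @param seed seed for the common random numbers.
#' @param verbose print per-iteration residuals.
#' @return object of class `dmft_solution` with `tgrid`, `m`, `C_phi`, `R`,
#'   `G`, `cov_x`, `cov_z`, `residuals`, `iter_count`, `converged`, and the
#'   parameters.
#' @export
solve_dmft <- function(alpha, gamma, m0, g = 1.5, tau_z = 1,
                       T = 50, dt = 0.2, M = 2000, tol = 1e-3,
                       damping = 0.5, max_iter = 30, eps = 0.05,
                       m_resp = max(200L, M %/% 4L), seed = 1L,
                       verbose = FALSE) {
  stopifnot(alpha > 0, g > 0, tau_z > 0, T > 0, dt > 0, M >= 1,
            damping > 0, damping <= 1)
  L <- round(T / dt) + 1L
  tgrid <- (seq_len(L) - 1) * dt
  kappa <- g / sqrt(alpha)

  seeds <- spawn_seeds(seed, c("Zx", "Zz", "x0", "z0"))
  Zx <- with_seed(seeds[["Zx"]], matrix(rnorm(M * L), M, L))
  Zz <- with_seed(seeds[["Zz"]], matrix(rnorm(M * L), M, L))
  eta0 <- with_seed(seeds[["x0"]], rnorm(M))
  z0 <- with_seed(seeds[["z0"]], rnorm(M))
  # cue coefficient matched to the target ensemble overlap at t = 0
  f0 <- function(c1) mean(tanh(c1 + eta0)) - m0
  c1 <- if (f0(0) >= 0) 0 else uniroot(f0, c(0, 30), tol = 1e-10)$root
  x0 <- c1 + eta0

  # initial guesses: constant overlap, exponentially decorrelating C, bare G
  m_cur <- rep(m0, L)
  C_cur <- m0^2 + (1 - m0^2) * exp(-abs(outer(tgrid, tgrid, "-")))
  R_cur <- matrix(0, L, L)
  G <- resolvent_kernel(R_cur, kappa, dt)

  residuals <- numeric(0)
  converged <- FALSE
  paths <- NULL
  for (it in seq_len(max_iter)) {
    cov_x <- alpha * dt^2 * (G %*% C_cur %*% t(G))
    eta_x <- sample_gaussian_paths(cov_x, M, Z = Zx)
    eta_z <- sample_gaussian_paths(C_cur, M, Z = Zz)
    paths <- single_site_integrate(eta_x, eta_z, x0, z0, m_cur, G,
                                   alpha, g, gamma, tau_z, dt)
    if (!all(is.finite(paths$x)))
      stop("non-finite single-site paths; reduce dt or damping")
    m_new <- colMeans(paths$phi)
    C_new <- crossprod(paths$phi) / M
    R_new <- estimate_response(paths, eta_x, m_cur, G, alpha, g, dt,
                               eps = eps, m_resp = m_resp)
    res <- max(abs(m_new - m_cur))
    residuals <- c(residuals, res)
    # the sup-norm change of m cannot be resolved below the Monte-Carlo
    # standard error of the ensemble mean; floor the tolerance there
    mc_floor <- max(apply(paths$phi, 2, sd)) / sqrt(M)
    if (verbose)
      message(sprintf("  dmft iter %2d: sup|dm| = %.3e", it, res))
    if (res < max(tol, mc_floor) && it > 1) {
      # converged: keep the undamped Monte-Carlo estimates, since the damped
      # mix would retain a lag bias of the order of the final residual
      m_cur <- m_new
      C_cur <- C_new
      R_cur <- R_new
      G <- resolvent_kernel(R_cur, kappa, dt)
      converged <- TRUE
      break
    }
    m_cur <- (1 - damping) * m_cur + damping * m_new
    C_cur <- (1 - damping) * C_cur + damping * C_new
    R_cur <- (1 - damping) * R_cur + damping * R_new
    G <- resolvent_kernel(R_cur, kappa, dt)
  }
  cov_x <- alpha * dt^2 * (G %*% C_cur %*% t(G))
  structure(list(tgrid = tgrid, m = m_cur, C_phi = C_cur, R = R_cur, G = G,
                 cov_x = cov_x, cov_z = C_cur,
                 residuals = residuals, iter_count = length(residuals),
                 converged = converged, M = M, m_resp = m_resp,
                 params = list(alpha = alpha, gamma = gamma, g = g,
                               tau_z = tau_z, m0 = m0, dt = dt, T = T,
                               eps = eps, damping = damping, seed = seed)),
            class = "dmft_solution")
}

#' @export
print.dmft_solution <- function(x, ...) {
  cat(sprintf(
    "<dmft_solution> alpha=%g gamma=%s m0=%g: %d iterations, residual %.2e%s; m(T)=%.4f\n",
    x$params$alpha, format(x$params$gamma), x$params$m0, x$iter_count,
    utils::tail(x$residuals, 1), if (x$converged) "" else " (NOT converged)",
    utils::tail(x$m, 1)))
  invisible(x)
}

#' Time-asymptotic DMFT fixed point with an imposed frozen sub-population
#'
#' Solves the static self-consistency obtained by assuming the single-site
#' dynamics reach a stable fixed point. Active neurons (gate open) satisfy
#' x* = b phi(x*) + (g/sqrt(alpha)) m + s u with u standard normal, where
#' b = g sqrt(alpha) / (1 - kappa chi) is the static limit of the resolvent
#' self-interaction, s^2 = g^2 q / (1 - kappa chi)^2 the static crosstalk
#' variance, chi the static susceptibility and q the static self-overlap.
#' The frozen sub-population contributes its imposed overlap `mF_ss` with
#' weight `rhoF_ss` and its imposed self-overlap `qF_ss` (adding
#' rhoF * qF_ss to q and nothing to chi, since frozen neurons do not
#' respond). Solved by damped scalar iteration with Gauss-Hermite
#' quadrature over the static field.
#'
#' @param alpha memory load.
#' @param mF_ss imposed steady-state overlap of the frozen population
#'   (in `[-1, 1]`).
#' @param rhoF_ss frozen fraction (in `[0, 1]`).
#' @param qF_ss imposed frozen self-overlap (mean squared frozen
#'   activation). Defaults to the coherent closure `mF_ss^2`, which is exact
#'   when frozen activations are aligned with the pattern; supplying the
#'   measured second moment instead is markedly more accurate at small
#'   `mF_ss`, where frozen activations are large but incoherent.
#' @param g gain.
#' @param m_init initial guess for the total overlap.
#' @param n_quad Gauss-Hermite nodes.
#' @param damping damping of the scalar iteration.
#' @param tol residual tolerance.
#' @param max_iter iteration cap.
#' @return object of class `asymptotic_solution`: `m_ss`, active-population
#'   overlap `mA_ss`, static `q`, susceptibility `chi`, and a `converged`
#'   flag (false if the iteration stalls or the static denominator
#'   1 - kappa chi closes).
#' @export
asymptotic_fixed_point <- function(alpha, mF_ss, rhoF_ss, qF_ss = mF_ss^2,
                                   g = 1.5,
                                   m_init = max(abs(mF_ss), 0.5),
                                   n_quad = 80, damping = 0.1,
                                   tol = 1e-10, max_iter = 20000) {
  stopifnot(alpha > 0, rhoF_ss >= 0, rhoF_ss <= 1, abs(mF_ss) <= 1,
            qF_ss >= 0, qF_ss <= 1)
  if (rhoF_ss == 1)
    return(structure(list(alpha = alpha, g = g, mF_ss = mF_ss,
                          rhoF_ss = 1, m_ss = mF_ss, mA_ss = NA_real_,
                          q = qF_ss, chi = 0, converged = TRUE,
                          iterations = 0L),
                     class = "asymptotic_solution"))
  kappa <- g / sqrt(alpha)
  gh <- pracma::gaussHermite(n_quad)
  u <- sqrt(2) * gh$x
  w <- gh$w / sqrt(pi)
  rhoA <- 1 - rhoF_ss
  mF <- if (is.na(mF_ss)) 0 else mF_ss

  m <- m_init
  q <- max(m^2, 0.1)
  chi <- 0.1
  converged <- FALSE
  it <- 0L
  ok <- TRUE
  x_warm <- NULL
  while (it < max_iter) {
    it <- it + 1L
    den <- 1 - kappa * chi
    if (den < 1e-3) { ok <- FALSE; break }
    b <- g * sqrt(alpha) / den
    s <- g * sqrt(max(q, 0)) / den
    h <- kappa * m + s * u
    # stable root of x = b tanh(x) + h by fixed-point iteration; warm-started
    # across outer iterations so the selected branch varies continuously
    x <- if (is.null(x_warm)) h + b * sign(h) else x_warm
    for (r in 1:200) {
      x_new <- b * tanh(x) + h
      if (max(abs(x_new - x)) < 1e-13) { x <- x_new; break }
      x <- x_new
    }
    x_warm <- x
    phi <- tanh(x)
    dphi <- 1 - phi^2
    mA <- sum(w * phi)
    qA <- sum(w * phi^2)
    chiA <- sum(w * dphi / (1 - b * dphi))
    m_new <- rhoF_ss * mF + rhoA * mA
    q_new <- rhoF_ss * qF_ss + rhoA * qA
    chi_new <- rhoA * chiA
    res <- max(abs(m_new - m), abs(q_new - q), abs(chi_new - chi))
    m <- (1 - damping) * m + damping * m_new
    q <- (1 - damping) * q + damping * q_new
    chi <- (1 - damping) * chi + damping * chi_new
    if (res < tol) { converged <- TRUE; break }
  }
  structure(list(alpha = alpha, g = g, mF_ss = mF_ss, rhoF_ss = rhoF_ss,
                 m_ss = m, mA_ss = if (ok) mA else NA_real_, q = q,
                 chi = chi, converged = converged && ok, iterations = it),
            class = "asymptotic_solution")
}

#' @export
print.asymptotic_solution <- function(x, ...) {
  cat(sprintf(
    "<asymptotic_solution> alpha=%g mF=%.3f rhoF=%.3f -> m_ss=%.4f%s\n",
    x$alpha, x$mF_ss, x$rhoF_ss, x$m_ss,
    if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Steady-state overlap band from frozen-population extremes
#'
#' For each memory load, runs binary-gated many-body simulations from the
#' two extreme cues (near-perfect and near-zero initial overlap), extracts
#' the frozen sub-population overlap mF_ss, fraction rhoF_ss and
#' self-overlap qF_ss at the final time, and feeds them into
#' [asymptotic_fixed_point()] to obtain the upper
#' and lower edges of the steady-state overlap band. The ungated static
#' solution (no frozen population) is reported alongside as a single curve.
#'
#' @param alphas memory loads to scan.
#' @param N network size for the many-body runs.
#' @param g gain.
#' @param cfg a [sim_config()] for the many-body runs.
#' @param n_reps disorder realizations per extreme.
#' @param m0_hi,m0_lo the two extreme cue overlaps.
#' @param seed_base root seed.
#' @return data.frame with per-alpha band edges `mss_lo`, `mss_hi`, the
#'   measured frozen-population inputs, and the ungated static overlap.
#' @export
mss_band <- function(alphas, N = 500, g = 1.5, cfg = sim_config(),
                     n_reps = 5, m0_hi = 0.99, m0_lo = 0.01,
                     seed_base = 1L) {
  seeds <- spawn_seeds(seed_base, length(alphas))
  rows <- lapply(seq_along(alphas), function(i) {
    a <- alphas[i]
    ss <- spawn_seeds(seeds[i], 4L * n_reps)
    measure <- function(m0, off) {
      vals <- vapply(seq_len(n_reps), function(r) {
        spec <- network_spec(N = N, alpha = a, gamma = Inf, g = g,
                             seed = ss[off + 2 * r - 1])
        init <- construct_cued_state(as_pattern_matrix(spec$patterns)[1, ],
                                     m0, seed = ss[off + 2 * r])
        traj <- run_trajectory(spec, init, cfg)
        sp <- subpopulation_overlaps(traj$state$x, traj$state$z,
                                     as_pattern_matrix(spec$patterns)[1, ])
        closed <- gate(traj$state$z, Inf) == 0
        qF <- if (any(closed)) mean(activation(traj$state$x[closed])^2) else 0
        c(mF = if (is.na(sp$mF)) 0 else sp$mF, rhoF = sp$rhoF, qF = qF,
          mss = unname(traj$m_ss[1]))
      }, numeric(4))
      rowMeans(vals)
    }
    hi <- measure(m0_hi, 0L)
    lo <- measure(m0_lo, 2L * n_reps)
    fp_hi <- asymptotic_fixed_point(a, hi[["mF"]], hi[["rhoF"]],
                                    qF_ss = hi[["qF"]], g = g,
                                    m_init = max(abs(hi[["mF"]]), 0.5))
    fp_lo <- asymptotic_fixed_point(a, lo[["mF"]], lo[["rhoF"]],
                                    qF_ss = lo[["qF"]], g = g,
                                    m_init = max(abs(lo[["mF"]]), 0.05))
    fp_un <- asymptotic_fixed_point(a, 0, 0, g = g, m_init = 0.9)
    band <- sort(c(fp_lo$m_ss, fp_hi$m_ss))
    data.frame(alpha = a,
               mF_hi = hi[["mF"]], rhoF_hi = hi[["rhoF"]], mb_mss_hi = hi[["mss"]],
               mF_lo = lo[["mF"]], rhoF_lo = lo[["rhoF"]], mb_mss_lo = lo[["mss"]],
               mss_lo = band[1], mss_hi = band[2],
               mss_ungated = fp_un$m_ss,
               converged = fp_lo$converged && fp_hi$converged)
  })
  do.call(rbind, rows)
}
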