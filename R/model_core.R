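#' @useDynLib gatednet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif uniroot sd setNames
NULL

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed`, then restores the
#' previous RNG state, so library calls never disturb a user's random stream.
#' With `seed = NULL` the expression runs on the current stream.
#'
#' @param seed integer scalar or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Spawn deterministic child seeds from one root seed
#'
#' A single root seed controls every source of randomness in an experiment
#' (patterns, modulator couplings, cue noise, modulator initialisation, DMFT
#' sample paths). Children are drawn deterministically so one component can be
#' varied while the others stay pinned, as in the flow-map protocol where only
#' the initial neural state changes.
#'
#' @param seed integer root seed.
#' @param n number of child seeds, or a character vector of stream names.
#' @return integer vector of child seeds (named if `n` was names), each in
#'   `[1, 2^31 - 2]`.
#' @export
#' @examples
#' spawn_seeds(42, c("patterns", "W", "cue"))
spawn_seeds <- function(seed, n) {
  nm <- NULL
  if (is.character(n)) {
    nm <- n
    n <- length(n)
  }
  out <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  if (!is.null(nm)) names(out) <- nm
  out
}

#' Sample a set of stored patterns
#'
#' Draws `P` iid patterns of length `N`, either binary (entries uniform on
#' \{-1, +1\}, the default throughout) or standard Gaussian (used for the
#' universality check: the spectral statistics of the resulting Wishart-type
#' coupling matrix are insensitive to the entry distribution).
#'
#' @param N number of neurons (>= 2).
#' @param P number of patterns (>= 1).
#' @param kind `"binary"` or `"gaussian"`.
#' @param seed optional integer seed for reproducibility.
#' @return an object of class `pattern_set`: list with `patterns` (P x N
#'   matrix, rows are patterns) and `kind`.
#' @export
#' @examples
#' ps <- sample_patterns(100, 5, seed = 1)
#' dim(ps$patterns)
sample_patterns <- function(N, P, kind = c("binary", "gaussian"), seed = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(N) || length(N) != 1L || N < 2 || N != round(N))
    stop("N must be a single integer >= 2")
  if (!is.numeric(P) || length(P) != 1L || P < 1 || P != round(P))
    stop("P must be a single integer >= 1")
  patterns <- with_seed(seed, {
    if (kind == "binary") {
      matrix(sample(c(-1, 1), N * P, replace = TRUE), nrow = P, ncol = N)
    } else {
      matrix(rnorm(N * P), nrow = P, ncol = N)
    }
  })
  structure(list(patterns = patterns, kind = kind), class = "pattern_set")
}

#' Construct an exactly orthogonal +/-1 pattern pair
#'
#' The first pattern is uniform on \{-1,+1\}^N; the second flips the sign of
#' exactly N/2 randomly chosen components, which forces the inner product
#' to be exactly zero and the Hamming distance to be exactly N/2.
#'
#' @param N even number of neurons.
#' @param seed optional integer seed.
#' @return a `pattern_set` with two rows.
#' @export
#' @examples
#' pp <- make_orthogonal_pair(10, seed = 1)
#' sum(pp$patterns[1, ] * pp$patterns[2, ])  # exactly 0
make_orthogonal_pair <- function(N, seed = NULL) {
  if (!is.numeric(N) || length(N) != 1L || N < 2 || N != round(N) || N %% 2 != 0)
    stop("N must be a single even integer >= 2")
  patterns <- with_seed(seed, {
    xi1 <- sample(c(-1, 1), N, replace = TRUE)
    flip <- sample.int(N, N / 2)
    xi2 <- xi1
    xi2[flip] <- -xi2[flip]
    rbind(xi1, xi2, deparse.level = 0)
  })
  structure(list(patterns = patterns, kind = "binary"), class = "pattern_set")
}

#' Build the symmetric Hebbian coupling matrix
#'
#' Returns the dense outer-product matrix J = sum_mu xi^mu (xi^mu)^T,
#' including the diagonal (J_ii = P for binary patterns). The simulator never
#' materialises J (it uses the low-rank factorisation); this dense form exists
#' for inspection and as a cross-check.
#'
#' @param patterns a `pattern_set` or a P x N matrix.
#' @return N x N symmetric matrix of rank at most P.
#' @export
build_hebbian_couplings <- function(patterns) {
  Xi <- as_pattern_matrix(patterns)
  crossprod(Xi)
}

as_pattern_matrix <- function(patterns) {
  if (inherits(patterns, "pattern_set")) patterns$patterns
  else if (is.matrix(patterns)) patterns
  else if (is.numeric(patterns)) matrix(patterns, nrow = 1L)
  else stop("patterns must be a pattern_set, a matrix, or a numeric vector")
}

#' Neuronal activation function
#'
#' The graded-response transfer function phi(x) = tanh(x), odd and bounded
#' in (-1, 1).
#'
#' @param x numeric array.
#' @return elementwise tanh of `x`.
#' @export
activation <- function(x) tanh(x)

#' Neuromodulatory gating function
#'
#' Logistic gate sigma(z) = 1 / (1 + exp(-gamma * z)). `gamma = 0` gives the
#' constant 1/2 (the ungated network); `gamma = Inf` is implemented as an
#' exact step function, with sigma(0) = 1/2 as the pointwise limit of the
#' logistic family (no huge finite gamma, so no exponent overflow).
#'
#' @param z numeric array of modulator levels.
#' @param gamma nonnegative steepness, or `Inf` for the binary gate.
#' @return values in \[0, 1\], monotone nondecreasing in `z`.
#' @export
#' @examples
#' gate(c(-3, 0, 3), Inf)   # 0, 0.5, 1
#' gate(rnorm(5), 0)        # all 0.5
gate <- function(z, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) || gamma < 0)
    stop("gamma must be a single nonnegative number (Inf allowed)")
  if (is.infinite(gamma)) {
    out <- as.numeric(z > 0)
    out[z == 0] <- 0.5
    out
  } else if (gamma == 0) {
    rep(0.5, length(z))
  } else {
    stats::plogis(gamma * z)
  }
}

#' Assemble a full network specification with quenched disorder
#'
#' Bundles all static parameters and quenched random quantities of the
#' two-layer gated network: the stored patterns (defining the Hebbian
#' couplings), the modulator-neuron couplings W (iid standard normal,
#' asymmetric), the gain `g`, gate steepness `gamma`, and the modulator
#' time-constant `tau_z`. All randomness is derived from one root `seed`
#' via independent child streams.
#'
#' @param N number of neurons.
#' @param P number of patterns; alternatively give `alpha` and `P = round(alpha * N)`.
#' @param alpha memory load P/N (used only when `P` is missing).
#' @param gamma gate steepness (0 = ungated, `Inf` = binary gate).
#' @param g scalar gain (default 1.5).
#' @param tau_z modulator release time-constant (default 1).
#' @param pattern_kind `"binary"` or `"gaussian"`.
#' @param patterns optional pre-built `pattern_set` (overrides sampling).
#' @param W optional pre-built N x N modulator coupling matrix.
#' @param make_W force generation of W even when `gamma == 0` (where the gate
#'   is constant and W never enters the neuronal dynamics).
#' @param seed root seed for the quenched disorder.
#' @return object of class `network_spec`.
#' @export
#' @examples
#' spec <- network_spec(N = 200, alpha = 0.1, gamma = Inf, seed = 7)
#' spec$P / spec$N
network_spec <- function(N, P = NULL, alpha = NULL, gamma = 0, g = 1.5,
                         tau_z = 1, pattern_kind = "binary",
                         patterns = NULL, W = NULL, make_W = FALSE,
                         seed = NULL) {
  if (!is.numeric(N) || length(N) != 1L || N < 2 || N != round(N))
    stop("N must be a single integer >= 2")
  if (is.null(P)) {
    if (is.null(alpha)) stop("supply either P or alpha")
    P <- round(alpha * N)
    if (P < 1) stop("alpha * N rounds to zero patterns")
  }
  if (!is.numeric(tau_z) || tau_z <= 0) stop("tau_z must be positive")
  gate(0, gamma)  # validates gamma
  seeds <- spawn_seeds(if (is.null(seed)) sample.int(2^31 - 2, 1) else seed,
                       c("patterns", "W"))
  if (is.null(patterns))
    patterns <- sample_patterns(N, P, kind = pattern_kind, seed = seeds[["patterns"]])
  Xi <- as_pattern_matrix(patterns)
  if (nrow(Xi) != P || ncol(Xi) != N)
    stop("supplied patterns do not match N and P")
  need_W <- make_W || (gamma > 0)
  if (is.null(W) && need_W)
    W <- with_seed(seeds[["W"]], matrix(rnorm(N * N), N, N))
  if (!is.null(W) && (!is.matrix(W) || any(dim(W) != c(N, N))))
    stop("W must be an N x N matrix")
  structure(list(
    N = as.integer(N), P = as.integer(P), alpha = P / N,
    gamma = gamma, g = g, tau_z = tau_z,
    patterns = patterns, W = W, seed = seed, child_seeds = seeds
  ), class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf(
    "<network_spec> N=%d P=%d (alpha=%.4g) gamma=%s g=%g tau_z=%g patterns=%s W=%s\n",
    x$N, x$P, x$alpha, format(x$gamma), x$g, x$tau_z, x$patterns$kind,
    if (is.null(x$W)) "none" else "N x N"))
  invisible(x)
}

#' Instantaneous network state
#'
#' @param x length-N neuronal activity vector.
#' @param z length-N neuromodulator level vector.
#' @param t nonnegative time stamp.
#' @return object of class `network_state`.
#' @export
network_state <- function(x, z, t = 0) {
  if (length(x) != length(z)) stop("x and z must have equal length")
  if (!all(is.finite(x)) || !all(is.finite(z))) stop("state entries must be finite")
  if (t < 0) stop("t must be nonnegative")
  structure(list(x = as.numeric(x), z = as.numeric(z), t = t),
            class = "network_state")
}

#' Recurrent Hebbian drive via the low-rank factorisation
#'
#' Computes (g / sqrt(P N)) * J %*% phi without forming the dense J, as
#' (g / sqrt(P N)) * Xi^T (Xi phi) with Xi the P x N pattern matrix. The
#' 1/sqrt(PN) normalisation keeps the drive O(1) at fixed memory load as
#' N grows.
#'
#' @param spec a `network_spec`.
#' @param phi length-N vector of activations phi(x).
#' @return length-N drive vector, equal to the dense matrix product up to
#'   rounding.
#' @export
recurrent_drive <- function(spec, phi) {
  Xi <- as_pattern_matrix(spec$patterns)
  if (length(phi) != ncol(Xi)) stop("phi has wrong length for this spec")
  drop(crossprod(Xi, Xi %*% phi)) * (spec$g / sqrt(spec$P * spec$N))
}
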