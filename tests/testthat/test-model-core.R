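test_that("spawn_seeds is deterministic, named, and in range", {
  s1 <- spawn_seeds(42, 5)
  s2 <- spawn_seeds(42, 5)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 1 & s1 <= .Machine$integer.max - 1L))
  nm <- spawn_seeds(42, c("patterns", "W", "cue"))
  expect_named(nm, c("patterns", "W", "cue"))
  expect_identical(unname(nm), spawn_seeds(42, 3))
  expect_false(any(duplicated(s1)))
})

test_that("with_seed leaves the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(gatednet:::with_seed(7, rnorm(10)))
  expect_identical(.Random.seed, before)
  # and is itself reproducible
  expect_identical(gatednet:::with_seed(7, rnorm(3)),
                   gatednet:::with_seed(7, rnorm(3)))
})

test_that("sample_patterns draws the right shapes and entries", {
  ps <- sample_patterns(40, 7, seed = 1)
  expect_s3_class(ps, "pattern_set")
  expect_identical(dim(ps$patterns), c(7L, 40L))
  expect_true(all(ps$patterns %in% c(-1, 1)))
  expect_identical(ps$patterns, sample_patterns(40, 7, seed = 1)$patterns)
  pg <- sample_patterns(500, 4, kind = "gaussian", seed = 2)
  expect_gt(sd(pg$patterns), 0.9)
  expect_lt(sd(pg$patterns), 1.1)
  expect_error(sample_patterns(1, 3), "N must be")
  expect_error(sample_patterns(10, 0), "P must be")
})

test_that("make_orthogonal_pair is exactly orthogonal at Hamming distance N/2", {
  pp <- make_orthogonal_pair(100, seed = 3)
  xi1 <- pp$patterns[1, ]; xi2 <- pp$patterns[2, ]
  expect_identical(sum(xi1 * xi2), 0)
  expect_identical(sum(xi1 != xi2), 50L)
  expect_true(all(c(xi1, xi2) %in% c(-1, 1)))
  expect_error(make_orthogonal_pair(11), "even")
})

test_that("build_hebbian_couplings matches the double-loop outer-product sum", {
  ps <- sample_patterns(15, 4, seed = 4)
  J <- build_hebbian_couplings(ps)
  J_oracle <- matrix(0, 15, 15)
  for (mu in 1:4)
    J_oracle <- J_oracle + outer(ps$patterns[mu, ], ps$patterns[mu, ])
  expect_equal(J, J_oracle, tolerance = 1e-14)
  # self-couplings retained: J_ii = P for binary patterns
  expect_true(all(diag(J) == 4))
  expect_true(isSymmetric(J))
})

test_that("gate handles the ungated, finite and binary limits", {
  z <- c(-3, -1e-8, 0, 1e-8, 3)
  expect_identical(gate(z, 0), rep(0.5, 5))
  expect_identical(gate(z, Inf), c(0, 0, 0.5, 1, 1))
  expect_equal(gate(z, 2.5), plogis(2.5 * z))
  # monotone in z and increasing steepness pivots around 1/2
  expect_true(all(diff(gate(seq(-2, 2, 0.1), 4)) > 0))
  expect_error(gate(0, -1), "nonnegative")
  expect_error(gate(0, NA_real_), "nonnegative")
})

test_that("activation is bounded odd tanh", {
  x <- seq(-5, 5, 0.5)
  expect_equal(activation(x), tanh(x))
  expect_equal(activation(-x), -activation(x))
})

test_that("network_spec resolves P/alpha and builds W only when needed", {
  spec <- network_spec(N = 100, alpha = 0.13, gamma = 0, seed = 5)
  expect_identical(spec$P, 13L)
  expect_equal(spec$alpha, 0.13)
  expect_null(spec$W)           # gate constant: W never enters the dynamics
  spec2 <- network_spec(N = 50, P = 5, gamma = Inf, seed = 5)
  expect_identical(dim(spec2$W), c(50L, 50L))
  spec3 <- network_spec(N = 50, P = 5, gamma = 0, make_W = TRUE, seed = 5)
  expect_false(is.null(spec3$W))
  # same seed, same quenched disorder
  s_a <- network_spec(N = 30, P = 3, gamma = Inf, seed = 9)
  s_b <- network_spec(N = 30, P = 3, gamma = Inf, seed = 9)
  expect_identical(s_a$patterns$patterns, s_b$patterns$patterns)
  expect_identical(s_a$W, s_b$W)
  expect_error(network_spec(N = 100), "P or alpha")
  expect_error(network_spec(N = 100, alpha = 0.001), "rounds to zero")
})

test_that("recurrent_drive equals the dense double-loop oracle", {
  spec <- network_spec(N = 20, P = 6, gamma = 0, seed = 6)
  phi <- tanh(rnorm(20))
  expect_equal(recurrent_drive(spec, phi),
               oracle_dense_drive(spec$patterns$patterns, phi, spec$g),
               tolerance = 1e-12)
  expect_error(recurrent_drive(spec, phi[-1]), "wrong length")
})

test_that("network_state validates its inputs", {
  st <- network_state(rnorm(5), rnorm(5), t = 1.5)
  expect_s3_class(st, "network_state")
  expect_error(network_state(rnorm(5), rnorm(4)), "equal length")
  expect_error(network_state(c(1, NA), c(1, 2)), "finite")
  expect_error(network_state(1, 1, t = -1), "nonnegative")
})
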