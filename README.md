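# gatednet

Simulation and theory toolkit for **self-adaptively gated associative
memory networks**: two-layer recurrent networks in which a
neuromodulator-like layer multiplicatively gates the integration
time-constant of every neuron of an Amari–Hopfield memory layer.

## The scientific problem

Classical Hopfield-type networks store patterns as attractors of

```
dx_i/dt = -x_i + (g / sqrt(PN)) * sum_j J_ij phi(x_j),      J = sum_mu xi^mu (xi^mu)^T
```

but fail catastrophically above a critical memory load `alpha_c = P/N`
(about 0.13 at gain `g = 1.5`): stored patterns stop being attractors and
the network falls into a spin-glass regime. `gatednet` implements a gated
extension,

```
dx_i/dt = sigma(z_i) * [ -x_i + (g / sqrt(PN)) * sum_j J_ij phi(x_j) ]
tau_z dz_i/dt = -z_i + (1 / sqrt(N)) * sum_j W_ij phi(x_j)
```

with logistic gate `sigma(z) = 1 / (1 + exp(-gamma z))`. A closed gate
(`sigma = 0`) freezes its neuron instead of letting it relax into the
spin-glass state. The package provides the machinery to show that this
gating stabilises retrieval far above the classical capacity and replaces
the discrete pattern attractors by a continuum of fixed points:

* compiled many-body Euler integrators with low-rank Hebbian drive
  (`network_spec()`, `run_trajectory()`);
* retrieval observables: Mattis overlaps, frozen/active sub-population
  decomposition, gate-flip traces;
* phase diagrams and storage-capacity sweeps
  (`phase_diagram()`, `estimate_critical_capacity()`);
* a self-consistent dynamical mean-field (DMFT) solver for the single-site
  process with colored noise, two-time correlations, impulse-response
  estimation and a resummed memory kernel (`solve_dmft()`);
* time-asymptotic fixed-point equations and steady-state overlap bands
  (`asymptotic_fixed_point()`, `mss_band()`);
* two-pattern flow maps and attractor clustering exposing continuous
  multistability (`flow_map()`, `cluster_attractors()`).

See the vignette (`vignettes/gated-associative-memory.Rmd`) for the model,
the mean-field reduction, and the numerical design choices.

## Worked example

Overload the network (`alpha = 0.4`, about three times the classical
capacity) and cue it with a noisy pattern of overlap 0.55, with and without
the binary gate:

```r
library(gatednet)

spec <- network_spec(N = 500, alpha = 0.4, gamma = Inf, seed = 1)
spec
#> <network_spec> N=500 P=200 (alpha=0.4) gamma=Inf g=1.5 tau_z=1 patterns=binary W=N x N

init <- construct_cued_state(spec$patterns$patterns[1, ], 0.55, seed = 2)
traj <- run_trajectory(spec, init, sim_config(dt = 0.2, T = 2000))
traj
#> <trajectory> 1001 records to t=2000; m_ss = 0.6341

# the identical protocol without gating loses the pattern
spec0 <- network_spec(N = 500, alpha = 0.4, gamma = 0, seed = 1)
init0 <- construct_cued_state(spec0$patterns$patterns[1, ], 0.55, seed = 2)
run_trajectory(spec0, init0, sim_config(dt = 0.2, T = 2000))
#> <trajectory> 1001 records to t=2000; m_ss = 0.2440

# about half the gated neurons end up frozen, and the overlap decomposes
# exactly over the frozen/active split
sp <- subpopulation_overlaps(traj$state$x, traj$state$z,
                             spec$patterns$patterns[1, ])
sprintf("rhoF = %.3f, mF = %.3f, mA = %.3f", sp$rhoF, sp$mF, sp$mA)
#> [1] "rhoF = 0.478, mF = 0.633, mA = 0.635"
```

The gated network holds an order-one overlap (0.63) where the ungated one
collapses to the residual spin-glass scale (0.24).

## Tests

```r
testthat::test_dir("tests/testthat", package = "gatednet",
                   load_package = "installed")
```

The suite contains per-module unit tests against naive reference oracles
(dense double-loop couplings, plain-R Euler integration, closed-form
kernels) and `tests/testthat/test-acceptance.R`, one block per headline
claim (critical capacity, exact gate limits, attractor quartet vs.
gated continuum, overload rescue, DMFT/many-body agreement).

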