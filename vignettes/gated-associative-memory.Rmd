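---
title: "Gated associative memory: model, phase structure, and mean-field reduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gated associative memory: model, phase structure, and mean-field reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatednet)
```

## The scientific problem

Classical associative memory networks of the Amari–Hopfield type store
patterns as fixed points of a recurrent dynamics with Hebbian couplings.
Their central failure mode is a sharp *storage capacity*: above a critical
memory load $\alpha_c = P/N$ the stored patterns cease to be attractors and
the network falls into a spin-glass regime of useless low-overlap states.

`gatednet` implements and analyses a two-layer extension in which a second,
neuromodulator-like layer *multiplicatively gates the integration
time-constant* of every neuron. A neuron whose gate is closed does not relax
toward the spin-glass state — it is frozen and simply holds its value. The
package provides the tools to show, by simulation and by dynamical mean-field
theory (DMFT), that this self-adaptive gating

* stabilises retrieval far above the classical capacity, and
* replaces the discrete set of pattern attractors by a *continuum* of fixed
  points (continuous multistability), whose selection depends on the initial
  condition.

## The model

The neuronal layer $x \in \mathbb{R}^N$ and the modulator layer
$z \in \mathbb{R}^N$ evolve as

$$
\dot{x}_i = \sigma(z_i)\Big[-x_i + \frac{g}{\sqrt{PN}}\sum_j J_{ij}\,
  \phi(x_j)\Big],
\qquad
\tau_z \dot{z}_i = -z_i + \frac{1}{\sqrt{N}}\sum_j W_{ij}\, \phi(x_j),
$$

with $\phi = \tanh$, Hebbian couplings
$J = \sum_{\mu=1}^{P} \xi^\mu (\xi^\mu)^\top$ built from binary
$\pm 1$ patterns (the raw outer-product sum, so $J_{ii} = P$), iid standard
normal, asymmetric inter-layer couplings $W$, and the logistic gate

$$
\sigma(z) = \frac{1}{1 + e^{-\gamma z}}.
$$

The two prefactors $1/\sqrt{PN}$ and $1/\sqrt{N}$ are the unique scalings
that keep both drive terms $O(1)$ at fixed load $\alpha = P/N$ as
$N \to \infty$; with them, the condensed pattern contributes a drive
$(g/\sqrt{\alpha})\, \xi_i\, m$ and the $P-1$ non-condensed patterns an
$O(g)$ crosstalk noise. Two gate limits are special:

* $\gamma = 0$: $\sigma \equiv 1/2$ exactly. The modulator never influences
  the neurons and the dynamics is the classical network with time rescaled
  by $t \mapsto t/2$ (this equivalence is asserted to $10^{-10}$ in the test
  suite). `network_spec()` therefore does not even generate $W$ in this
  case unless asked to.
* $\gamma = \infty$: implemented as an *exact* step function with
  $\sigma(0) = 1/2$ (the pointwise limit of the logistic family), avoiding
  overflow from any "large finite $\gamma$" stand-in. Neurons split into a
  frozen population $F_t$ ($z_i < 0$) and an active one $A_t$, and the
  overlap decomposes exactly as $m = \rho_F m_F + \rho_A m_A$
  (`subpopulation_overlaps()`, asserted to $10^{-12}$ along whole
  trajectories).

The retrieval order parameter throughout is the Mattis overlap
$m^\mu = \frac{1}{N}\sum_i \xi_i^\mu \phi(x_i)$.

Default parameters follow the reference protocol: gain $g = 1.5$,
$\tau_z = 1$, $N = 1000$, Euler step $dt = 0.2$ (flow maps: $0.25$), horizon
$T = 2000$.

## Synthetic inputs

The package needs no external data; every input is generated:

* **Patterns**: iid uniform $\pm 1$ entries (`sample_patterns()`), with a
  Gaussian option for universality checks of the coupling spectrum.
* **Exactly orthogonal pairs** (`make_orthogonal_pair()`): the second
  pattern flips the sign of exactly $N/2$ randomly chosen components of the
  first, which forces $\xi^{1\top}\xi^2 = 0$ *exactly*, not just in
  expectation. The two-pattern experiments rely on this.
* **Cues**: $x(0) = c_1 \xi + \eta$ with $\eta$ standard normal and $c_1$
  root-found so the realized overlap matches the target $m_0$ to $10^{-3}$
  (`construct_cued_state()`); the two-pattern version solves a $2\times 2$
  damped Newton system with the exact Jacobian
  (`construct_two_pattern_init()`). $z(0)$ is standard normal.
* **Seeds**: one root seed is split into named child streams
  (`spawn_seeds()`), so e.g. a flow map can vary *only* the initial neural
  state while patterns, $W$ and $z(0)$ stay pinned.

```{r example, eval = TRUE}
spec <- network_spec(N = 300, alpha = 0.4, gamma = Inf, seed = 1)
init <- construct_cued_state(spec$patterns$patterns[1, ], 0.55, seed = 2)
traj <- run_trajectory(spec, init, sim_config(dt = 0.2, T = 400))
traj
```

## Numerical choices

* **Integrator**: explicit Euler, matching the reference protocol; the
  compiled loop (RcppArmadillo) applies the Hebbian drive in its low-rank
  form $\Xi^\top(\Xi\phi)$, never materialising the dense $N \times N$
  matrix, so a step costs $O(PN)$ instead of $O(N^2)$ for $P < N$.
  A readable R-level `euler_step()` is the tested reference for the
  compiled loop.
* **Early stopping**: optional (`convergence_tol` in `sim_config()`); runs
  halt when $\max_i |\dot x_i|$ falls below the tolerance. It is off by
  default so fixed-horizon runs are exactly reproducible, and enabled in
  sweeps, where it cuts the capacity protocol to minutes without changing
  endpoints (verified against full-horizon runs).
* **Self-couplings**: $J_{ii} = P$ is retained, as the outer-product
  definition dictates. We verified that removing the diagonal moves neither
  the transition ($\alpha_c$ unchanged within grid resolution) nor the
  qualitative overload behaviour.

### A caveat on the overload endpoint

Above capacity the ungated network loses the retrieved pattern after a
transient plateau, but the final state is a spin-glass-like attractor with a
*small residual overlap* of roughly $0.15$–$0.30$, not literally zero. This
residual is stationary, insensitive to $N$ (checked at $N = 1000$ and
$2000$) and to the diagonal convention, so it is genuine model physics; the
tests and any claims of "retrieval failure" in this documentation mean
"collapse to this residual scale", in contrast to the gated network, which
holds an order-one overlap ($\approx 0.55$–$0.6$) under the same protocol.

## Phase mapping and capacity

`estimate_critical_capacity()` sweeps the load at a strong cue
($m_0 = 0.95$) and reports the largest $\alpha$ whose mean steady-state
overlap still exceeds half the retrieval-plateau value. At the reference
scale ($N = 1000$, grid step $0.01$, 20 realizations) this gives
$\alpha_c \approx 0.13$–$0.14$ for the ungated network at $g = 1.5$. The
half-plateau threshold is deliberate: near the sharp transition the estimate
is insensitive to its exact value. `phase_diagram()` and `delta_map()`
produce the $(\alpha, m_0)$ retrieval maps and the gated-minus-ungated
difference map whose sign structure (slightly negative below $\alpha_c$,
strongly positive above) summarises what gating buys.

## Dynamical mean-field theory

For $N \to \infty$ the network maps onto a single-site process for a neuron
condensed on pattern $\xi = +1$ (legitimate by sign symmetry):

$$
\dot{x} = \sigma(z)\Big[-x + \tfrac{g}{\sqrt{\alpha}}\, m(t) + \eta_x(t)
 + \alpha \int_0^t G(t,u)\, \phi(x(u))\, du\Big], \qquad
\tau_z \dot{z} = -z + \eta_z(t),
$$

with self-consistent order parameters $m(t) = \langle \phi \rangle$,
$C_\phi(t,t') = \langle \phi\phi' \rangle$, the impulse response $R(t,t')$,
and colored noises with
$\mathrm{cov}(\eta_z) = C_\phi$ and
$\mathrm{cov}(\eta_x) = \alpha\, G C_\phi G^\top$. Because $W$ is
independent of the patterns, $z$ is autonomous — the gate does not respond
to perturbations of $x$, which is what makes frozen neurons genuinely
frozen.

Two kernels are provided, deliberately:

* `update_propagator()` integrates the propagator ODE
  $\partial_t G = \delta(t - t') + \int R\,G$ by forward Volterra stepping —
  the textbook object, validated against step-function and exponential
  oracles.
* `resolvent_kernel()` solves the algebraic resummation
  $G = \kappa(\delta + R \circ G)$, i.e. $G = \kappa (I - \kappa R)^{-1}$
  with $\kappa = g/\sqrt{\alpha}$ and the Dirac delta carried as $1/dt$ on
  the grid diagonal. This is the kernel the solver actually uses: it is the
  resummed crosstalk of the non-condensed patterns, and with it the
  retarded term $\alpha \int G \phi$ and the noise covariance
  $\alpha\, G C_\phi G^\top$ reproduce many-body averages quantitatively.

`solve_dmft()` iterates: sample colored noises (Cholesky with a PSD
safeguard), integrate the $M$-path ensemble (compiled), re-estimate
$m, C_\phi$, and estimate $R$ by rerunning the ensemble with an impulse of
area $\varepsilon$ injected into the gated drift at every grid time, under
common random numbers. Three implementation details matter:

* **Common random numbers across iterations**: the standard-normal matrices
  behind both noises are drawn once and re-multiplied by the current
  Cholesky factors, so the fixed-point residual is not drowned in fresh
  sampling noise.
* **Convergence floor**: the sup-norm change of $m$ cannot be resolved
  below the Monte-Carlo standard error $\max_t \mathrm{sd}(\phi_t)/\sqrt{M}$;
  the stopping rule floors the tolerance there.
* **Undamped acceptance**: when the test fires, the solver returns the
  current Monte-Carlo estimates rather than the damped mix, which would
  otherwise retain a lag bias of the order of the final residual (this bias
  is exactly what the $\alpha \to 0$ consistency check caught during
  development).

Validation: on matched reduced budgets ($T = 50$, $dt = 0.2$, $M = 2000$
paths vs. $N = 500$, 20 disorder realizations) the DMFT overlap tracks the
many-body mean within $\approx 0.05$ sup-norm for $\gamma \in \{0, 10,
\infty\}$, and for $\alpha \to 0$ the steady state reproduces the scalar
self-consistency root $m = \tanh(g m / \sqrt{\alpha})$ to $10^{-3}$.

## Time-asymptotic fixed points

Assuming the single-site dynamics reaches a fixed point, the active
population satisfies $x^* = b\,\phi(x^*) + \kappa m + s u$ with
$u \sim \mathcal{N}(0,1)$,

$$
b = \frac{g\sqrt{\alpha}}{1 - \kappa\chi}, \qquad
s^2 = \frac{g^2 q}{(1 - \kappa\chi)^2},
$$

where $\chi$ is the static susceptibility and $q$ the static self-overlap;
a frozen population enters through its imposed overlap $m_F$ and fraction
$\rho_F$ (frozen activations closed as $\phi_i = \xi_i m_F$, contributing
$\rho_F m_F^2$ to $q$ and nothing to $\chi$). `asymptotic_fixed_point()`
solves this closure by damped iteration with Gauss–Hermite quadrature and
warm-started root branches; `mss_band()` feeds it the frozen-population
extremes measured from binary-gate simulations at near-perfect and
near-zero cues ($m_0 = 0.99$ and $0.01$ as numerically realisable stand-ins
for perfect and empty cues — an exact $m(0) = 1$ cue is unreachable with a
noisy Gaussian background), producing the band of steady-state overlaps
that gating makes available at each load.

Three honest caveats. First, the statics retains metastable solutions the
dynamics cannot reach: above $\alpha_c$ the *ungated* closure still admits
a retrieval-like branch when iterated from a high initial guess, so the
static curve must be read jointly with the dynamics. Second, the frozen
population enters through its measured low-order moments ($m_F$, $\rho_F$,
$q_F$), a mean-field surrogate for the true frozen microstate. Third, the
fixed-point ansatz itself degrades at the *low-overlap* band edge: there
the active neurons keep wandering rather than settling, and the closure
overestimates their residual pattern alignment by about $0.1$ at
$\alpha = 0.4$. The retrieval-side edge — the quantity of interest — is
accurate.

## Flow maps and continuous multistability

`flow_map()` integrates a grid of initial overlap pairs $(m_1(0), m_2(0))$
toward an orthogonal pattern pair, holding *all* quenched randomness fixed
(patterns, $W$, $z(0)$) and varying only the cue. Endpoints are merged by
single-linkage clustering at radius $0.1$ in overlap space
(`cluster_attractors()`): two endpoints belong to the same attractor if
they are chainwise closer than the merge radius, which is far above the
$1/\sqrt{N}$ endpoint jitter yet far below the inter-pattern distance.

The ungated network yields exactly four clusters, at $(\pm 1, 0)$ and
$(0, \pm 1)$. The binary-gated network, from the identical experiment,
yields many more: frozen neurons remember the initial condition, so the
final state varies continuously with the cue — a continuum of fixed points
sampled at grid resolution. The same mechanism makes the gated endpoint of
the $(0.4, 0)$ and $(0.6, 0.3)$ cues differ, while the ungated ones
coincide.

## Limitations

* Explicit Euler at $dt = 0.2$ matches the reference protocol but is first
  order; conclusions were spot-checked at smaller $dt$, not systematically
  extrapolated to $dt \to 0$.
* The DMFT response estimate is $O(L^2 M_{\mathrm{resp}})$ per iteration
  and dominates the solver cost; budgets beyond $T \approx 100$, or
  two-time quantities deep in the aging regime, are out of intended scope.
* The asymptotic closure treats the frozen fraction as an *input* measured
  from simulation; the package does not predict $\rho_F$ from first
  principles.
* Finite-$N$ simulations at $N \le 1000$ carry $O(N^{-1/2})$ fluctuations
  that the stochastic tests absorb with explicit tolerances; single runs
  near the transition can straddle it.
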