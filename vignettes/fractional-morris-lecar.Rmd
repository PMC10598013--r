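---
title: "Discrete fractional-order Morris-Lecar dynamics: models, stability theory, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete fractional-order Morris-Lecar dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracml)
```

## The models

The Morris-Lecar neuron is a two-variable conductance-based membrane
model: the membrane potential $u_1$ carries a fast calcium current, a
potassium current gated by $u_2 \in (0,1)$, and a leak,

$$C\,\dot u_1 = I_m - \bar I(u_1, u_2), \qquad
  \dot u_2 = \varphi\,\ell(u_1)\,\big(w_\infty(u_1) - u_2\big),$$

with
$\bar I(u_1,u_2) = W_{Ca}\, r_\infty(u_1)\,(u_1 - d) + W_K u_2 (u_1 - F_K)
 + W_L (u_1 - F_L)$ and the tanh/cosh gating curves
$r_\infty, w_\infty, \ell$ (`gating_functions()`).  Two parameter
groups are registered (`ml_group()`): the class-I excitable set
(group `"i"`, firing onset through a saddle-node, calcium driving force
$d = F_{Ca}$, $C = 20$) and the class-II set (group `"ii"`, onset
through a Hopf bifurcation; overrides $W_{Ca}=4.4$, $F_3=2$, $F_4=30$,
$\varphi=0.04$).

The slow-fast three-variable extension (dimensionless, $C = 1$,
$d = 1$) adds a slow recovery variable $u_3$ with time-scale ratio
$\theta \in (0,1)$ that modulates both the applied current,
$I_m(u_3) = 0.08 - 0.03\,u_3$, and the potassium half-activation,
$F_3(u_3) = 0.08 - u_3$:

$$\dot u_3 = \theta\,(u_1 + F_0).$$

Three dimensionless groups `"i"`, `"ii"`, `"iii"` are registered.  One
printed rendering of the slow-fast model writes the gating-rate cosh
with the fixed constant $F_2$ instead of $F_3(u_3)$; we treat this as a
typographical slip because it contradicts the model's own steady-state
gating, but the variant is selectable via
`ml_params_3d(ell_arg = "F2")`.

## The discrete fractional solver

Replacing the time derivative by the Caputo delta difference of order
$\vartheta \in (0,1]$ yields a map with full memory: the explicit
solution of the initial value problem is

$$x(n) = x(0) + \frac{h^\vartheta}{\Gamma(\vartheta)}
  \sum_{\lambda=0}^{n-1}
  \frac{\Gamma(n-\lambda-1+\vartheta)}{\Gamma(n-\lambda)}\,
  f\big(x(\lambda)\big),$$

implemented in `solve_commensurate()` /
`solve_incommensurate()` (per-component orders).  The
$\Gamma$-ratio weights are the falling-factorial kernel
$c_j = \Gamma(j+\vartheta)/(\Gamma(\vartheta)\Gamma(j+1))$, computed by
the multiplicative recurrence $c_j = c_{j-1}(j-1+\vartheta)/j$
(`kernel_weights()`); direct $\Gamma$ quotients overflow beyond
argument $\approx 170$ and are never formed.  At $\vartheta = 1$ every
weight is 1 and the scheme is exactly forward Euler; for
$\vartheta < 1$ the weights decay monotonically and sum to
$\Gamma(n+\vartheta)/(\Gamma(\vartheta+1)\Gamma(n))$ (a telescoping
identity used as a test oracle).

Numerical choices:

* **Step size.** The published scheme has no explicit step, i.e.
  $h = 1$; with `step = 1` the solver reproduces it verbatim, and that
  is the default for the dimensional 2D model.  The dimensionless
  slow-fast model is stiff at $h = 1$ (the gating slope $1/F_4$
  reaches 25 and the cosh rate grows exponentially), and diverges
  immediately; 3D fixtures therefore default to $h = 0.1$, which is
  documented wherever used.  The source text never states the step or
  horizon behind its figures, so only qualitative regime outcomes are
  reproducible.
* **Memory.** Full memory (quadratic cost) by default; an optional
  short-memory truncation `memory_length = L` keeps the $L$ most
  recent terms.  Network runs default to $L = 500$: the truncation
  error decreases monotonically as $L$ grows (a tested invariant) and
  the cost drops from $O(NT^2)$ to $O(NTL)$.
* **Divergence.** A non-finite state or right-hand side aborts with
  the step index rather than clipping; silent clipping would corrupt
  bifurcation sweeps.
* **Capacitance.** $C$ divides only the membrane equation, inside
  `rhs_2d()`/`rhs_3d()`, so the solver is model-agnostic.

## Equilibria and fractional stability

For the 2D model the steady-state current
$I_\infty(u_1) = \bar I(u_1, w_\infty(u_1))$ has two critical points
$u_{1,\max} < u_{1,\min}$ splitting the line into three monotone
branches; `find_equilibria_2d()` brackets roots of
$I_\infty(u_1) = I_m$ on each branch (1, 2 or 3 equilibria depending on
whether $I_m$ lies below, inside or above the window
$[I_{\min}, I_{\max}]$).  Middle-branch equilibria have negative
Jacobian determinant and are saddles at every order.  For the slow-fast
model the slow equation pins $u_1^* = -F_0$ and $u_3^*$ is found by
monotone bisection (`find_equilibrium_3d()`).

Jacobians are differentiated analytically from the right-hand sides
(`ml_jacobian()`), not transcribed from the printed matrices, whose
third row and two cubic coefficients contain typographical errors (the
printed third row "$u_1\;0\;0$" must be $(\theta, 0, 0)$, since
$\partial_{u_1}\,\theta(u_1+F_0) = \theta$).  The printed forms are
exercised only as cross-checks in tests.

Stability at order $\vartheta$ follows the Matignon criterion: an
equilibrium is asymptotically stable iff every eigenvalue satisfies
$|\arg\lambda| > \vartheta\pi/2$ (`classify_equilibrium()`, with saddle
ranks counting the violating eigenvalues).  For a planar equilibrium
with trace $\chi \ge 0$, determinant $\zeta > 0$, the threshold order is

$$\vartheta^* = \tfrac{2}{\pi}\arccos\!\big(\chi / 2\sqrt{\zeta}\big),$$

(`hopf_threshold_2d()`); below $\vartheta^*$ the equilibrium is stable,
above it a Hopf-type oscillation appears.  In three dimensions the
threshold is the Matignon boundary order $(2/\pi)\min|\arg\lambda|$
(`critical_order_3d()`).

Two discrete-map criteria complement the Matignon test:

* `commensurate_stability_test()` checks the modulus-and-angle region
  of the linearized commensurate map.  The published statement carries
  a leading factor 2 on the modulus bound,
  $|\lambda| \le 2\,(2\cos\frac{|\arg\lambda|-\pi}{2-\vartheta})^\vartheta$.
  Direct simulation of the scalar map contradicts the factor: at
  $\vartheta = 0.75$ the decay/divergence flip sits between
  $|\lambda| = 1.6$ and $1.75$, i.e. at $2^{0.75} \approx 1.68$,
  matching the bound *without* the factor (and similarly along other
  rays).  The package therefore uses
  $|\lambda| \le (2\cos\frac{|\arg\lambda|-\pi}{2-\vartheta})^\vartheta$
  by default and exposes the printed variant behind
  `printed_bound = TRUE`.  This correction is what lets the
  prediction-versus-simulation panel reach its required agreement.
* `incommensurate_stability_test()` handles rational per-component
  orders $\vartheta_\iota = w_\iota/\sigma_\iota$ with least common
  denominator $H$: the determinant
  $\det(\mathrm{diag}(\rho^{H\vartheta_1},\dots) - (1-\rho^H)J)$ is
  expanded symbolically into a univariate polynomial (cofactor
  expansion with polynomial arithmetic) and its roots — obtained as
  companion-matrix eigenvalues — must all avoid the region $K^{1/H}$.
  Irrational orders are rejected with instructions to rationalize;
  the polynomial degree is capped (default 600).

## What the worked examples do and do not reproduce

The published worked-example numbers were re-derived from the published
parameter groups, with mixed results, and the package reports what it
computes rather than what is printed:

* The class-II Hopf threshold attached to the phase-portrait study
  (printed 0.89342, with equilibrium $u_1^* = 6.23101$) is not
  consistent with any printed applied current: at $I_m = 100$ the
  unique equilibrium sits at $u_1^* = -23.09$ with
  $\vartheta^* = 0.85454$ (the printed threshold would require
  $I_m \approx 98.5$, the printed potential $I_m \approx 196$).  A
  simulated order sweep at $I_m = 100$ collapses the oscillation
  between $\vartheta = 0.83$ and $0.84$, bracketing the computed
  threshold and confirming the implementation over the print.
* The two bifurcation-panel thresholds (printed 0.83241 and 0.96720)
  have an ambiguous (group, current) pairing.  `stability_report()`
  therefore carries a *pairing scan*: for each published anchor it
  records the scanned combination whose computed threshold lies
  closest.  The scan lands on the class-I set at $I_m = 50$
  (computed 0.81547) and $I_m = 90$ (computed 0.97647); the class-II
  set is stable for all orders at the panel currents, so it cannot
  host either threshold.
* The slow-fast group-iii critical order (printed 0.7391) presumes a
  complex eigenvalue pair with positive real part.  With the printed
  constants the Jacobian spectrum is $\{1.319, 0.219, -0.006\}$ —
  all real, cubic discriminant $+0.107$ — so no such pair exists and
  the faithful Matignon boundary order is 0 (a positive real
  eigenvalue is unstable at every order).  The printed premise would
  hold only for $\varphi \approx 0.295$, nine times the printed
  0.033; no single-token correction restores it, so the package keeps
  the printed constants and the honest value.

## Regime classification and sweeps

`classify_regime()` labels a post-transient trace as quiescent, tonic,
bursting or mixed-mode (MMO) from deterministic rules; the source text
defines none of the required cut-offs, so the defaults are package
choices, all configurable: spike threshold = midpoint of the
post-transient range; refractory = 3 samples; quiescence = amplitude
below 1% of a reference oscillation amplitude (absolute 0.01 when no
reference is given); burst detection = largest inter-spike interval
exceeding 3x the median; MMO = coexisting small (< 0.4 of the largest)
and large peaks.  The transient discard defaults to 50% of the run
because fractional memory makes transients long.  `bifurcation_sweep()`
records all post-transient voltage extrema over a grid of orders or
currents; `sweep_flip_point()` reads off where the extremum band
collapses, which brackets the analytic threshold within one grid step
on the tested fixtures (for a subcritical Hopf the large-amplitude
cycle survives slightly below the threshold, so the bracket is asserted
with one-grid-step slack on both sides).

## Coupled populations and the reduced cluster model

`build_er_network()` draws an Erdős–Rényi graph with edge probability
$p = \langle\eta\rangle/(N-1)$; nodes left isolated are rewired to one
random neighbour because the electrical coupling normalizes by degree.
`simulate_network()` integrates $N$ two-variable neurons, each at its
own fractional order (first $r$ nodes at $\vartheta$, last $s$ at
$\Phi$; `assign_orders()`), coupled diffusively on the membrane
potential only.  `sync_error()` quantifies synchronization as the mean
absolute deviation from the population mean voltage, optionally per
cluster.  On the registered fixture (N = 100, mean degree 7,
$r/s = 65/35$, orders 1 and 0.8) the time-averaged error decreases
monotonically with the coupling strength across
$W_\epsilon \in \{0.0005, 0.05, 1\}$.

`simulate_reduced()` integrates the two- or three-cluster mean-field
reduction: each cluster is one slow-fast three-variable neuron at its
own order, receiving coupling scaled by the opposing cluster's
population fraction ($\wp_\epsilon = s/N$, $\wp_0 = r/N$,
$\wp_1 = x/N$).  Choices made where the source is silent: the third
cluster's size is undefined, so three-order runs default to an
equal-thirds split (configurable); the full network is two-variable
per node while the reduction is three-variable per cluster, and both
are kept as printed; the reduced model accepts either the slow-variable
current law $I_m(u_3)$ (default, consistent with the 3D groups) or a
constant current (for saddle-homoclinic sweeps over
$I_m \in [23, 70]$).

## What a green test establishes — and what it does not

The test suite validates the solver against independent brute-force
double-sum oracles (to $10^{-12}$ at $n \le 50$), the kernel against
log-$\Gamma$ evaluation, the Jacobians against central differences, the
stability verdicts against long-run simulation on random linear panels,
and the regime machinery against synthetic traces with known labels.
Because stable fractional maps decay only algebraically
($\sim n^{-\vartheta}$) and eigenvalues of tiny modulus barely move on
any affordable horizon, the simulation oracle judges *growth versus
non-growth* rather than decay to a small absolute level.  None of this
establishes quantitative agreement with the published figures: their
step size, horizon and initial data are unstated, so figure-level
claims are tested only at the level of regime labels and orderings.

## Known limitations

Full-memory cost is quadratic in the horizon; there is no adaptive
stepping and no continuous-time (predictor-corrector) solver; the
incommensurate criterion requires rational orders with a moderate
common denominator; spike/burst thresholds are heuristics and need
re-tuning for models far from the registered groups.
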