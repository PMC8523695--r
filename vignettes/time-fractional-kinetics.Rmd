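---
title: "Time-fractional kinetics on free-energy landscapes: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-fractional kinetics on free-energy landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfkinetics)
```

## The model

Many biological relaxation processes are not Markovian: conformational
disorder, entropic restrictions or structural deformation (for instance a
mutated ion channel) produce waiting times with a diverging mean, and the
relaxation toward equilibrium slows from exponential to a power law. The
standard description starts from a generalized master equation whose memory
kernel factorizes into a spatial transition kernel $W(x, x')$ and a
power-law time kernel

$$\Pi(t) = \frac{1}{\Gamma(\gamma)}\left(\frac{t}{\tau}\right)^{\gamma-1},
\qquad 0 < \gamma < 1,$$

the signature of a long-tailed waiting-time distribution. Pulling the
memory into a fractional operator turns the master equation into a
*time-fractional* equation, and the relaxation of a state variable $x$ on
a free-energy landscape $F(x)$ obeys

$$D^{\gamma}_t\, x(t) + \Gamma \beta\, \frac{\partial F}{\partial x} = 0,$$

where $\beta$ is the inverse temperature and $\Gamma$ a kinetic
coefficient inherited from the width $\Delta$ of the spatial jump kernel,
$\Gamma = (2\pi\Delta)^{m/2}\Delta$ in $m$ dimensions
(`gamma_from_delta()`). On a harmonic landscape the solution is the
Mittag-Leffler relaxation $x(t) = x_0 E_\gamma(-\lambda t^\gamma)$ with
$\lambda = \Gamma\beta\kappa$: stretched-exponential at short times,
algebraic ($\sim t^{-\gamma}$) at long times, and exactly exponential at
$\gamma = 1$.

The package implements this framework as four layers:

* `mittag_leffler()` / `ml_relaxation()` — the solution family;
* `rl_derivative()`, `caputo_derivative()`, `gl_weights()`,
  `memory_kernel()` — the discrete fractional operators;
* `solve_fractional_kinetic()` — the kinetic equation on arbitrary
  one-dimensional landscapes, plus the two-state voltage-gated channel
  application (`simulate_channel()` and friends);
* `build_rate_matrix()` / `propagate_gme()` — the lattice
  time-fractional master equation with the free-energy transition kernel.

## Riemann–Liouville versus Caputo

The fractional operator in the model equations is the Riemann–Liouville
derivative with lower limit $0$. For trajectories that start at a nonzero
state (an open probability of 0.1, say), a Riemann–Liouville
initial-value problem requires initial data for a fractional integral,
which has no direct physical reading. We therefore integrate all
initial-value problems in the **Caputo** sense — the Riemann–Liouville
operator applied to the increment $x(t) - x(0)$ — which coincides with
Riemann–Liouville for $x(0) = 0$ and is the standard well-posed reading
for physical initial conditions. Both operators are exposed in the
package, so the residual of a computed trajectory can be verified
directly against the Riemann–Liouville form when $x_0 = 0$.

Both discrete operators use the Grünwald–Letnikov convolution with the
signed binomial weights $w_k = (-1)^k\binom{\gamma}{k}$ on uniform grids
with $t_0 = 0$ (the lower limit of the defining integral). Full memory is
kept; no short-memory truncation is applied, because the grids used at
desk scale are small enough that the $O(n^2)$ convolution cost is
irrelevant. The scheme is first-order in $dt$ in the grid interior; close
to $t = 0$ the error of the power-function benchmarks carries the usual
boundary layer of order $dt^{\,1-\gamma}$, which is why convergence tests
measure on $t \gtrsim 0.5$.

## Evaluating the Mittag-Leffler function

No installed package evaluates $E_{\alpha,\beta}$, and the function is
the backbone of every analytic check here, so the package carries its own
evaluator for real arguments with three routes:

1. **Taylor series** whenever it is numerically safe. The alternating
   series for $z < 0$ loses roughly $|z|^{1/\alpha}/\ln 10$ digits to
   cancellation, so the series is used only while
   $|z|^{1/\alpha} \le$ `z_switch` (default 5, bounding the amplification
   by $e^5$), and always for $z > 0$ where all terms are positive.
2. **Asymptotic expansion**
   $E_{\alpha,\beta}(z)\approx-\sum_{k\ge1} z^{-k}/\Gamma(\beta-\alpha k)$
   for $z \le -$`asymp_switch` (default 30), truncated optimally (at the
   smallest term); terms whose Gamma argument hits a pole are exact
   zeros and are skipped rather than treated as convergence.
3. **Integral representation** (Gorenflo–Loutchko–Luchko) for the
   remaining window of moderately negative arguments, after a
   substitution that removes the endpoint singularity of the kernel so
   that adaptive quadrature converges at the requested tolerance. For
   $\beta \ge 1 + \alpha$ the second parameter is first reduced with the
   standard recursion $E_{\alpha,\beta}(z) = (E_{\alpha,\beta-\alpha}(z)
   - 1/\Gamma(\beta-\alpha))/z$.

The exactly known orders $\alpha = 1$ (exponential) and $\alpha = 2$
(cos/cosh) dispatch to their closed forms, as production implementations
generally do. Default tolerance is $10^{-10}$: the solver oracles need
$10^{-6}$ and the headroom is cheap. Only real arguments are supported —
the kinetic equation needs real negative arguments — and the two routes
that overlap (asymptotic and integral) agree to better than $10^{-9}$
where their ranges meet, which the test suite checks explicitly. Both the
one- and two-parameter functions are provided; the relaxation law uses
the one-parameter form ($\beta = 1$), which is the case the kinetic
equation's solution actually requires.

## The fractional initial-value solver

`solve_fractional_kinetic()` integrates $D^\gamma x = -\Gamma\beta F'(x)$
with the fractional Adams–Bashforth–Moulton predictor–corrector
(Diethelm–Ford–Freed weights, one corrector pass). At $\gamma = 1$ the
weights collapse to the classical trapezoidal predictor–corrector, and
the solver is cross-checked against an adaptive classical integrator in
the tests. An implicit Grünwald–Letnikov scheme (`scheme = "gl_implicit"`,
one scalar root solve per step) is available for stiff landscapes; both
schemes are first-order, so they agree to their $O(dt)$ constants.

**Domain exits.** Landscapes with boundary singularities — the channel
free energy has entropy terms whose derivative diverges at 0 and 1 — can
be overshot by an explicit predictor. States are clamped to the domain
interior at a distance of $10^{-12}$ of the domain width, the event is
counted in `meta$n_clamped` and a warning is raised, because a single
overshoot would otherwise poison the entire convolution history. The
predictor (an internal quantity) is kept at a slightly wider margin,
$10^{-6}$ of the width, so that near-boundary evaluations of logarithmic
drifts do not inject $\mathcal{O}(\ln 10^{12})$ spikes into the corrector.
On the default channel grids ($dt \le 10^{-2}$, composite rate of order
one) no clamping occurs at all, which the tests assert.

**Units.** Time is dimensionless: the memory kernel's $\tau$ is set to 1
by convention, and the single composite rate constant the user controls
is $\Gamma\beta$ (times the landscape curvature). `memory_kernel_params`
retains $\tau$ for kernel evaluation only. Note the symbol collision in
the field's notation: $\Gamma(\cdot)$ the Gamma function versus $\Gamma$
the kinetic coefficient. The code names them `gamma()` and `Gamma_coef`.

**Stationary states.** `stationary_state()` brackets and bisects
$F'(x) = 0$ near a user-supplied guess and polishes with Newton steps to
$|F'| < 10^{-10}$. Multiple minima require a guess per basin — no global
search is attempted. The root is independent of $\gamma$: the memory
kernel changes the approach to equilibrium, never the target, and the
tests verify this across modules.

## The voltage-gated channel application

The two-state channel population (closed energy $\varepsilon_1$, open
energy $\varepsilon_2$, $z$ gating charges of magnitude $e_0$, membrane
voltage $V$) has Helmholtz free energy

$$F(x) = n[(1-x)\varepsilon_1 + x\varepsilon_2] + z e_0 n (1-x) V
 - \beta^{-1}\ln\Omega(x), \qquad
 \ln\Omega(x) = -n[(1-x)\ln(1-x) + x\ln x],$$

in the open fraction $x = n_2/n$. Its stationarity condition is the
Boltzmann sigmoid

$$P_0 = \left\{1 + e^{-\beta z e_0 (V - V_0)}\right\}^{-1},
\qquad V_0 = -\frac{\varepsilon_1 - \varepsilon_2}{z e_0},$$

with exactly half the channels open at the threshold voltage $V_0$. The
time-fractional relaxation of the open probability is

$$D^\gamma_t P_0 = \frac{\Gamma}{n}\left\{\beta z e_0 (V - V_0)
 - \ln\frac{P_0}{1-P_0}\right\}.$$

One structural point deserves a note. Applying the kinetic equation
directly to $x = P_0$ with the free energy above would give a drift
proportional to $\Gamma n$, while the open-probability equation carries
$\Gamma/n$. The two are reconciled if the kinetic variable is the open
*count* $n_2 = n P_0$ rather than the fraction: then
$D^\gamma P_0 = (1/n) D^\gamma n_2$ produces exactly the $\Gamma/n$
scaling. The package implements the open-probability equation as printed
above — its drift is the free-energy gradient flow
$-(\Gamma/n^2)\beta F'(p)$, an identity the tests verify to $10^{-8}$ —
and the CLI exposes the composite rate $\Gamma/n$ directly as `--rate`.

Defaults are reduced units ($e_0 = 1$, energies in units of
$\beta^{-1}$); physical units are a matter of passing $e_0$ in coulombs,
$\beta = 1/k_BT$ and $V$ in volts. The initial condition for a deformed,
far-from-equilibrium population defaults to $p_0 = 0.1$ (mostly closed).
Only constant voltage is treated.

## The lattice master equation

`build_rate_matrix()` discretizes the Langer/Glauber-form transition
kernel

$$W(x \leftarrow x') = \exp\!\left[-\frac{(x-x')^2}{\Delta}\right]
\exp\!\left\{-\frac{\beta}{2}\left[F(x) - F(x')\right]\right\}$$

on a uniform lattice. Three conventions are fixed here, each with a
reason:

* **Direction and diagonal.** `W[i, j]` is the rate from $j$ to $i$
  (column-generator layout, so propagation is a plain matrix–vector
  product), and the diagonal is minus the column sum. The kernel itself
  only defines the jump rates; probability conservation forces the
  gain–loss diagonal, and with it conservation of total mass is exact in
  the scheme, not approximate.
* **Energy-difference factor.** The half-Boltzmann factor
  $e^{-\beta[F(x)-F(x')]/2}$ gives the exact pairwise identity
  $W(x\leftarrow x')/W(x'\leftarrow x) = e^{-\beta[F(x)-F(x')]}$, i.e.
  detailed balance with respect to $e^{-\beta F}$, which in turn makes
  the stationary distribution the lattice Boltzmann measure regardless
  of $\gamma$.
* **Cutoff.** Off-diagonals are kept while the Gaussian factor exceeds
  $10^{-12}$ (overridable); boundary columns simply have fewer neighbors,
  which acts as a reflecting boundary by truncation.

`propagate_gme()` advances $\partial_t P = D^{1-\gamma}[W P]$ with the
explicit Grünwald–Letnikov convolution over the full history of $WP$:
$P^{m+1} = P^m + dt^{\gamma} \sum_{k\le m} w^{(1-\gamma)}_k (WP)^{m-k}$.
At $\gamma = 1$ this is the forward-Euler master equation step, checked
against the matrix exponential of the generator. Explicit stepping can
blow up, so a guard warns when $dt^{\gamma}\max_j |W_{jj}| > 0.5$ and any
excursion $|P| > 2$ aborts with the estimated maximal stable step in the
message — a silent instability becomes a diagnostic. An eigendecomposition
route is deliberately *not* used for propagation, so that the memory
convolution itself is what the equivalence tests exercise.

## Problem sizes and tolerances used in validation

All validation is analytic-oracle or property-based; the sizes were
chosen so each check isolates the claimed effect.

* Mittag-Leffler values are compared to a frozen high-precision series
  oracle at $10^{-10}$ relative error for $|z| \le 10$ and into the
  asymptotic range; the $\alpha = 1$ route reproduces $\exp$ on
  $[-20, 5]$ at $10^{-10}$.
* The harmonic-well solver runs $dt = 10^{-3}$ over $t \in [0, 10]$:
  observed agreement with the Mittag-Leffler law is a few parts in
  $10^4$ at $\gamma = 0.5$ (tolerance $10^{-2}$), and $6\times10^{-8}$
  against the classical solution at $\gamma = 1$ (tolerance $10^{-6}$).
* Long-horizon attraction tests use horizons with
  $\lambda t^{\gamma} \ge 100$: the Mittag-Leffler tail is algebraic,
  $\sim (\lambda t^\gamma \Gamma(1-\gamma))^{-1}$, so reaching a $10^{-2}$
  neighborhood of equilibrium from a unit-scale displacement genuinely
  requires two orders of magnitude in $\lambda t^\gamma$ — a physical
  statement about subdiffusive kinetics, not a numerical artifact.
* The Boltzmann-stationarity check runs a 21-point harmonic lattice
  ($\Delta = 4\,dx^2$, chosen for a spectral gap that makes the slow
  algebraic transient affordable) to total-variation distance $10^{-3}$
  for $\gamma \in \{0.6, 1\}$.
* The anomalous-spreading check fits the variance growth of a delta
  field on an 81-point flat lattice over $t \in [10, 1000]$ (two decades)
  and recovers $\gamma = 0.5$ within $\pm 0.1$; the fit window starts
  late enough that lattice discreteness has washed out and ends before
  boundary effects bite.

## What the synthetic sweeps emulate — and what they do not

`fixture_sweep()` generates seeded parameter sets spanning
$\gamma \in [0.3, 1]$, composite rates in $[0.1, 10]$ (log-uniform),
voltage offsets $\beta z e_0 (V - V_0) \in [-5, 5]$ and the built-in
landscapes. These are plausible ranges for reduced-unit gating studies,
and they exercise the solver across stiffness regimes. They do **not**
emulate real patch-clamp data: there is no measurement noise, no
multi-state (Hodgkin–Huxley-type) gating, no inactivation, no
single-channel stochasticity, and no time-dependent voltage protocol.
Passing tests therefore demonstrate the correctness of the numerics and
the internal consistency of the thermodynamic model — not that any
particular recorded channel is described by a given $\gamma$. Fitting
$\gamma$ to experiments is explicitly out of scope.

## Known limitations

* State is scalar (one-dimensional); the $m$-dimensional structure
  enters only through the coefficient $\Gamma$.
* The explicit lattice scheme's stability bound $dt^\gamma
  \max|W_{jj}| \lesssim 0.5$ forces small steps on stiff lattices; the
  implicit trajectory scheme helps for the scalar solver, but no implicit
  lattice propagator is provided.
* Mittag-Leffler support is real-line only, and for $1 < \alpha < 2$
  only arguments within the safe Taylor range are accepted (large
  negative arguments in that order range raise an evaluation error
  rather than returning degraded values).
* Full-memory convolutions make cost quadratic in step count; at the
  desk scales used here (up to a few times $10^4$ steps) this is
  seconds, not a constraint.
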