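---
title: "Characterising intrinsic noise with the linear noise approximation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterising intrinsic noise with the linear noise approximation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnakit)
```

## The model and its assumptions

A single-compartment biochemical network of $\hat K$ species and $M$
irreversible reactions is described stochastically by the chemical master
equation: the state is the vector of particle numbers $n$, and reaction
$\mu$ fires with propensity $T_\mu(n)$ and changes the state by the
stoichiometric column $\nu_{\cdot\mu} = p_{\cdot\mu} - r_{\cdot\mu}$.
`lnakit` works with number densities $x = n/\Omega$, where the system size
$\Omega$ converts densities to particle numbers, and identifies the
propensities with the macroscopic kinetic laws in density form,
$T_\mu(n) = \Omega f_\mu(n/\Omega)$. For bimolecular mass action this
neglects the $n(n-1)$ combinatorial correction, an $O(1/\Omega)$ effect
below the resolution of the approximation that follows.

The van Kampen system-size expansion writes $n/\Omega = x + \xi/\sqrt\Omega$
about the macroscopic trajectory and keeps the leading fluctuation order.
At an asymptotically stable fixed point $x^*$ of the rate equations
$\dot x_i = \sum_\mu \nu_{i\mu} f_\mu(x)$, the fluctuations $\xi$ become a
stationary Gaussian (Ornstein-Uhlenbeck) process governed by two constant
matrices evaluated at $x^*$:

$$A_{ij} = \sum_\mu \nu_{i\mu}\,\partial f_\mu/\partial x_j,
\qquad
B_{ij} = \sum_\mu \nu_{i\mu}\nu_{j\mu} f_\mu(x^*).$$

The stationary particle-number covariance $C$ solves the Lyapunov equation

$$A C + C A^{\mathsf T} + \Omega B = 0 .$$

This *linear noise approximation* (LNA) is accurate when fluctuations are
small relative to the means and the state is not pressed against a
boundary (a species near zero particles has visibly non-Gaussian,
"squashed" statistics). Everything the package computes — variances,
covariances, correlation coefficients, coefficients of variation, Fano
factors — derives from $C$ and the steady-state means $\Omega x^*$.

## Conserved moieties and the reduced system

Closed sub-pools (e.g. free + complexed enzyme, or the total of a kinase's
phosphoforms) make rows of the stoichiometry matrix linearly dependent; the
drift matrix of the full system is then singular and the Lyapunov solution
non-unique. `reduce_network()` therefore eliminates the dependencies first:

* Left null vectors $g$ of the stoichiometry matrix ($g^{\mathsf T} N = 0$)
  are found by fraction-free integer elimination, so each conservation
  relation holds *exactly*, not to a floating tolerance. Species are
  scanned in declared order and retained as independent while their row
  increases the rank; later, dependent species are expressed as
  $n_j = c_j + \sum_k \alpha_{jk} n_k$ with constants taken from the
  network's initial state (and recomputed whenever initial densities
  change). Any valid choice of dependent species yields the same full
  covariance; the test suite asserts this by permuting species
  declarations.
* The link matrix $L$ (identity rows for independent species, $\alpha$
  rows for dependent ones) recovers the full covariance as
  $C = L\,C^{\mathrm{red}}\,L^{\mathsf T}$. A conserved total then has
  exactly zero variance — a structural property the acceptance tests
  check on the enzyme moiety of the Michaelis-Menten model.

## Numerical choices

**Steady state.** A damped Newton iteration (analytic Jacobian, steps
halved until all densities including reconstructed dependents stay
non-negative) runs from the supplied start. On failure the stiff ODEs are
relaxed with `deSolve::lsoda` over increasing horizons ($10^3$ to $10^6$
time units), re-attempting Newton from each endpoint. Convergence requires
the residual $\max_i|\dot x_i|$ to fall below $10^{-9}$ relative to the
largest reaction flux. A remaining failure is a distinguishable
"no steady state found" condition that the closed loop converts into an
infeasible evaluation rather than an exception.

**Stability.** The Lyapunov solution is unique only for asymptotically
stable $A$; `solve_lyapunov()` rejects matrices with
$\max\mathrm{Re}\,\lambda > -10^{-10}\,\max|A|$. Because the approximation
degrades near a bifurcation, `lna()` additionally warns when the dominant
eigenvalue is within a fraction `stability_margin` (default $10^{-3}$) of
the spectral radius of zero. `find_instability_point()` bisects the sign
change of $\max\mathrm{Re}\,\lambda$ along one parameter to a tolerance of
$10^{-4}$ by default and labels the crossing `"hopf"` when the crossing
pair is complex, rather than assuming it.

**Lyapunov solve.** The equation is solved by the Bartels-Stewart method:
`Matrix::Schur()` brings $A$ to real Schur form and the transformed
equation is solved by back-substitution over the $1\times1/2\times2$
diagonal blocks. The $O(K^6)$ Kronecker-vectorised solve
$(I\otimes A + A\otimes I)\,\mathrm{vec}(C) = -\Omega\,\mathrm{vec}(B)$ is
retained in the test suite as an independent oracle only; the two routes
agree to better than $10^{-8}$ relative error on batteries of random
stable systems.

**Differentiation.** Rate laws are stored as a restricted arithmetic
expression tree (numbers, symbols, `+ - * / ^`), differentiated
analytically via `stats::D` and chained through the conservation relations
($A = N_{\mathrm{red}}\,\partial f/\partial x\, L$). The suite
cross-checks against central finite differences. Analytic derivatives
avoid step-size pathologies precisely where they matter, close to
bifurcations.

## The closed loop: scans, objectives, optimisers

`evaluate_objective()` performs one iteration of the closed loop: set
parameters, find the steady state, run the LNA, evaluate a statistic, and
check steady-state particle-number constraints. Failures of any step are
encoded as a sentinel worst value ($-\infty$ when maximising, $+\infty$
when minimising) with a reason string — never an exception — so scans and
optimisers traverse unstable or steady-state-free regions gracefully. A
sentinel rather than a finite penalty avoids tuning a penalty magnitude
against the objective scale. Constraints may be absolute particle numbers
or fractions of reference means ("within 50%–200% of the original
value"); references are captured once from the unmodified model.

Minimising a coefficient of variation invites degenerate optima in which
the mean is driven towards zero; relative statistics therefore error (and
the evaluation becomes infeasible) when a mean falls below $10^{-8}$
particles, and particle-number constraints are the recommended guard.

Two stochastic global optimisers are provided, both generation-synchronous
and bit-reproducible under a seed:

* `particle_swarm()`: global-best PSO with the standard constriction
  parameters (inertia 0.729, cognitive/social weights 1.49445), velocities
  clamped to half the box width, positions clipped to the bounds. Default
  swarm size 50.
* `evolutionary_programming()`: classical self-adaptive (meta-EP) Gaussian
  mutation with log-normal step-size adaptation and round-robin tournament
  survival (q = 10% of the combined population).

Both terminate on an iteration cap or on stalling (no relative improvement
above $10^{-6}$ over a window). These settings are documented package
choices; the algorithms' families, not their constants, are what the
method requires.

## The stochastic simulation oracle

`gillespie_direct()` implements the exact Direct Method (exponential
waiting times at the total propensity; reaction picked proportionally to
individual propensities). Networks whose rate laws are all mass action run
in a compiled kernel; general kinetics use an R event loop. Stationary
moments are *ergodic* time-weighted averages over one long trajectory
(`ssa_moments()`), not ensemble averages — cheaper and sufficient at
stationarity — with a default burn-in of 10% of the horizon and the
initial state placed at the rounded LNA means to shorten the transient.
Standard errors come from 20 equal-width batch means, which makes "within
sampling error" statements assertable.

## What the bundled models emulate — and what they do not

* `michaelis_menten()` (defaults $k_{1..5}=1$, $\beta=10$, $\Omega=100$):
  the textbook open enzyme mechanism with its single enzyme moiety; the
  steady state has the closed form $x^* = (2/9, 1, 1, 9)$ at the defaults.
  For LNA-vs-SSA validation the suite uses the parameter set
  $k = (1, 4, 0.5, 2.5, 3.5)$, $\beta = 0.75$, $\Omega = 300$, chosen so
  that every species pair is appreciably correlated (weakest correlation
  $\approx 0.1$) and means are of order $10^2$; ergodic covariance
  estimates then converge to sub-2% standard errors within
  $t = 3\times10^5$ time units (about $4\times10^8$ events).
* `birth_death()` and `linear_chain()`: open monomolecular networks whose
  stationary law is product-form Poisson. The LNA is *exact* here
  (variance = mean, zero cross-covariances), giving machine-precision
  oracles.
* `erk_cascade()`: a three-tier MAPK cascade with saturating kinetics and
  negative feedback of the doubly phosphorylated output on the first
  activation step (Kholodenko's generic ERK model, BioModels
  BIOMD0000000010), with the feedback constant weakened to $K_I = 45$ so a
  stable steady state exists, and $\Omega$ set to $10^{-9} N_A V$ with
  $V = 10^{-14}\,$l (≈ 6.022 particles per nM). Against this model the
  acceptance suite reproduces: an interior maximum of var(MKKK) of
  $987.7\ \mathrm{particles}^2$ at $v_2 = 0.32$ under a phosphatase-activity
  scan; loss of stability at $v_2 = 0.446$ through a Hopf bifurcation; and
  a covariance maximum cov(MKKK, MKK-P) $\approx 4035\ \mathrm{particles}^2$
  near $(v_2, k_4) = (0.3226, 0.0166)$ found by particle swarm and
  confirmed by a $40\times40$ grid.
* `two_branch_cascade()`: a synthetic mass-action stand-in for two-branch
  MAPK topologies (two parallel kinases activated by a shared fluctuating
  receptor, converging on one downstream kinase and an output tier). It
  exercises the correlation-maximisation and CV-minimisation workflows
  with conservation per tier. It is deliberately *not* a transcription of
  any published p38 model: it has mass-action (not saturating) kinetics,
  no compartments, no scaffolding or multi-site detail. Passing tests on
  it show the workflows function, not that any real pathway behaves this
  way.

Problem sizes used by the test and acceptance runs — 39-point 1D scans, a
$40\times40$ 2D grid, PSO with swarm 50 for 40 iterations, SSA horizons of
$2\times10^4$–$3\times10^5$ time units — are the package's documented
defaults for these studies.

## Synthetic data and real data

The stochastic "data" in this package are generated by the exact SSA from
the same model the LNA approximates. Agreement between the two therefore
validates the *approximation*, not the models: real signalling data add
extrinsic noise, cell-to-cell parameter variability, measurement error and
non-stationarity, none of which the intrinsic-noise machinery here
represents.

## Known limitations

* Single compartment only; multi-compartment models are rejected at
  import.
* Stationary covariances only: no time-dependent $\Xi(t)$, no two-time
  correlations, no corrections beyond leading (Gaussian) order.
* The LNA loses accuracy near bifurcations and boundaries; the
  near-instability warning and particle-number constraints are guards,
  not fixes.
* Reversible reactions must be syntactically separable (`forward -
  backward`) for automatic splitting; anything else needs a manual split.
* The SBML importer covers a deliberate subset (single compartment,
  explicit kinetic laws over arithmetic MathML, irreversible reactions);
  the native YAML format is the source of truth.

## A worked example

```{r mm}
net <- michaelis_menten()
res <- lna(net)
round(res$C, 3)          # particle-number covariance
res$means                # steady-state particle numbers
noise_statistic(res, "corr(E, SE)")   # exactly -1: binary moiety
```

```{r scan, fig.width = 5, fig.height = 3.2}
sc <- scan_statistic(birth_death(), "var(X)",
                     param_range("d", 0.25, 1), points = 16)
autoplot(sc)
```
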