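---
title: "Exact closures, edge-based models, and survival inference for SIR epidemics on configuration model networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact closures, edge-based models, and survival inference for SIR epidemics on configuration model networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netsir)
```

## The model

A stochastic SIR epidemic runs on a configuration model graph of $N$ nodes:
degrees are drawn i.i.d. from a prescribed distribution $(p_k)$ and
half-edges are matched uniformly at random.  Infectious nodes contact each
neighbour at Poisson rate $\beta$ and recover at rate $\gamma$; a contacted
susceptible becomes infectious immediately.  Everything the mean-field
theory needs about the graph is carried by the probability generating
function (PGF) of the degree distribution,
$\psi(u) = \sum_k p_k u^k$, and the variable $\theta(t)$: the probability
that infection has not yet crossed a randomly chosen edge.  A node of
degree $k$ is then still susceptible with probability $\theta^k$, so the
susceptible fraction is $\psi(\theta)$, the mean degree of susceptibles is
$\theta\psi'(\theta)/\psi(\theta)$, and their mean excess degree is
$\theta\psi''(\theta)/\psi'(\theta)$.

Three deterministic large-$N$ descriptions of the same process coexist:

* the **pairwise model**, ODEs for expected counts of nodes $[S], [I]$ and
  ordered pairs $[SI], [SS]$, which needs a closure
  $[ASI] \approx \kappa\,[AS][SI]/[S]$ to eliminate triples;
* the **edge-based (Volz) model** in $\theta$ and the conditional edge-type
  probabilities $p_I, p_S$;
* the **DSA (dynamical survival analysis) model** in the per-node edge
  densities $x_{SS}, x_{SI}$ and $x_\theta$, whose susceptible fraction
  $x_S(t)$ reads as the survival probability of a typical node.

The Volz and DSA systems are equivalent for *any* degree distribution with
finite second moment, and both are exact large-$N$ limits.  The closed
pairwise model joins them exactly when the closure ratio
$$\kappa(\theta) = \frac{\psi''(\theta)\,\psi(\theta)}{\psi'(\theta)^2}
  \;=\; \frac{\text{mean excess degree of susceptibles}}
             {\text{mean degree of susceptibles}}$$
is constant in $\theta$ — which happens if and only if the degree
distribution is **Poisson-type (PT)**: Poisson ($\kappa = 1$), binomial
($\kappa = (n-1)/n$, including the degenerate regular case $p = 1$), or
negative binomial ($\kappa = (r+1)/r$).  These are exactly the solutions of
$\psi'(u) = \alpha\,\psi(u)^\kappa$, with $\alpha = \psi'(1)$ the mean
degree.  `kappa_trajectory()` evaluates $\kappa(\theta(t))$ along a solved
trajectory; for any non-PT network it drifts as susceptibles are depleted,
which is the structural reason no constant-$\kappa$ closure can be exact
there.

For PT networks the whole system collapses further to one autonomous
equation for the survival probability $S_t \equiv x_S(t)$,
$$-\dot S_t = \tilde\beta(1 - S_t^{\kappa}) S_t^{\kappa}
  + \frac{\tilde\gamma}{1-\kappa} S_t (1 - S_t^{\kappa-1})
  + \tilde\rho\, S_t^{\kappa},$$
with the limit form
$\tilde\beta(S_t - S_t^2) + \tilde\gamma S_t \log S_t + \tilde\rho S_t$ at
$\kappa = 1$, where $\tilde\beta = \mu\beta$,
$\tilde\gamma = \beta + \gamma$, $\tilde\rho = \beta\mu\rho$.  Setting
$\dot S = 0$ gives the final-size equation whose root $S_\infty \in (0,1)$
is the fraction never infected.  $S_t$ is an *improper* survival function
($S_\infty > 0$), so the likelihood of observed infection times on a window
$[0, T]$ conditions on infection by $T$:
$$\ell(\tilde\beta, \tilde\gamma, \tilde\rho \mid t_1, \dots, t_k)
  = \sum_{i=1}^k \log\big({-\dot S_{t_i}}\big) - k \log(1 - S_T).$$
Some printed accounts of this likelihood show $\log S_{t_i}$ inside the
sum; a likelihood of observed infection *times* requires the density
$-\dot S_{t_i}$, so the density form is the default and the literal
survival form is available via `form = "survival"` in `dsa_loglik()` and
`dsa_fit()`.

## Parameters and defaults

| parameter | meaning | unit | default |
|---|---|---|---|
| `beta` | per-edge transmission rate | 1/time | — |
| `gamma` | recovery rate | 1/time | — |
| `rho` | initially infected fraction | — | — |
| `mu` | initial SS-edge density per node | edges/node | $\psi'(1)$ |
| `kappa` | closure constant | — | from the PT family |

The default $\mu = \psi'(1)$ deserves a note.  The edge-based initial
conditions are $x_{SS}(0) = \mu$, $x_{SI}(0) = \mu\rho$, while the Volz
model starts from $\theta(0) = p_S(0) = 1$, $p_I(0) = \rho$.  Matching the
two states ($x_{SI} = p_I\,\theta\psi'(\theta)$ at $t = 0$) forces
$\mu = \psi'(1)$; any other choice (for instance the superficially
attractive $\psi'(1)(1-\rho)$, which discounts edges lost to initial
infecteds) breaks the Volz–DSA correspondence at order $\rho$.  We keep
$\mu$ overridable per run because data-matching applications may prefer the
discounted value.  For the same reason the pairwise counts start from
$[S](0) = N$ (the scaled $x_S(0) = 1$), not $(1-\rho)N$: all three models
then start from literally the same state and the conserved total
$x_S + x_I + x_R$ equals $1 + \rho$, an $O(\rho)$ bookkeeping convention
inherited from the mean-field initial conditions rather than an error.
The recovered compartment is integrated explicitly
($\dot x_R = \gamma x_I$) so conservation stays a testable property.

## What the stochastic simulator emulates

`sample_network()` draws i.i.d. degrees (resampling one node's degree until
the stub sum is even) and matches stubs uniformly — a pure multigraph by
default, matching the theory's uniform-matching assumption.  `simple = TRUE`
erases self-loops/multi-edges and re-matches the affected stubs among
themselves (bounded retries); the difference is $O(1/N)$ and invisible at
the scales tested.  `simulate_sir()` generates the exact continuous-time
Markov dynamics by the percolation-style shortest-path construction: each
directed edge carries an $\mathrm{Exp}(\beta)$ first-contact time censored
at the infector's $\mathrm{Exp}(\gamma)$ recovery, and infection times are
propagated in increasing order.  This is equivalent in law to event-driven
Gillespie simulation and yields the per-node infection times the inference
module consumes.  `run_ensemble()` averages retained runs (those reaching a
cumulative infection threshold; concurrent prevalence optional) on a common
grid without re-alignment.

What the generator does **not** emulate: degree correlations, clustering,
household or spatial structure, non-Markovian infectious periods,
behavioural change.  Tests passing against this generator therefore
validate the mean-field and inference machinery on exactly the random-graph
model the theory assumes — they say nothing about robustness to real
contact-network features outside it.

## Numerical choices

* ODE integration: `deSolve::lsoda` with `rtol = 1e-8`, `atol = 1e-10`,
  one order below the tightest cross-model tolerance asserted in tests.
  States are never clipped inside right-hand sides; excursions below
  $-10^{-9}$ abort with an error, smaller ones are clipped for reporting.
* The $\kappa \ne 1$ survival branch evaluates
  $S(1 - S^{\kappa-1})/(1-\kappa)$ via `expm1((kappa-1)*log(S))/(kappa-1)`
  to avoid cancellation near $\kappa = 1$; the branch split is
  $|\kappa - 1| < 10^{-9}$.  The survival flow is frozen below
  $S = 10^{-12}$ so that extreme parameter points probed during likelihood
  maximization remain integrable.
* `final_size()` brackets on $[10^{-12}, 1 - 10^{-12}]$ (the $S = 1$
  endpoint is excluded since $\tilde\rho > 0$ leaves a positive residual
  there) and solves with `uniroot` to $10^{-12}$.
* `classify_pt()` tests $\kappa$-constancy on 9 equispaced $\theta$ values
  in $[0.1, 1]$ with tolerance $10^{-6}$, then moment-matches the mean
  degree to native parameters; the $\kappa = 1$ branch is selected by
  $|\kappa - 1| < 10^{-9}$.  Parametric tails are tabulated to cumulative
  mass $1 - 10^{-12}$.  Single-atom pmfs route directly to the regular
  case, which satisfies the constancy condition but not the interior ODE
  characterization ($\psi(0) = 0$); such results carry a `boundary` flag.
* `dsa_fit()` maximizes in log-parameter space over $[10^{-4}, 100]^3$ by
  screening 48 Latin-hypercube candidates and polishing the best 8 with
  L-BFGS-B.  The screen-then-polish design matters: the likelihood surface
  has a long, nearly flat ridge (see below) and a handful of blind starts
  regularly miss the global basin.

## Test problem sizes

The suite exercises ensembles of 30 retained epidemics on networks of
2,000 nodes (5 networks × 6 runs, 50 initial infecteds, retention at 100
cumulative infections), solver cross-checks on $t \in [0, 15]$ grids of
301 points, an independent fixed-step classical Runge–Kutta oracle at step
$10^{-3}$ on $[0, 5]$, and likelihood fits at $k$ between 300 and 5,000.
These sizes make Monte-Carlo error comfortably smaller than the asserted
tolerances while keeping the default test run fast.

## Known limitations

* **Joint identifiability of the compound rates.**  The infection-time
  likelihood constrains $(\tilde\beta, \tilde\gamma, \tilde\rho)$ through
  the shape of one conditional density, and its information matrix is
  severely ill-conditioned: one direction (roughly, increasing
  $\tilde\beta$ and $\tilde\gamma$ together) moves the density very
  little.  Point estimates from samples of a few thousand times can
  therefore land far along this ridge even when the fitted curve is
  visually indistinguishable from the truth; `vcov()` and `summary()`
  expose the large, strongly correlated standard errors.  The difference
  $\tilde\beta - \tilde\gamma$ (the early growth rate) and $\tilde\rho$
  are much better determined than the rates individually.  When any one of
  the rates is known — e.g. the recovery rate from clinical data — fixing
  it is strongly advisable; `dsa_fit()` deliberately keeps $\kappa$ fixed
  for the same reason.
* The survival reduction (and hence the likelihood) requires a PT degree
  distribution; for non-PT networks only the full Volz/DSA systems are
  available, and `as_survival_params()` refuses to build compound rates.
* Heavy-tailed degree distributions with infinite second factorial moment
  are rejected at construction: every model here assumes
  $\psi''(1) < \infty$.
* The regular family ($\psi(u) = u^n$) satisfies the closure-constancy
  condition but not the interior conditions of the PT characterization;
  its survival reduction is validated against the full DSA solve in the
  tests rather than assumed.
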