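---
title: "Non-Markovian SIR epidemics on configuration-model networks: models and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-Markovian SIR epidemics on configuration-model networks: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netsir)
```

## The stochastic model

An SIR epidemic spreads on an undirected, unweighted, static contact
network. When a node becomes infected it draws an infectious period from a
law $q(a)$ ($a$ is the *age of infection*, time since the node was
infected) and, independently for each neighbour, a transmission delay from
a law $\tau(a)$; the transmission is attempted only if the delay falls
before the recovery. Neither law need be exponential, so the process is
non-Markovian in general. Recovery confers permanent immunity. All nodes
respond homogeneously, and the two delays are independent — correlated
transmission/recovery processes are out of scope.

The network is a configuration model (CM): degrees are drawn i.i.d. from a
prescribed distribution $p_k$ and stubs are paired uniformly at random.
The package supports regular, (truncated) Poisson, truncated power-law and
explicit empirical degree distributions, summarised through the
probability generating functions

$$G_0(x)=\sum_k p_k x^k,\qquad
  G_1(x)=\frac{1}{\langle k\rangle}\sum_k p_k k x^{k-1},\qquad
  G_2(x)=G_1'(x),$$

with $\langle k\rangle$ the mean degree. The mean excess degree — the
expected number of *further* neighbours of a node reached along a random
edge — is computed as $G_2(1)=G_1'(1)$. (One occasionally sees it written
as a derivative of $G_2$; that is inconsistent with the definition of the
excess-degree distribution generated by $G_1$, and the package deliberately
uses $G_2(1)$.)

Two derived objects drive everything:

* the competing-risk kernels
  $f(a)=\tau(a)\,\xi_q(a)$ (transmission attempted at age $a$, before
  recovery) and $g(a)=q(a)\,\xi_\tau(a)$ (recovery at age $a$ with no prior
  attempt on the given edge), where $\xi_\tau,\xi_q$ are the survival
  functions; these are exhaustive, $\int_0^\infty (f+g)\,da = 1$;
* the transmissibility $\tilde T=\int_0^\infty f(a)\,da$, the probability
  that an infected node ever attempts transmission across a given edge.

Time units are arbitrary; all rates and durations must simply be mutually
consistent.

## The deterministic layer

**Message passing (`solve_mp`).** The average message $H_1(t)$ — the
probability that a random neighbour has not attempted transmission to a
cavity-state test node by time $t$ — solves the Volterra renewal equation

$$H_1(t)=1-\int_0^t f(a)\,[1-z\,G_1(H_1(t-a))]\,da,\qquad H_1(0)=1,$$

with $z$ the initially susceptible fraction. Then
$S=zG_0(H_1)$, $R(t)=\int_0^t q(a)[1-S(t-a)]\,da$, and $I$ by complement.
On the ensemble of infinite CM networks this model is exact; on a finite
*tree*, solving one message per directed edge (`solve_mp_per_edge`) is
exact for the given network, with
$P(u \text{ susceptible}) = z\prod_{v\in N(u)} H^{u\leftarrow v}$.

**Edge-based compartmental model (`solve_ebcm`).** An equivalent
age-structured formulation: the message $\Theta$ obeys
$\dot\Theta=-\int_0^t\zeta(a)\phi_I(t,a)\,da$ with $\zeta=\tau/\xi_\tau$
the transmission hazard, $\phi_I(t,a)$ the age density of infected
neighbours that have not yet transmitted (transported along
characteristics with decay $\zeta+\rho$, $\rho$ the recovery hazard), and
$i(t,a)$ the age density of infected nodes (decay $\rho$). The two
formulations produce identical trajectories for the same inputs;
`equivalence_report` measures the sup-norm gaps, which should vanish at
the discretisation order under grid refinement. This equivalence is the
package's central correctness diagnostic and is exercised directly in the
test suite.

**Pairwise hierarchy.** For Poisson transmission at rate $\beta$ the
message model re-parametrises exactly into a pairwise-like system in
$(H_1,[SI])$ with $[S]=zNG_0(H_1)$ and
$[I](t)=\beta\int_0^t[SI](t-a)\xi_q(a)\,da+N(1-z)\xi_q(t)$
(`solve_pairwise_cm`). No moment closure is involved. Three classical
reductions are provided and verified against it: degree-regular networks
(`solve_pairwise_regular`, a closed $[S],[SS],[SI]$ system with an
incrementally maintained exponential memory kernel), exponential recovery
(`solve_pairwise_markovian`, a plain ODE system), and fixed infectious
periods (`solve_pairwise_fixed_delay`, a delay-differential system whose
delta sources act as impulsive jumps at $t=\sigma$).

**Analytics.** `final_size` iterates
$\Theta_\infty = 1-\tilde T+\tilde T G_1(\Theta_\infty)$ from $0$, which
converges monotonically to the smallest root in $[0,1]$, and returns
$r_\infty = 1-G_0(\Theta_\infty)$; `epidemic_threshold` returns the
percolation ratio $\tilde T\times$ mean excess degree, with a large
outbreak possible iff it exceeds one.

## Numerical choices

* **Shared uniform grid.** Every solver uses a fixed step $h$ for both
  calendar time and (in the EBCM) infection age, so characteristic
  transport and delay lags are exact grid shifts and convolution weights
  never change. Adaptive stepping is deliberately avoided: the history
  integrals would otherwise need re-interpolation at every step.
* **Implicit endpoints.** The trapezoidal evaluation of the Volterra
  integral references the unknown endpoint value; it is resolved by
  fixed-point iteration (tolerance $10^{-10}$, at most 50 sweeps — the
  contraction factor is $O(h)$ so a handful suffice). The EBCM boundary
  condition is linear in the force of infection and is solved in closed
  form inside a small $\Theta$ iteration (tolerance $10^{-12}$).
* **Atoms.** Point masses (fixed periods, empirical tables) are never
  smeared into densities. They enter integrals by direct evaluation:
  lagged point terms in the Volterra sums, survival-ratio decays in the
  EBCM transport (the recovery hazard is never evaluated at an atom), and
  impulsive state jumps in the pairwise systems. One consequence: the
  EBCM requires an absolutely continuous *transmission* law, because its
  force-of-infection integral needs the pointwise hazard $\zeta$; atomic
  transmission delays are handled by the message-passing solver instead.
* **Jump corrections.** Where a survival function jumps (a recovery atom
  at $\sigma$), integrands such as $f$ are discontinuous and the grid node
  carries the right limit; a half-cell correction restores the missing
  mass, keeping the fixed-period comparisons at the $10^{-4}$ level
  rather than $10^{-3}$.
* **Convergence order.** With smooth inputs the schemes are second order
  (gaps shrink $\sim 4\times$ per halving of $h$); with survival jumps the
  order drops to one ($\sim 2\times$), which the refinement tests assert
  with a small margin below the asymptotic factor.
* **Truncated normal.** A normal infectious period with mean 2 and sd
  0.75 has about 0.4% of its mass below zero; the package restricts it to
  $[0,\infty)$ and renormalises. Its mean is therefore slightly above 2
  (by $\approx 0.0085$); this is a deliberate, documented choice rather
  than mean-preserving re-shifting.
* **Quadrature.** Static integrals (transmissibility, kernel masses,
  survival-function means) use adaptive quadrature with absolute tolerance
  $10^{-10}$, the domain split at survival jumps and capped where
  $\xi_\tau\xi_q<10^{-12}$.
* **Degenerate inputs.** $z=1$ yields the quiescent equilibrium in every
  solver; an all-isolated-nodes degree distribution has no excess degree
  and is rejected; `solve_pairwise_regular` truncates cleanly if $[S]$
  reaches zero.

## The stochastic layer and what the generator emulates

`sample_configuration_network` draws degrees i.i.d., fixes stub parity by
redrawing the last node's degree, pairs stubs uniformly, and *erases*
self-loops and duplicate edges. Erasure (rather than resampling or
rewiring) introduces a small downward bias in edge counts — under 2% at
$N\ge 1000$ for the validation distribution — accepted for simplicity and
documented here. The generator emulates only the degree distribution: real
contact networks additionally show clustering, degree–degree correlations,
weighted and time-varying contacts, none of which are produced here, so
passing validation says nothing about those features.

Two exact simulators produce sample paths. `simulate_rejection`
(Poisson transmission only) draws the next putative transmission time at
rate $\beta\times$ (S–I edge count) and discards it if a scheduled
recovery comes first — valid by memorylessness. `simulate_event_driven`
(general $\tau$, $q$) schedules, at each infection, a recovery $r\sim q$
and per-neighbour attempts at delays $d\sim\tau$ iff $d<r$, so the
per-edge first-attempt law is exactly $f(a)$. Ties are broken by
(time, node id, kind). One master seed derives per-run seeds through a
fixed splitting rule, making ensembles reproducible run by run.

Two initial-condition protocols are offered. *Fresh cohort* (the default
for validation) infects each node independently with probability $1-z$ at
$t=0$ with infection age 0 — exactly the mean-field source terms, so the
comparison is confound-free. The *burn-in* protocol
(`align_at_threshold`) instead grows the epidemic from a single seed and
resets the clock when prevalence first reaches a threshold (default 5%);
this matches how field data are aligned but leaves the infected cohort
with nonzero residual ages, which the mean-field initial condition
ignores — the reported susceptible fraction at reset should then be used
as $z$.

## Validation design and problem sizes

The test-suite and acceptance-script checks run at desk scale, chosen as
the smallest sizes at which each claim is statistically meaningful:
equivalence and hierarchy checks on a horizon of 15 time units at
$h=0.01$ (with $h=0.005$ refinements); tree exactness on a 5-node star
with $10^5$ runs; finite-network validation on truncated power-law
networks ($p_k\propto k^{-2.5}$, $3\le k\le 60$) of $N=1000$ nodes with
200 runs per recovery law (exponential rate 0.5, truncated normal (2,
0.75), fixed 2 — all with mean infectious period 2) under Poisson
transmission at rate $\beta=0.3$ and $z=0.99$.

Three caveats that the numbers themselves make visible:

* At $N=1000$ with hubs of up to 60 contacts the network is *not* yet
  locally tree-like, and the ensemble mean lies a few percent below the
  mean-field curve near the epidemic peak — visibly more than the very
  narrow standard-error band of a 200-run ensemble, so strict
  SE-band-coverage checks fail there by design of the comparison, not by
  error of either side. The deviation shrinks roughly like the inverse
  network size and is at the one-SE level by $N\approx 16000$. The
  qualitative signature — lower-variance infectious periods give faster,
  larger epidemics (exponential < truncated normal < fixed at matched
  means) — is reproduced with well-separated peak confidence intervals.
* The maximum standardised deviation over a grid of points is itself a
  random variable; with ~20 points a bound of three standard errors is
  comfortable but not certain for every seed.
* Final-size analytics assume a vanishingly small initial infected
  fraction; dynamic runs use $z=1-10^{-4}$ and agree to $10^{-2}$.

## Limitations

SIR only (no SEIR/SIS), static networks, homogeneous and independent
delays. The per-edge message solver is exact on forests and only
approximate (with an explicit opt-in flag) on cyclic graphs. The pairwise
hierarchy requires Poisson transmission by construction. Efficient
large-scale EBCM solvers (implicit age-lumping, adaptive memory
truncation) are out of scope; the reference implementation favours
transparency over speed.
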