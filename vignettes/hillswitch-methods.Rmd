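---
title: "Methods: Hill ODE ensembles, switching-system combinatorics, and their comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Hill ODE ensembles, switching-system combinatorics, and their comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hillswitch)
```

## The two models

A regulatory network assigns each gene $k$ an ODE for its concentration
$x_k$.  The **Hill-ensemble model** uses graded regulation,

$$\dot x_k \;=\; P_k \prod_{j \to k} \frac{H^s(x_j,\theta_{kj},n_{kj},a_{kj})}{a_{kj}}
  \prod_{j \dashv k} H^s(x_j,\theta_{kj},n_{kj},i_{kj}) \;-\; \gamma_k x_k,$$

with the shifted Hill function
$H^s(x,T,n,\lambda) = \lambda + (1-\lambda)\,T^n/(T^n+x^n)$, activation
folds $a_{kj} > 1$ and repression folds $i_{kj} < 1$.  Each repressing
factor falls from 1 to $i$; each activating factor $H^s/a$ rises from
$1/a$ to 1, so $P_k$ is the maximal production rate.

The **switching system** is the $n \to \infty$ limit: every factor
becomes a step between a lower level $L_{kj}$ and an upper level
$U_{kj}$ at the threshold $\theta_{kj}$,

$$\dot x_i = -\gamma_i x_i + \Lambda_i(x), \qquad
  \Lambda_i = \prod_{j \multimap i} \sigma^{\pm}_{ij}(x_j).$$

Interaction logic is a pure product of per-edge terms in both models;
the more general sum-of-products switching logic is deliberately out of
scope, because the Hill ensemble has no counterpart for it.

The exact translation (`to_switching()`) attributes production evenly
across a node's $m_k$ inputs: $U_{kj} = P_k^{1/m_k}$, and
$L_{kj} = U_{kj}/a_{kj}$ or $U_{kj}\, i_{kj}$ by edge sign; thresholds
and decay rates are common to both formalisms.  The inverse map
(`to_racipe()`) exists only where no $L_{kj}$ equals $P_k^{1/m_k}$, and
composing the two in the other order is *not* the identity — sampling in
switching space and mapping back is therefore not used anywhere in the
pipeline, and `to_racipe()` is provided for completeness and testing
only.

## What the sampler emulates

`sample_parameters()` is the package's synthetic-data generator; its
defaults are the study conditions for every statistic the package
reports.  They emulate RACIPE-style random circuit perturbation with
BioNumbers-informed ranges:

| parameter | default | units | note |
|---|---|---|---|
| production $P$ | Uniform(1, 100) | conc/time | ensemble median 50 |
| degradation $\gamma$ | Uniform(0.1, 1) | 1/time | |
| fold change $FC$ | Uniform(1, 100) | — | $a = FC$, $i = 1/FC$ |
| Hill coefficient $n$ | Uniform(1, 6) | — | presets (1,10), (10,50), (50,100), (100,1000) |
| threshold $\theta_{kj}$ | Uniform(0.02, 1.98) × $M_j$ | conc | $M_j$ = half-functional median of source $j$ |

Two conventions deserve emphasis because alternatives fail basic sanity
anchors:

* **Repression folds are reciprocal-uniform**, $i = 1/FC$ with $FC$
  uniform, not uniform on (0, 1).  This is how fold changes are actually
  drawn in random-circuit-perturbation practice, and it is what makes
  strong repression typical.
* **Thresholds follow the half-functional rule.**  For an edge with
  source $j$, the threshold range is $(0.02\,M_j,\ 1.98\,M_j)$ where
  $M_j$ is the Monte-Carlo median of $j$'s steady level
  $(P/\gamma)\prod (1/FC)^{\text{Bernoulli}(1/2)}$ — each regulation of
  $j$ active half the time.  This centres each threshold on the
  source's attainable scale, so each link is roughly equally likely to
  be on or off.  Design-time Monte Carlo showed that plausible
  alternatives (e.g. a threshold scale tied to the unregulated median
  level with uniform repression folds) push the central, bistable
  region of parameter space down to a few percent occupancy and make
  corner regions unreachable; the half-functional/reciprocal convention
  yields the expected behavior — about 60% of toggle-switch samples in
  the central region and all nine regions populated.

Initial conditions are log-uniform over
$[10^{-2}\min_k(P_k/\gamma_k),\ 10\max_k(P_k/\gamma_k)]$, spanning every
attractor basin across the decades of scale a random parameter set can
produce.

Every sampled set is passed through `regularity_screen()` after
translation: a set whose production levels coincide with some
$\gamma_i\theta$ product (within $10^{-9}$), or with two coincident
thresholds on one variable, has no well-defined state transition graph
and is resampled.  For continuous ranges this is a measure-zero event;
the resample count is recorded and is zero in practice.

## Parameter-space decomposition

Phase space splits into $\prod_i(|T(i)|+1)$ rectangular domains.  Within
each, the flow is linear toward the target point
$T(\alpha) = (\Lambda_1(\alpha)/\gamma_1, \ldots)$, so the qualitative
dynamics is a finite directed graph: the state transition graph
(`build_stg()`), with a self-edge where the target lies inside its own
domain and exactly one directed edge through every wall.  Its recurrent
strongly connected components, ordered by reachability, form the Morse
graph (`morse_graph()`); minimal components are the predicted
attractors — `FP(β)` for singleton components (labelled by the domain's
discrete coordinates) and `"cycle"` for anything recurrent and
nontrivial.  No finer cycle classification is attempted; none is needed
for the statistics here.

For networks whose nodes have one input and one output, each node's
position in parameter space reduces to a three-way choice
($\gamma\theta < L < U$, $L < \gamma\theta < U$, $L < U < \gamma\theta$),
and the parameter graph is the product of these factors
(`enumerate_parameter_graph()`): nine nodes for two-node motifs.  We
index them row-major over the node order, 0–8, which places the
doubly-central node at **index 4** — the only index statements depend
on.  The enumeration is verified internally by rebuilding each node's
representative parameters and checking `parameter_node()` returns its
index.  Multi-input networks (the toggle triad) are handled per sample:
`dsgrn_signature()` records the full inequality table, and
`switching_repertoire()` computes each sample's Morse-graph attractors
directly, avoiding the combinatorially large full enumeration.

## Integration and steady-state processing

*Hill ensembles* are integrated by fixed-step forward Euler, the
convention of the simulation tools this package emulates; discrepancies
it introduces are themselves an object of study (see the agreement
diagnostics below).  The step is dimensionless: `dt = 0.05 / min(γ)` per
set, i.e. 4000 steps across a horizon of 200 slowest-decay times.  An
adaptive high-order integrator (deSolve) is available via
`hill_settings(integrator = "adaptive")` for accuracy checks; it
confirms, for example, that central parameter sets that remain
monostable at moderate Hill coefficients do so genuinely and not as an
artifact of the Euler step.

Final states are merged at a relative tolerance of $10^{-2}$ per
coordinate, and each distinct state is verified against the
root-mean-square derivative criterion
$\sqrt{\sum_k (\dot x_k)^2 / N} < 10^{-4}$.  Weights are the fraction
of initial conditions converging to each state.  A set that accumulates
10 distinct final states (the conventional cap) with none verified is
flagged **cyclic** — this is exactly how oscillatory negative-feedback
sets manifest under steady-state-seeking simulation.  Non-finite
trajectories are dropped from normalization and counted; they do not
occur for positive parameters under the default step.

*Switching systems* get two integrators.  `integrate_event_driven()` is
exact: within a domain the solution is
$x_i(t) = T_i + (x_i(0)-T_i)e^{-\gamma_i t}$, so wall-crossing times
have closed forms and the trajectory advances wall to wall without
discretization error; cycles are detected by a repeating (domain,
exit-wall) pair.  Because the networks here have no self-loops, a
coordinate's production is identical on both sides of its own walls and
sliding motion cannot occur; the only degeneracy is an exact
crossing-time tie, which is retried once from a minutely perturbed
start and otherwise reported `"ambiguous"` rather than silently
resolved.  `integrate_switching_euler()` mirrors the Hill integrator's
fixed-step scheme and exists to quantify how much classification error
the numerical route contributes (about 1–5% of initial conditions near
basin boundaries at the default step, vanishing as the step shrinks).

For the bistable toggle switch and double-activation pair the basin
boundary is available in closed form: inside the two domains not
containing a fixed point it is the locus of equal first-crossing times
of the two thresholds (`ts_separatrix_side()`, `da_separatrix_side()`),
and containment decides the rest.  The event-driven integrator serves
as the oracle for these formulas in the test suite, with exact
agreement required.  `basin_report()` summarizes fractions and the
basin-strength product (at most 1 for monostable, $0.25$ for bistable
sets, attained at even basins).

## Discretization and comparison conventions

Steady states are pooled across the ensemble and converted to weighted
z-scores per node; $z \ge 0$ binarizes to 1 (ties at exactly zero are a
measure-zero event and count as high).  Two conventions matter:

* **z-scores are taken on log2 expression.**  Random ensembles span
  decades of scale; on a linear axis the pooled mean sits far above the
  "high" states of low-production parameter sets and the binarization
  degenerates.  `log2 = FALSE` restores the literal linear reading for
  sensitivity analysis.
* **The switching side is binarized through the same pipeline.**
  `switching_state_table()` collects each sample's exact fixed points
  (equal weights within a set) and `discretize_states()` applies the
  identical z-score machinery.  This matters because threshold-relative
  FP labels and expression-relative z-labels genuinely differ in corner
  regions — a toggle switch with both repressions permanently active
  has its fixed point *above* both thresholds (FP(11)) yet at *low*
  absolute expression — and only the like-for-like comparison is
  meaningful.  The threshold-label route remains available by passing a
  `parameter_graph` where that is the question being asked, with
  `repertoire_label_map()` translating binary labels to discrete-level
  labels (e.g. toggle-triad `100` to `200`).

Node-wise comparison stratifies by parameter node and reports the
maximum absolute frequency discrepancy and Jensen–Shannon divergence
per stratum; empty strata are omitted.  Ensemble comparison reports the
pooled distribution, the parameter-node occupancy histogram (the
sampling-bias diagnostic), and the bias-corrected distribution in which
every occupied parameter node contributes its own repertoire
distribution with equal weight — the reading of "normalized by the
number of samples per node" that restores the match to the
node-uniform switching prediction.  JSD is reported in bits (base 2,
range [0, 1]); the base is configurable.

PCA of stability classes (`pca_delineation()`) is covariance-based on
the raw parameter matrix: only unscaled PCA can show that production
rates and thresholds dominate the leading components, since scaling
would equalize every parameter's variance by construction.  The
correlation-based variant is a flag away.

## Problem sizes and determinism

Every statistic is reproducible from (network, configuration, seed).
The test suite runs ensembles of 40–2000 parameter sets with 20–100
initial conditions each, chosen so the full suite completes in minutes
while leaving each statistic's sampling error well inside its asserted
margin; `scripts/acceptance.R` recomputes the headline quantities at
5000 parameter sets (2000 for the toggle triad) with 100 initial
conditions, the package's reference scale.  The JSD sweep across Hill
ranges reuses one seed so consecutive ranges share every draw except
the Hill coefficients, making the monotone-convergence check nearly
noise-free.

## Known limitations

* Interaction logic is restricted to products of per-edge terms;
  additive logic would need both a different translation and different
  factor graphs.
* Self-loops and multi-edges are rejected outright.
* The full parameter-graph enumeration covers only
  single-input/single-output networks; multi-input networks are handled
  per sample.
* The sampler emulates the *statistical* conventions of random circuit
  perturbation; it does not reproduce any specific published run, and
  statistics that depend on fine features of the threshold distribution
  (e.g. how often samples land near region boundaries, where finite-$n$
  dynamics genuinely departs from the switching limit) can shift by a
  few percentage points under defensible alternative conventions.
* Stochastic simulation, delays, and analytic separatrices for three or
  more nodes (or for cyclic attractors) are out of scope; basin
  estimation there is numerical.
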