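---
title: "Likelihood-free inference for stochastic lattice tissue models"
author: "tissueABC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Likelihood-free inference for stochastic lattice tissue models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The inference problem

Spatial models of tissue dynamics — infection spreading through a cell
sheet, a growing tumour spheroid, regenerating liver lobules — are
stochastic simulators: for parameters $\theta$ they produce data
$y = M(\theta, \xi)$, where $\xi$ collects process and measurement noise.
Their likelihood $\pi(y \mid \theta)$ is intractable, so `tissueABC`
approximates the Bayesian posterior
$\pi(\theta \mid y_\mathrm{obs}) \propto \pi(y_\mathrm{obs} \mid \theta)\,\pi(\theta)$
by approximate Bayesian computation with sequential Monte Carlo (ABC-SMC):
a population of $N$ weighted particles is propagated through a decreasing
sequence of acceptance thresholds $\varepsilon_1 > \varepsilon_2 > \dots$,
each particle accepted when its simulated summary statistics fall within
$\varepsilon_t$ of the observed ones under a weighted distance.

The package is organised around five pieces: a tab-separated
problem-specification dialect, a desk-scale lattice simulator, summary
statistics with adaptive distances, the SMC engine with its scheduling
contract, and a result store with diagnostics.

## The problem-specification dialect

A problem bundle is a yaml index naming an XML model document and four
UTF-8, tab-separated tables ('.' decimal, no cell quoting, mandatory
header): parameters, conditions, measurements and summary statistics. The
layout follows the PEtab lineage of parameter-estimation formats; this
package implements a deliberately self-consistent dialect, not the full
externally hosted grammar.

Design choices that were genuinely open:

* **Target paths.** Parameters and condition overrides address model
  values through a restricted XPath-like grammar — child steps,
  `[@name='…']` predicates, and a final `/@attr` or `/text()` selector.
  This covers automatic parameter referencing into an XML model document
  without committing to a full XPath engine, and it can be validated
  syntactically with one regular expression.
* **Priors.** `uniform`, `log10-uniform` and `normal` only; each
  parameter carries a `scale` (`lin` or `log10`). Sampling and
  perturbation happen on the declared scale; back-transformation
  (`10^theta`) happens only when a value is written into the model
  document. `log10-uniform` bounds are given on the natural scale (hence
  must be positive) and transformed once.
* **Condition overrides.** Columns of the condition table beyond
  `condition_id` are themselves target paths; a cell holds the override
  value, an empty cell means no override — one row per condition, as in
  the PEtab condition table.
* **Gridded data references.** A measurement row may reference a
  2-D array file (CSV matrix, one array per file) instead of carrying a
  scalar value; statistic functions consume either form.

`validateProblem()` returns a deterministic, ordered report of coded
entries rather than throwing, so a whole corpus of bundles can be audited
mechanically; `parseProblem()` collects I/O, schema and link errors and
raises them together as classed conditions.

## The lattice simulator

### Two-route viral spread

The reference application is an infection spreading through a lattice of
cells by two routes: *cell-free* transmission through a diffusing virion
field, and *cell-to-cell* transmission through direct contact. Each site
holds one cell in state susceptible, infected or dead, plus a local virion
concentration $V$.

One synchronous step of length $\mathrm{d}t$:

1. **Field update.** Forward-Euler five-point-stencil diffusion with
   diffusion coefficient $D$, linear decay $c$, and production $p$ at
   sites that were infected before the step; reflecting (zero-flux)
   boundaries. Stability requires $D\,\mathrm{d}t \le 1/4$ (lattice
   spacing 1) and is checked before any stepping. The update is provably
   non-negative when $4D\,\mathrm{d}t + c\,\mathrm{d}t \le 1$ (the centre
   coefficient is then non-negative, making the update a non-negative
   combination); outside that bound values are clipped at zero. With zero
   source and decay the zero-flux stencil conserves total mass exactly.
2. **Infection.** Each susceptible site independently becomes infected
   with probability
   $1 - \exp\{-(\beta_\mathrm{cf} V + \beta_\mathrm{cc} n)\,\mathrm{d}t\}$,
   where $V$ is its post-diffusion local concentration and $n$ its count
   of infected 4-neighbours in the *pre-step* configuration.
3. **Death.** Each pre-step infected site independently dies with
   probability $1 - \exp(-\delta\,\mathrm{d}t)$.

All hazards are evaluated on the pre-step cell configuration, which makes
single-step infection counts exactly binomial — the tests exploit this
with a closed-form oracle. The 4-neighbourhood (von Neumann) is the
smallest contact stencil; boundaries are non-periodic, matching the
reading of a finite tissue patch with a central plaque.

The step is implemented twice: a readable, vectorised R function
(`viralStep()`) and a compiled run kernel behind `runViralModel()`. Both
consume the R random stream in a documented order — infection draws over
susceptible sites in column-major order, then death draws — so their
trajectories are bit-identical for the same seed, and the test suite
asserts exactly that. Sites whose per-step infection probability is below
$10^{-12}$ are treated as zero-hazard and consume no random number; this
cutoff changes any trajectory with probability below
$\sim 2.5\times10^{-7}$ per run and keeps both implementations in lockstep
while skipping the vast inactive part of the lattice.

The reference synthetic-truth setting used by the fixtures is
$\beta_\mathrm{cf} = 0.05$ (per concentration per time),
$\beta_\mathrm{cc} = 0.2$ (per infected neighbour per time), $p = 1$,
$c = 0.1$, $D = 0.5$, $\delta = 0.05$, $\mathrm{d}t = 0.1$ on a
$50 \times 50$ lattice with one central infected cell, observed over
$t \in [0, 10]$. These are desk-scale values chosen to produce a growing
but unsaturated plaque within the observation window; the acceptance
experiments are parameter-recovery studies against this self-generated
truth, not reproductions of any published rate table.

### Cellular Potts kernel

`cpmStep()` implements standard Metropolis boundary-copy dynamics for the
cellular Potts energy
$H = \sum_{\langle a,b\rangle:\,\sigma_a \ne \sigma_b} J(\tau_a, \tau_b)
   + \lambda_V \sum_k (v_k - V_k)^2$
on a 4-neighbourhood without wraparound. One sweep is `width * height`
attempts: pick a random site and neighbour, propose copying the
neighbour's spin, accept with probability $\min(1, e^{-\Delta H/T})$.
Energy changes are computed locally and volumes tracked incrementally;
tests verify the local $\Delta H$ against a brute-force recomputation and
the telescoping identity over a 50-sweep run. The CPM is a library kernel
exercised at small sizes; the inference fixtures use the cheaper viral
model.

## Summary statistics and distances

The statistic registry covers the data types that imaging studies of such
systems produce: `count_timeseries` (an observable's counts on a time
grid), `patch_radius_timeseries` (equivalent-circle radius
$\sqrt{A/\pi}$ of the infected+dead region), `radial_profile` (means over
concentric bins around the lattice centre, binned to radius
$\min(w,h)/2$), and `final_fraction`. Observed counterparts are assembled
from the measurement table with replicates averaged; a
`radial_profile` may alternatively be computed from a referenced gridded
array.

Distances are weighted $L^p$ norms ($p \in \{1, 2\}$, default 2) over the
statistic vector. Because statistics live on wildly different scales
(counts up to thousands, fractions in $[0,1]$), per-statistic weights are
adapted: $w_i = 1/\mathrm{scale}_i$ with the scale taken as the median
absolute deviation (robust, the default) or standard deviation across a
population of simulations. The schedule is: generation 1 uses weights from
a pilot sample of 100 prior simulations; every later generation refits
them from the previous generation's accepted summaries. A statistic with
zero spread that generation is uninformative and receives weight 0 with a
warning.

Two numerical conventions keep the adaptive distance well-behaved:

* Refit weights are rescaled to mean 1. Weights carry *relative*
  importances only; without the rescaling, the overall distance scale
  drifts as populations concentrate (scales shrink, weights grow), and
  the non-increasing threshold clamp would strangle acceptance.
* When weights change at the start of a generation, the previous
  generation's accepted distances are *recomputed under the new weights*
  before the threshold quantile is taken, so the threshold and the
  acceptance rule always use the same distance.

`fitRegressionStatistics()` provides the inverse-regression construction
of projected summaries: on pilot samples, one least-squares fit per
parameter of $\theta$ on the raw summary vector; the fitted map
$s \mapsto b_0 + Bs$ (the predicted parameters) then replaces the raw
statistics. The map is fit once on the pilot sample and frozen —
refitting per generation would change the acceptance target mid-run.
Rank-deficient designs fall back to ridge regression with fixed
$\lambda = 10^{-8}$.

## The ABC-SMC engine

* **Generation 1** accepts the first $N$ prior draws
  ($\varepsilon_1 = \infty$ unless configured otherwise) with uniform
  weights — the simplest calibration of the threshold sequence.
* **Thresholds.** $\varepsilon_t$ is the $\alpha$-quantile (type 1: the
  smallest value whose empirical cdf reaches $\alpha$; no interpolation,
  the same convention as every quantile in the package) of the previous
  generation's accepted distances, clamped to be non-increasing;
  $\alpha = 0.5$ by default.
* **Kernel.** Proposals resample a previous particle by weight and add
  multivariate Gaussian noise with covariance $2\,\hat\Sigma_{t-1}$,
  where $\hat\Sigma_{t-1}$ is the weighted empirical covariance of the
  previous generation — the standard adaptive SMC choice. Draws outside
  the prior support are handled by redrawing (resample, perturb again, up
  to $10^4$ attempts), which keeps $N$ fixed and weights strictly
  positive.
* **Weights.** The standard sequential importance weight
  $w \propto \pi(\theta') / \sum_j w_j K(\theta' \mid \theta_j)$,
  normalised per generation. The engine evaluates the denominator for the
  whole population at once through pairwise Mahalanobis distances under
  the kernel's Cholesky factor.
* **Early rejection.** A per-simulation budget, counted in simulation
  steps (deterministic and portable, unlike wall seconds, which are also
  supported at the evaluation level): a particle whose simulation would
  exceed the budget is rejected with distance $\infty$ before (or as soon
  as) the budget binds. With a non-binding budget, results are identical
  to budget-free evaluation at the same seed.
* **Stopping.** $\varepsilon \le \varepsilon_\min$, a generation cap, or
  a wall-time limit; the running generation is always finished rather
  than aborted, so the final population is complete.
* **Reproducibility.** Every proposal consumes its own RNG substream
  derived from `(seed, generation, task index)` through an affine map
  over a prime modulus — injective in the task index within a generation,
  logged per task, and checked unique in the tests. Identical
  (problem, configuration, seed, single worker) runs are byte-identical
  after the timing field is stripped; wall-clock seconds are the one
  genuinely non-deterministic record.

## The scheduling contract

Sampling a generation is distributed through one of two strategies.
*Static* scheduling fixes per-worker acceptance quotas (balanced to
within one particle) — each worker samples until its quota, minimising
total CPU time; results are deterministic for a fixed worker count.
*Dynamic* scheduling issues tasks on demand until $N$ acceptances,
minimising wall time. Its correctness rule: the accepted population is
the $N$ accepted particles with the smallest *issue* indices; later
acceptances are discarded. Accepting by *completion* time instead would
favour fast-simulating parameter regions whenever evaluation time
correlates with the parameter — a length-biased selection of the
discarded in-flight tasks. The test suite demonstrates this concretely:
with latency proportional to the parameter and the worker count
comparable to $N$, completion-order selection fails a two-sample KS test
against the sequential reference while issue-order selection passes, and
is unchanged by the worker count.

The scheduler in this package is a deterministic in-process emulation
with an injectable latency model — exactly what is needed to verify the
contract's statistical properties on one CPU; a multicore or networked
backend is an adapter point behind the same interface, with the
`parallelEfficiency()` metric ($PE = t_1 / (t_i \cdot i)$) available for
profiling deployments.

## Result store and diagnostics

A run is recorded as a fingerprint of the problem bundle, a configuration
snapshot, the observed summary vector, and one record per generation
(threshold, proposal count, wall seconds, particle table, summary
matrix). The store serialises to a single JSON file at 17 significant
digits, which round-trips IEEE doubles bit-exactly; non-finite values
(the generation-1 threshold) are kept as strings. A relational backend
was considered and set aside: a single self-describing text file keeps
stores diffable and dependency-free, and a tsv exporter
(`exportResultStore()`) writes the diagnostic tables any plotting tool
can consume.

Diagnostics follow standard definitions: effective sample size
$1/\sum w_i^2$; equal-tailed weighted credible intervals from type-1
weighted quantiles; epsilon and proposal-count trajectories; and a
weighted Gaussian-product 2-D KDE with per-dimension bandwidth
$n_\mathrm{eff}^{-1/6}$ (the two-dimensional Silverman factor) times the
weighted standard deviation. A lone sample falls back to a unit
bandwidth; a zero-variance dimension is an error suggesting a rug plot.
The weighted two-sample KS test uses effective sample sizes in the
asymptotic Kolmogorov distribution; below $\lambda = 0.27$ the
alternating series is numerically meaningless and the p-value is
reported as 1.

## What the fixtures emulate — and what they do not

`makeGaussianToy()` builds the conjugate toy (model $y = \theta + \xi$,
$\xi \sim N(0,1)$, prior $\theta \sim N(0,1)$, observed $y = 1$) whose
exact posterior $N(0.5, 0.5)$ is the engine's primary oracle.
`makeViralFixture()` generates observed data from *one stochastic draw*
of the viral model at the reference setting — the well-specified case: the
inference model is exactly the data-generating process. Real applications
face misspecification, observation noise with unknown structure, and
summary statistics chosen before seeing the model; passing the recovery
tests therefore shows the machinery is correct and calibrated under
well-specified conditions, not that any particular biological dataset
would be fit well. `makeInvalidCorpus()` produces six bundles each
violating exactly one validation rule.

With the fixture's modest signal (a plaque reaching ~40 infected cells
out of 2500, one realisation, 16 summary components), the two
transmission rates are only weakly identified: posteriors concentrate
relative to the two-decade priors but remain wide, and the distances
bottom out at the model's intrinsic stochastic noise floor — visible as
acceptance rates collapsing once $\varepsilon$ approaches the expected
self-distance at the truth. This is the honest behaviour of ABC on a
stochastic model; the recovery criterion is interval coverage, which is
insensitive to the exact stopping generation.

## Study sizes used by the tests

The automated experiments use: $N = 1000$, $\alpha = 0.5$, stop at
$\varepsilon \le 0.1$ for the conjugate toy (closed-form check of the
posterior mean and variance); $N = 2000$ for the one-generation
rejection-ABC equivalence at fixed $\varepsilon = 0.4$; and ten repeat
recovery runs at $N = 500$, four generations, pilot 100 on the
$50 \times 50$ viral fixture — sizes chosen so the whole battery runs on
one CPU in minutes while keeping Monte-Carlo error well inside the
asserted tolerances. Production analyses would use larger populations and
more generations; nothing in the engine is specific to these sizes.

## Known limitations

* Square lattices with 4-neighbourhoods only; no hexagonal or 3-D
  support, and no intracellular ODE/SDE sub-models.
* The adaptive distance assumes summary scales are meaningfully estimated
  from ~100 pilot simulations; with fewer, weights are noisy.
* `normal` priors are unbounded, so the support-redraw step never rejects
  for them; truncated priors are not implemented.
* The scheduling backend is an in-process emulation; real distributed
  deployment (brokers, worker fault tolerance across machines) is out of
  scope, though the contract is designed for it.
* Exact (noise-augmented) ABC and model selection across competing models
  are not implemented.
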