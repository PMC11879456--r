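---
title: "Modelling signalling time courses with the retarded transient function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling signalling time courses with the retarded transient function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtfmod)
```

## The model

Cellular signalling responses to a stimulus typically rise after a delay and
then either settle at a new steady state, or peak and relax. The retarded
transient function (RTF) captures both behaviours phenomenologically as the
sum of a *sustained* and a *transient* component plus an offset:

$$R(t) \;=\; \mathrm{sign}_{sus}\, A\,(1 - e^{-\alpha t})
\;+\; \mathrm{sign}_{trans}\, B\,(1 - e^{-\beta t})\, e^{-\gamma t} \;+\; b,$$

where $A,B \ge 0$ are amplitudes, $\alpha$ the sustained rate, $\beta$ and
$\gamma$ the transient rise and decay rates, and the signs allow activating
or inhibiting components. The argument $t$ is not raw time but a
*retarded* (delayed) transform of the experimental time axis,

$$t(t_{real}, \tau) = \log_{10}\!\big(10^{\,t_{real}\cdot 10/T} + 10^{\tau}\big)
 - \log_{10}\!\big(1 + 10^{\tau}\big),$$

with $T$ the range of the measurement times. The transform maps
$[0, T]$ to roughly $[0, 10]$, is exactly zero at $t_{real} = 0$, strictly
increasing, and tends to the linear rescaling $t_{real}\cdot 10/T$ as
$\tau \to -\infty$; larger $\tau$ delays the onset of the response. All
rates act on the transformed axis, so they are per transformed-time unit.
We evaluate the transform in max-shifted form so that large exponents
cannot overflow.

### Dose dependence

To describe responses measured at several doses $d$, every kinetic
parameter becomes a Hill curve
$H(d) = M d^h / (K^h + d^h)$ with maximum $M$, Hill coefficient $h$ and
half-maximal dose (EC50) $K$. Amplitudes and rates increase with dose;
the time shift $\tau$ decreases, which we parameterize with the reversed
Hill curve $\tau(d) = M_\tau K^{h}/(K^{h} + d^{h})$ so that
$\tau(0) = M_\tau$ and $\tau(\infty) = 0$, keeping the same triple
semantics. The reversed form is this package's choice — a decreasing,
bounded, smooth curve expressed with the standard $(M,h,K)$ triple; any
alternative decreasing law could be substituted without affecting the rest
of the machinery. At $d = 0$ all amplitudes vanish; the rates, which are
then without effect, are clamped to $10^{-10}$ so their positivity
invariant survives.

## Fitting

Parameters are estimated jointly by maximum likelihood. With residuals
$\Delta_i$ and per-point noise $\sigma_i$ the objective is

$$-2\ln L = \sum_i \left[\ln(2\pi\sigma_i^2) + \Delta_i^2/\sigma_i^2\right].$$

If the table carries a `sigmaExp` column the $\sigma_i$ are taken as known;
otherwise a single free $\sigma$ is estimated with everything else. At any
fixed kinetic parameters the optimal $\sigma$ has the closed form
$\hat\sigma^2 = \overline{\Delta^2}$, so the fitter finishes with this
profile update followed by a polish run — the stationarity relation then
holds to high accuracy at every optimum.

Optimization uses bounded quasi-Newton (`L-BFGS-B`) with the *analytic*
gradient of the objective, derived in closed form through the chain rule of
the time transform and, in dose mode, the Hill curves. Tests verify the
gradient against central finite differences at random feasible points.
Positive scale-spanning parameters (rates, $\sigma$, Hill $h$ and $K$, and
the $M$ of rate parameters) are optimized on $\log_{10}$ scale.

Default bounds are scale-free in the data's units (`ry` is the observed
response range): amplitudes in $[0, 2\,\mathrm{ry}]$, rates in
$[10^{-2}, 10^2]$, $\tau \in [-2, \max(t)\cdot 10/T]$, offset within one
range beyond the observed extremes, $\sigma \in
[10^{-4}\mathrm{ry}, \mathrm{ry}]$, $h \in [0.1, 10]$ and $K$ spanning the
observed doses a decade outwards. All are user-overridable.

### Multi-start strategy

The likelihood surface of exponential sums is multi-modal, so each fit runs
many local optimizations: the data-derived default guess first, then a
seeded Latin-hypercube sample of the bound box (log-uniform along
log-scaled axes). When signs are `"auto"` the four sign combinations are
enumerated, splitting the start budget equally. The sorted final
objectives form the waterfall diagnostic: a plateau at the minimum
indicates the global optimum was found repeatedly.

Two refinement stages follow. A seeded *basin-hopping* polish perturbs the
incumbent best (Gaussian hops of 10–50% of the box width alternating with
uniform re-draws of a few coordinates) and re-optimizes, keeping
improvements; in our experiments plain multi-start at realistic budgets
leaves a substantial fraction of runs in side basins dozens of likelihood
units above the optimum, and the hop stage recovers most of them at small
cost. Second, [fit_collection] adds a cross-course pass: because all
courses of a collection share one sampling design, their optimal objectives
concentrate, and a course far above the collection median is a flagged
multi-start miss that is refitted warm-started from the best-fitting other
courses' solutions.

### Identifiability, honestly

Two facts shape what fitted RTF parameters can and cannot mean.

First, an **exact symmetry**: writing the model as
$R = (A + b) - A e^{-\alpha t} + B e^{-\gamma t} - B e^{-(\beta+\gamma)t}$
(positive signs), one sees that when $A = B$ the exchange
$\alpha \leftrightarrow \beta + \gamma$ produces *identical* curves. On the
$A = B$ manifold the parameters are not identifiable even from noise-free
data. The simulation defaults therefore keep the amplitudes distinct
(`default_rtf_truth()` uses $B = 1.5$, $A = 1$), and a strictly
sustained-only truth ($B = 0$) — which admits exact re-representations with
an active transient — is avoided wherever fitted *parameters*, rather than
likelihood values, are the quantity of interest.

Second, **sloppiness**: away from exact symmetry the likelihood is still
extremely flat along combinations of rates and amplitudes, the classic
behaviour of exponential-sum models. At, say, 21 points and 1% noise the
Fisher information gives asymptotic relative standard errors above 100% for
several parameters. Precise per-parameter recovery at such conditions is
impossible for *any* estimator — not an implementation defect; the
corresponding acceptance checks in the test suite document the achieved
rates rather than hiding them. What remains well-determined are the fitted
curve itself, likelihood differences between nested models (the basis of
model reduction), and coarse dynamic classes.

## Model reduction

`reduce_model()` performs backward elimination with likelihood-ratio tests.
Candidates remove a whole feature at a time; because dropping an amplitude
leaves its rates unidentifiable, those are frozen jointly and the
$\chi^2$ degrees of freedom count every removed parameter: transient
($B = 0$ with $\beta, \gamma$ frozen, df 3), sustained ($A = 0$ with
$\alpha$ frozen, df 2), retardation ($\tau = 0$, df 1) and offset
($b = 0$, df 1); in dose mode the removals act on whole Hill triples
(df 3 per triple) and each Hill coefficient can also be tested against 1.
Per round every candidate is refitted (warm-started from the surviving
fit, with fresh multi-starts, signs kept fixed so models stay nested) and
the candidate with the largest p-value is accepted if $p \ge \alpha$
(default 0.05), ties going to fewer df. $\sigma$ is never a candidate.

One consequence of sloppiness deserves note: for data whose truth is
sustained-only, the delay and the transient can partially substitute for
one another in the *full* model, so the greedy largest-p order sometimes
removes the retardation first, after which the transient — now carrying
the delay — survives the test. The final model then has the same number of
parameters and an equivalent fit, but a different structure than the
generating one. This is a property of backward elimination on a flat
likelihood, not of the test statistic; the calibration of the individual
LRT is verified separately in the suite.

## Low-dimensional representation of many fits

`low_dim_rtf()` fits every course of a collection, assembles the matrix of
fitted parameters (plus the resolved signs as $\pm 1$ columns), z-scores
each column (rates on $\log_{10}$ scale), embeds the standardized matrix in
2-D and clusters it with k-means. Clustering operates on the standardized
parameters, not on the 2-D coordinates — clusters then reflect kinetics and
the embedding is display-only. When `k` is not given it is chosen by mean
silhouette width over $k = 2..\min(10, n-1)$. Cluster summaries report the
25th/50th/75th percentiles (type-7) of each parameter, and per-cluster
dynamics are drawn unscaled and min-max scaled (constant curves map
to 0.5).

Standardization uses a variance floor: a column whose spread across
courses is below 10% of its own typical magnitude varies only by fitting
noise, and plain unit-variance scaling would blow that noise up into
order-one coordinates that drown the informative parameters — visible as
spurious displacement of paired courses whose dynamics did not change.

For the embedding the default is PCA of the standardized matrix: the
workflow compares displacement *magnitudes* between paired conditions, and
a metric projection keeps those comparisons meaningful. Non-metric
multidimensional scaling (`vegan::monoMDS`, initialized from classical MDS
so the result is deterministic) is available for display purposes; being
rank-based it can unfold nonlinear structure but inflates small distances,
so it is not used for shift ranking by default. Identical parameter rows
map to coincident points under both.

Paired courses (the same molecular entity under two conditions) can be
connected in the embedding, and `condition_shift()` ranks pairs by their
2-D displacement — the entities at the top are those whose dynamics the
perturbation changed most.

## What the generator emulates — and what it does not

`sim_timecourse()` emulates a single experimental time course: by default
21 points on $[0, 10]$, Gaussian noise with sd 0.02, and the
default truth above (visible sustained plus dominant transient). Dose mode
uses 11 points at each of 5 doses (1.25–20) with all EC50s at the
mid-ladder dose 5 and Hill coefficient 2.

`sim_collection()` emulates the embedding's primary input: a collection of
*trajectories extracted from a simulated pathway model*, i.e. densely
sampled (41 points) and nearly noise-free (sd $10^{-4}$, the scale of a
solver tolerance), with a sustained-dominant class ($A = 1, B = 0.3$) and a
transient-dominant class ($A = 0.2, B = 1.5$) and optional paired
conditions. This matters for interpreting the tests: with sparse, noisy
*experimental* collections the fitted parameter vectors of one class
scatter across near-tied likelihood basins and parameter-space clustering
degrades — a limitation of the approach itself that users should expect on
such data. Passing embedding tests demonstrate the trajectory regime, not
the sparse noisy one.

Test problem sizes were chosen to exercise the full pipeline at moderate
cost: recovery studies use 20 replicates of 21-point (single-dose) or
55-point (dose) datasets with 50 starts; calibration uses 100 replicates at
10 starts; embedding studies use 20 courses per collection at 10 starts.

## Numerical choices and degenerate inputs

* Transform evaluated in max-shifted base-10 log-sum form; $t(0) = 0$ is
  exact by construction.
* Optimizer tolerance `factr = 1e7` (about $2\times10^{-9}$ relative),
  `maxit = 1000` per start; every source of randomness flows from one
  integer seed through a documented derivation, so fits, fit files and
  embeddings are bit-reproducible.
* Constant-`y` data are fitted after a warning (expected outcome
  $A \approx B \approx 0$); zero dissimilarity collections embed to a
  single point; constant curves min-max scale to 0.5.
* Negative LRT statistics from refit noise are clamped to zero.
* Fit files are JSON at 17 significant digits, so write/read round-trips
  are bit-exact.

## Limitations

* No parameter uncertainties (profile likelihood is the natural next
  step); point estimates of sloppy parameters should not be
  over-interpreted — see the identifiability section.
* Gaussian, independent noise only; `sigmaExp` covers known per-point
  errors but there is no replicate-aware error model.
* The dose layer assumes monotone Hill dependencies with a single shared
  sign pair per fit.
* Model-reduction structure recovery is reliable only where the data
  actually separate the components (see above); the likelihood-based
  decisions themselves remain calibrated.
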