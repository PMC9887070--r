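---
title: "Models and methods behind regimap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind regimap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regimap)
```

`regimap` chains four statistical stages over banded registry tables:
direct age standardization, segmented trend estimation, an age–period–
cohort (APC) decomposition identified by a constant-relative-variation
(CRV) rule, and stabilized kriging of small-area risk. This vignette is
the package's account of those methods: the models and their assumptions,
the tunable parameters and their defaults, the numerical choices, and what
the synthetic validation scenarios do and do not demonstrate.

## Rates and standardization

Age-specific rates are `r_a = 10^5 O_a / P_a` per 100,000 person-years on
5-year bands with inclusive integer bounds (registry tables are banded;
half-open notation appears only in documentation). Direct standardization
uses the WHO 2000 world standard (18 bands 0–4 … 85+), shipped as a
fixture table and re-normalized over the analysis age range — needed
because the APC analysis restricts to ages 30–84. The ASR variance is the
Poisson delta-method form `Σ w_a² r_a 10^5 / P_a`; intervals use the gamma
approximation, standard registry practice for low counts. Indirect
standardization applies reference age-specific rates (by default the last
five data years, configurable) to each area's person-years to get expected
counts `E_i`, and `SIR_i = O_i / E_i`.

Two conventions matter downstream:

* **SIR variance floor.** `var(SIR_i) = max(O_i, 1) / E_i²`. The
  delta-method Poisson variance is `O_i / E_i²`, which is zero for
  zero-count areas; the one-case floor gives them a finite, large variance
  so shrinkage and kriging treat them as very noisy rather than perfectly
  precise. Shrinkage therefore operates on the raw SIR scale, not the log
  scale, so `SIR = 0` needs no continuity correction.
* **Conservation.** When the reference rates are computed from the pooled
  study population itself and the observation window equals the reference
  window, the person-years-weighted expected counts reproduce the observed
  total exactly, so the pooled SIR is 1 to machine precision. The test
  suite asserts this to 1e-12 on synthetic data.

## Trends: segmented Poisson regression and AAPC

Annual count series are modelled as continuous piecewise log-linear:
`log rate(t) = b0 + b1 t + Σ_j d_j (t − bp_j)_+`, fitted as a Poisson GLM
with log person-years offset (zero counts are unproblematic). Breakpoints
are searched exhaustively over interior integer years with a minimum
segment length of 3 years; the number of joinpoints (default maximum 2
nationally, 1 per area) is selected by BIC in which each breakpoint
location also costs a degree of freedom. The permutation test used by some
registry software is deliberately out of scope: the exhaustive/BIC scheme
is deterministic, desk-scale, and testable against a closed-form oracle. A
weighted-least-squares fit on log rates (`method = "wls"`, weights
proportional to counts) is provided to mimic that software's model form;
whether AAPCs are computed on count series with offsets (default) or on
log-ASR series is a user choice, both being defensible readings of common
practice.

The average annual percent change over `[t0, t1]` is
`100(exp(Σ_j w_j β_j) − 1)` with `β_j` the per-segment slopes and `w_j` the
fraction of the interval each segment covers; its interval is normal on
the log scale using the slope covariance from the GLM. Two properties are
worth stating precisely, because the tests rely on them: slopes (hence
AAPC at fixed segmentation) are exactly invariant to rescaling counts and
person-years by a common constant, but the BIC *selection* is not —
evidence for a joinpoint grows with counts, as it should. Per-area series
can produce degenerate maximum-likelihood fits (a near-empty final
segment with an enormous slope); these are legitimate MLEs with enormous
variances, and the spatial stage is designed so they are harmless (see
below).

## The APC decomposition and the CRV rule

On the A×P grid (defaults mirror the 11 age bands 30–84 × 4 periods of a
20-year analysis, giving 44 cells and A+P−1 = 14 cohorts), cohort index
`c = p − a + (A−1)` and cohort median birth year = period midpoint − age
midpoint, which for 1997–2016 / 30–84 yields the sequence 1917, 1922, …,
1982. Cells are Poisson with log person-years offset and log-rate
`μ + α_a + π_p + γ_c`, all effect sets zero-sum coded.

**Identifiability.** Because `c = p − a + const`, the design has a
one-dimensional null space: adding `(−δ·a, +δ·p, −δ·c)` (centered scores)
to `(α, π, γ)` changes no fitted rate. A consequence worth spelling out:
a reallocation that touches only period and cohort — `π + δ(p − p̄)`,
`γ − δ(c − c̄)` — changes fitted log-rates by `δ(a − ā)`, an age-linear
term, so exact invariance *requires* the compensating
`α − δ(a − ā)`. `drift_reallocate()` therefore adjusts all three; fitted
rates and the Poisson deviance are then invariant to machine precision
(asserted in tests), while curvatures (second differences of π and γ) and
the net drift are invariant by construction.

**Reference fit.** The internal reference constraint assigns all drift to
cohort: the period design is the orthogonal-polynomial curvature basis
(zero sum *and* zero linear trend; for P = 2 this forces a null period
effect), age and cohort use zero-sum contrasts. The fit is plain IRLS via
`glm.fit`; non-convergence is a hard error.

**The CRV rule.** Relative variation of an effect set is defined here as
the coefficient of variation of the exponentiated effects — population SD
of the rate ratios divided by their mean. It is dimensionless and
invariant to adding a constant on the log scale, matching the intuition
that "relative variation" lives on the rate-ratio scale; this definition
is a package choice among several the term could support, which is why
`solve_crv()` returns the full δ-profile of both RVs for inspection. The
CRV solution is the δ* at which `RV(π(δ)) = RV(γ(δ))`, found by bracketed
root search (`uniroot`, bracket between the two pure allocations, padded,
then widened in bounded steps for near-null structures; tolerance 1e-8 on
the RV gap). Degenerate and ambiguous cases are handled explicitly rather
than silently: an exactly-null period/cohort structure returns the
drift-free solution; if the bracket contains several balancing roots, or
none, the solver fails with the candidate locations listed. The
point-estimate balancing rule is used rather than a full random-effects
likelihood: it is deterministic, reproduces the qualitative behaviour
(deterministic age curve, stochastic period/cohort with equal relative
variation), and is testable by parameter recovery.

Confidence bands for the effect curves come from a parametric bootstrap
(Poisson resampling of cell counts around the fitted means, CRV refit per
replicate, default 200 replicates, fixed seed).

## Stabilized disease mapping

Per-area indicators (SIR with null 1, AAPC with null 0) are stabilized in
two coupled senses.

1. **Empirical-Bayes shrinkage.** The between-area variance τ² is
   estimated by a precision-weighted moment equation about the null
   (the DerSimonian–Laird form with known mean):
   `τ² = max(0, (Σ w_i (v_i − m0)² − n) / Σ w_i)` with `w_i = 1/σ_i²`.
   Precision weighting is essential: a handful of areas with enormous
   sampling variance (tiny populations, degenerate trend fits with
   variances around 1e13) would drive the unweighted estimator to zero and
   collapse the whole map. For equal variances the estimator reduces to
   `mean((v − m0)²) − σ²`, and for all-zero variances to the empirical
   variance about the null. Stabilized values are
   `z_i = m0 + w_i (v_i − m0)` with `w_i = τ²/(τ² + σ_i²)`; they are
   reported per area and used for area classification.

2. **Joint kriging of the raw values.** The mapped surface is ordinary
   kriging of the *raw* values with the full heteroscedastic sampling
   variance `σ_i²` added to the data–data diagonal only (measurement error
   does not propagate to data–prediction covariances; weights sum to 1).
   This one linear predictor performs shrinkage and spatial pooling
   simultaneously: a high-variance area is trusted little and its
   prediction moves to the neighborhood level — toward the null when the
   surroundings are unremarkable — while a low-variance area is honored
   nearly exactly. The alternative two-stage scheme (krige the shrunken
   values with the residual uncertainty `w_i σ_i²`) is available as
   `error_mode = "twostage"` but is not the default: the shrunken values
   are already attenuated by `w_i`, kriging them with an error term
   attenuates again, and in simulation the two-stage surface sometimes
   recovers the true field *worse* than the raw SIR map, whereas the
   joint predictor beat the raw map at every seed tried. This choice is
   the package's resolution of a genuinely open design point.

**Variography.** The exponential model
`γ(h) = c0 + c1(1 − exp(−h/φ))` is the default (spherical available),
fitted by Cressie-weighted least squares (`N_k / γ(h_k)²`) with
nonnegativity constraints, multi-start on the range, and `optim`
parameter scaling. The empirical (Matheron) semivariances are computed
from the *stabilized* values — robust to infinite-variance areas — and
corrected before fitting: the mean residual noise `mean(w_i² σ_i²)` is
subtracted (the variogram of noisy data estimates signal plus mean error
variance, and noise must not be counted twice given the `σ_i²` diagonal),
and the mean shrinkage attenuation is undone by dividing by `mean(w)²`.
Distances are Euclidean in the declared projected CRS; no reprojection is
performed. Prediction grids are clipped to the polygon union
(`mgcv::in.out`); default resolution 1 CRS unit, configurable.

**Classification and rendering.** Surfaces and areas are classified
above/near/below the null with a symmetric band — relative
(`m0(1 ± t)`, default t = 0.05) for ratio indicators, absolute (`±t`) for
AAPC — and rendered as red/white/blue maps with contour lines at
`m0·{0.8, 0.9, 1, 1.1, 1.25}` (SIR) or `{−2, −1, 0, 1, 2}` percent
(AAPC), all configurable. Areas excluded from kriging input (no cases, or
unestimable trend) are drawn grey. Rendering is deterministic in the
plotted data; the determinism tests assert the numeric surface and
classes, not PNG bytes, which depend on the graphics device.

## The synthetic registry: what it emulates, and what not

`generate_registry()` draws
`O ~ Poisson(N_{iat} · exp(μ + α_a + π_p(t) + γ_c(a,t) + u_i + θ_i(t − t̄)))`:
a log-additive age curve, period and cohort structure applied at 5-year
bands, an area-level Gaussian log-relative-risk field `u` sampled by
Cholesky factorization of the exponential-variogram covariance, and a
small per-area trend perturbation θ (SD 0.005 per year) so area AAPCs vary
spatially. Person-years are log-normal per area (median 20,000 per area,
year and sex; sdlog 0.6), with a fixed, gently declining adult age
structure, constant over years.

Default scenario choices, made once: 18 × 17 = 306 unit-square areas
(matching the ~300-area scale of a national small-area analysis), years
1997–2016 in four 5-year periods, eleven age bands 30–84, field parameters
c0 = 0.005, c1 = 0.09, φ = 4 lattice units (area-level relative risks
mostly within ±1.8-fold, spatially coherent over a few neighbors), and
four strata combining male/female with a rising adenocarcinoma-like
(cohort drift +0.04/+0.05 per band) and a falling squamous-cell-like
(−0.03) trend; base rates 1.8e-4, 1.2e-4, 1.5e-4 and 3e-5 per person-year
put crude rates in the tens per 100,000. `make_crv_effects()` builds the
truth *under the CRV condition*: the period shape (slope sharing the
cohort drift's sign, plus curvature) is rescaled by root search until its
relative variation equals the cohort set's, so the estimator's identifying
assumption holds exactly in the generator and parameter recovery is a
meaningful test.

The grid-level validation scenario (`generate_apc_grid()`) uses 1e9
person-years per cell with rate scale 4e-4. That size was chosen by a
power calculation, not realism: the extreme cohorts are identified by a
single cell each, so holding the maximum absolute effect error under 0.02
on the log scale requires the lowest-rate cell (young age, ≈2e-5 per
person-year under the ~150-fold age curve) to carry an expected count
above ~2×10⁴, i.e. a cell log-rate standard error below 0.007. The
recovery tests demonstrate *estimator correctness* in the large-sample
limit; they say nothing about CRV behaviour at realistic registry counts,
where the identifying assumption itself, not sampling error, dominates.

What the generator does **not** emulate: real geography (areas are a
lattice; real adjacency and population are far more irregular),
registry quality artifacts (late registration, death-certificate-only
cases, histology misclassification), demographic change (the age
structure is frozen), and any exposure covariates. Passing tests
demonstrate internal consistency and estimator correctness under the
stated model, not epidemiological conclusions about any real population.

## Numerical choices and degenerate inputs

* Poisson fits muffle the non-integer-count warning: noise-free
  validation grids legitimately carry expected counts.
* `solve_crv` tolerances: 1e-8 on the RV gap, `uniroot` tol 1e-12;
  bracket widening is bounded at |δ| = 1 log per band.
* Kriging refuses coincident data centroids (singular system) with the
  cause named; kriging variances are floored at 0 against roundoff.
* Zero-count areas are excluded from AAPC kriging input with an
  aggregated warning, and drawn grey on maps.
* A zero-variance spatial field (`c0 = c1 = 0`) short-circuits to a flat
  field rather than a failed Cholesky.
* All generator and pipeline randomness derives from one master seed via
  named substreams (`child_seed`), so stages are reproducible
  independently of execution order.

## Problem sizes in the shipped tests

The test and acceptance runs use the default 306-area scenario (one
stratum where only one is needed), the 1e9-person-year validation grid,
and small lattices for I/O and pipeline smoke tests; the complete suite
runs in well under a minute on a single core. These sizes are the
package's validation design: large enough for the asymptotic checks to be
sharp, small enough that every check reruns on every change.

## Known limitations

* The CRV definition (CV of exponentiated effects) is one reasonable
  reading of "constant relative variation"; others (e.g. variance
  components of a hierarchical model) would give different allocations.
  The δ-profile diagnostic exists precisely so users can see how sensitive
  conclusions are to the allocation.
* Joinpoint selection by BIC can differ from permutation-test software on
  the same series, particularly for short noisy series.
* Kriging is performed on area centroids, ignoring area shape and size
  (no polygon-averaged covariances); with very uneven area sizes the
  centroid approximation coarsens.
* The mapping stage assumes a planar projected CRS; it performs no
  reprojection and no great-circle corrections.
* Fully Bayesian disease-mapping alternatives (BYM/CAR models) and
  covariate regression are out of scope.
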