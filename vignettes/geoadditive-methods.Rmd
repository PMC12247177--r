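---
title: "Methods: Bayesian geo-additive modelling of areal ANC utilization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian geo-additive modelling of areal ANC utilization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ancspatial)
```

## The problem

Utilization of recommended antenatal care (at least four contacts with a
skilled provider under the pre-2016 WHO guideline, at least eight under
the 2016 revision) varies enormously across sub-Saharan Africa, from
under 1% to over 76% of surveyed women per country. Neighbouring regions
share infrastructure, culture and policy, so the indicator is spatially
autocorrelated, and community-level risk factors (media exposure,
facility delivery, wealth, distance to care, ...) often act
non-linearly. This package implements the corresponding analysis chain
for areal data: weighted aggregation, spatial dependency testing, and a
geo-additive Bayesian model, with a synthetic-data generator that
reproduces the assumed generative structure so every stage can be
validated without restricted survey microdata.

## Aggregation conventions

A group's proportion is `100 * sum(events) / sum(sample)`: units enter
with weight proportional to their survey sample, which makes the pooled
figure exactly the count ratio of the pooled counts. This identity —
pooled value equals the sample-size-weighted mean of subgroup values —
is asserted in the tests. Display rounding is half-up to 2 decimals
(`round()`'s banker's rounding would disagree with conventionally
printed tables on exact ties); full precision is always retained
internally. Survey years up to 2016 are labelled "Before 2017" and 2017
onward "After 2017 (included)", because fieldwork through 2016 measured
the four-contact recommendation and later fieldwork the eight-contact
one.

The packaged 34-country table carries a sub-regional grouping (West,
East, Southern, Central). Published country tables typically print the
four sub-regional pooled percentages without enumerating membership; the
grouping shipped here is the standard United Nations sub-regional
assignment of these 34 countries, and it reproduces all four printed
sub-regional aggregates exactly, which is the strongest available
confirmation that it is the grouping in use.

## Neighbourhood structure and autocorrelation tests

Three graph constructions are provided. Queen contiguity links polygons
whose boundaries share at least one point; sharing is detected through
coincident vertices and vertex-on-edge incidences (tolerance `1e-8`
coordinate units), which covers valid areal partitions including
T-junctions. Self-intersecting rings are rejected by unit name rather
than silently repaired. k-nearest-neighbour graphs default to `k = 5`
(a common default for admin-level areal analysis; the choice is
configurable because no single k is canonical) and are symmetrised by
union, so minimum degree ≥ k; distance ties are broken deterministically
by node label order. Distance-band graphs default to an automatic
threshold — the largest nearest-neighbour distance — the smallest band
that leaves no unit isolated; smaller bands warn and list isolates
rather than failing.

Weight matrices default to binary style because the closed-form
moments of Moran's I and Geary's C are stated for general `w_ij` with
`S0 = sum w_ij` appearing explicitly, and binary weights keep the
worked examples hand-checkable; row-standardization is a flag. The
diagonal is identically zero by convention.

Both tests report the estimate, the null expectation (−1/(N−1) for I,
exactly 1 for C), a closed-form null variance, z-score and a two-sided
analytic p-value, plus an optional permutation p-value with the add-one
estimator `(1 + #extreme) / (n_perm + 1)` (default 999 permutations).
The randomization (permutation-consistent) variance is the default
assumption since it matches the permutation null that the seeded
Monte-Carlo machinery produces; agreement of the analytic variance with
the empirical permutation variance is the central correctness oracle in
the test suite. Note the standard reading of Geary's C is used
throughout: C below 1 means positive spatial autocorrelation (small
squared differences between neighbours), C above 1 negative — some
secondary descriptions of C garble this, so the package documentation
states it explicitly. For C the "greater" alternative is oriented so
that it means *greater positive autocorrelation* (C below its
expectation), keeping the two tests' one-sided alternatives aligned in
meaning.

## The response transform

The model is Gaussian with an identity link, so bounded, skewed
proportions are first passed through a normalizing transform. Of the
usual candidate families (Box–Cox, Yeo–Johnson, ordered quantile), only
the ordered-quantile (rank inverse-normal) transform is defined for
arbitrary bounded data without tuning, and it is deterministic — so it
is the one implemented: rank r maps to
`qnorm((r - c) / (n - 2c + 1))` with offset `c = 0.5` (the variant that
sends the median of an odd-length tie-free sample exactly to 0);
`c = 0.375` (Blom) is available for sensitivity analysis. Ties share
their average rank. Between observed values the transform interpolates
linearly and beyond the range it extrapolates linearly from the two
extreme support points, making it monotone and exactly invertible
everywhere — the inverse is needed to report fitted values back on the
proportion scale. Which transform the original ANC analysis selected is
not recoverable from the publication; the ordered-quantile choice is
recorded here as the package's own default.

## The geo-additive model

On the transformed scale, for unit i,

y_i = X_i β + Σ_j f_j(x*_ji) + u_i + v_i + ε_i

* **X_i β** — linear fixed effects with independent N(0, 1000²) priors.
  Covariates are standardized to mean 0, sd 1 before design
  construction; summaries are transformed back to the original
  covariate scale.
* **f_j** — nonlinear smooths. Each smooth covariate is cut into
  `n_bins = 20` equal-width bins over its observed range (empty bins
  merged into the nearest occupied bin), giving a one-hot incidence
  matrix, and the bin coefficients get a second-order random-walk (RW2)
  penalty K = D2ᵀD2 of rank B−2, the discretized analogue of penalizing
  curvature. 20 bins resolves the smooth shapes used in the simulation
  studies while keeping at least a handful of observations per bin at
  the lattice sizes considered. Merged bins are treated as equally
  spaced in the penalty; with ≥ 4 occupied bins required this
  approximation is mild.
* **u** — structured spatial field with the intrinsic CAR prior: each
  u_i is conditionally Gaussian around the mean of its neighbours with
  precision τ_u·n_i, i.e. joint (improper) precision τ_u(D − A). The
  classic BYM parameterization (u + v entered additively) is used, not
  the rescaled BYM2, because the model is specified and interpreted in
  the classic form.
* **v** — exchangeable heterogeneity, v_i ~ N(0, 1/τ_v).
* **ε** — observation error, ε_i ~ N(0, σ_ε²).

All precisions (τ_ε, τ_u, τ_v and one τ_j per smooth) carry Gamma(1,
5e-5) priors — the conventional weak default for latent Gaussian
spatial models; priors are configurable per precision.

The variant ladder mirrors standard model building: `linear_fixed`
(β only), `additive_fixed` (adds smooths), `additive_iid` (adds v),
`bym` (adds u and v).

## Gibbs sampler

Every full conditional is conjugate: Gaussian for the effect blocks
(β; each f_j; u; v) and Gamma for each precision, with shape increased
by half the rank of the corresponding structure matrix (N for τ_ε and
τ_v, N − #components for τ_u, B_j − 2 for each τ_j) and rate increased
by half the corresponding quadratic form. Blocks are updated
sequentially each sweep; the u-update is accelerated by caching the
eigendecomposition of D − A once, so each draw costs two dense
matrix–vector products instead of a fresh factorization.

Two design points matter for correctness:

1. **Identifiability.** The iCAR prior is flat along each graph
   component's constant vector and the RW2 prior along the constant (and
   linear) bin directions, all confounded with the intercept. After each
   sweep u is recentred to mean zero per graph component and each f_j to
   mean zero, with the subtracted mean absorbed into the intercept —
   equivalent in distribution to constrained sampling for this model
   class, and it makes every retained draw satisfy the sum-to-zero
   constraints exactly. A unit that is its own component (an isolated
   node) is thereby constrained to u_i = 0, which also makes a BYM fit
   over an edgeless graph collapse exactly to the i.i.d. variant.
2. **The v/ε ridge.** With one Gaussian observation per unit, v_i + ε_i
   is only jointly identified; naive sequential Gibbs freezes when τ_ε
   drifts large (v absorbs the residual and the β-update conditions on
   it), which in simulation destroyed the frequentist calibration of
   the β intervals. The sampler therefore marginalizes v out of the β,
   smooth and u updates — their effective noise is w = v + ε with
   precision (1/τ_v + 1/τ_ε)⁻¹ — and redraws v from its own conditional
   afterwards (a partially collapsed Gibbs scheme). v is never
   conditioned on between its marginalization and its redraw, so the
   stationary distribution is unchanged; with the collapse, credible
   intervals for β achieve nominal coverage in the recovery study
   below.

Divergent precisions (non-finite or above 1e15) abort with a
diagnostic rather than producing silent garbage. A seed is mandatory;
fits are bit-reproducible given (data, spec, controls, seed). Default
controls are 10,000 iterations, 2,000 burn-in, thinning 2.

The sampler's correctness is tested along two independent routes: the
closed-form conjugate posterior for the linear sub-model with pinned
error precision, and a brute-force oracle that draws (β, u, v) in one
dense constrained joint Gaussian block (constraint imposed by
conditioning-by-kriging) with its own Gamma updates — the two samplers'
posteriors agree within Monte-Carlo error on small lattices. The iCAR
conditional-mean property (slope ≈ 1 of u_i on its neighbour mean in a
prior-dominated fit, ≈ 0 against a shuffled graph) is checked as well.

## Model comparison and calibration diagnostics

All criteria are computed from the S × N pointwise predictive
log-likelihood matrix. The predictive *focus* excludes a unit's own
unstructured effect: for variants carrying v the density of y_i under
draw s is N(X_iβ + Σf_j + u_i, 1/τ_ε + 1/τ_v). The reasoning: v_i is
idiosyncratic and unobservable for a new or held-out observation at
unit i, and under a Gaussian likelihood a conditional-likelihood focus
lets v interpolate the data, collapsing DIC/WAIC/CPO into rewarding
pure memorization (the i.i.d. variant would "win" on spatially
structured truth with pD of the order of N). The structured field u is
retained in the predictive mean since neighbours inform it. For
variants without v the focus coincides with the plain conditional
likelihood.

* **DIC** = D̄ + pD, pD = D̄ − D(θ̄), plug-in at the posterior-mean
  predictive mean and posterior-mean predictive variance. Negative pD
  is reported with a warning, never clipped.
* **WAIC** = −2(lppd − pWAIC), lppd via log-sum-exp, pWAIC the sum of
  per-observation draw variances of the log-density (sample variance,
  denominator S − 1); observations with variance above 0.4 trigger a
  reliability warning.
* **CPO_i** — harmonic-mean estimator of the leave-one-out predictive
  density, computed via log-sum-exp; the reported figure is Σ log CPO_i
  (the magnitude comparable to half a deviance). By Jensen's inequality
  Σ log CPO ≤ lppd, which the tests assert.
* **PIT_i** — posterior-predictive probability of a new observation
  below the observed one, scored against uniformity with a
  Kolmogorov–Smirnov test. This is the conditional (posterior-
  predictive) PIT computable from MCMC draws; it is the same diagnostic
  object in spirit as leave-one-out PIT but not identical, and the
  documentation says so rather than pretending otherwise.

Model ranking is by DIC ascending, ties broken by WAIC ascending, then
by Σ log CPO descending; comparisons across fits computed on different
data are refused outright.

## The synthetic-data generator

`make_scenario()` emulates the generative model on a rows × cols queen
lattice: covariates i.i.d. Uniform(0, 1); smooth effects drawn from a
fixed named library (sinusoid sin(2πx), centred quadratic, ±0.5
changepoint at x = 0.5, flat ≡ 0), each centred over the realized
covariates; u from the iCAR distribution restricted to the sum-to-zero
subspace via eigendecomposition; v i.i.d. Gaussian; and either Gaussian
observation y = η + ε or binomial counts events ~ Bin(n_trials,
logistic(η)). What it deliberately does *not* emulate: real
administrative geographies (lattice cells stand in for provinces),
DHS-style multi-stage cluster sampling and survey weights (handled
upstream of this package in real analyses), and spatially correlated
covariates. Passing calibration on these scenarios therefore
demonstrates correctness of the machinery under the model's own
assumptions, not robustness to the messiness of real survey data.

`make_table2_like()` generates country-style count tables with sample
sizes 1,000–20,000, survey years 2010–2023 and event probabilities
log-uniform on 0.002–0.8, mimicking the very wide spread seen in real
country tables (0.27%–76.28%).

## Study conditions for the calibration checks

The acceptance-level simulation studies run at sizes chosen to finish
in minutes on one CPU while keeping Monte-Carlo error well below the
decision thresholds:

* **Recovery.** 15×15 lattice, β = (1, −0.5), one sinusoid smooth,
  τ_u = 1, τ_v = 10, σ_ε = 0.5; 100 replicates at 900 iterations (300
  burn-in, thin 2). Checked: 95% credible intervals cover the true β in
  95 ± 7% of replicates; mean correlation between the posterior-mean
  smooth curve and the true sinusoid over bin midpoints exceeds 0.9.
* **Selection.** 10×10 lattice with strong structure (τ_u = 0.5,
  τ_v = 20, σ_ε = 0.5); 50 replicates, fitting the linear, i.i.d. and
  BYM variants; the BYM variant must be ranked best in at least 80%.
* **PIT.** 50 well-specified linear-model replicates (n = 100) must
  pass KS uniformity (p > 0.05) at least 90% of the time; replacing the
  Gaussian noise with t₂ noise of matched scale must raise the
  rejection rate far above that baseline.

## Known limitations

* The published province-level autocorrelation estimates and posterior
  summaries for the real 429-province analysis require restricted
  survey microdata and boundary files that are not packaged; those
  numeric values are out of scope here, and the package instead
  validates the machinery by oracle agreement and parameter-recovery
  calibration.
* Inference is exact-model Gibbs MCMC, not a nested-Laplace
  approximation; the posterior is the same object, but run-to-run
  Monte-Carlo noise replaces deterministic approximation error.
* Non-Gaussian spatial likelihoods (binomial/Poisson GLMMs) are not
  fitted; binomial synthetic data is intended to be aggregated to
  proportions and rank-normalized, as in the Gaussian workflow.
* Which covariates enter linearly versus as smooths is fully
  configurable because the split is analysis-specific; the package
  takes no position beyond the examples.
* τ_v and τ_ε are individually only weakly identified (only their
  variance sum is); their separate posteriors should be read with that
  in mind.
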