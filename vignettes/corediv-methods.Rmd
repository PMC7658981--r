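---
title: "Methods: diversity, repeatability and core-collection inference in corediv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, repeatability and core-collection inference in corediv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corediv)
```

`corediv` implements the analysis chain used to characterize in-situ sampled
perennial germplasm — the reference case being a 203-accession collection of
the miracle berry *Synsepalum dulcificum* from seven populations across two
West African ecological regions, the Dahomey Gap (DG) savannah corridor and
the Upper Guinea (UG) rain-forest block. This vignette explains each stage's
model, its assumptions, the tunable parameters, and the design choices made
where the underlying procedure left them open.

## Raw data model and trait derivation

Three raw tables describe a collection. Per accession (an individual tree):
population, region, habitat (home garden vs farm), optional age estimate and
coordinates, and the tree measurements — circumference at ground level (cm),
height (m), and two directional crown diameters (m). Fruit masses are
measured on replicate bulks of 10 fruits (fresh mass and seed mass, g);
fruit length/width (mm) on a per-fruit subsample.

Nine analysis traits are derived, one row per accession:

* `DiamGr` = circumference / pi (cm); `PlHgt` = height (m); `CrDiam` = mean
  of the two crown measures (m).
* `AvFM`, `AvSM`: replicate means of bulk mass / 10 (g).
* `EdRt` = mean over replicates of (FM10 − SM10)/FM10, stored in percent.
  The replicate mean of ratios is used, not the ratio of summed masses — the
  two differ whenever replicate masses differ, and the bulking protocol
  averages per-replicate ratios.
* `AvFL`, `AvFW`: means of all measured fruits; `FrSh` = AvFL/AvFW.

Traits are derived independently; an accession with tree measurements but no
fruit replicates keeps its tree traits and gets missing fruit cells.
Descriptive summaries use the sample (n − 1) SD and CV% = SD/mean × 100.

## Group effects, contrasts, correlations

The field convention "t-test or Mann–Whitney, where relevant" is automated
by a per-group Shapiro–Wilk gate at `alpha = 0.05` (configurable, and
forcible to either branch by `method_policy`): two-level factors get Welch t
or Mann–Whitney U; multi-level factors one-way ANOVA F or Kruskal–Wallis H.
All fitted models are single-factor, so type-II and type-I sums of squares
coincide. The edible ratio is a proportion; rather than a quasi-binomial
GLM — whose denominator is undefined for a mass ratio — the same tests are
applied to logit(EdRt/100), and every output carrying this substitution is
flagged in an `approximation` field.

The ecological-region effect is a linear contrast inside the one-way
population model: mean of UG population means minus mean of DG population
means, `t = L / sqrt(s² Σ cᵢ²/nᵢ)` on N − g residual df. The pipeline only
runs it when the population effect itself is significant, mirroring the
sequential logic of the original workflow; the function itself does not
enforce that gate.

Pairwise correlations use Pearson's r when both traits pass the normality
gate, Spearman's rho otherwise, on pairwise-complete observations. No
multiple-testing correction is applied by default (raw p-values are
reported, as is conventional in this literature).

## SMA allometry

Standardized major axis regression fits the bivariate axis minimizing areas
rather than vertical offsets: slope `b = sign(r)·sd(y)/sd(x)`, elevation
`a = ȳ − b·x̄`. Between regions the tests are sequential:

1. *Common slope*: the likelihood-ratio statistic
   `−Σ nᵢ log(1 − rᵢ(b)²)`, where `rᵢ(b)` is the within-group correlation of
   residual scores `y − bx` with axis scores `y + bx`, minimized over `b` and
   compared to chi-square with g − 1 df. The statistic is exactly zero within
   a group when `b` equals that group's SMA slope (because
   `cov(y − bx, y + bx) = var(y) − b² var(x)`). Besides the bounded
   1-D search, the per-group slopes are always evaluated as candidates:
   with exactly collinear data the profile collapses to a needle that a
   golden-section search can miss.
2. *Elevation shift*, only when the common slope survives at
   `alpha_slope = 0.05`: a Wald statistic on the group means of
   `y − b_common·x`, weighted by group residual variances, again chi-square
   with g − 1 df. Slope-estimation uncertainty is ignored in this Wald step —
   a deliberate simplification that is conservative only mildly at the
   sample sizes involved (n ≥ 30 per region).

## Clustering tendency and multivariate structure

The Hopkins statistic samples `m = max(10, ⌈0.1·n⌉)` probe accessions and m
uniform points over the bounding box of the (internally standardized) data
and compares nearest-neighbour distances: `H = Σw / (Σu + Σw)`.
**Orientation**: H ≈ 0.5 means unstructured, H near 0 means clusterable.
Part of the literature defines Hopkins with the reciprocal orientation
(high = clusterable); this package follows the convention of the source
analyses, and the pipeline output says so next to the number.

PCA is the eigen-decomposition of the trait correlation matrix
(covariance optional) on complete cases, with a deterministic sign
convention (largest-magnitude loading entry positive). Retention policies:
smallest k with cumulative explained fraction ≥ τ (default τ = 0.80, which
retains four components on data shaped like the reference collection),
Kaiser (eigenvalue > 1), or fixed k.

Clustering operates on the retained component scores: Ward linkage
(`ward.D2`) on Euclidean distances, with k ∈ 2..10 chosen by the largest
ratio of successive within-inertia gains — the usual heuristic for
hierarchical clustering on principal components — and an optional seeded
k-means consolidation pass (10 iterations, started from the hierarchical
centroids; kept only if it preserves k non-empty clusters). Cluster
profiles use v-tests,
`v = (x̄_k − x̄) / sqrt(((N − n_k)/(N − 1)) · s²/n_k)` with the *population*
variance s² (the v-test convention), flagging |v| ≥ 1.96. Cluster-by-region
association is a Pearson chi-square without continuity correction, with a
warning when expected counts fall below 5.

## Repeatability

For a replicate-measured trait, repeatability is the among-accession
variance fraction `R = σ²_among / (σ²_among + σ²_within)` from the
random-intercept model `y = Xβ + u_accession + e`, an upper-bound proxy for
broad-sense heritability. "Adjusted" means the provenance population enters
as a fixed effect, so among-population variance is excluded from both the
numerator and the denominator.

The REML fit is exact for this one-random-effect structure: the criterion is
profiled over the variance ratio λ = σ²_among/σ²_within, every term reduces
to per-accession group sums because `(I + λJ)⁻¹ = I − λ/(1 + kλ)·J`, and the
1-D criterion is minimized by bounded search on log λ (tolerance 1e-10, range
e±30); a boundary solution collapses to σ²_among = 0. On balanced designs
without fixed effects the solution coincides with the ANOVA
method-of-moments estimator whenever MSB ≥ MSW (tested to 1e-6), and on
unbalanced designs with fixed effects it matches `lme4::lmer` (an
independent implementation used only as a test oracle).

Uncertainty comes from a parametric bootstrap (default 1000 simulations from
the fitted model on the same design; percentile 95% CI, SD of the bootstrap
estimates as SE). Significance is a likelihood-ratio test of the accession
effect between REML fits with identical fixed effects, with the
boundary-corrected null mixture ½χ²₀ + ½χ²₁.

The edible ratio is handled by `proportion_repeatability()`: Gaussian REML
on logit-transformed proportions, reporting a latent-scale R and flagging
the approximation. A binomial GLMM is not identifiable here — a mass ratio
has no binomial denominator — so the published latent-scale estimate for
this trait is not directly comparable and is not treated as a reference
value. Replicate units are configurable in spirit: mass traits use the
10-fruit bulks, dimension traits the per-fruit subsample (per-fruit ratios
for `FrSh`), via `trait_replicates()`.

## Core collection

Gower distances over the nine traits (all interval-scaled numerics in this
application; categorical columns are supported as 0/1 mismatches for
generality): per-trait absolute difference scaled by the trait's whole-
collection range, averaged over the traits observed in both accessions;
zero-range traits are dropped with a warning.

Selection maximizes the average entry-to-nearest-entry distance
`E-NE(S) = (1/|S|) Σ_{e∈S} min_{e'≠e} d(e, e')`, which spreads the core
across trait space. The search is greedy farthest-point seeding followed by
steepest-ascent single-swap local search until no improving swap exists,
repeated over seeded restarts (default 10; the first start is deterministic,
an endpoint of the largest pairwise distance). The objective trace is
monotone by construction. Against exhaustive enumeration at n = 12, k ≤ 5
the search attains the optimum in ≥ 95% of random instances (tested; 50/50
in the committed runs) and can never exceed it. Core size defaults to a 20%
sampling intensity with round-half-up (203 × 0.2 = 40.6 → 41); floor would
give 40, and round-half-up is the convention that matches how cores of this
collection are sized.

Quality statistics per trait i over m traits, W = whole, C = core:

* CR% (coincidence rate of range) = mean of `R_C/R_W × 100`;
* VR% (variable rate) = mean of `CV_C/CV_W × 100`;
* VD% (variance difference) = mean of `|V_W − V_C|/V_C × 100`;
* MD% (mean difference) = mean of `|M_W − M_C|/M_C × 100`.

The *core-side* denominators in VD and MD are implemented exactly as the
statistics are defined, although whole-side denominators are common
elsewhere. `core_quality_from_summary()` computes the same statistics from
published per-trait cells; when variances are absent they are derived as
`(cv/100 × mean)²` — the bundled reference table omits the published
variance cells deliberately, because for two traits they are internally
inconsistent with the published CVs, while the CV-derived variances
reproduce the published per-trait VD wherever those cells are coherent.
A good core keeps CR > 80%, small MD, and VR/VD large (the core deliberately
over-represents spread). Whole-vs-core trait comparisons reuse the two-sample
machinery (EdRt again on the logit scale); note the whole collection includes
the core — the comparison is intentionally the same one used in practice.

## The synthetic generator

The generator exists so every stage is testable at desk scale without the
raw field data, and its defaults *are* the reference study conditions:
seven populations (19, 67, 67, 11 accessions in DG; 25, 4, 10 in UG; 203
total), three 10-fruit replicate bulks per accession, a five-fruit dimension
subsample, trait means and SDs from the published descriptive table,
UG-vs-DG mean gaps with the published signs (UG: taller trees, heavier /
longer / wider fruits, higher edible ratio; DG: more oblong fruits), sized
so the population-weighted overall means stay at the published values, and
fruit-trait repeatability targets from the published estimates
(AvFL 0.745, AvFW 0.666, AvFM 0.883, EdRt 0.015 on the logit scale).

Structure: accession-level latent trait vectors are multivariate normal with
region-specific means, marginal SDs `sd·sqrt(R)` for replicate-measured
traits (so the *observation-level* SD matches the published one), and a
target correlation matrix (strong published pairs set explicitly, weak ones
at plausible small values; the matrix is repaired to the nearest PSD matrix
and the repair errors out, naming the worst pair, if it moves any entry by
more than 0.1). Replicates add independent Gaussian noise with SD
`sd·sqrt(1−R)`. Positivity is enforced by whole-row rejection sampling; the
edible ratio is generated on the logit scale and back-transformed, which
keeps it in (0,1) and gives the logit-scale repeatability machinery a
coherent generating model. One master seed drives per-population streams
derived from a label hash, so adding a population leaves the others'
draws untouched.

Identifiability forces one derivation: FM10, SM10 and EdRt are functionally
dependent (EdRt = 1 − SM10/FM10), so the generator targets FM10 and
logit-EdRt and derives SM10 = FM10·(1 − EdRt). Consequently `AvSM` and
`FrSh` have *emergent* (not targeted) repeatabilities and correlations. Raw
tree measurements are emitted so derivation recovers the latents exactly:
circumference = latent diameter × π, and the two crown diameters are latent
crown ± a symmetric deviation.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: spatial autocorrelation (coordinates are population
centroids plus jitter), tree age effects (ages are decorative draws),
pedigree or genetic structure, non-Gaussian trait distributions, and
habitat effects on tree traits. Two quantitative caveats are documented and
tested: rejection sampling at the positivity bound attenuates correlations
of traits whose mean sits within ~2 SD of zero (up to ≈ 0.05 for the tree
traits under the reference parameterization), and accession-level *observed*
correlations for low-repeatability traits (EdRt, R = 0.015) are strongly
attenuated by replicate noise relative to the latent targets — the
convergence guarantees hold on the latent values the generator also emits
as ground truth.

## Numerical choices and degenerate inputs

* Variance/SD conventions: sample (n − 1) everywhere except the v-test's
  population variance.
* REML: bounded search on log λ ∈ [−30, 30], tolerance 1e-10; explicit
  boundary comparison at λ = 0; LRT statistic clipped at 0 and an error
  raised if the reduced model beats the full one beyond 1e-6.
* Hopkins: all-identical data raise an error (zero denominators); zero-range
  columns are dropped before standardization; m is capped at n − 1.
* Gower: an accession pair sharing no observed traits is an error; identical
  rows sit at distance 0 and are legal.
* E-NE search: improvement threshold 1e-12; requested size ≥ n returns the
  whole set with a warning; size < 2 is an error.
* evaluate_core: traits constant in the core flag VR/VD as NA with a
  warning rather than dividing by zero.
* Proportions at exactly 0/1 are clamped to ±1e-6 with a warning before the
  logit.

## Problem sizes used in the committed tests

The test suite exercises the generator at up to 500 accessions × 10
replicates (repeatability convergence), 2000 accessions (correlation
convergence), recovery studies at 200 accessions × 5 replicates × 100
simulations per generating R, bootstrap coverage at 80 replicates of
100-resample bootstraps, optimizer oracles at n = 12 with exhaustive
enumeration, and the full pipeline end-to-end on 20-accession collections.
These sizes were chosen as the smallest at which the Monte-Carlo error of
each check is comfortably below its assertion margin.

## Known limitations

* The E-NE search is a local-search heuristic; optimality is only guaranteed
  empirically at small n (it is verified against enumeration there), and at
  203 accessions different seeds can return different, near-equivalent cores.
* The elevation Wald test ignores slope-estimation uncertainty.
* The logit-Gaussian treatment of the edible ratio is an approximation with
  a latent-scale estimand; its R is not comparable to proportion-scale
  estimates.
* The inertia-gain rule for k can be unstable when clusters are not well
  separated; `k_policy = "fixed"` is provided for confirmatory use.
* Hopkins H is reported in the low-means-clusterable orientation; compare
  with care against software using the reciprocal convention.
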