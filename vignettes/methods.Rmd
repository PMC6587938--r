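---
title: "Methods: geostatistics for transect-scale microbial ecology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geostatistics for transect-scale microbial ecology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microgeostat)
```

This vignette is the package's own account of the models it implements, the
choices made where the methodology was genuinely open, and what the synthetic
data generator does and does not establish about real data.

## The setting and its assumptions

The package targets short-transect studies of soil prokaryotic communities:
on the order of ten to twenty georeferenced samples a few to a few tens of
metres apart, each with an OTU count table (taxa × samples, with taxonomy
lineages) and a set of soil covariates (pH, electrolytic conductivity EC in
dS/m, gravimetric water content WC in %, organic and inorganic carbon in
g/kg, sand/silt/clay in % closing to 100). Three modelling assumptions run
through every spatial stage:

* **Planarity.** UTM eastings/northings are treated as planar metres;
  distances are Euclidean. At a 200 m extent this is exact for all practical
  purposes.
* **Intrinsic stationarity.** The semivariogram γ(h) = ½ E[Z(u) − Z(u+h)]²
  depends on lag only, and only omnidirectionally: with ~13 points there is
  no information to resolve anisotropy, so none is modelled.
* **Gaussian-like fields for interpolation.** Ordinary kriging is the best
  linear unbiased predictor regardless of distribution, but its variance map
  and the cross-validation flags are most interpretable when the attribute
  is roughly Gaussian. Strongly skewed attributes (EC in saline soils) are
  better kriged after a log transform; the pipeline kriges what it is given
  and leaves transformation to the caller.

## Variograms

`empirical_variogram()` computes the cloud — every pair contributes
(h, (z_i − z_j)²/2); the ½ is kept in the cloud so that bin means equal the
classical 1/(2N(h)) estimator — and averages it in equal-width bins.
Defaults: `n_bins = 12` and `max_lag = "half-max"` (half the maximum
pairwise distance). These are the conventional working rules when the study
itself fixes neither: beyond half the extent the pair counts collapse and the
estimator is dominated by the few most distant pairs.

`fit_variogram()` does box-constrained weighted least squares over
(c₀, c, a) per candidate family with a deterministic multi-start grid over
the range (quantiles of the observed lags and multiples of the maximum lag;
two nugget and two partial-sill starts each), then picks the family with the
smallest weighted RSS. The default weights N(h)/h² privilege short lags,
which carry the information kriging actually uses; Cressie weights
N(h)/γ_model(h)² and OLS are available. Ties between fits cannot occur in
exact arithmetic and are broken by candidate order in the degenerate case.

The five families are the standard spherical, exponential and Gaussian forms
(the latter two parameterized by their *practical* range, i.e. the factor-3
forms), a pure nugget, and a **periodic** (hole-effect) model
γ(h) = c₀ + c(1 − cos(2πh/a)) for patchy fields whose semivariance returns
to the nugget level once per period a. The exact functional form of a
"periodic" fit is a documented choice — hole-effect cosine is the common
textbook form; for the non-monotone periodic curve the "sill" used in the
nugget/sill ratio is taken as c₀ + c, its maximum-amplitude level, since the
ratio is otherwise undefined for a model with no plateau. All families
evaluate to exactly 0 at h = 0 (the nugget is a discontinuity, not a value
at the origin).

Spatial dependence is classified from the nugget/sill ratio with the usual
cuts: high < 0.25, medium 0.25–0.75, low > 0.75.

## Ordinary kriging and cross-validation

`ordinary_kriging()` solves the (n+1)-dimensional semivariance-form system
with the unbiasedness constraint through a Lagrange multiplier, using the
**global neighbourhood**: with n ≈ 13 there is no reason to truncate, and a
search neighbourhood would only add a discontinuous tuning knob. Weights may
legitimately be negative for smooth models (screening); predictions are then
not guaranteed inside [min z, max z]. Numerical choices:

* Exactly duplicated locations with identical values are deduplicated with a
  warning; with conflicting values the system is singular and the error says
  which pair.
* Very smooth zero-nugget models (notably Gaussian) can make the system
  numerically singular. The solver then adds a vanishing nugget
  (starting at 10⁻¹² of the semivariance scale, growing ×100 up to four
  times) until the factorization succeeds. This is the standard
  regularization and changes predictions by amounts far below any
  scientific resolution.
* Kriging variances are clamped at 0 from below (they can come out at
  −10⁻¹⁵ in floating point).

`build_prediction_grid()` rasterizes a polygon into square cells of side
√pixel_area anchored at the bounding-box lower-left corner, keeping cells
whose centres are inside by the even-odd rule, in row-major order. The
default pixel area of 2.38 m² reproduces the ~3,000-pixel grid of a
0.71 ha (7,141 m²) prediction polygon. Point-in-polygon and the shoelace
area are implemented directly (about thirty lines); no geometry dependency
is available in the target environment, and the even-odd rule is the whole
requirement.

`loo_cross_validation()` removes one site at a time and re-predicts it with
the *same* fitted model — no per-fold refit, matching how gstat-style
cross-validation is conventionally run. The summary statistics are
ASE (the spread √(1/N Σ [Z′ − mean(Z′)]²) of the LOO estimates), RMSE
(√(1/N Σ [Z − Z′]²)), and RMSE_r = RMSE/S_z. Two conventions are worth
stating explicitly because typeset formulas often misplace the radical: both
ASE and RMSE take the square root of the *mean* of squares (the printed
forms with √(1/N) alone are typesetting slips — they would not even have the
units of Z), and S_z is the ordinary N−1 standard deviation of the observed
values. `prediction_accuracy_flag()` encodes the two working rules: ASE and
RMSE "similar" within a relative tolerance (default 20%), and RMSE_r at most
about 40% (the same tolerance widens the bound) for an "accurate"
interpolation.

## Diversity

Rarefaction (`rarefy()`) subsamples each sample without replacement to the
requested depth — a uniform draw of reads, so each taxon's subsampled count
is hypergeometric — and *drops* samples below the depth, recording every
decision in a log that downstream tables carry along. The seed is a required
argument: subsampling is the one stochastic step in an otherwise
deterministic analysis, and silent global-RNG use would make pipelines
unreproducible.

Shannon entropy defaults to **log base 2**. The practical reason: at a
rarefaction depth near 139 reads, published per-sample Shannon values near
5.9 are only attainable in base 2 (2^5.9 ≈ 60 effective taxa; e^5.9 ≈ 365
would exceed the read count), so base 2 is what comparable tables report.
The base is an argument. "Simpson" diversity is reported as Gini–Simpson
1 − Σp², alongside reciprocal Simpson 1/Σp² (the effective number of taxa)
and Simpson evenness (1/Σp²)/S. Chao1 uses the bias-corrected form
S + F₁(F₁−1)/(2(F₂+1)), defined also when no doubletons exist; the classic
form is a flag. ACE uses the standard rare/abundant split at 10 (configurable);
when every rare taxon is a singleton its coverage is zero and the
implementation falls back to bias-corrected Chao1 with a warning. Faith's PD
is the branch-length sum of the minimal rooted subtree spanning the observed
tips, computed by climbing parent pointers (and cross-checked in the tests
against picante and a brute-force path-union oracle).

`domain_ratio()` divides matched sample/metric values between two diversity
tables (e.g. Archaea over Bacteria) and rounds to 2 decimals by default,
the precision at which such ratios are conventionally reported.

## Mantel correlograms

For each of `n_classes` equal-width geographic distance classes the
statistic is the standardized Mantel correlation between the class indicator
over sample pairs and the attribute dissimilarity (|z_i − z_j| for a vector;
any ready-made dissimilarity matrix is accepted), with the sign flipped so
positive values mean positive spatial autocorrelation — the ncf/vegan
convention, and the one that makes the monotone-gradient sign pattern
(near classes positive, far classes negative) read naturally. Significance
is a two-sided permutation test: sample identities are shuffled
(simultaneous row/column permutation), p = (#{|T_perm| ≥ |T_obs|} + 1)/(n_perm + 1),
so p can never fall below 1/(n_perm+1) and the test is exactly valid at any
n_perm. 1,000 permutations is the study-scale default. Classes with no
pairs are dropped with a warning. Equal-width classes over the full lag
range keep the classes exhaustive; their number is a knob because no
principled default exists at n = 13.

## Taxa–environment correlation and BIOENV

Spearman correlations use average ranks and the two-sided t approximation on
n − 2 degrees of freedom (the behaviour of `cor.test`); with ≤ 13 samples
the t approximation is the conventional choice and exact permutation p-values
change no tier assignments in practice. Constant vectors yield r = NA and
tier "ns" rather than an error, so one degenerate taxon cannot abort a table.
The collinearity screen is a deliberately simple greedy rule — repeatedly
drop, from the worst-correlated pair above the threshold (default |r| 0.8),
the member with the larger mean absolute correlation to everything else,
tie-broken by name order. It stands in for fuzzy corSelect-style rankings
whose exact criterion is not reproducible; the tests verify it recovers the
largest admissible subset on small cases.

BIOENV evaluates **every** non-empty subset of the (internally standardized)
environmental variables up to `max_subset_size`: Euclidean distance on the
scaled subset against the community dissimilarity, Spearman rank correlation
between the two lower triangles. The community side defaults to Bray–Curtis
on relative abundances — the vegan convention, chosen because the
environmental side is the only side the method's definition fixes; the
metric is an argument. With ≤ 11 candidate variables (2,047 subsets at most)
exhaustive search costs well under a second, so no heuristic search is
provided.

## The synthetic-data generator

`simulate_transect()` + `simulate_community()` generate fixtures with the
statistical structure the analysis assumes, so every stage has a ground
truth. What it emulates (the defaults are the study conditions, chosen once):

* 13 sites along a ~211 m NW–SE diagonal at lightly jittered regular
  spacing (real transects are never exactly regular);
* per-property Gaussian random fields with covariance C(h) = sill − γ(h),
  drawn by Cholesky factorization, deterministic per seed. Defaults use the
  periodic (patchy) family with nugget/sill ≈ 0.1 — high spatial
  dependence — and periods of 60–90 m;
* near-constant alkaline pH (mean 10.45, sd ≈ 0.06), EC as an exp-transformed
  log-scale field (mean log 3.6, sd ≈ 0.78, i.e. spanning roughly 8–180 dS/m
  across realizations), WC around 35 ± 10%, organic and inorganic C at
  realistic means; physical ranges enforced by post-hoc truncation
  (WC ∈ [0, 100] etc.) — acceptable distortion for fixtures, and visible in
  the config echo;
* sand/silt/clay as a softmax closure of three positive latent fields to
  exactly 100 — compositional by construction;
* taxon intensities exp(baseline + B·x) with standardized covariates x and a
  taxa × covariates effect matrix B (defaults plant strong EC responders and
  some WC/organic-C responders on a log-linear rank-abundance baseline);
  counts multinomial at per-sample depths uniform on [120, 1500], wide
  enough that a sample occasionally falls below a 139-read rarefaction
  threshold and exercises the drop-and-log path;
* the periodic covariance is admitted with a 10⁻⁸·sill diagonal jitter, the
  minimal insurance for a family on the boundary of positive definiteness.

What it does **not** emulate: sequencing error, chimeras and OTU-clustering
artefacts; phylogenetic correlation among taxon responses; zero inflation
beyond what the multinomial induces; temporal variation; non-stationary
trends. Passing tests therefore establish that the *algorithms* are correct
under the stated model — unbiased semivariograms, calibrated permutation
tests, exact kriging algebra, recoverable planted signals — not that any
particular field dataset satisfies the model.

## Problem sizes used by the test suite

Chosen as the smallest sizes at which each property is statistically
decisive: variogram recovery on twenty 200-point transects (spherical
c₀ = 0.1, c = 1, a = 50 m; median fitted range within ±30%); Mantel null
calibration on 200 unstructured 15-sample datasets at 999 permutations
(per-class rejection within the binomial 95% band around 5%); field-vs-model
semivariance over 500 realizations of a 100-point transect; BIOENV
planted-driver recovery over 100 seeded communities; kriging algebra checked
to 10⁻⁸–10⁻¹⁰ on randomized configurations against closed forms and a naive
solver.

## Known limitations

* Thirteen samples support only coarse variogram estimation; fitted ranges
  on real 13-point transects are noisy, and the package reports diagnostics
  (`glance()`, accuracy flags) rather than pretending otherwise.
* The periodic family's parameters are weakly identified when the period
  approaches the transect length; the multi-start grid keeps the fit
  deterministic but cannot create information that is not there.
* No anisotropy, no trend (universal kriging), no co-kriging, and no
  geodetic transformations — out of scope by design.
* Published per-sample diversity tables shipped with the package are used
  for arithmetic checks (totals, ratios); recomputing those tables from raw
  reads requires the archived sequencing data and the original upstream
  pipeline, which is outside this package's scope.
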