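---
title: "Methods: paired-condition connectome analysis with NBS and graph metrics"
author: "connstate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired-condition connectome analysis with NBS and graph metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(connstate)
```

## The analysis

`connstate` implements a paired two-condition resting-state functional
connectivity analysis.  Each subject contributes one ROI timeseries per
condition (here called *natural* and *built*, after the viewing
conditions the design emulates).  The pipeline is

1. **prep** — framewise displacement (FD) from six realignment
   parameters, the 0.5 mm inclusion rule, removal of the first 10
   volumes, nuisance regression (motion parameters, optional WM/CSF
   columns) with linear detrending, and zero-phase band-pass filtering
   to 0.01–0.09 Hz;
2. **connectome** — Pearson correlation matrices between all ROI pairs,
   at two granularities: a 7-node functional parcellation (one node per
   canonical network) and a 90-region anatomical parcellation grouped
   into the same seven networks;
3. **nbs** — network-based statistics: paired edge-wise t-tests,
   a primary t threshold (default 2.5), breadth-first-search connected
   components of suprathreshold edges, and family-wise error control by
   sign-flip permutation of the maximal component extent;
4. **graph** — five graph measures (mean betweenness fraction B,
   transitivity T, degree assortativity A, global efficiency Geff,
   small-worldness S) over a proportional-threshold cost grid,
   aggregated as areas under the curve (AUC) and compared between
   conditions by paired sign-flip permutation with BH–FDR over the five
   measures;
5. **stats** — paired rating t-tests, correlation of mean component
   connectivity with a subject covariate (years of urban upbringing),
   a gated per-edge follow-up, a ≤5 vs ≥10 years repeated-measures
   ANOVA, and a global-signal-fluctuation (GSF) confound check.

Because the cohort data the design describes is not publicly available,
the package ships a first-class synthetic generator
(`synthetic_config()`, `simulate_dataset()`) whose defaults *are* the
study conditions, and every inferential component is validated against
that generator by calibration, power, and recovery studies
(`nbs_null_calibration()`, `nbs_power_study()`,
`covariate_recovery_study()`, `auc_null_calibration()`).

## The synthetic generator

Per subject and condition the generator draws `n_volumes = 150` i.i.d.
Gaussian vectors (TR = 2 s; the first 10 volumes are the discardable
lead-in) with a block correlation matrix: `base_within_r = 0.5` within a
network community and `base_between_r = 0.1` between communities, unit
diagonal.  (The emulated design does not report its within/between
baseline levels, so these are free parameters of the generator, not
estimates of that study.)  In the natural condition only, the planted
community pairs (Default–DorsalAttention, Default–Somatomotor,
DorsalAttention–VentralAttention) are raised by
`delta_r + covariate_slope * (years_urban − mean)`.  The construction is
on the correlation scale because the downstream analysis operates on
Pearson r; the implied matrix must be positive definite or the config is
rejected with the offending eigenvalue.  The series are band-limited with
the *same* zero-phase Butterworth filter the prep module uses (identical
filtering of every column preserves contemporaneous correlations), scaled
to unit variance, and white observation noise (`noise_sd = 0.2`) is
added.

Choices worth stating explicitly:

* **Years of urban upbringing** are drawn as `15 * Beta(a, b)` with
  `(a, b)` solved by the method of moments from the target mean 7.65 and
  SD 6.29.  A truncated normal on [0, 15] cannot reach an SD of 6.29
  (the uniform limit has SD 4.33); those moments force a U-shaped law —
  most people spent either almost none or almost all of their first 15
  years in a city — which the Beta family represents exactly.
* **Motion** is a Gaussian random walk on the six parameters with
  per-step SD `motion_scale = 0.026` mm (rotation steps divided by the
  50 mm head radius so their arc length matches), multiplied per run by
  a unit-mean lognormal factor (sdlog 0.5) so subjects differ in overall
  motion.  The resulting cohort has mean FD near 0.125 mm with
  between-subject SD near 0.07 mm — the magnitudes typical of compliant
  adults — and stays below the 0.5 mm exclusion threshold in almost all
  runs, so the FD-difference covariate carries realistic variance.
* **Ratings** (PSS, rumination, valence, arousal, dominance; 0–100
  slider) are generated with zero true condition effect: the testable
  property of the rating analysis is its null behaviour.
* **Effect-size calibration.**  The condition effect can be specified in
  Cohen's d units via `delta_for_cohens_d()`: the helper Monte-Carlo
  estimates the sampling SD of the paired planted-edge correlation
  difference under the config's own conditions (series length, band,
  noise, preprocessing) and multiplies by d.  Likewise
  `slope_for_target_r()` converts a target population correlation ρ
  between the covariate and mean planted-edge connectivity into a
  per-year slope, `ρ/√(1−ρ²) · σ_e/σ_years`, with the per-subject noise
  SD σ_e estimated the same way.  The default `covariate_slope = −0.010`
  was fixed once with this helper at the design target ρ = −0.47.
  Band-pass filtering matters here: limiting 140 volumes to
  0.01–0.09 Hz leaves roughly a third of the bandwidth, so per-edge
  correlation estimates have an effective sample size far below 140 and
  σ_e ≈ 0.1 for the three-edge mean.
* **What the generator does not emulate**: voxel-level images,
  hemodynamic response shapes, scanner drift/spike artifacts,
  physiological noise structure, or spatial autocorrelation within
  ROIs.  Passing calibration and recovery tests therefore demonstrates
  the statistical machinery is correct and calibrated under the assumed
  data-generating process, not that the original biological findings
  would replicate.

On the 90-region atlas a planted `delta_r` acts on whole between-network
blocks; bumps much above ~0.04 make the implied matrix indefinite (the
block perturbation has eigenvalues ±delta·√(p·q) for block sizes p, q),
and the generator rejects such configs.  The 90-region analysis is
therefore exercised with small or null planted effects — consistent with
the emulated design, whose anatomical-atlas contrast was null.

## NBS details

The paired design is realised as a one-sample test on the per-subject
difference vectors with sign-flip permutation — the standard
exchangeable scheme for a paired contrast.  With a covariate (the
pipeline uses the per-subject natural−built difference in mean FD,
centred), each edge's differences are modelled as
`d = b0 + b1·covariate + e` and the intercept is tested (df = n−2); the
covariate is re-residualised inside every permutation.  Zero-variance
edges report t = 0 with a warning rather than ±∞.  The headline
contrast is one-sided (natural > built); the pipeline always runs the
reverse contrast as well.  Component p-values use the add-one estimator
`p = (1 + #{null ≥ obs}) / (1 + n_perm)`, so p can never be exactly
zero and is reproducible given the seed.

**Discreteness of extent on small networks.**  On the 7-node atlas there
are only 21 edges, so the maximal-component-extent null distribution is
supported on a handful of integers.  At the default primary threshold
2.5 the measured null law is approximately P(≥1) ≈ 0.18, P(≥2) ≈ 0.016:
the smallest rejectable extent is 2, and a single one-sided NBS call
therefore operates at an achieved level near 0.016 — valid (below
0.05) but conservative.  This is a structural property of extent-based
NBS on small graphs, not an implementation artifact.  The package's
null-calibration study consequently reports two rates: the
single-contrast rate and the pipeline-level family-wise rate (a false
positive in either one-sided contrast), the latter being the operating
characteristic of the NBS stage as actually run (≈ 0.03 under the
default conditions).

## Graph measures

All measures are computed on dense 0/1 adjacency matrices (N ≤ 90), with
conventions fixed as follows:

* `proportional_threshold()` ranks edges by |r| (so strong negative
  edges are retained), keeps `round(K · N(N−1)/2)` edges with
  round-half-away-from-zero, and breaks boundary ties lexicographically
  by (i, j) — every subject and condition has exactly the same edge
  count at a given cost K.
* Betweenness is reported as the ordered-pair fraction, normalised by
  (N−1)(N−2) (star centre = 1); disconnected pairs contribute 0.
* Transitivity is 3·triangles / connected triples, 0 when no triple
  exists; the clustering coefficient C used inside S is the mean nodal
  (Watts–Strogatz) coefficient, a distinct quantity.
* Assortativity is the Pearson correlation of end-point degrees over
  both edge orientations; on regular graphs it is undefined and
  propagates as NaN.
* Characteristic path length L averages over *connected* pairs only and
  flags disconnection; global efficiency uses 1/∞ = 0 instead.
* Small-worldness S = (C/Crand)/(L/Lrand) against one rewired
  realisation per graph (configurable upward), NaN whenever a part is
  zero or non-finite.
* AUC integrates by trapezoid over the cost grid, dropping non-finite
  grid points pairwise; grids start inclusively at the printed lower
  bound with step 0.02 and end strictly below the upper bound (43
  points from 0.05 for the 90-region atlas, 35 points from 0.15 for the
  7-node atlas).

The rewired null performs Maslov–Sneppen double-edge swaps (10,000
attempts for the 90-region atlas, 500 for the 7-node atlas), preserving
the degree sequence exactly and never creating self-loops or
multi-edges.  One subtlety: each drawn edge must be randomly oriented
before pairing the replacement endpoints.  Always pairing the
lexicographically smaller endpoints makes the swap chain biased (it
systematically under-samples one of the two legal replacements and
drives clustering far below the configuration-model expectation); with
random orientation the chain converges to the uniform
degree-constrained ensemble, which the tests verify by S ≈ 1 on
Erdős–Rényi graphs.

## Statistics downstream of NBS

Mean component connectivity is the arithmetic mean of r over the
component's edges, per subject and condition.  Its correlation with the
covariate is a plain Pearson test (df = n−2); the per-edge exploratory
correlations are computed only when the mean-level test is significant,
mirroring the gated post-hoc design, and are reported both uncorrected
(as in that design) and BH-adjusted.  The urbanicity split ANOVA is a
2 (condition, within) × 2 (group, between) mixed model fitted by
`aov()` with a subject error stratum; its interaction F equals the
between-group F on difference scores, which the tests verify against an
independent linear-model fit.  The GSF confound check correlates the
covariate with GSF averaged over the two conditions (which run's GSF to
use is not otherwise determined).  A note on degrees of freedom: with
n = 24 paired observations the correlation df is 22 and the paired-t df
is 23; outputs always report df = n−2 (correlations) and n−1 (paired
t), whatever labelling conventions appear elsewhere.

## Numerical and design choices

* The band-pass filter is an order-2 Butterworth applied
  forward-backward (`signal::filtfilt`) with 100-sample reflective
  padding; the filter family and padding are this package's documented
  choices — the emulated design names only the band.  DC gain is ~1e−4
  and a 0.2 Hz tone is attenuated below 4% amplitude at TR = 2 s.
* Pearson r is used raw (no Fisher z) in NBS by default: the
  permutation calibrates the null distribution, and the monotone
  transform does not change suprathreshold sets at a matched threshold.
  `pearson_matrix(..., fisher_z = TRUE)` is available.
* The FD boundary is strict: mean FD exactly at the threshold excludes.
* Undefined AUCs drop that subject for that measure only, with a
  warning.
* One global seed spawns per-stage/per-subject substreams via a small
  multiplicative hash (`derive_seed`), keeping every seed below 2^31.
* Manifests record content hashes, seeds, and versions but no
  wall-clock timestamps, so identical configs yield byte-identical
  manifests.

## Problem sizes used in validation

The shipped validation studies use the study conditions themselves
(24 subjects, 7 nodes, 140 usable volumes): 200 replicates × 1,000
permutations for the NBS null calibration, 50 replicates at d = 1.0 for
power/recovery, 100 + 200 replicates for covariate recovery and its
null calibration, and 200 replicates × 500 permutations for the AUC
test calibration; brute-force oracle equivalence uses 100 random graphs
with N ≤ 12.  These sizes were chosen so the whole suite completes on a
single CPU in well under half an hour while keeping Monte-Carlo error
small relative to every acceptance band.

## Known limitations

* Extent is the only component statistic (no intensity), and only
  paired designs are supported.
* The generator's Gaussian block-covariance world has no spatial or
  temporal noise structure beyond the band limit; calibration results
  transfer to real data only insofar as sign-symmetric exchangeability
  of paired differences holds there.
* The 90-region atlas's region-to-network grouping is an editable
  convenience default (`inst/extdata/aal90_networks.tsv`), not a
  canonical mapping.
* GSF is defined here as the temporal SD of the across-ROI mean signal;
  other definitions exist.
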