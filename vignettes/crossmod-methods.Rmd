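---
title: "Methods: cross-modularity parcellation and case-control connectome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-modularity parcellation and case-control connectome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossmod)
```

# Overview

`crossmod` analyses case-control cohorts (here labelled control vs TBI,
traumatic brain injury) that carry three kinds of measurements per
subject: a structural connectome (white-matter streamline counts between
ROIs), resting-state BOLD series, and posturography (balance) recordings.
The pipeline has six stages:

1. **atlas** — build functional and structural dendrograms over ROIs, cut
   them at candidate module counts M, and pick the M that maximizes
   cross-modularity;
2. **structural** — aggregate binary ROI links to inter-module degree and
   compare groups with a covariate-adjusted GLM contrast plus a
   subject-label permutation null;
3. **dynamics** — summarize each module's first-principal-component BOLD
   timecourse by variance, skewness, kurtosis and a point-process peak
   count, and compare groups the same way;
4. **funcnet** — map each module's functional network by PCA + ICA of its
   voxel series, voxel-wise spatial regression, k-means clustering of the
   pooled spatial maps into "most representative clusters" (MRCs), and
   group contrasts with Monte-Carlo cluster-extent FWE correction;
5. **behavior** — score balance trials (inverse path length, directional
   control) and correlate imaging descriptors with the scores;
6. **simulate** — generate full synthetic cohorts with planted effects so
   that every stage has a ground-truth acceptance surface.

# Models and procedures

## Hierarchical multimodal parcellation

Both modalities are clustered with average-linkage (UPGMA) agglomerative
clustering on a dissimilarity matrix: `1 - fc` for the functional
correlation matrix and `1 - sc_binary` for the binarized structural
matrix. UPGMA guarantees monotone merge heights, and `stats::hclust` makes
the merge order deterministic for a given input. Cutting a single tree at
increasing M yields nested partitions by construction.

A cut is scored by three quantities:

* **Newman modularity** `Q = sum_m (e_mm - a_m^2)`, where `e` is the
  matrix of (weighted) edge fractions between modules. We only *evaluate*
  Q for partitions produced by the tree; no modularity optimization is
  performed. The structural Q uses the binary graph; the functional Q uses
  the positive part of the correlation matrix as edge weights.
* **Sorensen similarity** between intramodule edge sets,
  `S = 2|A∩B| / (|A|+|B|)`, computed between the structural partition's
  modules (edges of the binary structural graph) and the functional
  partition's modules (edges with correlation above a configurable
  threshold, default 0). Modules are matched greedily by best Sorensen
  score, and the mean best-match similarity is symmetrized over both
  matching directions.
* **Cross-modularity** `X = (Q_s · Q_f · <S>)^(1/3)`, the geometric mean
  of the three factors, clipped to 0 when any factor is negative. The
  geometric mean is our reading of an index "simultaneously accounting"
  for all three properties: it rewards balanced quality and vanishes if
  any one property fails. The optimal level `M*` is the argmax of X over
  the candidate range, with ties broken toward the smallest M.

Design choices made where the method is genuinely open: the linkage
(UPGMA), the functional edge threshold (0), the greedy symmetric module
matching, and the geometric-mean combination rule are all documented
stand-ins validated by planted-structure recovery rather than by
reproducing any published atlas bit-exactly. On stochastic-block pairs
with within/between link probabilities 0.6/0.05 and four planted modules,
`select_optimal_level` recovers M = 4 in ≥ 95% of seeds.

## Group statistics

All group comparisons share one engine: a cell-means design with one
indicator column per group followed by mean-centred covariates (age plus a
motion summary — mean eddy-correction displacement for structural
comparisons, mean framewise displacement for BOLD-derived measures). The
statistic is `t = c'β̂ / se(c'β̂)` for the contrast `c = (1, -1, 0, ...)`
(control minus TBI); without covariates this is algebraically the classical
pooled-variance two-sample t (asserted to 1e-10 in the tests).

Significance uses a subject-label permutation null: the full GLM is refit
under each of `n_perm = 1000` (tests use 200) random relabelings and
`p = (1 + #{|T_perm| ≥ |T_obs|}) / (1 + n_perm)` — the add-one estimator,
which cannot return zero. Features with p ≥ 0.05 are flagged discarded.
Effect sizes are Hedges g derived from t,
`g = J t sqrt(1/n1 + 1/n2)`, `J = 1 - 3/(4 df - 1)`, with a
normal-approximation 95% interval
`g ± 1.96 sqrt((n1+n2)/(n1 n2) + g²/(2(n1+n2)))`.

Brain-behavior association residualizes the imaging variable on age and
motion ("corrected" variance) and correlates the residuals with the
balance score by both Pearson and Spearman; a `residualize = "both"`
switch gives the full partial correlation instead. The imaging-only
default matches the "corrected variance" reading of the analysis it
replicates; both modes are exposed because the published description does
not settle the point.

## Module BOLD dynamics

Frames with framewise displacement above 0.5 are replaced by natural
cubic-spline interpolation through clean frames; flagged frames before the
first (or after the last) clean frame are held at the nearest clean value
rather than extrapolated, since spline extrapolation is unstable. Each
module's representative timecourse is the first principal component of its
(column-centred) voxel series, with sign fixed so the component correlates
nonnegatively with the module-mean timecourse. The sign convention matters
only for skewness: variance, kurtosis and the peak count are
sign-invariant, so group tests on skewness are convention-dependent and
documented as such.

Descriptors: sample variance (n−1), skewness and kurtosis as 3rd/4th
standardized moments (kurtosis raw, Gaussian reference 3), and the
point-process peak count `#{t : x_t > mean + 1·SD}` with the sample SD and
a strict inequality. For a Gaussian series the expected peak fraction is
`P(Z > 1) ≈ 0.1587`, which the tests verify at T = 1e5.

## Functional-network mapping (MRC procedure)

Per module and subject, the voxel series is reduced to `n_pca = 20`
principal components and unmixed by fixed-point ICA (logcosh contrast,
symmetric decorrelation, random orthogonal start from the stage seed) into
`C = 20` unit-variance component timecourses, ordered by the energy of
their back-projection so the ICA permutation ambiguity does not affect
downstream bookkeeping; component sign is fixed to positive skewness. Each
component's spatial map is its coefficient image from a *joint* multiple
regression of every brain voxel on all C components — joint rather than
one-at-a-time because the components enter one linear model of the voxel
signal.

The pooled maps (subjects × C per module) are clustered with k-means under
the `1 - Pearson` spatial-correlation distance into `k = 5` MRCs. Maps are
row-standardized first; on standardized vectors the correlation distance
is an affine function of squared Euclidean distance, so standard k-means
(best of `n_restarts` seeded starts) minimizes exactly the intended
criterion. Centroids are reported unit-normalized. k = 5 follows the
source analysis, which chose it by inspection; it is a config parameter.

Group contrasts per MRC and module average each subject's maps in that
cell first (one observation per subject, avoiding pseudo-replication — the
published procedure is silent here), then fit the voxel-wise GLM for the
four contrasts `[1 0 0 0]`, `[0 1 0 0]`, `[1 -1 0 0]`, `[-1 1 0 0]`.
Multiple comparisons are controlled by a Monte-Carlo cluster-extent
threshold: `n_iter = 10000` Gaussian fields smoothed to a configurable
FWHM (supplied as a parameter because upstream spatial smoothing is
outside this pipeline), thresholded two-sided at `voxel_p = 0.005` by
default, clustered per sign under a face-connectivity (6-neighbor) rule
(18/26 available), recording the maximum cluster size; the surviving-size
threshold is the smallest s with `P(max ≥ s) ≤ α`. At FWHM 0 the max-size
distribution is extremely discrete, so the attainable FWE can sit far
below α; calibration checks therefore use smooth fields, matching real
use.

## Balance scores

The sensory organization test (SOT) trials are 20-s, 100-Hz
center-of-pressure recordings scored by inverse path length (iPL = 1 /
total path length); per protocol, trial scores are averaged over the three
non-fall trials of each of four sensory conditions and then over
conditions with equal weights (the cross-condition rule is unstated in the
source; equal weights are the neutral choice). Limits-of-stability (LOS)
and rhythmic-weight-shift (RWS) trials are scored by directional control:
each displacement increment is decomposed into its absolute projection on
the target direction (on-target) and the orthogonal remainder (off-target),
and `DC = (on - off)/on × 100`. A perfectly straight path scores exactly
100%. The "summed absolute projection" reading of on-target movement is a
documented choice (vendor internals are unavailable); a `net` mode sums
signed projections instead, which differs for oscillatory RWS paths. iPL
units follow directly from the trajectory units; the analyses that use
iPL are scale-invariant, so no vendor scaling is applied.

# The synthetic-cohort generator

`simulate_cohort()` emulates the study conditions: 27 controls and 14 TBI
subjects; 200 ROIs in a nested hierarchy of 8 coarse and 20 fine modules;
BOLD on a 24³ voxel grid with T = 200 frames at TR = 3 s; ages uniform on
8–19 years and motion summaries lognormal with identical parameters in
both groups (matched design); 5 spatial-map families; 20-s 100-Hz sway
trials. Structural connectomes come from a nested stochastic block model
(within-fine 0.6, between-coarse 0.05; same-coarse/different-fine pairs
use `p_out + 0.25 (p_in - p_out)` — at the midpoint rate, merging sibling
fine modules would score a *higher* Newman Q than the planted fine cut,
so the lower intermediate rate is what makes the hierarchy genuinely
nested with the fine level as its modularity optimum) with a per-subject
lognormal perturbation of the background link rate; functional matrices
come from module-coherent latent signals.

Planted effects are parameterized in Cohen's d units and injected by
explicit mechanisms calibrated against the control group's spread, so the
planted mean shift equals d control SDs:

* **degree deficit** (control > TBI, default d = 1.0 in two coarse
  modules): removal of `round(d · SD_ctrl)` inter-module links incident to
  the module. Links touching the surplus module are protected so the two
  structural injections stay orthogonal.
* **degree surplus** (TBI > control, default d = 1.0 in one "prefrontal"
  fine module): links added from that module to sibling fine modules
  inside the same coarse module, leaving coarse-level degrees untouched.
* **variance surplus** (default d = 0.9): the module's voxel series are
  rescaled per TBI subject so the measured first-component variance rises
  by exactly `d · SD_ctrl` (additive shift; the TBI spread is not
  inflated). The ground-truth descriptor is computed through the same
  scrub-then-PCA path the analysis uses.
* **frontal recruitment**: TBI subjects' BOLD gains extra loading of one
  map family on a spherical blob in a "frontal" corner of the grid, so the
  `[-1 1 0 0]` contrast — and only that contrast — should show a surviving
  cluster there.
* **behavior coupling**: iPL-SOT scores are drawn as
  `100 - 8·z(variance) + noise` with the noise SD set so the planted
  correlation equals `behavior_r` (default −0.85), then sway trajectories
  are synthesized whose expected path length matches each target score
  (per-step jitter σ chosen from the Rayleigh step-length mean).

Module and family signals have heterogeneous voxel loadings, and family
maps carry signed weights: with uniform loadings the two sources span a
rank-1 subspace that PCA/ICA cannot separate (and all-positive loading
vectors are strongly mutually aligned). Family time courses are
supergaussian and positively skewed — burst-like, as BOLD network
activity — which both enables ICA recovery and makes the positive-skewness
sign convention orient maps consistently across subjects. With the default
amplitudes the median first-component explained variance falls in the
28–54% band reported for real module BOLD.

What the generator does **not** emulate: hemodynamic convolution and
realistic BOLD autocorrelation beyond a mild AR(1), spatial noise
correlation, tractography error structure, lesion heterogeneity, or any
vendor-specific posturography scaling. Passing the planted-recovery tests
therefore demonstrates that the pipeline detects effects of the stated
size under idealized noise, not that it would have identical power on
real scans.

# Test and acceptance problem sizes

The test suite exercises the pipeline at reduced problem sizes chosen to
keep the full suite within a few minutes while preserving the statistical
structure: planted-recovery cohorts use 120 ROIs, a 12³ grid and T = 120
over 10 fixed seeds; null-calibration runs use 25 zero-effect cohorts of
100 ROIs at 10³ (500 module-level tests per stage, permutation count 200);
cluster-extent FWE calibration uses 200 smooth null t-fields against a
1,200-iteration null on a 10³ grid; atlas recovery uses 100
stochastic-block pairs of 120 ROIs. All stochastic tests run under fixed
seeds and are bit-reproducible.

A note on attainable rates: with n = 27 + 14 and two-sided α = 0.05, the
per-module power of the degree comparison at the default planted d = 1.0
is 0.846 (noncentral t, ncp = 3.04, df = 37), and 0.757 for the variance
surplus at d = 0.9. Recovery-rate checks asserted above those powers
cannot be met by any correct implementation under these cohort sizes;
the suite states the intended rates and reports honestly.

# Numerical and degenerate-input conventions

* Dendrogram ties follow `stats::hclust`'s deterministic merge order;
  equal inputs give equal trees.
* `Q` of a single-module partition is exactly 0; edgeless graphs are an
  error (Q undefined), as are Sorensen comparisons of two empty edge sets.
* Constant module series, constant spatial maps, zero-variance residuals,
  zero path length and zero on-target movement are errors, not silent
  NAs.
* Permutation p-values use the add-one estimator; every random procedure
  takes an explicit seed and restores the caller's RNG state.
* The pipeline driver derives per-stage seeds from one master seed by a
  fixed affine map modulo 2³¹ − 1.

# Known limitations

* The cross-modularity combination rule and the atlas construction are
  documented stand-ins for an external reference implementation that is
  not reproduced here; validation is via planted-structure recovery.
* Confidence intervals for Hedges g use the normal approximation; exact
  noncentral-t intervals would differ slightly at these sample sizes.
* The cluster-extent null assumes stationary Gaussian smoothness supplied
  as a parameter; residual-based smoothness estimation is not implemented.
* Skewness group tests inherit the first-component sign convention.
* `aggregate_scores` requires every condition/direction to retain at least
  one non-fall trial; partially missing protocols yield NA scores rather
  than imputation.
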