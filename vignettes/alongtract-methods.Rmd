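---
title: "Along-tract multivariate statistics for multi-compartment diffusion MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Along-tract multivariate statistics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alongtract)
```

`alongtract` implements a tractometry analysis chain for multi-shell
diffusion MRI: a free-water + multi-zeppelin mixture model fitted per voxel
with automatic selection of the number of fiber compartments, projection of
the derived microstructure metrics onto 100-node bundle centroid lines, and
multivariate along-tract statistics with permutation-based cluster-size
familywise error control. This vignette explains the models, the tunable
parameters, the numerical choices, and what the synthetic data generator
does and does not emulate.

## The diffusion signal model

In a multi-compartment model the diffusion-weighted signal of a voxel is a
weighted sum of compartment signals. The mixture used here has one
isotropic free-water compartment and $N \in \{0,1,2,3\}$ anisotropic
zeppelin compartments (axially symmetric tensors, the two transverse
eigenvalues equal). In attenuation space, for b-value $b$ and unit
gradient direction $g$:

$$
\frac{S(b, g)}{S_0}
  = \alpha\, e^{-b\, d_{\mathrm{iso}}}
  + \sum_{j=1}^{N} \beta_j\, e^{-b\, g^\top D_j\, g},
\qquad \alpha + \sum_j \beta_j = 1,
$$

with $g^\top D_j g = \lambda_{\perp,j} + (\lambda_{\parallel,j} -
\lambda_{\perp,j})\,(g \cdot u_j)^2$ for axis $u_j$. The free-water
diffusivity is fixed at $d_{\mathrm{iso}} = 3.0\times10^{-3}$ mm²/s
(body-temperature CSF) rather than estimated: two free isotropic
compartments are not stably identifiable from a 60-gradient acquisition,
and fixing the free-water term keeps $\alpha$ interpretable as a free-water
fraction.

Per-compartment scalar metrics use the standard eigenvalue formulas on
$(\lambda_\parallel, \lambda_\perp, \lambda_\perp)$ — $AD_k =
\lambda_\parallel$, $RD_k = \lambda_\perp$, $MD_k = (\lambda_\parallel + 2
\lambda_\perp)/3$, and FA reduces to $(\lambda_\parallel -
\lambda_\perp)/\sqrt{\lambda_\parallel^2 + 2\lambda_\perp^2}$ — and the
voxel-level FA, MD, AD, RD are unweighted means over the anisotropic
compartments, with FW the free-water weight. In voxels selected as purely
isotropic the four anisotropic metrics are undefined (`NA`), never zero.

### Fitting

The fit is maximum likelihood under Gaussian noise on attenuations, i.e.
penalty-free least squares, with one amendment: the fitted magnitude is
$\sqrt{S^2 + 2\sigma_n^2}$ with a single non-negative noise-floor parameter
$\sigma_n$ shared across measurements. This matches the second moment of
Rician-distributed magnitudes ($E[M^2] = S^2 + 2\sigma^2$). Without it, the
Rician bias at high b-values (where the true attenuation approaches the
noise floor) is systematically absorbed by spurious extra compartments —
in our simulations the compartment-count selection at SNR 50 dropped from
~90% to ~75% correct. `fit_config(noise_floor = FALSE)` restores the plain
Gaussian objective. A full Rician likelihood was evaluated during
development and brought no further precision (the moment-matched estimator
is already at the sampling-information bound for this protocol), so the
smooth least-squares objective is kept.

Optimization is bounded local search (`stats::nlminb`) over a
reparameterized space: weights through a softmax (the simplex constraint
holds by construction, and the weight sum is re-normalized to cancel float
drift, keeping $\alpha + \sum\beta_j = 1$ to $10^{-9}$), axes through
spherical angles, $\lambda_\parallel \in [0.1, 3.0]\times10^{-3}$ mm²/s
directly, and $\lambda_\perp$ through a fraction of the
$[0.01\times10^{-3}, \lambda_\parallel]$ interval so the eigenvalue
ordering can never invert. Five multi-starts are run per candidate model:
one seeded from the data (candidate axes are the gradient directions of
largest apparent diffusivity at the strongest shell, thinned to be pairwise
> 25° apart) and four from seeded random draws; the best residual wins.
Axes are stored with non-negative z component (zeppelins are antipodally
symmetric) and compartments in descending weight order, so fits are
comparable across voxels and runs.

### Choosing the number of compartments

All candidate models ($N = 0$ to `max_compartments`) are fitted and scored
with AICc; Akaike weights are exposed for audit and the highest-weight
model is returned (ties: lower criterion, then fewer compartments). Two
details matter:

* The concentrated Gaussian log-likelihood floors its variance estimate at
  $(10^{-6})^2$ attenuation units. On noise-free signals the achievable
  residual is set by optimizer tolerance, not data, and without a floor the
  likelihood of nested models diverges so the richest model always wins;
  with the floor the parameter penalty decides, and noise-free phantoms
  select their generating count for $N = 0, 1, 2, 3$.
* Akaike-weight *averaging* of the metrics across candidate models (rather
  than selection) is available as `fit_config(metric_averaging = TRUE)`;
  selection is the default because a single integer compartment count per
  voxel is the quantity reported and mapped downstream.

At SNR 50 (Rician) the selection returns the generating single-fiber model
in about 90% of seeded repeats; most errors are one extra compartment
absorbing borderline-AICc noise (criterion gaps of 1–2 units), which is the
expected liberal behavior of Akaike-type criteria.

## Tractometry

A bundle's centroid line is the pointwise mean of its streamlines after
resampling each to $s$ equidistant arc-length points (default $s = 100$)
and orientation-aligning each against a reference with the
minimum-direct-flip (MDF) rule: a streamline is flipped when the flipped
mean pointwise distance is smaller. The reference is the streamline with
the largest endpoint separation (ties broken by lexicographic first point),
a deterministic, storage-order-independent choice; the mean polyline is
re-resampled so the final nodes are equidistant.

Metric projection assigns every streamline vertex to its nearest centroid
node and reads the vertex's metric value from its containing voxel
(nearest-voxel lookup through the volume affine; trilinear interpolation is
a config option). A node's value is the weighted mean of its vertices with
weights decreasing in distance $d$ from the node, $w = 1/(1 + d/h)$ with
$h$ the inter-node arc spacing — so the kernel is scale-normalized and
distant spurious streamlines contribute little. A Gaussian kernel
$\exp(-d^2/2h^2)$ is the alternative. "Distance" is Euclidean
point-to-node distance normalized by node spacing; this is our
interpretation of a relative geodesic weighting, and the kernel choice is
deliberately configurable because any monotone decreasing, scale-free
kernel serves the same purpose. Nearest-node search is exact vectorized
assignment (a blocked point-by-node distance computation); with only 100
nodes this is faster than a spatial tree and bit-reproducible. Nodes
receiving no vertex are `NA` and are excluded from testing downstream;
weighted node values are clamped to their contributors' range, which makes
the constant-field identity (constant map in, constant profile out) hold
bit-exactly. All geometry lives in world RAS mm; TRK files are converted
from their corner-origin voxel-mm convention on read and write, TCK files
are native world mm.

## Along-tract statistics

For one bundle the data are a subjects × nodes × metrics array (56 × 100 ×
5 under the default synthetic cohort). The chain is:

1. **Pruning.** Pairwise Pearson correlations over pooled subject × node
   observations; while any $|r| > 0.8$, the metric with the largest mean
   $|r|$ against the other retained metrics is dropped (ties keep the
   earlier of FW, FA, MD, AD, RD). The threshold is strict, so a pair at
   exactly 0.8 survives.
2. **PCA.** Metrics are z-scored over the pooled observations of *both*
   groups and reduced to the smallest $L$ components reaching 80%
   cumulative explained variance. Components are sign-ambiguous; a
   component with an appreciable free-water loading ($|$loading$| \ge
   0.1$) is oriented FW-positive (the inflammation-positive direction in
   which such components are reported), others largest-loading-positive.
3. **Covariate removal.** Per node and component, OLS residuals on
   intercept + age + sex + center; residuals are orthogonal to every
   covariate column to $10^{-10}$. Constant covariates (e.g. a single
   center) are dropped silently; genuinely collinear columns raise an
   error naming them.
4. **Group test.** Per node, a two-sample Hotelling $T^2$ on the $L$
   residualized components, converted to an F statistic with
   $(L,\ n_1+n_2-L-1)$ degrees of freedom; Cohen's d per component is
   reported as the effect size.
5. **Score association.** Within one group, a per-node joint F test of the
   $L$ components as predictors of a covariate-residualized clinical
   score, with error degrees of freedom reduced by the covariate count.
   The effect size $r$ is the signed partial correlation for $L = 1$ and
   $\sqrt{\text{partial } R^2}$ carrying the sign of the
   largest-magnitude per-component correlation for $L > 1$ (per-component
   values are also emitted).
6. **FWE correction.** Labels (or the residualized score) are permuted;
   per permutation the per-node p-values are recomputed and the maximum
   run length of contiguous nodes with $p < \alpha$ recorded (`NA` nodes
   break runs — significance never bridges unmeasured nodes). The
   corrected cluster size is the smallest integer whose null exceedance
   probability is $\le \alpha$ — the exactly valid discrete version of the
   $(1-\alpha)$ upper quantile, chosen because the plain empirical
   quantile is slightly anticonservative on a discrete null. Observed
   clusters at least that long are significant. The observed labeling is
   included in the null set, so the familywise p-value is never zero; a
   matrix of labelings can be supplied directly for exact enumeration on
   tiny designs.

Covariates are residualized once on the observed data and the labels
permuted afterwards. This is a pragmatic scheme (sometimes called
Freedman–Lane "lite"): it is exact when the covariates are independent of
the group labels, which holds by construction in the synthetic cohort and
approximately in matched case-control designs.

The permutation engine is vectorized across nodes: group moments come from
matrix cross-products and the per-node covariance inverses use closed
forms for $L \le 2$ (the dominant case; a node loop handles $L \ge 3$), so
500 permutations of a 56 × 100 × 2 score array take well under a second.

## The synthetic data layer

Because raw clinical MRI of this kind is not shareable, every input is
generated:

* **Gradient schemes** emulate a cube-and-sphere multi-shell acquisition:
  60 gradients, half on the unit sphere at b = 1000 s/mm² (Fibonacci
  spiral), half on a cube surface whose squared radius maps b up to
  3000 s/mm², plus one b0.
* **Voxel signals** are forward-model attenuations with Rician noise
  (magnitude of a complex Gaussian perturbation, $\sigma = S_{b0}$/SNR);
  Gaussian noise is available for fast tests.
* **Phantoms** are small grids of disjoint regions with known mixture
  ground truth, used for simulate-then-fit recovery scoring. The
  recovery benchmark voxel is $\alpha = 0.3$ free water plus one zeppelin
  (1.7, 0.3) × 10⁻³ mm²/s — elevated free water representative of aging
  white matter, the regime this pipeline targets.
* **Bundles** are line / arc / helix base curves plus a constant
  per-streamline offset and pointwise Gaussian jitter.
* **Group profile datasets** (21 + 35 subjects × 100 nodes × 5 metrics by
  default) are built from two node-smooth latent factors (moving-average
  width 5 nodes, unit marginal variance) with fixed metric loadings, plus
  per-metric noise, covariate effects (age 75 ± 6 years, sex, two
  centers; a small age slope on factor 1), and a clinical score of
  41.78 ± 8.71 with optional planted factor associations. The default
  loadings were calibrated once, at design time, so that exactly one
  metric pair (FA–RD, $r \approx -0.8$) straddles the pruning threshold
  and two components carry ≈ 88% of the variance. Planted group shifts
  and score slopes are expressed in factor-SD units on stated node
  intervals, and the ground-truth effect mask is returned for recovery
  scoring.

What the generator does **not** emulate: real anatomy and partial-volume
geometry, susceptibility or motion artifacts (preprocessing is upstream of
this package), white-matter hyperintensities, spatially varying SNR, and
between-bundle correlation structure. Passing tests therefore demonstrate
statistical correctness (calibration, recovery, determinism) of the chain
under a realistic correlation/smoothness model — not robustness to
acquisition pathology.

## Problem sizes and determinism

The shipped tests and the acceptance script use scaled simulation sizes
chosen as the package's own verification conditions: 50 seeded voxels for
recovery, 100–200 seeded null datasets with 500 permutations for the
familywise-error calibration, 50 seeded runs for power. Production
analyses would use `n_perm = 10000` (the package default for the
statistics functions).

Every stochastic component draws from its own seeded stream that neither
reads nor disturbs the global RNG; the pipeline derives one stream per
stage from the master seed, so stages can be rerun independently. Result
tables and the results JSON are byte-identical across reruns with the same
configuration and seed; the run manifest is the one deliberately
non-reproducible output (it records wall-clock timing and checksums).

## Known limitations

* The mixture fit is a local optimizer with restarts; pathological
  three-crossing geometries at low SNR can converge to permuted or merged
  compartments. Axis assignment across voxels is not attempted.
* AICc selection is liberal by construction; at moderate SNR roughly one
  voxel in ten gains a spurious extra compartment. The averaged metrics
  are less sensitive to this than the count map itself.
* Centroid-line tractometry summarizes a bundle by one curve; bundles with
  genuinely multi-modal cross-sections (fanning, sharp merges) are only
  partially described, and the profile inherits that limit.
* Cluster-size FWE controls error within a bundle; no cross-bundle
  correction is applied (each bundle is reported with its own corrected
  cluster size).
* The association effect size for $L > 1$ compresses a multivariate
  relation into one signed scalar; the per-component correlations should
  be consulted alongside it.
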