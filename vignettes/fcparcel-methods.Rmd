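---
title: "Methods: seed connectivity, fuzzy parcellation and reliability in fcparcel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed connectivity, fuzzy parcellation and reliability in fcparcel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures `fcparcel` implements,
the assumptions behind them, and the design decisions taken where the
methodology was genuinely open. It states no empirical result beyond what
the package's own tests and `scripts/acceptance.R` compute.

## The analysis problem

Resting-state BOLD fluctuations below ~0.1 Hz are temporally correlated
within large-scale brain networks, and two of those networks — often
called task-positive (TPN) and task-negative (TNN, largely the default
mode network) — fluctuate in opposite phase. Given a cortical target
region believed to straddle several networks, the pipeline answers:

* which voxels across the brain correlate with small seed ROIs placed in
  the target (seed branch), and
* whether the target's voxels segregate into connectivity-defined
  clusters matching those networks (parcellation branch),

followed by a split-half analysis of how reliable the group-level maps
are.

## The synthetic cohort: what it emulates, and what it does not

The generator (`make_default_atlas()`, `sim_config()`,
`simulate_cohort()`) is a first-class, tested component: it provides the
ground truth every downstream stage is validated against.

**Forward model.** Voxel $v$ of subject $s$ at time $t$:

$$ y_{v}(t) = 100 + \delta_v \tfrac{t}{T}
  + \mathrm{snr}\sum_k w_k(v)\, g_k(t)
  + a_G G(t) + a_{WM} W(t)\,[v \in WM] + a_{CSF} C(t)\,[v \in CSF]
  + \mathbf{m}(t)^\top \boldsymbol{\ell}_v + \varepsilon_v(t) $$

with $g_k$ the four network courses, $w_k \in [0,1]$ the planted spatial
weights, $G, W, C$ band-limited nuisance courses, $\mathbf{m}$ the six
motion parameters leaking into voxels through random loadings
$\boldsymbol{\ell}_v$, and $\varepsilon_v$ AR(1) noise with unit marginal
standard deviation.

**Defaults are the study conditions**: 16 subjects, 200 volumes at
TR = 2 s, network signals confined to 0.01–0.1 Hz, snr = 1 (signal and
noise standard deviations equal at a weight-1 voxel), AR(1) coefficient
0.3, nuisance amplitudes 0.5 (global/WM/CSF) and 0.3 (motion leakage) in
noise-sd units, on a 24 × 24 × 18 grid of 4 × 4 × 5 mm voxels — a
desk-scale analog of a 64 × 64 × 19 EPI acquisition. The snr and nuisance
amplitudes are calibration choices (no printed effect sizes exist to copy
from the motivating literature); they were fixed once at values giving a
planted-voxel correlation of ≈ 0.7 with its network course
($\mathrm{snr}/\sqrt{1+\mathrm{snr}^2}$ at snr 1), typical of
well-measured rsFC effects.

**Network courses.** Four independent white-noise series are band-pass
filtered twice (to confine ≥ 90 % of periodogram power strictly inside
the band), orthonormalized by QR, and rescaled to unit variance. The
anticorrelated pair is then constructed as
$g_{TNN} = -0.7\,g_{TPN} + \sqrt{1-0.7^2}\,q$ with $q$ orthogonal and
band-limited, so corr(TPN, TNN) = −0.7 exactly while all other pairs are
exactly uncorrelated. One set of courses is shared by the whole cohort:
subjects differ in noise, motion and nuisance realizations, not in the
planted network geometry — the simplest design that makes group maps and
split-half reliability meaningful.

**Geometry.** Each network owns a Gaussian blob on a "target band"
(spatial order TPN–MOT–VIS–TNN, so the anticorrelated pair is never
adjacent and their supports stay disjoint) plus a distal blob elsewhere
in gray matter. The target mask is a 3-voxel-thick band crossing all four
blobs; dominance shifts smoothly along it, so boundary voxels mix
adjacent networks' signals. Layout is a deterministic function of the
grid.

**Not emulated:** anatomical folding or template space, cardiac and
respiratory waveforms (nuisance courses are generic band-limited
signals), susceptibility dropout, and motion-induced *spatial*
misalignment (motion parameters are supplied, not estimated). Passing
tests therefore demonstrate algorithmic correctness and statistical
calibration, not robustness to all artifacts of real acquisitions.

## Preprocessing

* **Detrend then band-pass.** Common practice in this class of pipeline
  fixes only the band (0.01–0.1 Hz); the filter here is a second-order
  Butterworth applied forward and backward (`signal::filtfilt`), so the
  effective response is fourth-order with zero phase — correlation timing
  is preserved. Detrending precedes filtering to stop ramp energy leaking
  into the low band edge. Because `filtfilt` carries no initial-state
  handling, the operator mean-centers the series first (a band-pass has
  zero DC gain; centering kills it exactly instead of leaving edge
  transients) and mirror-pads both ends. The whole temporal operation is
  linear, so it is materialized once as a $T \times T$ matrix and applied
  to all voxels by one matrix product.
* **Smoothing.** Separable Gaussian with per-axis
  $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})/\mathrm{voxel}$,
  renormalized by the smoothed mask so signal is not diluted at the brain
  edge; `fwhm_mm = 0` is the identity. The seed branch smooths at 8 mm;
  the parcellation branch deliberately does not (smoothing would blur the
  very boundaries the clustering is meant to find).

## Seed branch

* **Seeds** are 125 mm³ cubes (5 mm edge, rounded to an odd voxel count
  per axis), validated by across-subject mean gray-matter coverage ≥ 0.70
  (inclusive), pairwise non-overlapping. A bilateral seed averages the
  cube and its mirror across the mid-sagittal plane.
* **Nuisance covariates.** The conventional count of nine tissue/global
  covariates is realized as 3 sources (global, WM, CSF mean courses) × 3
  terms (course, first temporal derivative, square); a plain 3-course
  mode is available. Plus the six motion parameters. All columns
  mean-centered; zero-variance motion columns are dropped with a warning.
* **Seed orthogonalization.** Seed courses are first residualized on the
  nuisance set plus intercept, then z-normalized and sequentially
  Gram–Schmidt-orthogonalized in ROI order (double pass; each output
  re-z-normalized). The pre-residualization step is this package's
  reading of "unique seed variance": without it the first seed retains
  the global-signal component and every later orthogonalized seed
  inherits a sign-flipped copy of it, which biases the whole joint map.
  By Frisch–Waugh it leaves single-seed models unchanged. Order
  dependence is inherent and documented: permuting the seeds changes
  later seeds' maps, never the first's.
* **Prewhitening.** Per voxel: OLS fit, lag-1 autocorrelation of the
  residuals, Cochrane–Orcutt quasi-differencing of response and design
  (first observation dropped), refit. Estimates are clipped to ±0.95 with
  a warning; numerically exact fits are treated as $\rho = 0$. For speed
  the per-voxel $\rho$ is rounded to a 0.01 grid and voxels sharing a bin
  are refit in one batched least-squares call.
* **t maps.** One joint GLM per voxel (intercept + all orthogonalized
  seeds + 15 nuisance columns); $t = \beta/\mathrm{SE}$, dof = T − 1 − p
  after quasi-differencing. Voxels whose series lies exactly in the
  design span (a seed's own cube regressing on itself) would give
  unbounded t; they are capped at ±10⁶ and flagged rather than poisoning
  downstream maps.
* **Cluster-extent correction.** K is calibrated by simulating Gaussian
  noise volumes on the mask, smoothing to the analysis FWHM,
  standardizing within the mask, two-tailed thresholding at `voxel_p`,
  and recording the maximum 6-connected supra-threshold cluster; K is the
  smallest size whose exceedance probability is ≤ alpha. Extent thresholds
  quoted in the literature are tied to a specific voxelwise p and data
  geometry, so K is always recomputed for the data at hand
  (default voxel_p = 0.01
  two-tailed, alpha = 0.05, 1000 iterations); connectivity is
  configurable to 18/26.
* **Group level.** Random-effects GLM of subject betas on intercept +
  mean-centered age + sex indicator; the intercept's t with n − 3 dof;
  zero-variance voxels flagged undefined. Probability maps are plain
  relative frequencies in percent.

## Parcellation branch

* **Input**: unsmoothed, temporally filtered target-voxel time courses,
  per subject; rows z-scored; PCA keeps the smallest number of components
  reaching 90 % cumulative variance.
* **Fuzzy c-means** with the standard Bezdek updates. The fuzziness
  exponent deserves care: the feasible range of $m$ shrinks as the
  feature dimension grows, and at the ~40+ dimensions a 90 %-variance PCA
  of band-limited time courses produces, exponents ≥ ~1.6 collapse all
  memberships toward $1/c$ and merge the centroids. Fuzziness values
  quoted on some analysis tools' own scales (e.g. 0.4) live on a
  different parameterization and cannot be used directly in the standard
  ($m > 1$) form. The package default is **m = 1.3**, which keeps memberships
  graded at high dimension while hardening cleanly; low-dimensional data
  tolerate the textbook m = 2 (used in several tests against brute-force
  oracles). Convergence: max membership change < 1e−5 or 300 iterations;
  initialization from seeded distinct random rows; coincident
  voxel/centroid pairs get membership 1; the objective is recorded every
  iteration and must never increase.
* **Cluster count** is chosen unsupervised: for each c in [2, 8], 10
  restarts, best objective kept, scored by the Xie–Beni index
  (compactness over minimal centroid separation); the cohort-level count
  is the modal per-subject optimum. Many published parcellations used
  tool-specific or undocumented selection procedures; Xie–Beni is a
  standard, documented criterion, and the selection step is swappable.
* **Cross-subject alignment.** Single-subject hardened labelings are
  aligned by the label permutation maximizing total Sørensen–Dice against
  a reference (first subject, then a running majority-vote consensus, two
  passes). The permutation is found exactly by dynamic programming over
  column subsets — verifiable against exhaustive search at small c. This
  deterministic, brute-force-checkable scheme stands in for the
  self-organizing group-ICA-style aggregation methods used elsewhere in
  the field, whose internals are tool-specific.
* **Cluster naming.** Each cluster's centroid course
  ($u^m$-weighted voxel mean) is correlated with candidate network
  courses; labels are assigned injectively by exact assignment
  optimization, with clusters flagged (not failed) when the top two
  correlations are within 0.05.
* **Reporting.** Probabilistic cluster maps are percentages of subjects;
  a 10 % display floor is applied only at the reporting layer, raw values
  retained.

## Reliability

For each of `n_splits` (default 100; the acceptance computation uses 50)
random equal splits, the group map is built per half and compared by
Sørensen overlap: fuzzy mode on probability maps (values scaled to
[0, 1]), binary mode on thresholded maps; the Spearman–Brown projection
$2r_h/(1+r_h)$ is reported per map per split with the mean summarized.
Conventions: an odd cohort is rejected with instructions to drop one
subject; two empty maps count as perfect agreement (1, flagged with a
warning) to avoid 0/0.

## Numerical and interface conventions

Voxel indices are 1-based inside R and 0-based in ROI files
(tab-separated `label cx cy cz edge_mm bilateral`); grids are RAS-like
with voxel sizes recorded in NIfTI pixdims. Ties in hardening break to
the lowest cluster index. NaN anywhere in a stage's input raises rather
than propagating. `run_pipeline()` validates every parameter before any
compute, logs the declared conventions (nuisance expansion, fuzziness
scale), and writes a JSON manifest from which every output is
reproducible.

## Problem sizes used by the test suite

Unit tests run on reduced fixtures (16 × 16 × 12 grids, 2–8 subjects,
80–100 volumes) chosen so each property is still identifiable; the
end-to-end checks use the full default conditions (16 subjects,
24 × 24 × 18, 200 volumes). Monte-Carlo calibrations use 100–2000
iterations depending on how tight the tested bound is.

## Known limitations

* The synthetic cohort shares one set of network courses across subjects;
  between-subject variability is purely noise/nuisance, which makes group
  maps more stable than real cohorts would be. Reliability numbers on
  synthetic data are therefore upper-end.
* AR(1) is the only autocorrelation model; real BOLD noise is closer to
  AR + white mixtures.
* The Xie–Beni cluster-count criterion and the Dice-consensus grouping
  are principled choices among several defensible ones; other criteria
  (silhouette, stability selection) could select differently on weakly
  structured data.
* No surface-based analysis, template registration, or anatomical
  labeling: outputs are voxel maps on the input grid.
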