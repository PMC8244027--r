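---
title: "Methods: vascular explanations of age effects on RSFA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vascular explanations of age effects on RSFA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind `rsfavasc`, the
choices made where the design was genuinely open, what the synthetic
cohort generator does and does not emulate, and the package's numerical
conventions. It states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## The scientific question and the two-stage model

The resting-state fluctuation amplitude (RSFA) — the standard deviation
over time of a band-passed, denoised resting BOLD series at each voxel —
is a practical proxy for vascular reactivity. Using RSFA to normalize BOLD
contrasts presumes that *age differences* in RSFA are vascular in origin.
The pipeline tests that presumption with a two-stage procedure applied to
every RSFA voxel (or ICA component):

* **Stage 1.** Regress RSFA across subjects on vascular and volumetric
  predictors plus covariates of no interest (sex, head motion,
  handedness; a CSF signal when grey-matter volume is a predictor). Age
  never enters stage one. Six nested models are defined: covariates only
  (I); adding cerebral blood flow (II); adding cardiovascular factor
  scores (III); both (IV); grey-matter volume (V); and grey-matter volume
  orthogonalized with respect to the cardiovascular factors (VI).
* **Stage 2.** Correlate the stage-1 residuals with age (Pearson, t-based
  two-sided p, Benjamini–Hochberg FDR across voxels/components at
  q = 0.05).

If a model's predictors fully account for the age effect on RSFA, its
residuals are uncorrelated with age. The mediation hypothesis predicts the
contrast: Model I shows widespread residual age correlations; Model IV
shows none.

Assumptions worth making explicit: linear, homogeneous predictor–RSFA
relationships across subjects; residual exchangeability across subjects
for the permutation test; and vascular predictors measured with little
enough error that conditioning on them actually removes the planted
pathways (see *Factor-score determinacy* below).

## RSFA estimation

RSFA is estimated by a single GLM per voxel whose design contains the
nuisance regressors *and* a discrete-cosine band-stop set, so nuisance
regression and 0.0078–0.1 Hz band-pass filtering are simultaneous — never
sequential. Conventions:

* **DCT set.** Orthonormal DCT-II columns `k = 1..N-1` with frequencies
  `k/(2 N TR)`; columns outside the passband are included as regressors.
  The printed band edges are taken literally. The filter's transition
  width is one frequency bin (about 1 mHz at N = 255, TR = 1.97 s), so
  sinusoid-retention contracts are evaluated a few bins away from the
  edges.
* **"Normalized" SD.** Two modes: `"mean"` (default) divides the residual
  SD by the voxel's raw temporal mean — a coefficient of variation,
  invariant to multiplicative scanner scaling — and `"raw"` returns the
  plain SD. The choice is surfaced in the configuration rather than fixed
  silently.
* **SD convention.** Sample SD (denominator N−1), fixed and documented.
* **Derivatives.** Backward first differences with a zero first element.
* **Head motion summary.** Root-mean-square volume-to-volume translation
  displacement.
* **Masking.** Voxels outside a supplied mask are `NA`, never zero.
* **Degeneracies.** A design with no residual degrees of freedom, an
  empty tissue mask at the 0.7 probability threshold, or NaNs in nuisance
  inputs are errors; constant or collinear design columns are dropped
  with a warning.

## Cardiovascular factors

The seven measures (mean HR, LF- and HF-HRV, systolic and diastolic blood
pressure, WMH volume, BMI) are each tested against a normal with its own
sample mean and SD (one-sample Kolmogorov–Smirnov, no Lilliefors
correction — matching the default behaviour of the tool this procedure
mirrors; the uncorrected test is anti-conservative, flagged here as a
sensitivity point). Failing variables must be strictly positive and are
log-transformed, then re-tested. Only the log transform is applied to
these variables (all seven are positive); an exponential transform is not
needed for them.

Factor extraction is maximum-likelihood on standardized variables with
varimax rotation and regression-method scores; scores are re-standardized
to mean 0, SD 1 before entering any regression. Factor order is by
explained variance, sign fixed so each factor's largest-|loading|
variable loads positively. Uniquenesses are floored at `1e-3`; hitting
the floor (Heywood case) warns. The factor count uses the Kaiser rule
(correlation eigenvalues > 1) with an override defaulting to the
three-factor structure the analysis is built around. PCA-flavoured
extraction was considered and rejected as the default because the cited
tool's default is the ML common-factor model; the Kaiser count is
computed from the correlation spectrum either way.

## Group spatial ICA

Each modality's subjects × voxels matrix is decomposed with subjects as
observations and voxels as samples (the source-based-morphometry
orientation), identically for RSFA, CBF and GMV:

* **Order selection.** The eigenvalue-based MDL functional
  `-N (p-k) log(GM/AM) + k (2p-k+1)/2 log N` over candidate orders
  `1..p-1`, computed from the subject-covariance spectrum, with *no*
  i.i.d.-subsampling smoothness correction — the synthetic data carry no
  fMRI-like spatial autocorrelation that such corrections compensate for.
  Note the functional is not invariant to duplicating subject rows (that
  doubles `p` and appends a zero tail to the spectrum); it *is* invariant
  to global rescaling.
* **Unmixing.** fastICA fixed-point iterations with the log-cosh
  negentropy contrast, symmetric decorrelation, tolerance `1e-6`, at most
  1000 iterations, 5 seeded restarts keeping the best-objective
  convergent run. Sources are sign-fixed to positive skewness and ordered
  by explained mixing variance; `mixing %*% sources` reconstructs the
  rank-k PCA approximation of the (voxel-centered) data by construction.
* **Missing voxels** are excluded before decomposition and reinserted as
  `NA`.

## The distribution-shape permutation test

Beyond voxel-wise FDR, the pipeline asks whether the *distribution* of
age–residual correlations across voxels differs from its permutation
null. P permuted datasets are built by jointly permuting the subject
labels of the RSFA matrix (one permutation per iteration, shared across
voxels — preserving the spatial dependence inside each null draw; the
per-voxel-independent alternative is available but destroys it). The
first-stage design is the observed one throughout; only RSFA is permuted.
Inside this procedure the first stage is OLS for observed and permuted
data alike — using one estimator on both sides keeps the comparison
exchangeable, and a robust refit inside every permutation is available at
a cost flag.

Given the P+1 correlation distributions, medians and shapes of observed
versus pooled-permuted data are compared by Wilcoxon rank-sum and KS
tests (pooling is the default; per-permutation comparison is a flag). All
P+1 distributions are then compared pairwise by the two-sample KS
statistic; each distribution's similarity profile is its row of that
matrix without the diagonal. `np` counts the permutation profiles the
observed profile differs from (two-sided rank-sum at alpha = 0.05,
uncorrected).

**Counting direction.** The source description of this procedure is
internally inconsistent: it defines Np as the number of *significant*
profile comparisons yet interprets a ratio *below* 0.05 as evidence
against randomness — under a gross shape difference the significant count
approaches P, so that reading can never fire. The package resolves this
by reporting the add-one Monte-Carlo ratio
`p_ratio = (P − np + 1)/(P + 1)`: the fraction of the permutation
ensemble whose similarity profile the observed profile is
indistinguishable from. Small values (observed resembles almost no null
draw) are significant, matching the small-is-significant semantics of
the reported tissue-by-model tables. Under a fully null generator the
decision `p_ratio < 0.05` is conservative (the profile comparisons are
strongly dependent, so `np` rarely approaches P); under planted shape
differences `np → P` and the ratio drops to `1/(P+1)`.

The tissue variants repeat the full procedure on voxels whose class
probability exceeds 0.4 (or whose synthetic label matches), for GM, WM,
CSF and the whole brain, and emit one table row per model. Desk-scale
default is P = 199; the full-scale setting (P = 4999, i.e. 5000
distributions) is a configuration value.

## The synthetic cohort: what it emulates

`cohort_spec()` defaults are the package's study conditions: n = 250
subjects, ages uniform on 18–88 years, a 16×16×16 grid (4096 voxels),
4 sources per modality, latent factor–age correlations
(+0.061, −0.417, +0.713), and a vanishing direct age→RSFA path.

* **Latent factors.** Age is uniform; the three factors are jointly
  Gaussian given standardized age via a Cholesky construction, mutually
  orthogonal by default (matching a varimax solution in which several
  orthogonal factors each correlate with age). Orthogonality given the
  age correlations requires the conditional covariance to be positive
  semi-definite (sum of squared age correlations at most 1); infeasible
  targets are rejected with a diagnostic, never repaired. The
  inter-factor covariance is a parameter (`factor_cor`), not an
  assertion.
* **Indicators.** The seven raw measures are linear mixtures of the
  factors mapped to realistic units; WMH is exponentiated so its marginal
  is log-normal and the normality-transform rule is genuinely exercised.
  Indicator communalities are deliberately high (0.63–0.88, giving
  factor-score determinacy² of 0.85–0.92): the mediation contrast is only
  recoverable if the factor scores measure the latent factors reliably —
  with weak indicators, score indeterminacy leaks planted age signal into
  every model's residuals, a measurement limitation no analysis can
  undo. This is a property of the emulated measurement battery, chosen
  once.
* **Spatial structure.** Tissue labels partition the grid concentrically
  (CSF core, WM shell, GM elsewhere). Sources are Gaussian blobs
  (σ = 1.8 voxels at grid 16) with compact thresholded support, unit
  norm, dominant tissue class cycling GM, GM, WM, CSF, and centers
  rejection-sampled at least 2.8σ apart (pairwise overlap < 0.15,
  |cosine| < 0.2).
* **Mediation.** Planted at the component-loading level and projected to
  voxels: CBF loadings depend on age; GMV loadings on age and a factor;
  RSFA loadings are `cvh_rsfa·factor + cbf_rsfa·CBF-loading +
  direct_age_effect·age + noise`. All modalities share one source layout
  by default (`shared_sources`): with per-modality layouts a voxel's CBF
  value is a different mixture of the age-carrying loadings than the CBF
  contribution to that voxel's RSFA, and voxel-matched regression cannot
  remove the cerebrovascular path even in principle; sharing the layout
  makes the voxel-matched models faithful to the planted causal
  structure and mirrors the idea that the same anatomy expresses itself
  in every modality.
* **BOLD series.** 255 retained volumes at TR 1.97 s (261 acquired minus
  6 discarded is the emulated acquisition), baseline 100, plus white
  noise projected onto the in-band DCT subspace and scaled per voxel so
  the sample SD equals the target RSFA, plus motion-locked drift and
  global WM/CSF signals. The in-band signal is additionally
  orthogonalized against the realized nuisance regressors (projected
  into the in-band subspace first, so the result stays in-band): without
  this the signal's chance overlap with ~20 nuisance columns attenuates
  recovered RSFA by 10–15 %. Residual mismatch comes only from the
  estimator measuring WM/CSF signals from the data rather than receiving
  the planted ones.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: no hemodynamic forward model or MR physics;
no spatial autocorrelation beyond the planted blobs (real fMRI noise is
smooth, which affects MDL order selection and FDR behaviour); no motion
image artifacts (motion enters only as regressors and planted drift); no
non-linear age trajectories; and GMV here carries a vascular-style age
signal through the shared sources, so the volumetric models can absorb
more of the age effect than atrophy does in real cohorts.

## Problem sizes and determinism

All randomness flows from one seed through named substreams
(`substream_seed`), so identical configuration and seed give identical
numerical outputs; the test suite checks this at the byte level on the
pipeline's TSV artifacts. The validation suite uses: 250 subjects × 4096
voxels × 20 seeds for the mediation contrast; 5 seeds for ICA recovery
and 20 for factor congruence (n = 500); 100 seeded runs at n = 60,
V = 500, P = 99 for permutation-test calibration and power; and 8³ grids
for BOLD round trips. These sizes were chosen as the smallest at which
the Monte-Carlo error of each property is comfortably below its margin.

## Known limitations

* The KS normality screen without small-sample correction is
  anti-conservative; borderline variables may be log-transformed more
  often than a corrected test would.
* The permutation test's profile comparisons are mutually dependent;
  `p_ratio` is a calibrated-by-construction Monte-Carlo quantity only
  under the package's counting direction, and is conservative under the
  null rather than uniform.
* Robust IRLS inside every permutation is exact but expensive; the OLS
  default inside the permutation test trades outlier resistance for
  exchangeability and speed (the robust estimator is still applied to
  the observed data in the model suite itself).
* Component matching is exhaustive only up to 8 components; beyond that a
  greedy assignment is used.
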