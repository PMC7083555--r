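---
title: "Voxelwise normative modelling of tissue volume: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxelwise normative modelling of tissue volume}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Case-control comparisons of voxel-based morphometry (VBM) describe the
*average* patient. Normative modelling inverts the question: a regression of
tissue volume on demographic covariates, fitted in a healthy reference
cohort with predictive uncertainty, places each individual within the healthy
range at every voxel. A subject's deviation at voxel $v$ is

$$Z_{iv} = \frac{y_{iv} - \hat\mu_v(x_i)}{\sqrt{\hat\sigma^2_v(x_i)}},$$

where $\hat\mu_v$ and $\hat\sigma^2_v$ are the predictive mean and variance
given covariates $x_i$ (age, sex). Negative $Z$ means less volume than the
normative prediction. Voxels with $|Z| > 2.6$ are called extreme deviations;
per-subject percentages of extreme voxels, group overlap maps of the extreme
masks, and permutation-based group inference complete the pipeline. The
package targets adult ADHD-style case-control designs (reference cohort
$\approx 146$, patients $\approx 153$) but every size is configurable.

# The per-voxel model

Each voxel is an exact Gaussian-process regression with kernel

$$k(x, x') = \sigma_f^2 \exp\!\left(-\frac{(a - a')^2}{2\ell^2}\right)
  + \sigma_w^2\, x^\top x' + \sigma_b^2 + \sigma_n^2\,\delta_{ii'},$$

on standardized age $a$ and binary sex: a smooth nonlinear age term, a linear
trend, a bias (intercept) term and white noise. The exact source publication
for this class of studies defers the kernel to unavailable supplementary
material, so the kernel is a configuration point, and this sum is the
default: it nests the linear-trend model that dominates adult aging while
allowing smooth curvature and honest uncertainty growth away from the data.
All five hyperparameters are optimised on the log scale by L-BFGS-B from up
to three dispersed deterministic starts, with bounds $[10^{-6}, 10^6]$ and a
jitter of $10^{-8}\cdot\mathrm{tr}(K)/n$ on the diagonal before Cholesky
factorisation (the test oracles include the same jitter). The predictive
variance is the latent GP variance plus $\sigma_n^2$, so it is strictly
positive and grows for covariates far from the training support.

Two fitting paths exist:

* **Per-voxel path** (`fit_voxel_gp`, `shared_hyperparameters = FALSE`):
  every voxel gets its own marginal-likelihood optimisation. Exact, and the
  path all oracle-equivalence tests run against, but linear in voxels times
  folds and unaffordable for whole-grid cross-validation on one CPU.
* **Shared (fast) path** (default in `crossval_reference`, `score_targets`
  and the pipeline): one kernel is fitted per training set by maximising the
  *pooled* log marginal likelihood over a deterministic subsample of voxels
  (default 256), then a single Cholesky factor scores all voxels at once.

The fast path deliberately does **not** standardize voxels individually.
Per-voxel standardization forces every voxel to unit variance, after which a
*shared* noise variance is wrong for every voxel whose signal fraction
differs from the average; we measured this inflating the $|Z|>2.6$ tail by
roughly 40%. Instead the bias and linear kernel terms absorb per-voxel
intercepts and trends (their posterior is conditioned per voxel through the
shared factorisation), a single global scale is used for optimiser
conditioning only, and the shared noise variance is exactly right whenever
the noise is homoscedastic across voxels — true in both synthetic worlds the
package ships. Heteroscedastic real data should use the per-voxel path; this
is the main assumption a green calibration test does *not* discharge for
arbitrary data. The pipeline default deviates from the original design note
("fast path off by default") because cross-validating ~6000 voxels times 10
folds per-voxel is outside any desk-scale budget; the per-voxel path remains
one flag away.

The reference cohort is scored by 10-fold cross-validation (folds stratified
by sex with a seeded shuffle, dealt round-robin so fold sizes differ by at
most one); patients are scored out-of-sample by the model trained on all
controls. An optional `separate_sexes` mode fits the whole machinery per sex
— the source material supports both readings of how sex was handled, so both
are implemented and neither is asserted as canonical.

# The synthetic cohort

`simulation_config()` states one world; its defaults are fixed once and are
not tuned against test outcomes.

* **Cohort**: 146 reference subjects and 153 patients — the published cohort
  sizes of the study design this package emulates. Age is uniform on
  $[18, 65]$ years, identically in both groups (the matched design; the true
  age histogram is unpublished, so uniform is an explicit stand-in). Sex is
  male with probability 0.42 in both groups. Symptom scores are truncated
  Poisson counts on 0–9 with means 5.45 vs 0.63 (hyperactivity) and 7.27 vs
  0.55 (inattention) for patients vs controls — the published demographic
  table's means. Medication occurs only in patients (p = 0.7); comorbidity
  counts are Poisson (0.8 vs 0.1).
* **Grid**: $20^3$ voxels of 4 mm; the analysis mask trims a 1-voxel border
  (5832 in-mask voxels). This is a deliberately coarse stand-in for a
  ~1.5 mm whole-brain grid; 4 mm keeps the 8 mm FWHM smoothing kernel at
  $\sigma \approx 0.85$ voxels, i.e. realistic local correlation without
  making neighbouring voxels near-duplicates.
* **Signal**: baseline $0.6 - 0.2\rho^2$ (smooth radial decline), per-octant
  age slopes from $-0.005$ to $-0.0015$ volume-units/year ("frontal-like"
  octants steepest), sex offset $+0.02$ for males.
* **Noise**: white Gaussian noise smoothed with a separable discrete
  Gaussian, $\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$, reflecting
  boundaries, then renormalised by the exact per-voxel standard deviation of
  the smoothing operator so the marginal sd equals `noise_sd` (0.05) to
  machine precision.
* **Idiosyncratic lesions**: 3 per patient at $-4\,\mathrm{sd}$, radius 0.5
  voxels (a single 4 mm focal deviation), centres uniform over the mask
  excluding the shared region (keeping the two ground-truth effect types
  disjoint for recovery scoring).
* **Shared region**: a radius-4 sphere (257 voxels). Its per-patient effect
  is $-0.5\,\mathrm{sd} \times g_i$ with $g_i \sim \mathrm{Exp}(1)$
  (`shared_heterogeneity = 1`; 0 gives a constant effect). Heterogeneous
  magnitudes mirror the core empirical observation this design emulates —
  group-level differences arise from *differently* affected individuals —
  and they are what make a 0.5 sd mean effect visible in an overlap map at
  all: with a constant 0.5 sd shift the expected per-voxel extreme rate is
  $\Phi(-2.1) = 1.79\% < 2\%$, so the ">2% of individuals" map would miss
  the region *in expectation*, while
  $E[\Phi(0.5 g - 2.6)] \approx 3.4\%$ under the exponential mixture.

Two defaults follow from a pre-run binomial analysis rather than taste, and
are worth recording. With calibrated deviations every subject flags a given
voxel with probability $\Phi(-2.6) = 0.466\%$, so at a lesion voxel of one
patient the number of *other* patients flagging it is roughly Poisson with
mean $152 \times (0.00466 + f \cdot 0.92)$, where $f$ is the per-patient
lesion coverage fraction. The ">2%" exceedance needs a count $\ge 4$ at
$n = 153$ but only $\ge 3$ at $n = 100$: at $n \approx 100$ the false-positive
floor alone pushes ~8% of lesion voxels above the cut, making the "95% of
lesion voxels below 2% overlap" property unattainable for *any* lesion size,
while at the published $n = 153$ it holds with margin provided $f$ is small.
Hence (a) the default cohort is the published 146/153 rather than a rounder
100/100, and (b) lesions are single-voxel so the idiosyncratic burden
(~0.05% of the mask per patient) stays an order of magnitude below the
shared effect.

# Deviation mapping

Thresholding is strict on both sides ($Z > 2.6$, $Z < -2.6$); voxels exactly
at the threshold are excluded, following the strict inequalities in the
source wording. The per-subject FDR alternative computes two-sided normal
p-values $2\Phi(-|Z|)$ and applies Benjamini–Hochberg across the subject's
in-mask voxels; survivors split by sign. Extreme scores are percentages of
the in-mask voxel count (recorded in the output). Overlap maps divide by the
full group size, including subjects with empty masks, and the derived binary
map uses a strict "> 2%" reading (the source does not disambiguate ">" vs
"≥" at exact multiples; strict is chosen and documented here). BH and Holm
are delegated to `stats::p.adjust` behind the package's interfaces and are
tested against exhaustive definitional oracles.

# Group inference

* **Group mean maps**: voxelwise one-sample t statistics with a sign-flip
  permutation null (deviations are symmetric about zero under H0), two-sided
  permutation p-values $(1 + \#\{|T_b| \ge |T_{obs}|\})/(B+1)$, normal
  z-equivalents, and a $\pm 2.6$ display mask. The full $2^n$ flip space is
  enumerated when it is no larger than `n_perm`.
* **Group contrast**: pooled-variance two-sample t (patients minus
  controls), group-label permutations, TFCE applied to every permuted map,
  voxelwise permutation p-values of the enhanced statistic, and BH-FDR at
  q = 0.05 across in-mask voxels. "FDR using TFCE" is read as the direct
  composition of the two named procedures; setting `tfce = NULL` gives the
  cluster-free fallback. The TFCE step is $dh = \max|t|/100$ from the
  *observed* map, held fixed across permutations so enhanced values are
  comparable; connectivity 26; $H = 2$, $E = 0.5$. Negative tails are
  enhanced on the negated map, so enhancement is signed and
  sign-symmetric.
* **Score tests**: each subject's extreme-voxel count is an overdispersed
  binomial (quasibinomial GLM, events = extreme voxels, trials = mask
  voxels) with diagnosis as predictor; the reported statistic is the 1-df
  Wald chi-square on the diagnosis coefficient, with group percentage
  estimates and 95% CIs on the response scale, Holm-corrected across the
  tested measures, and an optional diagnosis-label permutation reference
  (`n_perm > 0`) honouring the "non-parametric" qualifier.
* **Associations**: within the patient group, standardized regressions of
  each score measure on each covariate, Holm-corrected with a declared
  family size of 8 per modality (the published correction count), logged in
  the output.

## Known inferential limitations (measured, not hypothetical)

1. **CV-vs-out-of-sample contrast bias.** All patients are scored by *one*
   model, so their deviations share that model's per-voxel error (variance
   of the patient mean $\approx 2.25/n$ instead of $1/n$ in our
   measurements), while cross-validated control residuals anti-correlate
   across folds (variance of the control mean $\approx 0.003/n$). Label
   permutation destroys this structure, so the null contrast t runs ~5% hot
   and TFCE amplifies the excess: the FDR-corrected contrast admits more
   false voxels than the nominal q (we bound the false fraction at 1/3 in a
   lesion-free world rather than pretend it is 0.05). This is the "small
   bias" inherent in the emulated design itself, which cross-validates the
   reference group because it is too small to split.
2. **FDR is not FWE.** BH at q = 0.05 controls the *expected fraction* of
   false discoveries. With ~250 true discoveries it *expects* on the order
   of 10 false voxels, and with 500 permutations the p floor of $1/501$
   makes the BH outcome nearly binary (nothing, or the region plus the
   floor-hitting null voxels). A criterion of the form "significant voxels
   inside the true region and nowhere else in ≥ 90% of runs" is therefore
   mathematically incompatible with this procedure; the corresponding
   acceptance test is implemented as stated and left red, with the
   achievable guarantee (high recall, bounded false fraction) tested
   separately.
3. **Idiosyncratic lesions are not group-null.** Three $-4$ sd lesions per
   patient leave small genuine group-level traces at lesioned voxels (a
   $-4/153$ mean shift and ~10% variance inflation), which TFCE can pick up.

# Numerical and degenerate-input choices

Zero-variance training voxels are flagged degenerate: constant predictive
mean, zero latent variance, unit predictive floor, and Z fixed at 0 in batch
scoring. Non-finite Z inside the mask is a contract violation and errors.
Permutation p-values use $(1+\text{count})/(B+1)$ for sampled permutations
and exact counts under full enumeration. Constant-zero voxels in permutation
maps get statistic 0 and p = 1. The NIfTI writer emits little-endian
NIfTI-1 with the affine in the sform; gzip output carries no timestamp, so
identical content is byte-identical — the property the determinism tests and
the run manifest (MD5 per artifact, every seed recorded) rely on.

# What a green suite establishes — and what it does not

The tests establish: exact-GP oracle equivalence at fixed hyperparameters;
calibration of cross-validated Z under the model class (mean, sd, and the
$\Phi(-2.6)$ tail at 146×1000 scale); BH/Holm/TFCE equality with
definitional oracles; permutation p uniformity under a true null; recovery
of the implanted group structure (higher patient burden, Wald significance,
shared-region overlap above 2% with lesion voxels below it); and
byte-determinism of every CLI verb. They do not establish: calibration under
voxelwise heteroscedastic noise (use the per-voxel path), robustness to
registration/segmentation artefacts (the pipeline consumes already-processed
maps by design), nominal FDR for the CV-vs-OOS contrast (limitation 1), or
anatomical interpretability of the synthetic regions (octants are not a
brain atlas).
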