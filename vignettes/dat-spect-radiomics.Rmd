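---
title: "Striatal DAT-SPECT radiomics: models, phantom design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Striatal DAT-SPECT radiomics: models, phantom design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(striatomics)
```

## The problem

Dopamine-transporter SPECT (DAT-SPECT with ¹²³I-FP-CIT) images striatal
dopaminergic integrity. In Parkinson's disease (PD) transporter density
falls, beginning in the posterior putamen and progressing anteriorly, so
both the *amount* of striatal uptake and its *spatial texture* carry
diagnostic information. The conventional quantity is the striatum uptake
ratio against an occipital reference region,

$$\mathrm{SUR}(\%) = \frac{C_\text{striatum} - C_\text{background}}
{C_\text{background}} \times 100,$$

computed for caudate, putamen and pallidum and averaged over hemispheres,
with caudate ratios $\mathrm{CR}_x = \mathrm{SUR}_\text{caudate} /
\mathrm{SUR}_x$. `striatomics` implements this panel together with a
930-dimensional radiomics characterisation: 186 IBSI-style features per
region (50 first-order + 136 higher-order texture features from the GLCM,
GLRLM, GLSZM, GLDZM, NGTDM and NGLDM families) for three bilateral
striatal regions, plus elementwise caudate/putamen and caudate/pallidum
ratio blocks ($186 \times 5 = 930$). A sparse linear *radiomics
signature* is built from these features by LASSO:

$$\hat\beta = \arg\min_\beta \frac{1}{2n}\lVert y - \beta_0 - Z\beta
\rVert^2 + \lambda \lVert\beta\rVert_1,$$

on z-scored features $Z$ and 0/1 group labels $y$, with $\lambda$ chosen
by stratified ten-fold cross-validation; the signature score of a subject
is $\sum_i \hat\beta_i z_i$ over the selected features. Classification is
evaluated with Mann–Whitney AUCs, DeLong confidence intervals and paired
tests (Bonferroni-corrected), Wilcoxon rank-sum group comparisons, and
training-set Youden cut-offs, and with four fixed-hyperparameter
classifiers (cubic-polynomial SVM, 1-NN, LDA, decision tree) fed the
signature, the putaminal SUR, or both.

Because clinical DAT-SPECT databases are access-restricted, the package
ships a synthetic phantom cohort generator: every pipeline stage is
exercised end to end on simulated volumes with known construction, and
every claim the test suite makes is about that construction.

## The phantom

Phantoms live on the standard spatially normalised grid
(91 × 109 × 91 voxels, 2 mm isotropic). The atlas places six
mirror-symmetric ellipsoidal VOIs (caudate, putamen, pallidum; the
putamen elongated anteroposteriorly) and a posterior occipital slab.
A subject is built in four steps:

1. **Noiseless uptake map.** Background `mu_bg` everywhere (100 counts);
   each striatal region set to `contrast × mu_bg` with defaults 3.0
   (caudate), 2.5 (putamen), 2.0 (pallidum) — with these values the
   noiseless SURs have the closed forms 200%, 150%, 100%, which the
   tests exploit.
2. **Disease effect (PD only).** A multiplicative loss ramp in the
   putamen from `1 − gradient_depth` at the posterior pole to 1 at the
   anterior pole (default depth 0.6, linear), plus uniform fractional
   losses of 0.15 in the caudate and 0.25 in the pallidum — the
   posterior-dominant putaminal loss with milder caudate/pallidum
   involvement that characterises PD.
3. **Subject variability.** Log-normal multipliers (sd 0.08) on the
   regional contrasts and Gaussian jitter (sd 0.12) on the gradient
   depth, so cohorts have realistic overlap rather than two point
   masses.
4. **Measurement.** Additive Gaussian noise (sd 10 counts) *before*
   smoothing — the artifact emulates the post-reconstruction product, for
   which Gaussian noise is a reasonable description — then separable
   Gaussian smoothing at the 6-mm PSF FWHM
   ($\sigma = \mathrm{FWHM}/2\sqrt{2\ln 2}$, edge-renormalised so
   constants are preserved), a per-scanner global gain (1.0 / 0.9) and
   noise multiplier (1.0 / 1.3) for the two pseudo-scanners, and clipping
   at zero.

The default cohort design mirrors a two-scanner structure of
81 + 239 subjects (scanner 1, split 7:3 into train/test) and
20 + 73 subjects (scanner 2, entirely a second test set), 413 in all.
A root seed is forked deterministically per subject and per stage, so a
run is bit-for-bit reproducible and changing, say, the model list never
perturbs phantom noise.

**What the phantom does and does not emulate.** It reproduces the
*directions* of the group contrasts that motivate the analysis — lower
putaminal (and pallidal) SUR in PD, higher putaminal histogram skewness,
lower putaminal zone-distance non-uniformity (larger, fewer uniform
zones when uptake is lost posteriorly) — but no attempt is made to match
patient-data effect magnitudes, which depend on biology, scanner physics
and reconstruction that the phantom does not model (no projection/
reconstruction simulation, no attenuation, no partial-volume effect
beyond the PSF, no registration error). Passing tests therefore
demonstrate that the machinery is correct and that the analysis recovers
what was built in — not that the phantom's AUCs transfer to real
cohorts.

## Radiomics conventions

The defining choices, all config-exposed in `radiomics_config()`:

* **Discretisation:** fixed bin number (FBN), 64 bins, per-VOI min–max.
  FBN is the recommended choice for non-calibrated units such as SPECT
  counts and makes all discretised features invariant to positive affine
  intensity transforms (a tested property).
* **Aggregation:** GLCM and GLRLM are computed over the 13 unique 3D
  directions and reported both direction-averaged and merged
  (25 × 2 = 50 and 16 × 2 = 32 features), which is the only IBSI-consistent
  reading of the 50/32 family counts; GLSZM, GLDZM, NGTDM and NGLDM are
  single 3D matrices.
* **Connectivity:** 26-connectivity (Chebyshev distance 1) for
  co-occurrences, zones, neighbourhoods and dependence counts;
  NGLDM coarseness tolerance α = 0.
* **GLDZM distances:** straight-line Chebyshev distance to the nearest
  non-VOI voxel, with out-of-image counting as border and minimum
  distance 1, computed by an exact two-pass chamfer transform.
* **Bilateral handling:** features are computed per hemisphere and
  averaged at the *feature* level (left/right mean); merging the voxels
  first is available as `bilateral = "pooled"`. The caudate-ratio blocks
  are elementwise ratios of bilateral feature values; a denominator
  within machine epsilon of zero makes the entry undefined (`NA`), and
  undefined columns are dropped before selection rather than imputed.
* **Degenerate conventions:** constant VOIs define skewness/kurtosis as
  0, the coefficient of variation as 0 at zero mean, GLCM correlation as
  1 at zero marginal variance, NGTDM coarseness capped at 10⁶.
  Percentiles use R's default (type 7) convention. NGLDM dependence
  counts k = 0..26 enter emphasis weights as k + 1 so isolated voxels
  are well-defined.

The texture matrices themselves are built in C++ for speed; a pure-R
brute-force enumerator for every family lives in the test suite and the
builders are required to agree with it *exactly* on a thousand random
VOIs per run.

## Signature construction

Least-squares (Gaussian) LASSO on the 0/1 label is the deliberate model
family — the analysis this package reproduces used a linear lasso — with
logistic regression intentionally out of scope. The solver is cyclic
coordinate descent with soft-thresholding, warm starts down a 100-point
log-spaced grid from $\lambda_{\max} = \max_j |x_j^\top (y - \bar y)|/n$
to $10^{-4}\lambda_{\max}$, an active-set strategy, and convergence when
the largest coefficient change falls below $10^{-7}$. It is checked
against the soft-threshold closed form on orthonormal designs, OLS at
$\lambda = 0$, and an independent solver (glmnet).

Cross-validation is stratified by class and seeded. Two selection rules
are provided: the CV-minimum rule (the default, and the default of most
lasso toolboxes) and the one-standard-error rule. For the small-cohort
*recovery* analyses in the test suite — 20 replicate cohorts of 28
subjects whose disease effect is confined to the putamen — the 1-SE rule
is used, the standard parsimony choice when $p \gg n$, where the CV-min
rule deliberately overselects. Multi-collinearity is not pre-filtered;
that is LASSO's job.

The recovery cohorts use the phantom's `confine_effect` variant, which
applies the disease factors to the VOI voxels *after* smoothing. This is
deliberate: under the realistic model the 6-mm PSF carries a putaminal
loss into the adjacent pallidum (whose centre sits only ~8 mm away), and
the pallidum blocks then show genuine group differences — on an
independent cohort the spilled-over pallidum features separate the
groups at p < 10⁻⁴, and LASSO is *right* to select some of them. An
experiment that asks whether selection concentrates on the blocks
carrying the built-in effect therefore needs a construction in which the
effect is confined to those blocks, which is what the variant provides;
the spillover behaviour of the realistic variant is a finding about the
physics, not a selection failure.

The five-feature signature published for this analysis
(`published_pd_signature()`) ships verbatim as a packaged constant:
its coefficients were estimated on restricted patient data and are *not*
re-derivable from phantoms, so no numerical reproduction of
λ = 0.0967 or the coefficient values is attempted. Its source table
lists one feature tag twice; the in-text equation distinguishing the raw
from the normalised dependence-count non-uniformity is taken as
authoritative.

## Evaluation choices

* AUC is the Mann–Whitney probability with ties counted ½; an
  independent trapezoid ROC integration must agree to $10^{-12}$.
* Single-AUC confidence intervals use the DeLong standard error (the CI
  method was unstated in the source analysis; DeLong is the standard
  choice and keeps one covariance machinery for CIs and tests).
* Optimal cut-offs maximise Youden's J on training data only, ties going
  to the lower threshold; the positive orientation is fixed from the
  training group means, so indices that are *lower* in PD (all SURs) are
  evaluated in their discriminative direction.
* 1-NN has no continuous vote, so its decision score is the signed
  difference between the distances to the nearest training neighbour of
  each class — a documented scoring rule, not an inference about the
  original authors' software. SVM and LDA use signed boundary distances
  / posterior probabilities; the tree uses leaf class fractions.
* Wilcoxon rank-sum tests are two-sided, exact for small untied samples.

## Problem sizes used by the tests and the acceptance script

The full 413-subject design at ~0.5 s per subject is practical but
unnecessary for verification; the suite uses the same generator defaults
at reduced cohort sizes, chosen once: a 42-subject default-parameter
cohort (14 + 14 scanner 1, 7 + 7 scanner 2) for the directional and
model-comparison checks, and twenty 28-subject putamen-only cohorts for
selection recovery. The acceptance script runs a 128-subject cohort
(24 + 72 / 8 + 24), preserving the 3:1 PD:NC imbalance and both scanner
test sets. Grid resolution is never reduced: at half resolution the 6-mm
PSF bleeds putaminal signal into neighbouring structures and genuinely
changes the analysis.

## Known limitations

* The phantom's texture signal is whatever survives smoothing of a
  piecewise-constant construction; it does not model biological
  micro-heterogeneity.
* Exact numeric parity with any particular radiomics toolbox is not
  claimed: discretisation settings of the original software are not
  public. Parity is with the IBSI definitions under the documented
  configuration.
* Laterality/asymmetry indices and wavelet features are out of scope by
  design, as is everything upstream of the spatially normalised volume
  (reconstruction, attenuation correction, registration).
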