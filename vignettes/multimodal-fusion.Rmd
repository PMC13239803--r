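---
title: "Semi-supervised fusion of A-T-N brain maps: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised fusion of A-T-N brain maps: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atnfuse)
```

## The model

`atnfuse` addresses a recurring situation in multimodal neuroimaging of
aging and Alzheimer's disease: several feature matrices per subject —
gray matter density (GM), cortical thickness (CT), pial surface area
(PSA), amyloid PET Centiloid (AMY), tau PET SUVR (TAU) — that share
latent structure, plus a continuous clinical severity score (CDR Sum of
Boxes, 0–18 in half points) that the latent structure should predict.

With `X_m` the z-scored subjects-by-features matrix of modality `m` and
`y` the target, the package fits

$$X_m \approx Z\,\mathrm{diag}(W_m)\,S_m^\top, \qquad y \approx Z\beta + b_0$$

by minimizing

$$L = \sum_m \frac{a_m}{N P_m}\lVert X_m - Z\,\mathrm{diag}(W_m)\,S_m^\top\rVert_F^2
    + \frac{\gamma}{N}\lVert y - Z\beta - b_0\rVert^2
    + \lambda_1 \sum_m \lVert S_m\rVert_1 .$$

`Z` holds shared subject loadings (one row per training subject, columns
kept at mean 0 / variance 1), `S_m` the modality-specific spatial maps,
`W_m ≥ 0` scalar per-component modality weights that make uni- versus
multi-modality of a component a first-class, reportable quantity, and
`(β, b₀)` a linear prediction head. The supervised term makes the
decomposition *semi*-supervised: components are shaped both by what the
images share and by what predicts severity.

Assumptions worth stating plainly: the subject-level representation is
linear in the features and shared across modalities up to a per-component
scalar; the target is linear in the loadings; residuals are treated as
homoscedastic within modality (the `1/(N P_m)` normalization equalizes
modalities of different sizes, and `a_m = 1/M` weights them equally).

## Optimization and numerical choices

- **Initialization is deterministic**: loadings from a truncated SVD of the
  `\sqrt{a_m/P_m}`-weighted concatenated modalities, maps from least squares
  against those loadings (with the column RMS split off into `W_m`), and the
  head from OLS. This removes dependence on lucky random starts and makes
  small-instance oracles (the rank-K SVD optimum) meaningful: in the
  unsupervised single-modality limit the warm start *is* the Eckart–Young
  optimum.
- **Optimizer**: mini-batch Adam (batch `min(64, N_train)`, β₁ = 0.9,
  β₂ = 0.999), with a 5-epoch learning-rate warmup and a `1/(1 + 0.02·t)`
  decay schedule. The warmup matters: Adam's bias-corrected first step has
  magnitude `lr` in every coordinate regardless of gradient size, which
  would otherwise kick the parameters off an already-good warm start. `W`
  is projected onto the nonnegative orthant after every step.
- **Early stopping** monitors validation prediction loss (validation
  loadings come from the closed-form ridge projection below); patience is
  50 epochs within a 2,000-epoch budget. The initialization itself is a
  snapshot candidate, and the returned snapshot is constrained to have
  total training loss no worse than at initialization — so on data the warm
  start already explains, the fit degrades nothing.
- **Loading standardization** is maintained by re-standardizing `Z` each
  epoch and compensating the scale into `W_m` and `β` (the mean shift goes
  into `b₀`); with `γ = 0` the head is left bit-identical to its OLS
  initialization, since no gradient flows into it.
- **Projection of new subjects** solves
  `argmin_Z Σ_m (a_m/P_m)‖X_m − Z diag(W_m) S_mᵀ‖² + ρ‖Z‖²` in closed form
  with `ρ = 1e-6` — the mechanism for held-out loadings is a design choice
  of this package, made linear to match the linearity of the rest of the
  model.
- **Degenerate components** (zero map energy across all modalities) are
  flagged, never silently dropped; their modality-weight shares are NA.

A deliberate scope note: the published method this surrogate follows left
its exact objective, priors and dropout scheme to supplementary material
that is not reproduced here, so this loss is the package's own fully
testable formulation of the same inputs and outputs (loadings, maps,
modality weights, prediction weights) rather than a claimed re-derivation.

## What the synthetic generator emulates

`generate_dataset()` draws `Z ~ N(0,1)`, sparse maps (15% nonzero per
column by default, values two-sided Gamma(3, 1) to mimic the heavy-tailed
signal class the thresholding stage must detect), per-component modality
weights active in a random nonempty modality subset, additive +
multiplicative scanner effects, and Gaussian noise scaled so the
per-modality variance ratio matches the requested `snr`. Sites follow a
symmetric Dirichlet-multinomial; all subjects at a site share a scanner,
reproducing the confound structure that makes site-grouped splitting and
scanner harmonization necessary.

The target is linear in a 3-component support, noised to a known R²
ceiling (0.8 by default), affinely mapped to mean 3.5 / SD 3 on the
CDR-SOB scale, clipped to [0, 18] and rounded to half points; the mean/SD
were chosen once to give a realistic diagnostic mix (roughly 15% CN, 45%
MCI, 35% mild dementia) with enough mass in every pairwise classification
task. Diagnosis bands always come from `band_cdr_sob()` applied to the
stored target. The carrier label is Bernoulli with logit
`a₀ + 5·z_c` on the designated component's standardized loading, with
`a₀` solved for 35% prevalence — a deliberately strong genetic-risk
effect so that transfer-classification recovery is a sharp test. CSF
amyloid-β42 and p-tau181 are generated with correlations +0.3 / −0.4 to
that same loading, with draw dates scattered around the imaging visit so
the 1-year eligibility window actually filters.

What the generator does **not** emulate: spatial autocorrelation on a
voxel grid or surface, non-Gaussian residuals, site-by-disease
interactions, longitudinal drift, or missing modalities. Passing tests
therefore demonstrate correctness of the machinery under the stated
generative assumptions, not performance claims about any clinical
dataset.

One property of the generative setting deserves emphasis because it is
easy to mistake for an optimizer failure: additive scanner offsets are
low-rank structure (one direction per scanner, coherent across all
features), and when their between-scanner variance approaches that of the
weakest planted component, a rank-K unsupervised fit will prefer the
scanner direction and drop that component. Harmonization of *loadings*
cannot restore a component the decomposition never captured. The
factorization-recovery experiments therefore use batch-free generation,
and batch effects are exercised where they belong — in the harmonization
stage, with planted shifts and leakage AUROC as the criterion.

## Harmonization

`fit_combat()` implements the parametric empirical-Bayes location–scale
model: per-feature grand location/scale (and optional covariate effects)
by least squares, per-batch location `γ` and scale `δ²` estimates shrunk
toward method-of-moments normal and inverse-gamma hyperpriors by
iterative conditional updates to 1e-6. The batch variable is the scanner
manufacturer; sites only constrain the split. The fit/apply split exists
so the model can be estimated on training subjects and applied to
held-out subjects — the reason a widely used one-shot implementation
could not stand behind this interface. When a scanner level is entirely
absent from the training split (possible under site-grouped splitting),
the fit falls back to all subjects with a warning rather than leaving
held-out subjects unadjustable. Residual batch information is quantified
as cross-validated L1-logistic AUROC (`batch_leakage_auc()`); near-chance
leakage after harmonization is the operational success criterion.

## Mixture-model thresholding

Spatial maps are thresholded per component: values are median-centered
and SD-scaled, then fit with EM as a free Gaussian noise class plus a
positive Gamma class on values above zero and a mirrored negative class
below zero (signed maps need both sides). All M-steps are exact (the
weighted Gamma MLE uses Newton on the shape), so the log-likelihood trace
is monotone — a tested invariant. Class support boundaries stay fixed at
zero during EM; the retained class configuration (noise only, one-sided,
two-sided) is chosen by BIC across candidate fits, which is what lets a
pure-noise map collapse to a single Gaussian instead of shaving its tails
into spurious "signal". Features are retained when their posterior
probability of belonging to any signal class exceeds `mmthresh` (default
0.5); masks are monotone in the threshold and exactly invariant to
positive rescaling of the map.

## Transfer classification and comparators

Diagnosis is handled as three one-vs-one binary problems (CN vs MCI, CN
vs mild dementia, MCI vs mild dementia), macro-averaged; carrier status
is a fourth task. Classifiers are LASSO logistic fits (glmnet) with
lambda chosen by 5-fold stratified inner cross-validated deviance
(minimum rule), features z-scored on the fitting data; thresholded
metrics use the 0.5 probability operating point. Test-set AUROC/AUPRC
carry stratified bootstrap percentile intervals. Comparator feature sets
are built strictly from training-split statistics: demographics (age,
sex), per-modality PCs, per-modality ICs (whitened PCA plus a seeded
fixed-point tanh rotation, written in-package), concatenated-modality
PCs, and the 10 pooled per-modality PCs most correlated with the training
target. A leakage sentinel test corrupts test-split labels and asserts
that no training-side artifact changes.

## Validation statistics

`correlation_screen()` reports per-component Pearson r with
t-distribution p-values and Benjamini–Hochberg q-values; the significance
flag uses q < 0.05, the conventional level where none is stated. CSF
eligibility takes the draw nearest the imaging visit within 365 days
inclusive, breaking exact ties toward the earlier draw — deterministic
and auditable.

## Problem sizes and reproducibility

The test and acceptance experiments use deliberately scaled problem
sizes chosen as the package's own defaults for desk-scale verification:
the recovery study at N = 400 subjects, five modalities of 2,000 features,
K = 6, SNR = 5; the carrier transfer study at N = 250, three modalities of
150 features over 20 seeded replicates; the stability grid at nine
dimensionalities (10–50) by five seeds on a 160-subject, two-modality
dataset; mixture simulations at 5,000 features. Every stochastic stage
takes an explicit seed, identical seeds reproduce datasets and fits bit
for bit, and `run_pipeline()` writes a checksum manifest so reruns can be
compared mechanically.

## Known limitations

- The decomposition has no explicit batch term, so strong scanner effects
  compete with weak components at fixed K (see above).
- Modality-weight shares of a fitted model are diluted by dense noise in
  the estimated maps: a truly single-modality component shows a dominant
  but not unit share; the dominant-modality call is the reliable readout.
- The L1 penalty is handled by subgradient within Adam, which encourages
  small rather than exactly zero map entries; exact sparsity enters at the
  thresholding stage instead.
- The ICA comparator uses a tanh-contrast fixed-point rotation with
  symmetric decorrelation; it is seeded and reproducible but, like all
  ICA, only identified up to sign and order.
- With a near-optimal warm start and validation-based selection, the
  returned model can legitimately be the initialization itself; this is by
  design, not a failure to train.
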