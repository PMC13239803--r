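# atnfuse

Semi-supervised multimodal fusion of amyloid–tau–neurodegeneration (A–T–N)
brain maps, with the downstream analysis pipeline that turns the fused
representation into clinically interpretable results.

## The problem

Alzheimer's disease expresses itself across several imaging channels at
once: gray matter density (GM), cortical thickness (CT) and pial surface
area (PSA) capture neurodegeneration, amyloid PET Centiloid (AMY) captures
amyloid burden, and tau PET SUVR (TAU) captures tau pathology. Analyzing
each channel separately discards the shared structure that links them.
`atnfuse` jointly decomposes M such per-subject feature matrices into a
small set of latent components whose subject loadings are maximally
predictive of a continuous clinical severity score (CDR Sum of Boxes,
range 0–18), and then carries those loadings through harmonization,
thresholding, classification and biomarker validation.

For subjects-by-features matrices `X_m` (z-scored per feature on the
training split) and target `y`, the model

    X_m ≈ Z diag(W_m) S_mᵀ        y ≈ Z β + b₀

is fit by minimizing

    L = Σ_m a_m ‖X_m − Z diag(W_m) S_mᵀ‖²_F / (N·P_m)
        + γ ‖y − Z β − b₀‖² / N
        + λ₁ Σ_m ‖S_m‖₁

over shared subject loadings `Z`, nonnegative per-component modality
weights `W_m`, sparse modality-specific spatial maps `S_m` and a linear
prediction head — mini-batch Adam from a deterministic truncated-SVD warm
start, early stopping on validation prediction loss, all subjects from a
given imaging site confined to a single split.

Around this core the package provides:

- **Synthetic data with ground truth** (`simulation_config()`,
  `generate_dataset()`): low-rank multimodal structure, sparse maps,
  site/scanner batch effects, a CDR-SOB-like banded target, a
  genetic-risk carrier label driven by one designated component, CSF
  biomarkers — so every downstream stage is testable without restricted
  clinical data.
- **Site-grouped splitting** (`grouped_split()`), 70/15/15 by default.
- **Empirical-Bayes scanner harmonization** (`fit_combat()`,
  `apply_combat()`, `batch_leakage_auc()`) with a fit/apply split so the
  model is estimated on training subjects only.
- **Mixture-model map thresholding** (`fit_mixture()`,
  `threshold_map()`): Gaussian noise class plus signed Gamma signal
  classes fit by EM; features kept when their signal posterior exceeds
  `mmthresh` (0.5 by default).
- **Transfer classification** (`fit_lasso_logistic()`,
  `run_transfer_study()`, `build_comparators()`): L1-logistic models of
  diagnosis pairs (CN vs MCI, CN vs mild dementia, MCI vs mild dementia)
  and carrier status, compared against demographics, per-modality
  PCA/ICA, concatenated PCs and a top-10 pooled-PC combo, reported as a
  macro-averaged AUROC/AUPRC/accuracy battery with bootstrap CIs.
- **Validation statistics** (`correlation_screen()`,
  `select_csf_samples()`, `csf_association()`): per-component Pearson
  screens with Benjamini–Hochberg control, and CSF draw eligibility
  (within 365 days of the imaging visit, nearest draw, ties to the
  earlier one).
- **Pipeline & I/O** (`run_pipeline()`, `write_dataset()`,
  `write_fusion_model()`, `ingest_neuro_volumes()`): YAML-configured
  end-to-end runs with checksummed plain-text artifacts, and optional
  NIfTI ingestion. A thin CLI wrapper lives at `inst/cli/atnfuse.R`.

## Worked example

```r
library(atnfuse)

cfg <- simulation_config(N = 240, M = 3, features_m = rep(200L, 3),
                         K_true = 4, snr = 5, n_sites = 8, seed = 11)
ds <- generate_dataset(cfg)
ds
#> multimodal_dataset: 240 subjects, 3 modalities
#>    GM : 200 features
#>    CT : 200 features
#>    PSA : 200 features
#>   diagnosis: CN 30, MCI_SCD 122, mild 81, moderate 7
#>   ground truth stored (K_true = 4 )

sp <- grouped_split(ds$pheno$site, seed = 3)
sp
#> split_assignment: train=159, val=32, test=49 (fractions 0.662/0.133/0.204)

model <- fit_fusion(ds, sp, K = 4,
                    control = fusion_control(epochs = 300, patience = 30,
                                             seed = 1))

te <- which(sp$split == "test")
Zt <- project_subjects(model, lapply(ds$X, function(x) x[te, , drop = FALSE]))
cor(predict_target(model, Zt), ds$pheno$target[te])
#> [1] 0.931

match_components(model$Z, ds$truth$loadings_true[model$train_idx, ])$mean_abs_cor
#> [1] 0.933

## harmonize loadings across scanners, then screen against the target
Z_all <- project_subjects(model, ds$X)
tr <- which(sp$split == "train")
cm <- fit_combat(Z_all[tr, ], ds$pheno$scanner[tr])
Z_h <- apply_combat(cm, Z_all, ds$pheno$scanner)
correlation_screen(Z_h, ds$pheno$target)
#>   component   n       r        p        q significant
#> 1        C1 240 -0.1637 1.11e-02 1.48e-02        TRUE
#> 2        C2 240 -0.0454 4.84e-01 4.84e-01       FALSE
#> 3        C3 240 -0.7723 8.39e-49 3.36e-48        TRUE
#> 4        C4 240 -0.3950 2.18e-10 4.37e-10        TRUE
```

The held-out correlation (0.931) sits just under the generator's known
ceiling for this configuration; component C3 carries most of the severity
signal, and the screen's q-values flag the components whose loadings
survive false-discovery-rate control at 5%.

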