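test_that("the carrier task selects the planted component with high AUROC", {
  f <- small_fit()
  rep <- suppressWarnings(
    run_transfer_study(f$ds, f$model, f$sp, B = 150, seed = 5,
                       cv_metrics = FALSE))
  carrier <- rep$results$fused_loadings$tasks$carrier
  expect_false(carrier$skipped)
  mc <- match_components(f$model$Z,
                         f$ds$truth$loadings_true[f$model$train_idx, ])
  est_cc <- mc$perm[f$ds$truth$carrier_component_index]
  expect_true(est_cc %in% carrier$selected)
  expect_gte(unname(carrier$test_metrics["auroc"]), 0.9)
  ## confidence intervals bracket the point estimate
  expect_lte(carrier$test_ci$auroc[["lower"]],
             unname(carrier$test_metrics["auroc"]))
  expect_gte(carrier$test_ci$auroc[["upper"]],
             unname(carrier$test_metrics["auroc"]))
})

test_that("macro averages equal the mean over completed diagnosis tasks", {
  f <- small_fit()
  rep <- suppressWarnings(
    run_transfer_study(f$ds, f$model, f$sp, B = 150, seed = 5,
                       cv_metrics = FALSE))
  for (nm in rep$feature_sets) {
    r <- rep$results[[nm]]
    done <- Filter(function(t) !isTRUE(r$tasks[[t]]$skipped),
                   setdiff(names(rep$tasks), "carrier"))
    if (!length(done)) next
    recomputed <- colMeans(do.call(rbind,
      lapply(r$tasks[done], `[[`, "test_metrics")))
    expect_equal(r$macro_test, recomputed)
  }
})

test_that("label permutation drives held-out AUROC to chance", {
  f <- small_fit()
  ds2 <- f$ds
  set.seed(77)
  ds2$pheno$carrier <- sample(ds2$pheno$carrier)
  Z_all <- project_subjects(f$model, ds2$X)
  tr <- which(f$sp$split == "train"); te <- which(f$sp$split == "test")
  aucs <- vapply(1:5, function(s) {
    fit <- fit_lasso_logistic(Z_all[tr, ], ds2$pheno$carrier[tr], seed = s)
    unname(evaluate_binary(predict(fit, Z_all[te, ]),
                           ds2$pheno$carrier[te])["auroc"])
  }, numeric(1))
  expect_gte(mean(aucs), 0.35)
  expect_lte(mean(aucs), 0.65)
})

test_that("tasks with an empty class are reported as skipped, not dropped", {
  f <- small_fit()
  ds2 <- f$ds
  ## erase every CN subject outside the training split
  te_val <- which(f$sp$split != "train")
  ds2$pheno$diagnosis[intersect(which(ds2$pheno$diagnosis == "CN"), te_val)] <-
    "MCI_SCD"
  fsets <- list(fused = atnfuse:::new_feature_set(
    "fused", project_subjects(f$model, ds2$X), list()))
  rep <- suppressWarnings(
    run_transfer_study(ds2, NULL, f$sp, feature_sets = fsets,
                       B = 150, seed = 2, harmonize = FALSE,
                       cv_metrics = FALSE))
  expect_true(rep$results$fused$tasks$CN_vs_MCI$skipped)
  expect_false(rep$results$fused$tasks$MCI_vs_mild$skipped)
  expect_named(rep$results$fused$tasks, names(default_tasks()))
})

test_that("fused loadings beat the best single-modality comparator on average", {
  ## repeated small simulations with multimodal structure; compares the
  ## median macro AUROC of the fused loadings against the best
  ## per-modality PC comparator
  n_rep <- 7
  fused <- best_single <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    ## each latent component lives in a single distinct modality while the
    ## target mixes all three, so no single modality carries the whole signal
    cfg <- small_config(N = 200, M = 3, features_m = rep(120L, 3),
                        K_true = 3, beta_support = 3,
                        modality_weights = diag(3) * 1.2,
                        seed = 300 + r)
    ds <- generate_dataset(cfg)
    sp <- grouped_split(ds$pheno$site, seed = r)
    model <- suppressWarnings(
      fit_fusion(ds, sp, K = 3,
                 control = fusion_control(epochs = 120, patience = 20,
                                          seed = 1)))
    comp <- build_comparators(ds, sp, n_components = 3, seed = r)
    fsets <- c(list(fused_loadings = atnfuse:::new_feature_set(
      "fused_loadings", project_subjects(model, ds$X), list())),
      comp[paste0(names(ds$X), "_PCs")])
    tasks <- default_tasks()[c("CN_vs_MCI", "CN_vs_mild", "MCI_vs_mild")]
    rep_r <- suppressWarnings(
      run_transfer_study(ds, NULL, sp, feature_sets = fsets, tasks = tasks,
                         B = 100, seed = r, cv_metrics = FALSE))
    get_macro <- function(nm) {
      v <- rep_r$results[[nm]]$macro_test
      if (is.null(v)) NA_real_ else unname(v["auroc"])
    }
    fused[r] <- get_macro("fused_loadings")
    best_single[r] <- max(vapply(paste0(names(ds$X), "_PCs"), get_macro,
                                 numeric(1)), na.rm = TRUE)
  }
  ok <- is.finite(fused) & is.finite(best_single)
  expect_gte(sum(ok), 5)
  expect_gte(median(fused[ok]), median(best_single[ok]))
})
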