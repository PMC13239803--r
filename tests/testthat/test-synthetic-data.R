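test_that("noiseless batch-free generation reconstructs exactly", {
  cfg <- small_config(snr = Inf, batch_gamma_sd = 0, batch_delta_sd = 0,
                      N = 60, features_m = rep(80L, 3))
  ds <- generate_dataset(cfg)
  tr <- ds$truth
  for (m in seq_along(ds$X)) {
    recon <- tr$loadings_true %*%
      (t(tr$maps_true[[m]]) * tr$modality_weights_true[m, ])
    rel <- sqrt(sum((unname(ds$X[[m]]) - recon)^2)) /
      sqrt(sum(recon^2))
    expect_lt(rel, 1e-10)
  }
})

test_that("identical config and seed reproduce the dataset bit for bit", {
  cfg <- small_config(N = 80, features_m = rep(60L, 3))
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$X, d2$X)
  expect_identical(d1$pheno, d2$pheno)
  expect_identical(d1$truth$loadings_true, d2$truth$loadings_true)
})

test_that("empirical signal-to-noise matches the requested ratio", {
  cfg <- small_config(N = 300, snr = 2.0, features_m = rep(150L, 3))
  ds <- generate_dataset(cfg)
  tr <- ds$truth
  for (m in seq_along(ds$X)) {
    ## independent check: rebuild signal from the stored factors, undo the
    ## stored batch effects, and take the variance ratio directly
    signal <- tr$loadings_true %*%
      (t(tr$maps_true[[m]]) * tr$modality_weights_true[m, ])
    ridx <- match(ds$pheno$scanner, rownames(tr$batch_gamma[[m]]))
    nobatch <- unname(ds$X[[m]]) / tr$batch_delta[[m]][ridx, ] -
      tr$batch_gamma[[m]][ridx, ]
    noise <- nobatch - signal
    ratio <- var(as.vector(signal)) / var(as.vector(noise))
    expect_gte(ratio, 1.8)
    expect_lte(ratio, 2.2)
    expect_equal(ratio, tr$empirical_snr[m], tolerance = 1e-6)
  }
})

test_that("stored diagnosis always equals the banded target", {
  ds <- generate_dataset(small_config(N = 150, features_m = rep(60L, 3)))
  expect_identical(ds$pheno$diagnosis,
                   as.character(band_cdr_sob(ds$pheno$target)))
})

test_that("spatial maps honor the sparsity and weights the invariants", {
  cfg <- small_config(N = 100, features_m = rep(200L, 3), sparsity = 0.15)
  ds <- generate_dataset(cfg)
  tr <- ds$truth
  expect_true(all(tr$modality_weights_true >= 0))
  for (m in seq_along(tr$maps_true)) {
    nnz <- colSums(tr$maps_true[[m]] != 0)
    expect_true(all(abs(nnz - round(0.15 * 200)) <= 1))
  }
  expect_equal(sum(tr$beta_true != 0), cfg$beta_support)
})

test_that("carrier labels follow the designated component", {
  ds <- generate_dataset(small_config(N = 2000, features_m = rep(30L, 3),
                                      seed = 5))
  zc <- scale(ds$truth$loadings_true[, ds$truth$carrier_component_index])
  ## prevalence near the configured value and strong monotone association
  expect_equal(mean(ds$pheno$carrier), 0.35, tolerance = 0.05)
  expect_gt(
    mean(zc[ds$pheno$carrier == 1]) - mean(zc[ds$pheno$carrier == 0]), 1)
})

test_that("batch injection is an exact location-scale action", {
  X <- matrix(rnorm(50 * 20), 50, 20)
  scanner <- rep(c("A", "B"), each = 25)
  lv <- c("A", "B")
  g0 <- matrix(0, 2, 20, dimnames = list(lv, NULL))
  d1 <- matrix(1, 2, 20, dimnames = list(lv, NULL))
  expect_equal(inject_batch_effects(X, scanner, g0, d1), X)

  ## uniform shift on a single scanner
  gc <- matrix(3.5, 1, 20, dimnames = list("A", NULL))
  dc <- matrix(1, 1, 20, dimnames = list("A", NULL))
  expect_equal(inject_batch_effects(X[1:25, ], scanner[1:25], gc, dc),
               X[1:25, ] + 3.5)

  ## +/-2 shift: per-feature scanner mean difference is 4 up to noise
  g2 <- matrix(rep(c(2, -2), 20), 2, 20, dimnames = list(lv, NULL))
  Xb <- inject_batch_effects(X, scanner, g2, d1)
  diffs <- colMeans(Xb[scanner == "A", ]) - colMeans(Xb[scanner == "B", ])
  expect_equal(mean(diffs), 4, tolerance = 0.5)

  expect_error(inject_batch_effects(X, rep("C", 50), g0, d1), "unknown")
  expect_error(inject_batch_effects(X, scanner, g0, -d1), "positive")
})

test_that("generator rejects inconsistent configurations", {
  expect_error(simulation_config(N = 10, K_true = 6), "2 \\* K_true")
  expect_error(simulation_config(snr = 0), "positive")
  expect_error(simulation_config(n_sites = 2), "3 sites")
  expect_error(small_config(N = 600, K_true = 250,
                            features_m = rep(200L, 3)), "feature count")
  expect_error(simulation_config(M = 3, features_m = c(10, 10)),
               "per modality")
})
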