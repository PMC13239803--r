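# A tiny hand-built fusion model for closed-form checks.
toy_model <- function(S, W, beta, b0 = 0, P = nrow(S)) {
  structure(list(
    Z = NULL, S = list(S), W = list(W), beta = beta, b0 = b0,
    K = length(W), std = list(list(center = rep(0, P), scale = rep(1, P))),
    a_m = 1, modalities = "GM", P = P,
    control = fusion_control()), class = "fusion_model")
}

test_that("noiseless rank-K data is reconstructed almost perfectly", {
  cfg <- small_config(snr = Inf, batch_gamma_sd = 0, batch_delta_sd = 0,
                      N = 120, features_m = rep(100L, 3))
  ds <- generate_dataset(cfg)
  sp <- grouped_split(ds$pheno$site, seed = 2)
  m <- fit_fusion(ds, sp, K = 4,
                  control = fusion_control(lambda1 = 0, epochs = 100,
                                           patience = 100, seed = 1))
  tr <- m$train_idx
  for (mod in seq_along(ds$X)) {
    Xs <- atnfuse:::std_apply(ds$X[[mod]][tr, ], m$std[[mod]])
    R <- Xs - m$Z %*% t(sweep(m$S[[mod]], 2, m$W[[mod]], "*"))
    expect_lt(sqrt(sum(R^2)) / sqrt(sum(Xs^2)), 0.05)
  }
})

test_that("the unsupervised limit leaves the prediction head untouched", {
  ds <- generate_dataset(small_config(N = 90, features_m = rep(60L, 3)))
  sp <- grouped_split(ds$pheno$site, seed = 2)
  m <- fit_fusion(ds, sp, K = 3,
                  control = fusion_control(gamma = 0, epochs = 30,
                                           patience = 10, seed = 1))
  ## recompute the OLS initialization of the head on the initial loadings
  tr <- m$train_idx
  Xs <- lapply(seq_along(ds$X), function(i)
    atnfuse:::std_apply(ds$X[[i]][tr, ], m$std[[i]]))
  P <- vapply(Xs, ncol, integer(1))
  Xcat <- do.call(cbind, lapply(seq_along(Xs), function(i)
    Xs[[i]] * sqrt(m$a_m[i] / P[i])))
  Z0 <- scale(atnfuse:::.truncated_svd(Xcat, 3)$u)
  cf <- lm.fit(cbind(1, Z0), ds$pheno$target[tr])$coefficients
  expect_equal(m$beta, unname(cf[-1]), tolerance = 1e-12)
  expect_equal(m$b0, unname(cf[1]), tolerance = 1e-12)
})

test_that("training loadings stay standardized and loss never exceeds init", {
  f <- small_fit()
  m <- f$model
  expect_true(all(abs(colMeans(m$Z)) < 1e-6))
  expect_true(all(abs(apply(m$Z, 2, sd) - 1) < 1e-6))
  expect_true(all(m$W[[1]] >= 0))
  expect_lte(m$final_loss, m$init_loss)
})

test_that("component sign flips leave every loss term and prediction unchanged", {
  f <- small_fit()
  m <- f$model
  tr <- m$train_idx
  Xs <- lapply(seq_along(f$ds$X), function(i)
    atnfuse:::std_apply(f$ds$X[[i]][tr, ], m$std[[i]]))
  y <- f$ds$pheno$target[tr]
  base <- fusion_loss_terms(m$Z, m$S, m$W, m$beta, m$b0, Xs, y,
                            m$a_m, m$control$gamma, m$control$lambda1)
  for (k in seq_len(m$K)) {
    Z2 <- m$Z; Z2[, k] <- -Z2[, k]
    S2 <- lapply(m$S, function(s) { s[, k] <- -s[, k]; s })
    beta2 <- m$beta; beta2[k] <- -beta2[k]
    flip <- fusion_loss_terms(Z2, S2, m$W, beta2, m$b0, Xs, y,
                              m$a_m, m$control$gamma, m$control$lambda1)
    expect_equal(flip$total, base$total, tolerance = 1e-9)
    expect_equal(flip$recon, base$recon, tolerance = 1e-9)
    expect_equal(flip$pred, base$pred, tolerance = 1e-9)
  }
})

test_that("projection solves consistent linear systems exactly", {
  set.seed(7)
  S <- qr.Q(qr(matrix(rnorm(50 * 4), 50, 4)))  # orthonormal maps
  W <- rep(1, 4)
  m <- toy_model(S, W, beta = rep(0, 4))
  X_new <- matrix(rnorm(12 * 50), 12, 50)
  ## orthonormal S, W = 1, rho = 0: projection is X S
  expect_equal(project_subjects(m, list(X_new), rho = 0), X_new %*% S,
               ignore_attr = TRUE)
  ## consistent system: exact recovery of the generating loadings
  Z0 <- matrix(rnorm(12 * 4), 12, 4)
  X_exact <- Z0 %*% t(sweep(S, 2, c(1.5, 2, 0.5, 1), "*"))
  m2 <- toy_model(S, c(1.5, 2, 0.5, 1), beta = rep(0, 4))
  Z_rec <- project_subjects(m2, list(X_exact), rho = 1e-12)
  expect_lt(max(abs(Z_rec - Z0)) / max(abs(Z0)), 1e-6)
})

test_that("refitting the training matrices reproduces the fitted loadings", {
  f <- small_fit()
  m <- f$model
  Z_proj <- project_subjects(m, lapply(f$ds$X, function(x)
    x[m$train_idx, , drop = FALSE]))
  cors <- diag(cor(Z_proj, m$Z))
  expect_true(all(cors >= 0.99))
})

test_that("predict_target is the stated affine map", {
  m <- toy_model(matrix(rnorm(40), 10, 4), rep(1, 4),
                 beta = c(1.5, -2, 0.25, 3), b0 = 0)
  expect_equal(predict_target(m, diag(4)), m$beta)
  m$beta <- rep(0, 4); m$b0 <- 2.5
  expect_equal(predict_target(m, matrix(rnorm(20), 5, 4)), rep(2.5, 5))
  expect_error(predict_target(m, matrix(0, 2, 3)), "columns")
})

test_that("modality weight shares are a simplex and spot single-modality components", {
  f <- small_fit()
  sh <- modality_weight_distribution(f$model)
  expect_true(all(abs(rowSums(sh) - 1) < 1e-9))
  expect_true(all(sh >= 0 & sh <= 1))

  ## a component present in exactly one modality has share exactly 1
  toy <- structure(list(
    Z = NULL,
    S = list(matrix(rnorm(20), 10, 2), matrix(rnorm(20), 10, 2)),
    W = list(c(1.5, 0), c(0, 2)), beta = c(0, 0), b0 = 0, K = 2L,
    std = NULL, a_m = c(0.5, 0.5), modalities = c("GM", "CT"),
    P = c(10L, 10L), control = fusion_control()), class = "fusion_model")
  sh_toy <- modality_weight_distribution(toy)
  expect_equal(unname(sh_toy["C1", ]), c(1, 0))
  expect_equal(unname(sh_toy["C2", ]), c(0, 1))

  ## planted single-modality vs spread components: the dominant modality of
  ## the fitted shares matches the generating weights
  Wt <- matrix(0, 3, 3); Wt[1, 1] <- 1.2; Wt[, 2] <- 1; Wt[2, 3] <- 0.8
  cfg <- small_config(N = 150, K_true = 3, features_m = rep(150L, 3),
                      modality_weights = Wt, batch_gamma_sd = 0,
                      batch_delta_sd = 0, seed = 4)
  ds <- generate_dataset(cfg)
  sp <- grouped_split(ds$pheno$site, seed = 2)
  mod <- fit_fusion(ds, sp, K = 3,
                    control = fusion_control(epochs = 120, patience = 120,
                                             seed = 1))
  mc <- match_components(mod$Z, ds$truth$loadings_true[mod$train_idx, ])
  sh <- modality_weight_distribution(mod)
  uni_est <- mc$perm[1]  # estimated index of the GM-only component
  expect_equal(unname(which.max(sh[uni_est, ])), 1)
  expect_gt(sh[uni_est, "GM"], max(sh[uni_est, -1]) + 0.15)
  tri_est <- mc$perm[2]  # the evenly spread component stays spread
  expect_lt(max(sh[tri_est, ]), 0.45)
})

test_that("OLS on loadings matches a normal-equations oracle", {
  set.seed(3)
  Z <- matrix(rnorm(60 * 5), 60, 5)
  y <- rnorm(60)
  fit <- regress_target_on_loadings(Z, y)
  D <- cbind(1, Z)
  oracle <- solve(crossprod(D), crossprod(D, y))
  expect_equal(c(fit$intercept, fit$coefficients), as.vector(oracle),
               tolerance = 1e-10)
  expect_false(fit$rank_deficient)

  ## exact interpolation
  y_lin <- as.vector(Z %*% c(1, -1, 2, 0, 0.5)) + 3
  fit2 <- regress_target_on_loadings(Z, y_lin)
  expect_lt(sum(fit2$residuals^2), 1e-10)

  ## centered orthonormal columns: coefficients are the inner products
  Q <- qr.Q(qr(scale(matrix(rnorm(60 * 4), 60, 4), scale = FALSE)))
  yq <- rnorm(60)
  fit3 <- regress_target_on_loadings(Q, yq)
  expect_equal(fit3$coefficients, as.vector(crossprod(Q, yq)),
               tolerance = 1e-10)

  ## rank deficiency is flagged, minimum-norm solution returned
  Zr <- cbind(Z, Z[, 1])
  expect_warning(fitr <- regress_target_on_loadings(Zr, y), "rank-deficient")
  expect_true(fitr$rank_deficient)
  expect_equal(fitr$fitted, fit$fitted, tolerance = 1e-8)
})

test_that("K beyond the rank bound and empty splits are rejected", {
  ds <- generate_dataset(small_config(N = 60, features_m = rep(40L, 3)))
  sp <- grouped_split(ds$pheno$site, seed = 1)
  expect_error(fit_fusion(ds, sp, K = 50), "rank bound")
  expect_error(fit_fusion(ds, sp, K = 0), "K must be")
})
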