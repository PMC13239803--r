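test_that("full shrinkage gives the base-rate intercept and no features", {
  set.seed(2)
  X <- matrix(rnorm(200 * 8), 200, 8)
  y <- rbinom(200, 1, 0.3)
  fit <- fit_lasso_logistic(X, y, lambda_grid = c(100, 50), seed = 1)
  expect_equal(fit$coefficients, rep(0, 8))
  expect_length(fit$selected, 0)
  expect_equal(fit$intercept, qlogis(mean(y)), tolerance = 1e-6)
})

test_that("a single separating feature is found among noise", {
  set.seed(4)
  n <- 300
  y <- rbinom(n, 1, 0.5)
  X <- cbind(sep = y * 2 - 1 + rnorm(n, sd = 0.1),
             matrix(rnorm(n * 20), n, 20))
  tr <- seq_len(200); te <- 201:300
  fit <- suppressWarnings(fit_lasso_logistic(X[tr, ], y[tr], seed = 1))
  expect_true(1 %in% fit$selected)
  auc <- unname(evaluate_binary(predict(fit, X[te, ]), y[te])["auroc"])
  expect_gte(auc, 0.95)
  ## unpenalized refit on the selected feature agrees on direction
  refit <- suppressWarnings(glm(y[tr] ~ X[tr, 1], family = binomial))
  expect_gt(fit$coefficients[1] * coef(refit)[2], 0)
})

test_that("the informative support is recovered in most replicates", {
  hits <- 0
  n_rep <- 50
  for (r in seq_len(n_rep)) {
    set.seed(100 + r)
    n <- 400; p <- 50
    X <- matrix(rnorm(n * p), n, p)
    eta <- X[, 1] * 1.2 - X[, 2] * 1.0 + X[, 3] * 0.8
    y <- rbinom(n, 1, plogis(eta))
    fit <- fit_lasso_logistic(X, y, seed = r)
    hits <- hits + all(c(1, 2, 3) %in% fit$selected)
  }
  expect_gte(hits / n_rep, 0.8)
})

test_that("single-class labels and empty grids are rejected", {
  X <- matrix(rnorm(50 * 3), 50, 3)
  expect_error(fit_lasso_logistic(X, rep(1, 50)), "single class")
  expect_error(fit_lasso_logistic(X, rbinom(50, 1, 0.5),
                                  lambda_grid = numeric(0)), "empty")
})

test_that("comparator PCs match an eigendecomposition oracle", {
  f <- small_fit()
  comp <- build_comparators(f$ds, f$sp, n_components = 5, seed = 2)
  tr <- which(f$sp$split == "train")
  for (m in names(f$ds$X)[1]) {
    sc <- comp[[paste0(m, "_PCs")]]$matrix
    std <- atnfuse:::std_fit(f$ds$X[[m]][tr, ])
    Xs <- atnfuse:::std_apply(f$ds$X[[m]][tr, ], std)
    ei <- eigen(cov(Xs), symmetric = TRUE)
    oracle <- Xs %*% ei$vectors[, 1:5]
    for (k in 1:5) {
      expect_gt(abs(cor(sc[tr, k], oracle[, k])), 0.999)
    }
  }
})

test_that("rank-limited modalities give zero-variance trailing components", {
  set.seed(5)
  base <- generate_dataset(small_config(N = 80, features_m = rep(40L, 3)))
  ## make modality 1 exactly rank 2
  u <- matrix(rnorm(80 * 2), 80, 2)
  v <- matrix(rnorm(2 * 40), 2, 40)
  base$X[[1]] <- u %*% v
  rownames(base$X[[1]]) <- base$pheno$subject_id
  sp <- grouped_split(base$pheno$site, seed = 1)
  comp <- build_comparators(base, sp, n_components = 5, seed = 1)
  vars <- apply(comp$GM_PCs$matrix, 2, var)
  expect_true(all(vars[3:5] < 1e-10 * vars[1]))
})

test_that("the top-10 combo picks the most target-correlated pooled PCs", {
  f <- small_fit()
  comp <- build_comparators(f$ds, f$sp, n_components = 5, seed = 2)
  tr <- which(f$sp$split == "train")
  y_tr <- f$ds$pheno$target[tr]
  pooled <- do.call(cbind, lapply(names(f$ds$X), function(m)
    comp[[paste0(m, "_PCs")]]$matrix))
  cors <- abs(apply(pooled[tr, ], 2, cor, y = y_tr))
  picked <- colnames(comp$top10_PCs_combo$matrix)
  expect_setequal(picked, names(sort(cors, decreasing = TRUE))[1:10])
  ## and those include genuinely informative directions
  expect_gt(max(abs(apply(comp$top10_PCs_combo$matrix[tr, ], 2, cor,
                          y = y_tr))), 0.5)
})

test_that("independent components are seeded and decorrelated", {
  f <- small_fit()
  c1 <- build_comparators(f$ds, f$sp, n_components = 4, seed = 7)
  c2 <- build_comparators(f$ds, f$sp, n_components = 4, seed = 7)
  expect_equal(c1$GM_ICs$matrix, c2$GM_ICs$matrix)
  tr <- which(f$sp$split == "train")
  cc <- cor(c1$GM_ICs$matrix[tr, ])
  expect_true(all(abs(cc[upper.tri(cc)]) < 0.05))
})

test_that("corrupting test-split labels never changes training-side artifacts", {
  f <- small_fit()
  ds2 <- f$ds
  te <- which(f$sp$split == "test")
  set.seed(1)
  ds2$pheno$target[te] <- sample(ds2$pheno$target[te])
  ds2$pheno$carrier[te] <- sample(ds2$pheno$carrier[te])
  ds2$pheno$diagnosis[te] <- sample(ds2$pheno$diagnosis[te])
  c1 <- build_comparators(f$ds, f$sp, n_components = 4, seed = 3)
  c2 <- build_comparators(ds2, f$sp, n_components = 4, seed = 3)
  expect_identical(c1$top10_PCs_combo$provenance$selected,
                   c2$top10_PCs_combo$provenance$selected)
  expect_identical(c1$GM_PCs$matrix, c2$GM_PCs$matrix)
  tr <- which(f$sp$split == "train")
  y <- as.integer(f$ds$pheno$carrier)
  f1 <- fit_lasso_logistic(c1$concat_PCs$matrix[tr, ], y[tr], seed = 1)
  f2 <- fit_lasso_logistic(c2$concat_PCs$matrix[tr, ], y[tr], seed = 1)
  expect_identical(f1$coefficients, f2$coefficients)
  m2 <- suppressWarnings(
    fit_fusion(ds2, f$sp, K = 4,
               control = fusion_control(epochs = 300, patience = 30,
                                        seed = 1)))
  expect_identical(m2$Z, f$model$Z)
  expect_identical(m2$beta, f$model$beta)
})
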