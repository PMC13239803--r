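## Parametric empirical-Bayes location-scale harmonization of component
## loadings across scanner manufacturers, with a fit/apply split so the
## model can be estimated on the training split and reused on held-out
## subjects.

#' Fit a location-scale empirical-Bayes batch-harmonization model
#'
#' Estimates, per feature, a grand intercept (and optional covariate
#' effects), pooled variance, and per-batch additive/multiplicative batch
#' parameters shrunk by parametric empirical Bayes: batch locations toward
#' a normal prior, batch scales toward an inverse-gamma prior, with
#' method-of-moments hyperpriors and iterative conditional updates of the
#' shrunken estimates to convergence.
#'
#' @param features subjects-by-features numeric matrix (typically component
#'   loadings).
#' @param batch per-subject batch labels (at least 2 levels, each with at
#'   least 2 subjects).
#' @param covariates optional numeric design matrix (no intercept) of
#'   biological covariates whose effects are preserved.
#' @param tol convergence tolerance of the EB conditional updates.
#' @return object of class `combat_model`: batch levels, `alpha` (grand
#'   intercept per feature), `beta_cov`, `sigma2` (pooled variance),
#'   `gamma_star` and `delta2_star` (shrunken per-batch location and
#'   squared scale), and the EB hyperparameter estimates.
#' @export
fit_combat <- function(features, batch, covariates = NULL, tol = 1e-6) {
  X <- as.matrix(features)
  batch <- factor(batch)
  levels_ <- levels(batch)
  if (length(levels_) < 2) stop("harmonization needs at least 2 batch levels")
  n_i <- table(batch)
  if (any(n_i < 2)) {
    stop("singleton batch(es): ", paste(levels_[n_i < 2], collapse = ", "))
  }
  n <- nrow(X); G <- ncol(X)
  B <- stats::model.matrix(~ batch - 1)
  D <- if (is.null(covariates)) B else {
    covariates <- as.matrix(covariates)
    cbind(B, covariates)
  }
  if (qr(D)$rank < ncol(D)) stop("rank-deficient batch/covariate design")
  Bhat <- solve(crossprod(D), crossprod(D, X))       # (levels + q) x G
  nb <- length(levels_)
  batch_coef <- Bhat[seq_len(nb), , drop = FALSE]
  beta_cov <- if (is.null(covariates)) NULL else
    Bhat[-seq_len(nb), , drop = FALSE]
  alpha <- as.vector(crossprod(as.numeric(n_i) / n, batch_coef))
  fitted <- D %*% Bhat
  sigma2 <- colSums((X - fitted)^2) / n
  sigma2[sigma2 < 1e-12] <- 1e-12

  cov_part <- if (is.null(covariates)) 0 else covariates %*% beta_cov
  Zs <- sweep(X - cov_part, 2L, alpha, "-")
  Zs <- sweep(Zs, 2L, sqrt(sigma2), "/")

  gamma_hat <- rowsum(Zs, batch)[levels_, , drop = FALSE] / as.numeric(n_i)
  delta2_hat <- matrix(NA_real_, nb, G, dimnames = list(levels_, NULL))
  for (i in seq_len(nb)) {
    zi <- Zs[batch == levels_[i], , drop = FALSE]
    delta2_hat[i, ] <- apply(zi, 2L, stats::var)
  }
  delta2_hat[delta2_hat < 1e-12] <- 1e-12

  ## method-of-moments hyperpriors
  gamma_bar <- rowMeans(gamma_hat)
  tau2 <- apply(gamma_hat, 1L, stats::var)
  tau2[tau2 < 1e-12] <- 1e-12
  aprior <- function(d) { m <- mean(d); s2 <- stats::var(d); (2 * s2 + m^2) / s2 }
  bprior <- function(d) { m <- mean(d); s2 <- stats::var(d); (m * s2 + m^3) / s2 }
  lambda_p <- apply(delta2_hat, 1L, aprior)
  theta_p <- apply(delta2_hat, 1L, bprior)

  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  for (i in seq_len(nb)) {
    zi <- Zs[batch == levels_[i], , drop = FALSE]
    ni <- nrow(zi)
    g_new <- gamma_hat[i, ]; d_new <- delta2_hat[i, ]
    change <- Inf
    while (change > tol) {
      g_old <- g_new; d_old <- d_new
      g_new <- (ni * tau2[i] * gamma_hat[i, ] + d_new * gamma_bar[i]) /
        (ni * tau2[i] + d_new)
      sse <- colSums((zi - matrix(g_new, ni, ncol(zi), byrow = TRUE))^2)
      d_new <- (theta_p[i] + 0.5 * sse) / (ni / 2 + lambda_p[i] - 1)
      change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                    abs(d_new - d_old) / pmax(abs(d_old), 1e-12))
    }
    gamma_star[i, ] <- g_new
    delta2_star[i, ] <- d_new
  }

  structure(list(levels = levels_, n_per_batch = as.numeric(n_i),
                 alpha = alpha, beta_cov = beta_cov, sigma2 = sigma2,
                 gamma_star = gamma_star, delta2_star = delta2_star,
                 gamma_hat = gamma_hat, delta2_hat = delta2_hat,
                 hyper = list(gamma_bar = gamma_bar, tau2 = tau2,
                              lambda = lambda_p, theta = theta_p)),
            class = "combat_model")
}

#' Apply a fitted harmonization model
#'
#' Standardizes each feature with the stored grand location/scale (and
#' covariate effects), removes the shrunken batch location, divides by the
#' shrunken batch scale, then restores the grand structure. Batches must
#' have been seen at fit time.
#'
#' @param model a `combat_model`.
#' @param features subjects-by-features matrix (same features as at fit).
#' @param batch per-subject batch labels.
#' @param covariates covariate matrix matching the fit (if any was used).
#' @return harmonized matrix of the same shape.
#' @export
apply_combat <- function(model, features, batch, covariates = NULL) {
  stopifnot(inherits(model, "combat_model"))
  X <- as.matrix(features)
  batch <- as.character(batch)
  unseen <- setdiff(unique(batch), model$levels)
  if (length(unseen)) {
    stop("unseen batch level(s): ", paste(unseen, collapse = ", "))
  }
  if (is.null(model$beta_cov) != is.null(covariates)) {
    stop("covariates must match the fit (supplied at fit xor apply)")
  }
  cov_part <- if (is.null(covariates)) 0 else
    as.matrix(covariates) %*% model$beta_cov
  Zs <- sweep(X - cov_part, 2L, model$alpha, "-")
  Zs <- sweep(Zs, 2L, sqrt(model$sigma2), "/")
  ridx <- match(batch, model$levels)
  Zadj <- (Zs - model$gamma_star[ridx, , drop = FALSE]) /
    sqrt(model$delta2_star[ridx, , drop = FALSE])
  out <- sweep(Zadj, 2L, sqrt(model$sigma2), "*")
  out <- sweep(out, 2L, model$alpha, "+") + cov_part
  dimnames(out) <- dimnames(X)
  out
}

#' Cross-validated batch-leakage AUROC
#'
#' How well can an L1-regularized logistic classifier recover the batch
#' label from the features? Near-chance AUROC after harmonization is the
#' operational definition of successful batch-effect removal.
#'
#' @param features subjects-by-features matrix.
#' @param batch binary batch labels (exactly 2 levels).
#' @param folds number of stratified cross-validation folds.
#' @param seed integer seed for fold assignment and the classifier.
#' @return the pooled out-of-fold AUROC (scalar).
#' @export
batch_leakage_auc <- function(features, batch, folds = 5, seed = 1) {
  X <- as.matrix(features)
  batch <- factor(batch)
  if (nlevels(batch) != 2) stop("batch must be binary for leakage AUROC")
  y <- as.integer(batch) - 1L
  fold <- stratified_folds(y, folds, seed)
  scores <- numeric(length(y))
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) {
      stop("single-class fold; reduce `folds` or rebalance")
    }
    fit <- fit_lasso_logistic(X[tr, , drop = FALSE], y[tr],
                              inner_folds = min(5, sum(tr) %/% 2),
                              seed = seed + f)
    scores[!tr] <- predict(fit, X[!tr, , drop = FALSE])
  }
  unname(evaluate_binary(scores, y)["auroc"])
}
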