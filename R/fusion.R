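## Semi-supervised multimodal fusion.
##
## Model: for modality m with feature matrix X_m (subjects x P_m,
## z-scored on the training split),
##
##   X_m ~ Z diag(W_m) S_m^T,     y ~ Z beta + b0
##
## with shared subject loadings Z, nonnegative per-component modality
## weights W_m, sparse spatial maps S_m and a linear prediction head.
## The training objective is
##
##   L = sum_m a_m ||X_m - Z diag(W_m) S_m^T||_F^2 / (N P_m)
##       + gamma ||y - Z beta - b0||^2 / N
##       + lambda1 sum_m ||S_m||_1
##
## minimized by mini-batch Adam from a truncated-SVD warm start, with
## early stopping on validation prediction loss.

#' Optimization settings for [fit_fusion()]
#'
#' @param gamma reconstruction/prediction trade-off; `gamma = 0` is the
#'   purely unsupervised limit (the prediction head receives no gradient).
#' @param lambda1 L1 penalty weight on the spatial maps.
#' @param lr Adam base learning rate.
#' @param lr_decay learning-rate schedule: the step size at epoch t is
#'   `lr / (1 + lr_decay * (t - 1))`, damping late-stage stochastic jitter
#'   around the optimum.
#' @param batch_size mini-batch size (capped at the training-set size).
#' @param epochs maximum number of epochs.
#' @param patience early-stopping patience, in epochs, on validation
#'   prediction loss; ignored when `gamma = 0` or no validation split is
#'   supplied (model selection then falls back to total training loss).
#' @param rho ridge regularizer of the closed-form loading projection.
#' @param a_m optional per-modality reconstruction weights; default `1/M`.
#' @param seed seed for mini-batch shuffling.
#' @return list of class `fusion_control`.
#' @export
fusion_control <- function(gamma = 0.5, lambda1 = 1e-3, lr = 0.02,
                           lr_decay = 0.02, batch_size = 64, epochs = 2000,
                           patience = 50, rho = 1e-6, a_m = NULL, seed = 1) {
  stopifnot(gamma >= 0, lambda1 >= 0, lr > 0, lr_decay >= 0, epochs >= 1)
  structure(list(gamma = gamma, lambda1 = lambda1, lr = lr,
                 lr_decay = lr_decay, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 rho = rho, a_m = a_m, seed = as.integer(seed)),
            class = "fusion_control")
}

## Truncated SVD of a (possibly wide) matrix via the thin Gram matrix.
#' @keywords internal
.truncated_svd <- function(X, K) {
  n <- nrow(X); p <- ncol(X)
  if (n <= p) {
    ei <- eigen(tcrossprod(X), symmetric = TRUE)
    d <- sqrt(pmax(ei$values[seq_len(K)], 0))
    list(u = ei$vectors[, seq_len(K), drop = FALSE], d = d)
  } else {
    ei <- eigen(crossprod(X), symmetric = TRUE)
    d <- sqrt(pmax(ei$values[seq_len(K)], 0))
    v <- ei$vectors[, seq_len(K), drop = FALSE]
    u <- X %*% v
    u <- sweep(u, 2L, pmax(d, 1e-12), "/")
    list(u = u, d = d)
  }
}

#' Loss terms of the fusion objective
#'
#' Evaluates the per-modality reconstruction terms, the prediction term and
#' the L1 map penalty for given parameters on given (already standardized)
#' data. Exposed so invariances of the objective (e.g. component sign
#' flips) can be checked directly.
#'
#' @param Z loadings (subjects x K).
#' @param S list of spatial maps (features_m x K).
#' @param W list of nonnegative modality-weight vectors (length K).
#' @param beta,b0 prediction coefficients and intercept.
#' @param X list of standardized modality matrices aligned with `Z`.
#' @param y continuous target aligned with `Z`.
#' @param a_m per-modality reconstruction weights.
#' @param gamma,lambda1 objective hyperparameters.
#' @return list with `recon` (per modality), `pred`, `l1`, `total`.
#' @export
fusion_loss_terms <- function(Z, S, W, beta, b0, X, y, a_m, gamma, lambda1) {
  N <- nrow(Z)
  recon <- vapply(seq_along(X), function(m) {
    R <- X[[m]] - Z %*% t(sweep(S[[m]], 2L, W[[m]], "*"))
    a_m[m] * sum(R * R) / (N * ncol(X[[m]]))
  }, numeric(1))
  pred <- if (gamma > 0) {
    r <- y - as.vector(Z %*% beta) - b0
    gamma * sum(r * r) / N
  } else 0
  l1 <- lambda1 * sum(vapply(S, function(s) sum(abs(s)), numeric(1)))
  list(recon = recon, pred = pred, l1 = l1,
       total = sum(recon) + pred + l1)
}

#' Fit the semi-supervised multimodal fusion model
#'
#' Jointly learns shared subject loadings, per-modality sparse spatial
#' maps, nonnegative per-component modality weights and a linear prediction
#' head for the continuous target, by mini-batch Adam on the composite
#' reconstruction + prediction + L1 objective. Each modality is z-scored
#' per feature on the training split (the scalers are stored and reused for
#' projection of new subjects). Initialization is deterministic: loadings
#' from a truncated SVD of the weighted concatenated modalities, maps from
#' least squares against those loadings, the head from OLS. Training-set
#' loading columns are kept standardized (mean 0, variance 1), with scale
#' compensated into the modality weights and prediction head.
#'
#' Early stopping monitors validation prediction loss (validation loadings
#' come from the closed-form ridge projection); the returned snapshot is
#' the best validation epoch among those whose total training loss does not
#' exceed the loss at initialization.
#'
#' @param dataset a `multimodal_dataset` (or any list with `X` and `pheno`
#'   containing a `target` column).
#' @param split a [grouped_split()] assignment; `NULL` trains on all
#'   subjects without early stopping.
#' @param K number of latent components.
#' @param control a [fusion_control()].
#' @return object of class `fusion_model` with elements `Z` (training
#'   loadings), `S`, `W`, `beta`, `b0`, `K`, `std` (per-modality scalers),
#'   `a_m`, `train_idx`, `history`, `degenerate` (per-component flag),
#'   `control`.
#' @export
fit_fusion <- function(dataset, split = NULL, K, control = fusion_control()) {
  X_raw <- dataset$X
  y_all <- dataset$pheno$target
  M <- length(X_raw)
  N_all <- nrow(X_raw[[1]])
  if (K < 1) stop("K must be >= 1")
  if (K > min(vapply(X_raw, ncol, integer(1))) || K > N_all) {
    stop("K exceeds the rank bound min(features_m, subjects)")
  }
  if (is.null(split)) {
    train_idx <- seq_len(N_all); val_idx <- integer(0)
  } else {
    train_idx <- which(split$split == "train")
    val_idx <- which(split$split == "val")
  }
  if (!length(train_idx)) stop("training split is empty")
  a_m <- control$a_m %||% rep(1 / M, M)
  P <- vapply(X_raw, ncol, integer(1))

  ## per-feature z-scoring on the training split only
  std <- lapply(X_raw, function(x) std_fit(x[train_idx, , drop = FALSE]))
  Xs <- lapply(seq_len(M), function(m)
    std_apply(X_raw[[m]][train_idx, , drop = FALSE], std[[m]]))
  Xv <- if (length(val_idx)) lapply(seq_len(M), function(m)
    std_apply(X_raw[[m]][val_idx, , drop = FALSE], std[[m]])) else NULL
  y <- y_all[train_idx]
  y_val <- y_all[val_idx]
  N <- length(train_idx)
  gamma <- control$gamma; lambda1 <- control$lambda1

  ## --- deterministic warm start -------------------------------------
  Xcat <- do.call(cbind, lapply(seq_len(M), function(m)
    Xs[[m]] * sqrt(a_m[m] / P[m])))
  sv <- .truncated_svd(Xcat, K)
  Z <- sv$u
  Z <- scale(Z)  # exact: U columns of a centered matrix have mean 0
  attr(Z, "scaled:center") <- NULL; attr(Z, "scaled:scale") <- NULL
  G0 <- crossprod(Z) + diag(1e-10, K)
  S <- vector("list", M); W <- vector("list", M)
  for (m in seq_len(M)) {
    B <- t(solve(G0, crossprod(Z, Xs[[m]])))  # P_m x K
    w <- sqrt(colMeans(B^2))
    w[w < 1e-12] <- 1e-12
    S[[m]] <- sweep(B, 2L, w, "/")
    W[[m]] <- w
  }
  cf <- stats::lm.fit(cbind(1, Z), y)$coefficients
  cf[is.na(cf)] <- 0
  b0 <- cf[1]; beta <- cf[-1]
  if (gamma == 0) { }  # head stays at its initialization; no gradient flows

  loss0 <- fusion_loss_terms(Z, S, W, beta, b0, Xs, y, a_m, gamma, lambda1)
  init_total <- loss0$total

  ## --- Adam state ----------------------------------------------------
  nb <- min(control$batch_size, N)
  adam <- function(dim) {
    z <- if (length(dim) > 1) array(0, dim) else numeric(dim)
    list(m = z, v = z)
  }
  st <- list(Z = adam(dim(Z)), beta = adam(K), b0 = adam(1),
             S = lapply(S, function(s) adam(dim(s))),
             W = lapply(W, function(w) adam(K)))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; lr <- control$lr
  tstep <- 0L
  upd <- function(state, par, grad) {
    state$m <- b1 * state$m + (1 - b1) * grad
    state$v <- b2 * state$v + (1 - b2) * grad^2
    mh <- state$m / (1 - b1^tstep)
    vh <- state$v / (1 - b2^tstep)
    list(state = state, par = par - lr * mh / (sqrt(vh) + eps))
  }

  use_val <- gamma > 0 && length(val_idx) > 0
  val0 <- if (use_val) {
    Zv0 <- .project_loadings(Xv, S, W, a_m, control$rho)
    mean((y_val - as.vector(Zv0 %*% beta) - b0)^2)
  } else Inf
  ## the warm start itself is a snapshot candidate
  best <- list(val = val0, train = init_total,
               Z = Z, S = S, W = W, beta = beta, b0 = b0, epoch = 0L)
  wait <- 0L
  hist <- vector("list", control$epochs)
  set.seed(control$seed)

  for (epoch in seq_len(control$epochs)) {
    ## short warmup tames Adam's full-size first steps off the warm start,
    ## then the schedule decays the step size
    lr <- control$lr * min(1, epoch / 5) /
      (1 + control$lr_decay * (epoch - 1))
    ord <- sample.int(N)
    for (start in seq(1L, N, by = nb)) {
      rows <- ord[start:min(start + nb - 1L, N)]
      nbr <- length(rows)
      Zb <- Z[rows, , drop = FALSE]
      dZb <- matrix(0, nbr, K)
      tstep <- tstep + 1L
      for (m in seq_len(M)) {
        Mm <- sweep(S[[m]], 2L, W[[m]], "*")
        R <- Xs[[m]][rows, , drop = FALSE] - tcrossprod(Zb, Mm)
        cc <- -2 * a_m[m] / (nbr * P[m])
        dZb <- dZb + cc * (R %*% Mm)
        dMm <- cc * crossprod(R, Zb)
        dS <- sweep(dMm, 2L, W[[m]], "*") + lambda1 * sign(S[[m]])
        dW <- colSums(dMm * S[[m]])
        o <- upd(st$S[[m]], S[[m]], dS); st$S[[m]] <- o$state; S[[m]] <- o$par
        o <- upd(st$W[[m]], W[[m]], dW); st$W[[m]] <- o$state
        W[[m]] <- pmax(o$par, 0)  # projection to the nonnegative orthant
      }
      if (gamma > 0) {
        r <- y[rows] - as.vector(Zb %*% beta) - b0
        cp <- -2 * gamma / nbr
        dZb <- dZb + cp * outer(r, beta)
        dbeta <- cp * as.vector(crossprod(Zb, r))
        db0 <- cp * sum(r)
        o <- upd(st$beta, beta, dbeta); st$beta <- o$state; beta <- o$par
        o <- upd(st$b0, b0, db0); st$b0 <- o$state; b0 <- o$par
      }
      stz <- st$Z
      stz$m[rows, ] <- b1 * stz$m[rows, , drop = FALSE] + (1 - b1) * dZb
      stz$v[rows, ] <- b2 * stz$v[rows, , drop = FALSE] + (1 - b2) * dZb^2
      Z[rows, ] <- Z[rows, , drop = FALSE] -
        lr * (stz$m[rows, , drop = FALSE] / (1 - b1^tstep)) /
        (sqrt(stz$v[rows, , drop = FALSE] / (1 - b2^tstep)) + eps)
      st$Z <- stz
    }

    ## keep training loadings column-standardized; compensate the scale
    ## into weights and head, the mean shift into the intercept
    mu <- colMeans(Z); sg <- apply(Z, 2L, stats::sd)
    sg[sg < 1e-12] <- 1
    Z <- sweep(sweep(Z, 2L, mu, "-"), 2L, sg, "/")
    for (m in seq_len(M)) W[[m]] <- W[[m]] * sg
    if (gamma > 0) {  # with gamma = 0 the head stays at its initialization
      b0 <- b0 + sum(mu * beta)
      beta <- beta * sg
    }

    lt <- fusion_loss_terms(Z, S, W, beta, b0, Xs, y, a_m, gamma, lambda1)
    if (!is.finite(lt$total)) {
      bad <- c(recon = any(!is.finite(lt$recon)), pred = !is.finite(lt$pred),
               l1 = !is.finite(lt$l1))
      stop("non-finite fusion loss (term: ",
           paste(names(bad)[bad], collapse = ", "), ") at epoch ", epoch)
    }
    val_loss <- NA_real_
    if (use_val) {
      Zv <- .project_loadings(Xv, S, W, a_m, control$rho)
      rv <- y_val - as.vector(Zv %*% beta) - b0
      val_loss <- mean(rv^2)
    }
    hist[[epoch]] <- c(epoch = epoch, total = lt$total,
                       recon = sum(lt$recon), pred = lt$pred, l1 = lt$l1,
                       val_pred = val_loss)

    track <- if (use_val) val_loss else lt$total
    best_track <- if (use_val) best$val else best$train
    if (track < best_track - 1e-12 && lt$total <= init_total + 1e-12) {
      best <- list(val = if (use_val) val_loss else Inf, train = lt$total,
                   Z = Z, S = S, W = W, beta = beta, b0 = b0, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= control$patience) break
    }
  }

  Z <- best$Z; S <- best$S; W <- best$W; beta <- best$beta; b0 <- best$b0
  rownames(Z) <- rownames(X_raw[[1]])[train_idx]
  colnames(Z) <- paste0("C", seq_len(K))
  energy <- Reduce(`+`, lapply(seq_len(M), function(m)
    W[[m]]^2 * colSums(S[[m]]^2)))
  model <- structure(list(
    Z = Z, S = S, W = W, beta = as.vector(beta), b0 = as.vector(b0)[1],
    K = as.integer(K), std = std, a_m = a_m,
    modalities = names(X_raw), P = P,
    train_idx = train_idx, val_idx = val_idx,
    history = do.call(rbind, hist[!vapply(hist, is.null, logical(1))]),
    init_loss = init_total, final_loss = best$train,
    best_epoch = best$epoch,
    degenerate = energy <= 1e-12,
    control = control
  ), class = "fusion_model")
  if (any(model$degenerate)) {
    warning(sum(model$degenerate),
            " component(s) have zero map energy (flagged degenerate)")
  }
  model
}

#' @export
print.fusion_model <- function(x, ...) {
  cat("fusion_model: K =", x$K, "|", length(x$S), "modalities |",
      nrow(x$Z), "training subjects\n")
  cat("  loss:", format(x$init_loss, digits = 5), "(init) ->",
      format(x$final_loss, digits = 5),
      sprintf("(best epoch %d)\n", x$best_epoch))
  if (any(x$degenerate)) {
    cat("  degenerate components:",
        paste(which(x$degenerate), collapse = ", "), "\n")
  }
  invisible(x)
}

## Closed-form ridge projection of standardized modality matrices onto the
## component space: per subject, z solves
##   (sum_m (a_m/P_m) M_m^T M_m + rho I) z = sum_m (a_m/P_m) M_m^T x_m
#' @keywords internal
.project_loadings <- function(X_std, S, W, a_m, rho) {
  K <- length(W[[1]])
  G <- diag(rho, K)
  H <- 0
  for (m in seq_along(S)) {
    Mm <- sweep(S[[m]], 2L, W[[m]], "*")
    cm <- a_m[m] / nrow(S[[m]])
    G <- G + cm * crossprod(Mm)
    H <- H + cm * (X_std[[m]] %*% Mm)
  }
  t(solve(G, t(H)))
}

#' Project new subjects onto the fitted component space
#'
#' Computes loadings for new subjects as the ridge least-squares solution
#' against the fitted weighted spatial maps; raw modality matrices are
#' standardized internally with the training-split scalers.
#'
#' @param model a `fusion_model`.
#' @param X_new named list of modality matrices (same modalities and
#'   feature counts as at fit time).
#' @param rho ridge regularizer; defaults to the fitted control's value.
#' @return loading matrix (subjects x K).
#' @export
project_subjects <- function(model, X_new, rho = NULL) {
  stopifnot(inherits(model, "fusion_model"))
  if (inherits(X_new, "multimodal_dataset")) X_new <- X_new$X
  if (length(X_new) != length(model$S)) stop("modality count mismatch")
  for (m in seq_along(X_new)) {
    if (ncol(X_new[[m]]) != model$P[m]) {
      stop("feature-count mismatch in modality ", model$modalities[m])
    }
  }
  rho <- rho %||% model$control$rho
  Xs <- lapply(seq_along(X_new), function(m)
    std_apply(as.matrix(X_new[[m]]), model$std[[m]]))
  Z <- .project_loadings(Xs, model$S, model$W, model$a_m, rho)
  rownames(Z) <- rownames(X_new[[1]])
  colnames(Z) <- paste0("C", seq_len(model$K))
  Z
}

#' Predict the continuous target from loadings
#'
#' @param model a `fusion_model`.
#' @param Z loading matrix with `model$K` columns.
#' @return numeric vector `Z %*% beta + b0`.
#' @export
predict_target <- function(model, Z) {
  stopifnot(inherits(model, "fusion_model"))
  Z <- as.matrix(Z)
  if (ncol(Z) != model$K) stop("Z must have K = ", model$K, " columns")
  as.vector(Z %*% model$beta) + model$b0
}

#' Per-component modality weight shares
#'
#' For each component k, the share of modality m is
#' `W_m[k] * ||S_m[, k]||_2`, normalized to sum to 1 over modalities —
#' the quantity summarized when calling a component uni- or multi-modal.
#' Degenerate (zero-energy) components get NA shares and are flagged.
#'
#' @param model a `fusion_model`.
#' @return K x M matrix of shares in \[0, 1\] with a logical
#'   `degenerate` attribute.
#' @export
modality_weight_distribution <- function(model) {
  stopifnot(inherits(model, "fusion_model"))
  M <- length(model$S)
  v <- vapply(seq_len(M), function(m)
    model$W[[m]] * sqrt(colSums(model$S[[m]]^2)), numeric(model$K))
  v <- matrix(v, nrow = model$K, ncol = M,
              dimnames = list(paste0("C", seq_len(model$K)),
                              model$modalities))
  tot <- rowSums(v)
  degenerate <- tot <= 1e-12
  shares <- v / tot
  shares[degenerate, ] <- NA_real_
  attr(shares, "degenerate") <- degenerate
  shares
}

#' Multivariable OLS of the target on all loading columns
#'
#' Ordinary least squares of the continuous target on the K loading
#' columns plus an intercept — the multivariable view of how components
#' jointly predict severity. Rank-deficient designs fall back to the
#' minimum-norm solution and are flagged.
#'
#' @param Z loading matrix (N x K), with N > K.
#' @param y continuous target.
#' @return list with `coefficients` (length K), `intercept`, `fitted`,
#'   `residuals`, `rank_deficient`.
#' @export
regress_target_on_loadings <- function(Z, y) {
  Z <- as.matrix(Z)
  if (nrow(Z) <= ncol(Z)) stop("need more observations than components")
  D <- cbind(`(Intercept)` = 1, Z)
  qrd <- qr(D)
  rank_deficient <- qrd$rank < ncol(D)
  if (!rank_deficient) {
    cf <- qr.coef(qrd, y)
  } else {
    warning("rank-deficient loading matrix; returning the minimum-norm solution")
    sv <- svd(D)
    pos <- sv$d > max(sv$d) * 1e-10
    cf <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
    cf <- as.vector(cf)
  }
  fitted <- as.vector(D %*% cf)
  list(coefficients = unname(cf[-1]), intercept = unname(cf[1]),
       fitted = fitted, residuals = y - fitted,
       rank_deficient = rank_deficient)
}

#' Dimensionality and seed sensitivity of the fusion fit
#'
#' Refits the model over a grid of component counts and seeds, recording
#' the held-out test prediction for every run, the pairwise correlation of
#' held-out predictions between runs, and per-run best-match loading
#' correlations against a reference run (the first run of the same K).
#'
#' @param dataset a `multimodal_dataset`.
#' @param split a [grouped_split()] with a test split.
#' @param K_grid integer vector of component counts.
#' @param seeds integer vector of optimizer seeds.
#' @param control base [fusion_control()]; its seed is replaced per run.
#' @return object of class `stability_report`: list with `grid` (data.frame
#'   K, seed, test_r), `predictions` (runs x test subjects),
#'   `pairwise_prediction_correlations`, `component_reproducibility`.
#' @export
stability_analysis <- function(dataset, split, K_grid, seeds,
                               control = fusion_control()) {
  if (length(K_grid) * length(seeds) < 2) stop("need at least 2 runs")
  test_idx <- which(split$split == "test")
  X_test <- lapply(dataset$X, function(x) x[test_idx, , drop = FALSE])
  y_test <- dataset$pheno$target[test_idx]
  runs <- expand.grid(seed = seeds, K = K_grid)[, c("K", "seed")]
  preds <- matrix(NA_real_, nrow(runs), length(test_idx))
  test_r <- numeric(nrow(runs))
  ref_Z <- list()  # reference training loadings per K
  repro <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    ctl <- control; ctl$seed <- as.integer(runs$seed[i])
    model <- tryCatch(
      fit_fusion(dataset, split, K = runs$K[i], control = ctl),
      error = function(e) stop("stability run (K=", runs$K[i], ", seed=",
                               runs$seed[i], ") failed: ",
                               conditionMessage(e)))
    preds[i, ] <- predict_target(model, project_subjects(model, X_test))
    test_r[i] <- stats::cor(preds[i, ], y_test)
    kk <- as.character(runs$K[i])
    if (is.null(ref_Z[[kk]])) {
      ref_Z[[kk]] <- model$Z
      repro[[i]] <- rep(1, runs$K[i])
    } else {
      repro[[i]] <- abs(match_components(model$Z, ref_Z[[kk]])$cors)
    }
  }
  runs$test_r <- test_r
  structure(list(grid = runs, predictions = preds,
                 pairwise_prediction_correlations = stats::cor(t(preds)),
                 component_reproducibility = repro),
            class = "stability_report")
}
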