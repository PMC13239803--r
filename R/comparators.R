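## Comparator feature sets against which the fused loadings are judged:
## demographics, per-modality principal and independent components,
## concatenated-modality PCs, and the pooled top-10 target-correlated PCs.

#' @keywords internal
new_feature_set <- function(name, matrix_, provenance) {
  structure(list(name = name, matrix = matrix_, provenance = provenance),
            class = "feature_set")
}

## Fixed-point symmetric ICA (tanh contrast) on pre-whitened data.
## Rows of `Xw` are observations, columns whitened directions.
#' @keywords internal
.fast_ica_rotation <- function(Xw, seed, max_iter = 200, tol = 1e-6) {
  k <- ncol(Xw); n <- nrow(Xw)
  set.seed(seed)
  Wrot <- matrix(stats::rnorm(k * k), k, k)
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    solve_sqrt <- e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), k) %*%
      t(e$vectors)
    solve_sqrt %*% W
  }
  Wrot <- sym_decorrelate(Wrot)
  for (it in seq_len(max_iter)) {
    WX <- Xw %*% t(Wrot)           # n x k
    G <- tanh(WX)
    Gp <- 1 - G^2
    W_new <- crossprod(G, Xw) / n - diag(colMeans(Gp), k) %*% Wrot
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(abs(rowSums(W_new * Wrot)) - 1))
    Wrot <- W_new
    if (delta < tol) break
  }
  Wrot
}

#' Build the comparator feature sets
#'
#' All decompositions are fit on the training split only and applied to
#' every subject. Produces: demographics (age + sex); per-modality
#' principal-component scores; per-modality independent-component scores
#' (whitened PCA followed by a seeded fixed-point rotation maximizing
#' non-Gaussianity); concatenated-modality PCs; and the "top-10 PCs combo"
#' — the 10 per-modality PC score columns, pooled across modalities, most
#' correlated (in absolute value) with the training target.
#'
#' @param dataset a `multimodal_dataset` with `age` and `sex` phenotype
#'   columns.
#' @param split a [grouped_split()] assignment.
#' @param n_components components per decomposition.
#' @param seed integer seed (ICA rotation starts).
#' @return named list of `feature_set` objects.
#' @export
build_comparators <- function(dataset, split, n_components = 10, seed = 1) {
  train <- which(split$split == "train")
  pheno <- dataset$pheno
  y_train <- pheno$target[train]
  out <- list()

  demo <- cbind(age = pheno$age,
                sex = as.integer(factor(pheno$sex)) - 1L)
  rownames(demo) <- pheno$subject_id
  out$demographics <- new_feature_set("demographics", demo,
                                      list(columns = c("age", "sex")))

  pc_scores_all <- NULL  # pooled per-modality PC columns for the combo
  for (m in names(dataset$X)) {
    Xm <- dataset$X[[m]]
    k <- min(n_components, length(train) - 1L, ncol(Xm))
    std <- std_fit(Xm[train, , drop = FALSE])
    Xs <- std_apply(Xm, std)
    sv <- .truncated_svd(Xs[train, , drop = FALSE], k)
    rot <- crossprod(Xs[train, , drop = FALSE], sv$u)     # P x k
    rot <- sweep(rot, 2L, pmax(sv$d, 1e-12), "/")
    rot[, sv$d < max(sv$d) * 1e-5] <- 0   # rank limit: dead directions
    scores <- Xs %*% rot                                   # all subjects
    colnames(scores) <- paste0(m, "_PC", seq_len(k))
    rownames(scores) <- pheno$subject_id
    out[[paste0(m, "_PCs")]] <- new_feature_set(
      paste0(m, "_PCs"), scores,
      list(modality = m, n_components = k, fit_on = "train"))
    pc_scores_all <- cbind(pc_scores_all, scores)

    ## ICA: whiten the training PC scores, rotate, apply to all subjects
    d_tr <- sv$d / sqrt(length(train) - 1)
    keep <- d_tr > 1e-8
    white <- sweep(scores[, keep, drop = FALSE], 2L, d_tr[keep], "/")
    Wrot <- .fast_ica_rotation(white[train, , drop = FALSE], seed = seed)
    ics <- white %*% t(Wrot)
    colnames(ics) <- paste0(m, "_IC", seq_len(ncol(ics)))
    rownames(ics) <- pheno$subject_id
    out[[paste0(m, "_ICs")]] <- new_feature_set(
      paste0(m, "_ICs"), ics,
      list(modality = m, n_components = sum(keep), seed = seed,
           method = "whitened PCA + fixed-point tanh rotation"))
  }

  ## concatenated-modality PCs
  Xcat <- do.call(cbind, lapply(names(dataset$X), function(m) {
    std <- std_fit(dataset$X[[m]][train, , drop = FALSE])
    std_apply(dataset$X[[m]], std)
  }))
  k <- min(n_components, length(train) - 1L, ncol(Xcat))
  sv <- .truncated_svd(Xcat[train, , drop = FALSE], k)
  rot <- sweep(crossprod(Xcat[train, , drop = FALSE], sv$u), 2L,
               pmax(sv$d, 1e-12), "/")
  concat <- Xcat %*% rot
  colnames(concat) <- paste0("concat_PC", seq_len(k))
  rownames(concat) <- pheno$subject_id
  out$concat_PCs <- new_feature_set("concat_PCs", concat,
                                    list(n_components = k, fit_on = "train"))

  ## top-10 combo: pooled per-modality PCs ranked by |cor| with the
  ## training target
  cors <- abs(apply(pc_scores_all[train, , drop = FALSE], 2L,
                    function(v) suppressWarnings(stats::cor(v, y_train))))
  cors[is.na(cors)] <- 0
  top <- order(cors, decreasing = TRUE)[seq_len(min(10L, length(cors)))]
  combo <- pc_scores_all[, top, drop = FALSE]
  out$top10_PCs_combo <- new_feature_set(
    "top10_PCs_combo", combo,
    list(selected = colnames(pc_scores_all)[top],
         abs_cor_with_train_target = unname(cors[top])))
  out
}
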