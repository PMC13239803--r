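## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a per-column standardizer
#'
#' Computes per-column means and standard deviations on a reference set of
#' rows (typically the training split) so the identical affine transform can
#' be reused on validation/test data without leakage.
#'
#' @param x numeric matrix.
#' @return list with `center` and `scale` vectors; zero-variance columns get
#'   scale 1 so they map to constant zero rather than NaN.
#' @keywords internal
std_fit <- function(x) {
  center <- unname(colMeans(x))
  scale <- unname(apply(x, 2L, stats::sd))
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  list(center = center, scale = scale)
}

#' @keywords internal
std_apply <- function(x, std) {
  sweep(sweep(x, 2L, std$center, "-"), 2L, std$scale, "/")
}

#' @keywords internal
std_invert <- function(x, std) {
  sweep(sweep(x, 2L, std$scale, "*"), 2L, std$center, "+")
}

## Stratified fold assignment: each class is split as evenly as possible.
#' @keywords internal
stratified_folds <- function(labels, k, seed) {
  labels <- as.factor(labels)
  fold <- integer(length(labels))
  set.seed(seed)
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

## Exact linear-assignment matching of estimated to true components by
## maximizing total |correlation|; brute force over permutations for small K
## (exact), greedy otherwise.
#' Match estimated components to reference components
#'
#' Pairs columns of `est` with columns of `ref` to maximize the summed
#' absolute Pearson correlation, and reports the matched correlations.
#' Used to score factor-recovery because latent components are only
#' identified up to sign and permutation.
#'
#' @param est,ref matrices with the same number of rows; columns are
#'   components.
#' @return list with `perm` (for each ref column, the matched est column),
#'   `cors` (signed correlation of each matched pair) and `mean_abs_cor`.
#' @export
match_components <- function(est, ref) {
  stopifnot(nrow(est) == nrow(ref))
  k <- ncol(ref)
  stopifnot(ncol(est) >= k)
  cmat <- abs(stats::cor(ref, est))  # k x ncol(est)
  if (k <= 8 && ncol(est) <= 8) {
    perms <- .permutations(ncol(est))
    best <- NULL; best_val <- -Inf
    for (p in perms) {
      val <- sum(cmat[cbind(seq_len(k), p[seq_len(k)])])
      if (val > best_val) { best_val <- val; best <- p[seq_len(k)] }
    }
    perm <- best
  } else {
    perm <- integer(k); used <- logical(ncol(est))
    ord <- order(apply(cmat, 1L, max), decreasing = TRUE)
    for (i in ord) {
      j <- which.max(ifelse(used, -Inf, cmat[i, ]))
      perm[i] <- j; used[j] <- TRUE
    }
  }
  cors <- vapply(seq_len(k), function(i) {
    stats::cor(ref[, i], est[, perm[i]])
  }, numeric(1))
  list(perm = perm, cors = cors, mean_abs_cor = mean(abs(cors)))
}

#' @keywords internal
.permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    sub <- .permutations(n - 1L)
    rest <- setdiff(seq_len(n), i)
    for (s in sub) out[[length(out) + 1L]] <- c(i, rest[s])
  }
  out
}
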