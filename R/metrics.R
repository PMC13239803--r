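## Binary-classification metric battery.

#' @keywords internal
.auroc <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)  # midranks: tied pairs count 1/2
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @keywords internal
.auprc <- function(scores, labels) {
  ## step integration of the precision-recall curve over distinct
  ## score thresholds, descending
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  grp <- cumsum(!duplicated(s))              # tie groups share a threshold
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tp <- tp[last]; fp <- fp[last]
  n1 <- sum(y)
  recall <- tp / n1
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Evaluate a binary classifier's scores
#'
#' AUROC is the probability that a random positive outscores a random
#' negative (ties counted 1/2); AUPRC integrates the precision-recall step
#' curve; the thresholded metrics dichotomize the scores at `threshold`
#' (0.5, for probability outputs). When no positive is predicted,
#' precision and F1 are reported as 0.
#'
#' @param scores numeric classifier scores, higher = more positive.
#' @param labels binary labels (0/1, logical, or 2-level factor where the
#'   second level is positive).
#' @param threshold operating point for the thresholded metrics.
#' @return named numeric vector: auroc, auprc, accuracy,
#'   balanced_accuracy, sensitivity, specificity, precision, f1.
#' @export
evaluate_binary <- function(scores, labels, threshold = 0.5) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary")
  if (length(unique(labels)) < 2) {
    stop("both classes must be present (AUROC undefined otherwise)")
  }
  if (any(!is.finite(scores))) stop("scores must be finite")
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  f1 <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  c(auroc = .auroc(scores, labels),
    auprc = .auprc(scores, labels),
    accuracy = (tp + tn) / length(labels),
    balanced_accuracy = (sens + spec) / 2,
    sensitivity = sens, specificity = spec,
    precision = prec, f1 = f1)
}

#' Macro-average metric sets across tasks
#'
#' Arithmetic mean of each metric across per-task reports (the unweighted
#' average over the pairwise classification tasks).
#'
#' @param reports list of named metric vectors with identical names.
#' @return named numeric vector of macro-averaged metrics.
#' @export
macro_average <- function(reports) {
  if (!length(reports)) stop("need at least one task report")
  keys <- names(reports[[1]])
  for (r in reports) {
    if (!identical(names(r), keys)) stop("inconsistent metric keys")
  }
  colMeans(do.call(rbind, reports))
}

#' Stratified bootstrap percentile confidence interval for a metric
#'
#' Resamples subjects with replacement within each class (so every
#' resample retains both classes), recomputes the metric, and reports the
#' percentile interval.
#'
#' @param metric metric name (a column of [evaluate_binary()]) or a
#'   function `(scores, labels) -> scalar`.
#' @param scores,labels as in [evaluate_binary()].
#' @param B number of bootstrap resamples (at least 100).
#' @param seed integer seed.
#' @param conf confidence level.
#' @return numeric vector `c(lower, upper)`.
#' @export
bootstrap_ci <- function(metric, scores, labels, B = 2000, seed = 1,
                         conf = 0.95) {
  if (B < 100) stop("B must be at least 100")
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  fn <- if (is.function(metric)) metric else {
    function(s, l) unname(evaluate_binary(s, l)[metric])
  }
  point <- fn(scores, labels)  # errors here mean the metric is undefined
  if (!is.finite(point)) stop("metric undefined on the original data")
  idx1 <- which(labels == 1); idx0 <- which(labels == 0)
  set.seed(seed)
  stat <- numeric(B)
  for (b in seq_len(B)) {
    repeat {
      take <- c(sample(idx1, length(idx1), replace = TRUE),
                sample(idx0, length(idx0), replace = TRUE))
      v <- tryCatch(fn(scores[take], labels[take]), error = function(e) NA_real_)
      if (is.finite(v)) break
    }
    stat[b] <- v
  }
  alpha <- (1 - conf) / 2
  out <- unname(stats::quantile(stat, c(alpha, 1 - alpha)))
  names(out) <- c("lower", "upper")
  out
}
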