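## Mixture-model thresholding of component spatial maps: a Gaussian noise
## class plus (optionally) a positive-signal Gamma class and a mirrored
## negative-signal Gamma class, fit by EM on robustly standardized map
## values. Features are retained when their posterior probability of
## belonging to any signal class exceeds a cutoff (`mmthresh`).

## Weighted Gamma maximum-likelihood M-step: shape by Newton on
## log(k) - digamma(k) = s, rate in closed form. Exact maximizer, so the
## EM log-likelihood is monotone.
#' @keywords internal
.wgamma_mle <- function(x, w) {
  sw <- sum(w)
  mu <- sum(w * x) / sw
  s <- log(mu) - sum(w * log(x)) / sw
  s <- max(s, 1e-8)
  k <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (it in 1:50) {
    step <- (log(k) - digamma(k) - s) / (1 / k - trigamma(k))
    k_new <- k - step
    if (!is.finite(k_new) || k_new <= 0) k_new <- k / 2
    if (abs(k_new - k) < 1e-10 * k) { k <- k_new; break }
    k <- k_new
  }
  k <- min(max(k, 1e-3), 1e4)
  c(shape = k, rate = k / mu)
}

#' Fit a Gaussian-noise + Gamma-signal mixture to one spatial map
#'
#' Map values are standardized internally (median-centered, unit SD); the
#' noise class is a free Gaussian, the positive signal class a Gamma on
#' values above zero, the negative signal class a mirrored Gamma on values
#' below zero. Classes are initialized from a quantile split (central 80%
#' as noise, 10% tails as signal) and fit by EM with exact M-steps, so the
#' log-likelihood trace is monotone. A signal class whose support
#' collapses mid-EM is dropped and the EM restarted without it, and the
#' retained configuration (noise only, one-sided, or two-sided) is chosen
#' by BIC across candidate fits — pure-noise maps collapse to the single
#' Gaussian instead of shaving its tails into spurious signal classes.
#'
#' @param map_values numeric vector of per-feature map statistics (at
#'   least 100 finite values, not all equal).
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood convergence tolerance.
#' @param seed retained for interface stability; the fit itself is
#'   deterministic given the data.
#' @return object of class `mixture_fit`: `noise` (mean, sd on the
#'   standardized scale), `pos_signal` / `neg_signal` (shape, rate or NULL),
#'   `proportions` (named simplex), `posteriors` (per-feature probability
#'   of signal), `loglik_trace`, `converged`, `center`, `scale`.
#' @export
fit_mixture <- function(map_values, max_iter = 500, tol = 1e-7, seed = 1) {
  x_raw <- map_values[is.finite(map_values)]
  if (length(x_raw) < length(map_values)) stop("non-finite map values")
  if (length(x_raw) < 100) stop("need at least 100 finite values")
  center <- stats::median(x_raw)
  scale_ <- stats::sd(x_raw)
  if (scale_ < 1e-12) stop("all-constant map")
  x <- (x_raw - center) / scale_
  n <- length(x)

  ## quantile-split initialization
  qs <- stats::quantile(x, c(0.1, 0.9))
  mid <- x[x >= qs[1] & x <= qs[2]]
  init_class <- function(side) {
    tail_x <- if (side > 0) x[x > qs[2]] else -x[x < qs[1]]
    tail_x <- tail_x[tail_x > 0]
    if (length(tail_x) < 5) return(NULL)
    m <- mean(tail_x); v <- stats::var(tail_x)
    list(shape = max(m^2 / v, 0.1), rate = max(m / v, 1e-3))
  }
  classes <- list(
    noise = list(mean = mean(mid), sd = max(stats::sd(mid), 1e-6)),
    pos = init_class(+1), neg = init_class(-1)
  )
  prop <- c(noise = 0.8,
            pos = if (!is.null(classes$pos)) 0.1 else 0,
            neg = if (!is.null(classes$neg)) 0.1 else 0)
  prop <- prop / sum(prop)

  run_em <- function(classes, prop) {
    ll_trace <- numeric(0)
    converged <- FALSE
    post <- NULL
    for (iter in seq_len(max_iter)) {
      dens <- cbind(
        noise = prop["noise"] *
          stats::dnorm(x, classes$noise$mean, classes$noise$sd),
        pos = if (!is.null(classes$pos) && prop["pos"] > 0)
          prop["pos"] * ifelse(x > 0,
            stats::dgamma(x, classes$pos$shape, classes$pos$rate), 0)
          else 0,
        neg = if (!is.null(classes$neg) && prop["neg"] > 0)
          prop["neg"] * ifelse(x < 0,
            stats::dgamma(-x, classes$neg$shape, classes$neg$rate), 0)
          else 0
      )
      tot <- rowSums(dens)
      tot[tot < 1e-300] <- 1e-300
      ll <- sum(log(tot))
      ll_trace <- c(ll_trace, ll)
      post <- dens / tot
      ## collapse check: a signal class with vanishing support is dropped
      for (cl in c("pos", "neg")) {
        if (!is.null(classes[[cl]]) &&
            (sum(post[, cl]) < 2 || prop[cl] < 1e-4)) {
          classes[[cl]] <- NULL
          prop[cl] <- 0
          prop <- prop / sum(prop)
          return(list(classes = classes, prop = prop, restart = TRUE))
        }
      }
      ## M-step (exact maximizers; support boundaries are fixed at 0)
      prop <- colSums(post) / n
      w0 <- post[, "noise"]
      mu0 <- sum(w0 * x) / sum(w0)
      sd0 <- sqrt(sum(w0 * (x - mu0)^2) / sum(w0))
      classes$noise <- list(mean = mu0, sd = max(sd0, 1e-6))
      if (!is.null(classes$pos)) {
        sel <- x > 0
        g <- .wgamma_mle(x[sel], post[sel, "pos"])
        classes$pos <- list(shape = g[["shape"]], rate = g[["rate"]])
      }
      if (!is.null(classes$neg)) {
        sel <- x < 0
        g <- .wgamma_mle(-x[sel], post[sel, "neg"])
        classes$neg <- list(shape = g[["shape"]], rate = g[["rate"]])
      }
      if (iter > 1) {
        rel <- abs(ll - ll_trace[iter - 1]) /
          max(abs(ll_trace[iter - 1]), 1e-12)
        if (rel < tol) { converged <- TRUE; break }
      }
    }
    list(classes = classes, prop = prop, post = post,
         ll_trace = ll_trace, converged = converged, restart = FALSE)
  }

  ## Candidate class configurations, each fit by EM and compared by BIC:
  ## a signal class is retained only when it genuinely improves the fit,
  ## so pure-noise maps collapse to the single Gaussian.
  n_par <- function(classes) {
    2 + 2 * (!is.null(classes$pos)) + 2 * (!is.null(classes$neg)) +
      sum(!is.null(classes$pos), !is.null(classes$neg))  # free proportions
  }
  candidates <- list(c(FALSE, FALSE), c(TRUE, FALSE), c(FALSE, TRUE),
                     c(TRUE, TRUE))
  res <- NULL; best_bic <- Inf
  for (cand in candidates) {
    cl <- classes
    if (!cand[1]) cl$pos <- NULL
    if (!cand[2]) cl$neg <- NULL
    if ((cand[1] && is.null(classes$pos)) ||
        (cand[2] && is.null(classes$neg))) next
    pr <- c(noise = 0.8, pos = if (!is.null(cl$pos)) 0.1 else 0,
            neg = if (!is.null(cl$neg)) 0.1 else 0)
    pr <- pr / sum(pr)
    r <- run_em(cl, pr)
    restarts <- 0
    while (isTRUE(r$restart) && restarts < 3) {
      restarts <- restarts + 1
      r <- run_em(r$classes, r$prop)
    }
    if (isTRUE(r$restart)) next
    bic <- -2 * r$ll_trace[length(r$ll_trace)] + n_par(r$classes) * log(n)
    if (bic < best_bic) { best_bic <- bic; res <- r }
  }
  post_signal <- numeric(n)
  if ("pos" %in% colnames(res$post)) post_signal <- post_signal + res$post[, "pos"]
  if ("neg" %in% colnames(res$post)) post_signal <- post_signal + res$post[, "neg"]
  structure(list(
    noise = res$classes$noise,
    pos_signal = res$classes$pos,
    neg_signal = res$classes$neg,
    proportions = res$prop,
    posteriors = pmin(pmax(post_signal, 0), 1),
    loglik_trace = res$ll_trace,
    converged = res$converged,
    center = center, scale = scale_, n = n
  ), class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("mixture_fit:", x$n, "features | noise N(",
      round(x$noise$mean, 3), ",", round(x$noise$sd, 3), ") | signal prop",
      round(sum(x$proportions[c("pos", "neg")], na.rm = TRUE), 4),
      if (x$converged) "| converged\n" else "| NOT converged\n")
  invisible(x)
}

#' Threshold a spatial map by signal posterior
#'
#' Retains features whose posterior probability of belonging to any signal
#' class exceeds `mmthresh`. `mmthresh = 0` keeps every feature with a
#' nonzero posterior; `mmthresh = 1` keeps none.
#'
#' @param fit a [fit_mixture()] result.
#' @param mmthresh posterior cutoff in \[0, 1\]; 0.5 by default.
#' @return list with `mask` (logical) and `posteriors`.
#' @export
threshold_map <- function(fit, mmthresh = 0.5) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (mmthresh < 0 || mmthresh > 1) stop("mmthresh must lie in [0, 1]")
  list(mask = fit$posteriors > mmthresh, posteriors = fit$posteriors)
}
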