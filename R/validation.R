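## Component-phenotype correlation screening with FDR control, and CSF
## sample eligibility selection.

#' Correlation screen of component loadings against a phenotype
#'
#' Per-component Pearson correlation with two-sided t-distribution
#' p-values, Benjamini-Hochberg step-up adjustment across the K
#' components, and a significance flag at `q < alpha`.
#'
#' @param loadings subjects-by-components matrix.
#' @param variable numeric phenotype vector; pairs with missing values are
#'   dropped per component (at least 3 complete pairs required).
#' @param alpha FDR level for the significance flag.
#' @return data.frame of class `correlation_screen`: component, n, r, p,
#'   q, significant.
#' @export
correlation_screen <- function(loadings, variable, alpha = 0.05) {
  Z <- as.matrix(loadings)
  K <- ncol(Z)
  r <- p <- numeric(K); n_used <- integer(K)
  for (k in seq_len(K)) {
    ok <- is.finite(Z[, k]) & is.finite(variable)
    n <- sum(ok)
    if (n < 3) stop("fewer than 3 complete pairs for component ", k)
    if (stats::sd(Z[ok, k]) < 1e-12) stop("zero-variance component ", k)
    rk <- stats::cor(Z[ok, k], variable[ok])
    tk <- rk * sqrt((n - 2) / (1 - rk^2))
    p[k] <- 2 * stats::pt(-abs(tk), df = n - 2)
    r[k] <- rk; n_used[k] <- n
  }
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(
    component = colnames(Z) %||% paste0("C", seq_len(K)),
    n = n_used, r = r, p = p, q = q, significant = q < alpha
  )
  class(out) <- c("correlation_screen", "data.frame")
  out
}

#' Select the eligible CSF draw per subject
#'
#' Keeps, per subject, the draw closest in time to the imaging visit among
#' those within the eligibility window (365 days, inclusive); subjects
#' with no qualifying draw are omitted. Exact ties in distance break
#' toward the earlier draw.
#'
#' @param samples data.frame of dated draws with a `subject_id` column and
#'   either an `offset_days` column (draw minus visit, days) or a
#'   `draw_date` column (Date or parseable string, requires `visit_date`).
#' @param visit_date per-row imaging-visit dates, needed when offsets are
#'   not supplied directly.
#' @param window_days eligibility window (inclusive).
#' @return data.frame: one row per subject with a qualifying draw,
#'   including the computed `offset_days`.
#' @export
select_csf_samples <- function(samples, visit_date = NULL,
                               window_days = 365) {
  df <- as.data.frame(samples)
  if (!"subject_id" %in% names(df)) stop("samples need a subject_id column")
  if (!"offset_days" %in% names(df)) {
    if (is.null(visit_date) || !"draw_date" %in% names(df)) {
      stop("need either offset_days or draw_date plus visit_date")
    }
    parse_date <- function(x) {
      tryCatch(as.Date(x), error = function(e) stop("malformed dates"))
    }
    draw <- parse_date(df$draw_date)
    visit <- parse_date(visit_date)
    if (anyNA(draw) || anyNA(visit)) stop("malformed dates")
    df$offset_days <- as.numeric(draw - visit)
  }
  if (!is.numeric(df$offset_days)) stop("offset_days must be numeric")
  df <- df[is.finite(df$offset_days) &
             abs(df$offset_days) <= window_days, , drop = FALSE]
  if (!nrow(df)) return(df)
  ## nearest draw; ties toward the earlier (more negative offset) draw
  ord <- order(df$subject_id, abs(df$offset_days), df$offset_days)
  df <- df[ord, , drop = FALSE]
  df[!duplicated(df$subject_id), , drop = FALSE]
}

#' Correlation of one component's loadings with a CSF biomarker
#'
#' Pearson correlation over complete pairs of an eligible-subject loading
#' column and a CSF value.
#'
#' @param loadings subjects-by-components matrix (rows: eligible subjects).
#' @param component_index column to correlate.
#' @param csf_values numeric biomarker values aligned with the rows.
#' @return list with `r`, `p` (two-sided) and `n`.
#' @export
csf_association <- function(loadings, component_index, csf_values) {
  z <- as.matrix(loadings)[, component_index]
  ok <- is.finite(z) & is.finite(csf_values)
  if (sum(ok) < 3) stop("fewer than 3 complete pairs")
  ct <- stats::cor.test(z[ok], csf_values[ok])
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
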