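#' Translate CDR-SOB scores into diagnostic bands
#'
#' The Clinical Dementia Rating Sum of Boxes (CDR-SOB) sums six domains
#' scored 0-3 in half-point steps, for a total of 0 to 18. A standard
#' translation maps 0 to cognitively normal (CN), 0.5-4 to MCI/subjective
#' cognitive decline, 4.5-9 to mild dementia, 9.5-15.5 to moderate dementia
#' and 16-18 to severe dementia. The mapping is total on the half-point grid.
#'
#' @param score numeric vector of CDR-SOB scores, each in \[0, 18\] and
#'   quantized to half points.
#' @return factor with levels `CN`, `MCI_SCD`, `mild`, `moderate`, `severe`.
#' @examples
#' band_cdr_sob(c(0, 0.5, 4, 4.5, 9.5, 16, 18))
#' @export
band_cdr_sob <- function(score) {
  if (!is.numeric(score) || anyNA(score)) {
    stop("`score` must be numeric with no missing values")
  }
  if (any(score < 0 | score > 18)) {
    stop("CDR-SOB scores must lie in [0, 18]")
  }
  if (any(abs(score * 2 - round(score * 2)) > 1e-8)) {
    stop("CDR-SOB scores must be quantized to half points")
  }
  lv <- cdr_sob_bands()
  out <- character(length(score))
  out[score == 0] <- "CN"
  out[score >= 0.5 & score <= 4] <- "MCI_SCD"
  out[score >= 4.5 & score <= 9] <- "mild"
  out[score >= 9.5 & score <= 15.5] <- "moderate"
  out[score >= 16] <- "severe"
  factor(out, levels = lv)
}

#' Diagnostic band levels in severity order
#' @return character vector of the five band labels.
#' @export
cdr_sob_bands <- function() c("CN", "MCI_SCD", "mild", "moderate", "severe")
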