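#' L1-penalized logistic classifier with inner cross-validated lambda
#'
#' Fits LASSO logistic regression over a lambda grid, choosing lambda by
#' stratified inner cross-validated binomial deviance (minimum rule).
#' Features are z-scored internally on the fitting data and the scaler is
#' stored, so penalization is scale-fair and new data are transformed
#' identically. The L1 penalty performs feature selection and guards
#' against multicollinearity among components.
#'
#' @param features subjects-by-features numeric matrix.
#' @param labels binary labels (0/1, logical or 2-level factor).
#' @param lambda_grid optional decreasing lambda sequence; glmnet's
#'   data-driven path by default.
#' @param inner_folds number of stratified inner CV folds.
#' @param seed integer seed for fold assignment.
#' @return object of class `lasso_logistic`: `coefficients`, `intercept`,
#'   `selected` (indices of nonzero coefficients), `lambda`, `std`,
#'   `cv_deviance` (per-lambda mean deviance).
#' @export
fit_lasso_logistic <- function(features, labels, lambda_grid = NULL,
                               inner_folds = 5, seed = 1) {
  X <- as.matrix(features)
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  y <- as.integer(labels)
  if (length(unique(y)) < 2) stop("labels contain a single class")
  if (!is.null(lambda_grid) && !length(lambda_grid)) stop("empty lambda grid")
  std <- std_fit(X)
  Xs <- std_apply(X, std)
  inner_folds <- max(3L, min(inner_folds, min(table(y))))
  foldid <- stratified_folds(y, inner_folds, seed)
  cv <- glmnet::cv.glmnet(Xs, y, family = "binomial", alpha = 1,
                          lambda = lambda_grid, foldid = foldid,
                          type.measure = "deviance", standardize = FALSE)
  cf <- as.vector(stats::coef(cv, s = "lambda.min"))
  structure(list(coefficients = cf[-1], intercept = cf[1],
                 selected = which(abs(cf[-1]) > 0),
                 lambda = cv$lambda.min,
                 lambda_grid = cv$lambda, cv_deviance = cv$cvm,
                 std = std, feature_names = colnames(X)),
            class = "lasso_logistic")
}

#' Predict probabilities from a fitted LASSO logistic classifier
#'
#' @param object a `lasso_logistic`.
#' @param newx matrix of features (same columns as at fit).
#' @param type `"response"` (probability) or `"link"` (log-odds).
#' @param ... ignored.
#' @return numeric vector of predictions.
#' @export
predict.lasso_logistic <- function(object, newx, type = c("response", "link"),
                                   ...) {
  type <- match.arg(type)
  Xs <- std_apply(as.matrix(newx), object$std)
  eta <- as.vector(Xs %*% object$coefficients) + object$intercept
  if (type == "link") eta else stats::plogis(eta)
}
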