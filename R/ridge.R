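#' Ridge regression baseline
#'
#' Linear benchmark on `[expression | covariates]` with an L2 penalty.
#' The full regularization path over `lambda_grid` is computed from one
#' SVD of the centered training design; the penalty is chosen by
#' validation-set R^2 and the reported test predictions come from the
#' training-data coefficients at the selected lambda.
#'
#' @param splits List with `train`, `validation`, `test` cohorts (raw
#'   imputed splits; standardization on training statistics happens
#'   internally, as for [train_model()]).
#' @param lambda_grid Positive penalties to evaluate (default
#'   `10^seq(-4, 6, length.out = 60)`).
#' @return A `ridge_fit` with `coef`, `intercept`, `lambda`, `test_r2`,
#'   `test_predictions`, and the per-lambda `path`. Use [predict()],
#'   [tidy()], [glance()].
#' @export
ridge_fit <- function(splits, lambda_grid = 10^seq(-4, 6, length.out = 60)) {
  stopifnot(all(lambda_grid > 0))
  lambda_grid <- sort(lambda_grid)
  std <- standardize_cohorts(splits$train, validation = splits$validation,
                             test = splits$test)
  design <- function(co) cbind(co$expression, co$covariates)
  Xtr <- design(std$train)
  x_center <- colMeans(Xtr)
  Xtr <- sweep(Xtr, 2, x_center)
  ytr <- splits$train$phenotype
  y_center <- mean(ytr)
  sv <- svd(Xtr)
  uty <- crossprod(sv$u, ytr - y_center)
  coef_at <- function(lambda) {
    as.numeric(sv$v %*% (uty * sv$d / (sv$d^2 + lambda)))
  }
  pred_with <- function(co, beta) {
    as.numeric(sweep(design(co), 2, x_center) %*% beta) + y_center
  }
  val_r2 <- vapply(lambda_grid, function(l) {
    evaluate_r2(pred_with(std$validation, coef_at(l)),
                splits$validation$phenotype)
  }, 0)
  best <- which.max(val_r2)
  beta <- coef_at(lambda_grid[best])
  test_pred <- pred_with(std$test, beta)
  structure(list(
    coef = stats::setNames(beta, colnames(design(std$train))),
    intercept = y_center,
    x_center = x_center,
    lambda = lambda_grid[best],
    standardization = std$stats,
    path = tibble::tibble(lambda = lambda_grid, validation_r2 = val_r2),
    validation_r2 = val_r2[best],
    test_r2 = evaluate_r2(test_pred, splits$test$phenotype),
    test_predictions = test_pred,
    test_truth = splits$test$phenotype,
    kind = "ridge"
  ), class = "ridge_fit")
}

#' @export
print.ridge_fit <- function(x, ...) {
  cat("<ridge_fit> lambda = ", signif(x$lambda, 3), " (validation R^2 ",
      signif(x$validation_r2, 4), "), test R^2 ", signif(x$test_r2, 4),
      "\n", sep = "")
  invisible(x)
}

#' Predict from a ridge fit
#'
#' @param object A `ridge_fit`.
#' @param newdata A raw (imputed, unstandardized) `proteomics_cohort`.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.ridge_fit <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "proteomics_cohort"))
  st <- object$standardization
  X <- sweep(sweep(newdata$expression, 2, st$center), 2, st$scale, "/")
  Cov <- sweep(sweep(newdata$covariates, 2, st$cov_center), 2, st$cov_scale, "/")
  D <- sweep(cbind(X, Cov), 2, object$x_center)
  as.numeric(D %*% object$coef) + object$intercept
}

#' @describeIn ridge_fit Coefficients as a tibble.
#' @param x,object A `ridge_fit`.
#' @param ... Unused.
#' @export
tidy.ridge_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' @describeIn ridge_fit One-row fit summary.
#' @export
glance.ridge_fit <- function(x, ...) {
  tibble::tibble(kind = "ridge", lambda = x$lambda,
                 validation_r2 = x$validation_r2, test_r2 = x$test_r2,
                 n_parameters = count_parameters(x))
}
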