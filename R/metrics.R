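#' Coefficient of determination
#'
#' \eqn{r^2 = 1 - SS_{res}/SS_{tot}}. On out-of-sample predictions this
#' can be negative (worse than predicting the mean).
#'
#' @param y observed values.
#' @param yhat predicted values.
#' @return Dimensionless scalar.
#' @export
r2_score <- function(y, yhat) {
  stopifnot(is.numeric(y), is.numeric(yhat), length(y) == length(yhat))
  if (length(y) < 2) stop("need at least 2 observations")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("r2 undefined: target has zero variance")
  1 - sum((y - yhat)^2) / ss_tot
}

#' Mean absolute percentage error
#'
#' `mean(|y - yhat| / y)`, returned as a fraction (0.052 corresponds to
#' 5.2%); rendering as a percentage is left to the reporting layer.
#'
#' @inheritParams r2_score
#' @return Dimensionless fraction.
#' @export
mape <- function(y, yhat) {
  stopifnot(is.numeric(y), is.numeric(yhat), length(y) == length(yhat))
  if (length(y) < 1) stop("need at least 1 observation")
  if (any(y == 0)) stop("MAPE undefined: y contains zero")
  mean(abs(y - yhat) / abs(y))
}

#' Maximal absolute residual error
#'
#' @inheritParams r2_score
#' @return `max(|y - yhat|)`, in the units of `y`.
#' @export
max_residual_error <- function(y, yhat) {
  stopifnot(is.numeric(y), is.numeric(yhat), length(y) == length(yhat))
  if (length(y) < 1) stop("need at least 1 observation")
  max(abs(y - yhat))
}
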