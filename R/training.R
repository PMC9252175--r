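#' Fit a linear FFM model by ordinary least squares
#'
#' Fits `target ~ features` by least squares and wraps the estimate in
#' an [ffm_model()] container so that it can be evaluated and
#' serialised exactly like the published equations.
#'
#' @param features data.frame of predictor columns (all numeric).
#' @param target numeric vector of reference FFM values, kg.
#' @param feature_names optional subset/order of columns to use
#'   (default: all columns of `features` in order).
#' @param name name for the fitted model.
#' @param condition optional `(frequency, position)` label, e.g.
#'   `list(frequency = 50, position = "c")`.
#' @return An object of class `ffm_fit` with elements `model`
#'   (the fitted `ffm_model`), `fit` (the underlying [stats::lm] fit,
#'   kept for inference: `summary`, `confint`), `n_fit`, `condition`.
#' @export
fit_ols <- function(features, target, feature_names = NULL,
                    name = "ols_fit", condition = NULL) {
  stopifnot(is.data.frame(features), is.numeric(target),
            nrow(features) == length(target))
  if (is.null(feature_names)) feature_names <- names(features)
  missing <- setdiff(feature_names, names(features))
  if (length(missing))
    stop("features table lacks column(s): ", paste(missing, collapse = ", "))
  x <- features[feature_names]
  p <- length(feature_names)
  if (nrow(x) < p + 1)
    stop("need at least ", p + 1, " observations to fit ", p,
         " coefficients plus intercept")
  dat <- cbind(x, .ffm_target = target)
  fit <- stats::lm(stats::reformulate(feature_names, response = ".ffm_target"),
                   data = dat)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear feature(s): ",
         paste(bad, collapse = ", "))
  }
  cf <- stats::coef(fit)
  model <- ffm_model(name, features = feature_names,
                     units = rep("", p),
                     coefficients = unname(cf[feature_names]),
                     intercept = unname(cf["(Intercept)"]))
  structure(list(model = model, fit = fit, n_fit = nrow(x),
                 condition = condition),
            class = "ffm_fit")
}

#' @export
print.ffm_fit <- function(x, ...) {
  cat(sprintf("OLS FFM fit on n = %d subjects", x$n_fit))
  if (!is.null(x$condition))
    cat(sprintf(" at %g kHz, position %s", x$condition$frequency,
                x$condition$position))
  cat("\n")
  print(x$model)
  invisible(x)
}

#' @export
coef.ffm_fit <- function(object, ...) coef(object$model)

#' @export
predict.ffm_fit <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}

#' @export
summary.ffm_fit <- function(object, ...) summary(object$fit, ...)

#' Expected number of unique subjects in a size-n bootstrap resample
#'
#' Drawing n subjects with replacement from n, the expected count of
#' distinct subjects in the resample is \eqn{n(1 - (1 - 1/n)^n)}; the
#' remainder is the expected out-of-bag count. For n = 42 this gives
#' 26.73 in-bag / 15.27 out-of-bag.
#'
#' @param n cohort size.
#' @return Expected unique in-bag count.
#' @export
expected_inbag_unique <- function(n) {
  stopifnot(is.numeric(n), n >= 1)
  n * (1 - (1 - 1 / n)^n)
}

#' Monte-Carlo calibration of the bootstrap resampling scheme
#'
#' Draws `n_boot` size-n-with-replacement resamples and reports the
#' mean unique in-bag count and mean out-of-bag count, the two
#' data-free constants that identify the resampling scheme.
#'
#' @param n cohort size.
#' @param n_boot number of resamples.
#' @param seed RNG seed.
#' @return A list with `mean_inbag_unique`, `mean_oob`, `n`, `n_boot`.
#' @export
oob_calibration <- function(n, n_boot = 100000L, seed = 1L) {
  stopifnot(n >= 1, n_boot >= 1)
  set.seed(seed)
  uniq <- numeric(n_boot)
  chunk <- 10000L
  done <- 0L
  while (done < n_boot) {
    b <- min(chunk, n_boot - done)
    m <- matrix(sample.int(n, n * b, replace = TRUE), nrow = b)
    uniq[done + seq_len(b)] <-
      vapply(seq_len(b), function(i) length(unique(m[i, ])), integer(1))
    done <- done + b
  }
  list(mean_inbag_unique = mean(uniq), mean_oob = n - mean(uniq),
       n = n, n_boot = n_boot)
}

#' Bootstrap out-of-bag evaluation of a linear FFM model
#'
#' For each of `n_boot` replicates, a size-n resample of the cohort is
#' drawn with replacement, the linear model is fitted on the resample,
#' and r-squared, MAPE and maximal residual error are computed on the
#' out-of-bag subjects (those not drawn). Metrics are summarised as
#' mean and SD over replicates; the final reported coefficients are the
#' mean of the per-replicate coefficient vectors. Replicates with an
#' empty out-of-bag set or a rank-deficient in-bag design are redrawn
#' (and counted), keeping the number of evaluated replicates exact.
#'
#' @param features data.frame of predictor columns.
#' @param target reference FFM, kg.
#' @param feature_names optional subset/order of feature columns.
#' @param n_boot number of bootstrap replicates.
#' @param seed RNG seed.
#' @param model_kind label, e.g. `"SC"` or `"TTC"`.
#' @param condition optional `(frequency, position)` label.
#' @return An object of class `ffm_boot`: the per-metric mean/SD
#'   summary, the mean-coefficient `ffm_model`, resampling diagnostics
#'   (`mean_inbag_unique`, `mean_oob`, `n_redrawn`).
#' @export
bootstrap_oob <- function(features, target, feature_names = NULL,
                          n_boot = 10000L, seed = 1L,
                          model_kind = "custom", condition = NULL) {
  stopifnot(is.data.frame(features), is.numeric(target),
            nrow(features) == length(target), n_boot >= 1)
  if (is.null(feature_names)) feature_names <- names(features)
  x <- as.matrix(features[feature_names])
  storage.mode(x) <- "double"
  n <- nrow(x)
  p <- ncol(x)
  if (n < p + 2)
    stop("cohort too small for out-of-bag evaluation: need n >= ", p + 2)
  xx <- cbind(`(Intercept)` = 1, x)
  set.seed(seed)
  r2 <- ma <- mx <- numeric(n_boot)
  uniq <- integer(n_boot)
  cf <- matrix(0, n_boot, p + 1)
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      inbag <- unique(idx)
      if (length(inbag) == n) { n_redrawn <- n_redrawn + 1L; next }
      f <- stats::.lm.fit(xx[idx, , drop = FALSE], target[idx])
      if (f$rank < p + 1) { n_redrawn <- n_redrawn + 1L; next }
      break
    }
    oob <- setdiff(seq_len(n), inbag)
    beta <- f$coefficients
    yhat <- drop(xx[oob, , drop = FALSE] %*% beta)
    yo <- target[oob]
    cf[b, ] <- beta
    uniq[b] <- length(inbag)
    r2[b] <- if (length(oob) >= 2 && stats::var(yo) > 0)
      1 - sum((yo - yhat)^2) / sum((yo - mean(yo))^2) else NA_real_
    ma[b] <- mean(abs(yo - yhat) / abs(yo))
    mx[b] <- max(abs(yo - yhat))
  }
  mean_cf <- colMeans(cf)
  model <- ffm_model(paste0(model_kind, "_boot_mean"),
                     features = feature_names, units = rep("", p),
                     coefficients = mean_cf[-1], intercept = mean_cf[1])
  structure(list(model_kind = model_kind, condition = condition,
                 r2_mean = mean(r2, na.rm = TRUE),
                 r2_std = stats::sd(r2, na.rm = TRUE),
                 mape_mean = mean(ma), mape_std = stats::sd(ma),
                 maxerr_mean = mean(mx), maxerr_std = stats::sd(mx),
                 n_boot = n_boot, n = n,
                 mean_inbag_unique = mean(uniq), mean_oob = n - mean(uniq),
                 n_redrawn = n_redrawn, model = model),
            class = "ffm_boot")
}

#' @export
print.ffm_boot <- function(x, ...) {
  cat(sprintf("Bootstrap out-of-bag evaluation (%s", x$model_kind))
  if (!is.null(x$condition))
    cat(sprintf(", %g kHz, position %s", x$condition$frequency,
                x$condition$position))
  cat(sprintf("): %d replicates on n = %d\n", x$n_boot, x$n))
  cat(sprintf("  r^2      %.3f +/- %.3f\n", x$r2_mean, x$r2_std))
  cat(sprintf("  MAPE     %.3f +/- %.3f\n", x$mape_mean, x$mape_std))
  cat(sprintf("  max.err  %.3f +/- %.3f kg\n", x$maxerr_mean, x$maxerr_std))
  cat(sprintf("  mean in-bag unique %.2f, mean OOB %.2f, redrawn %d\n",
              x$mean_inbag_unique, x$mean_oob, x$n_redrawn))
  invisible(x)
}

#' @export
coef.ffm_boot <- function(object, ...) coef(object$model)

#' Bootstrap evaluation across the frequency-by-position grid
#'
#' Runs [bootstrap_oob()] for each requested model kind and measurement
#' condition (frequency in kHz, lower-electrode position a/b/c) and
#' tabulates the metric summaries; identifies the best condition per
#' model by lowest mean MAPE.
#'
#' @param cohort a cohort data.frame in the wide CSV layout (see
#'   [read_cohort()]), with a reference FFM column.
#' @param model_kinds subset of `c("SC", "TTC")`.
#' @param frequencies subset of `c(10, 50, 100)` kHz.
#' @param positions subset of `c("a", "b", "c")`.
#' @param n_boot bootstrap replicates per cell.
#' @param seed master seed; each cell derives its own stream from it,
#'   so results per cell do not depend on sweep order.
#' @return A data.frame of class `condition_sweep`, one row per
#'   (model, frequency, position) with columns `model`,
#'   `frequency_khz`, `position`, `r2_mean`, `r2_std`, `mape_mean`,
#'   `mape_std`, `maxerr_mean`, `maxerr_std`. The per-cell `ffm_boot`
#'   objects are in `attr(, "cells")`.
#' @export
condition_sweep <- function(cohort, model_kinds = c("SC", "TTC"),
                            frequencies = c(10, 50, 100),
                            positions = c("a", "b", "c"),
                            n_boot = 10000L, seed = 1L) {
  model_kinds <- match.arg(model_kinds, several.ok = TRUE)
  stopifnot(all(frequencies %in% c(10, 50, 100)),
            all(positions %in% c("a", "b", "c")))
  grid <- expand.grid(position = positions, frequency = frequencies,
                      model = model_kinds, stringsAsFactors = FALSE)
  cells <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fr <- grid$frequency[i]; po <- grid$position[i]; mk <- grid$model[i]
    feats <- derive_features(cohort, frequency = fr, position = po)
    fn <- ffm_feature_names(mk)
    # per-cell seed fixed by (model, condition), not by loop order
    cell_seed <- seed + 1000L * match(fr, c(10, 50, 100)) +
      100L * match(po, c("a", "b", "c")) + 10L * match(mk, c("SC", "TTC"))
    bs <- bootstrap_oob(feats, feats$ffm_ref, feature_names = fn,
                        n_boot = n_boot, seed = cell_seed,
                        model_kind = mk,
                        condition = list(frequency = fr, position = po))
    cells[[i]] <- bs
    rows[[i]] <- data.frame(model = mk, frequency_khz = fr, position = po,
                            r2_mean = bs$r2_mean, r2_std = bs$r2_std,
                            mape_mean = bs$mape_mean, mape_std = bs$mape_std,
                            maxerr_mean = bs$maxerr_mean,
                            maxerr_std = bs$maxerr_std,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("condition_sweep", "data.frame")
  attr(out, "cells") <- cells
  out
}

#' Best measurement condition per model
#'
#' @param sweep a [condition_sweep()] result.
#' @param metric metric to rank by: lowest `mape_mean` (default),
#'   lowest `maxerr_mean`, or highest `r2_mean`.
#' @return A data.frame with one row per model: its best condition.
#' @export
best_condition <- function(sweep, metric = c("mape_mean", "maxerr_mean",
                                             "r2_mean")) {
  metric <- match.arg(metric)
  stopifnot(inherits(sweep, "condition_sweep") || is.data.frame(sweep))
  pick <- function(d) {
    v <- d[[metric]]
    d[if (metric == "r2_mean") which.max(v) else which.min(v), , drop = FALSE]
  }
  out <- do.call(rbind, lapply(split(sweep, sweep$model), pick))
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' @export
print.condition_sweep <- function(x, digits = 3, ...) {
  cat(sprintf("Bootstrap OOB metrics over %d (model, condition) cells\n",
              nrow(x)))
  print.data.frame(x, digits = digits, row.names = FALSE)
  bc <- best_condition(x)
  for (i in seq_len(nrow(bc)))
    cat(sprintf("best by MAPE for %s: %g kHz, position %s (MAPE %.3f)\n",
                bc$model[i], bc$frequency_khz[i], bc$position[i],
                bc$mape_mean[i]))
  invisible(x)
}

# canonical feature sets of the two model families
ffm_feature_names <- function(model_kind) {
  switch(model_kind,
         SC = c("sex", "age", "tbm", "bi"),
         TTC = c("arm_volume", "bmi", "tbm", "bi"),
         stop("unknown model kind: ", model_kind))
}
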