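#' Bland-Altman agreement between two measurement series
#'
#' Computes the paired differences `d = x - y` (convention:
#' method-minus-reference), their mean (bias), the limits of agreement
#' `bias +/- z * sd(d)` (sample SD, n-1 denominator), and
#' normal-theory confidence intervals: `SE(bias) = sd/sqrt(n)` and
#' `SE(LOA) = sd * sqrt(3/n)`.
#'
#' @param x numeric series (e.g. model FFM estimates, kg).
#' @param y numeric series of equal length (e.g. reference FFM, kg).
#' @param z normal quantile for the limits of agreement (default 1.96,
#'   i.e. 95% limits).
#' @param conf_z normal quantile for the confidence intervals
#'   (default `z`).
#' @return An object of class `bland_altman` with elements `mean_bias`,
#'   `sd_diff`, `loa_lower`, `loa_upper`, `ci_bias`, `ci_loa_lower`,
#'   `ci_loa_upper`, `n`, plus the per-subject `means` and `diffs`
#'   used for plotting.
#' @export
bland_altman <- function(x, y, z = 1.96, conf_z = z) {
  stopifnot(is.numeric(x), is.numeric(y), is.numeric(z), z > 0)
  if (length(x) != length(y)) stop("series must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  half <- z * s
  se_bias <- s / sqrt(n)
  se_loa <- s * sqrt(3 / n)
  structure(list(mean_bias = bias, sd_diff = s,
                 loa_lower = bias - half, loa_upper = bias + half,
                 ci_bias = c(bias - conf_z * se_bias,
                             bias + conf_z * se_bias),
                 ci_loa_lower = c(bias - half - conf_z * se_loa,
                                  bias - half + conf_z * se_loa),
                 ci_loa_upper = c(bias + half - conf_z * se_loa,
                                  bias + half + conf_z * se_loa),
                 n = n, z = z,
                 means = (x + y) / 2, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, digits = 3, ...) {
  f <- function(v) format(round(v, digits), nsmall = digits)
  cat(sprintf("Bland-Altman agreement (n = %d)\n", x$n))
  cat(sprintf("  bias  %s  [%s, %s]\n", f(x$mean_bias),
              f(x$ci_bias[1]), f(x$ci_bias[2])))
  cat(sprintf("  LOA   (%s, %s)  (bias +/- %.2f x SD, SD = %s)\n",
              f(x$loa_lower), f(x$loa_upper), x$z, f(x$sd_diff)))
  cat(sprintf("  lower LOA CI [%s, %s], upper LOA CI [%s, %s]\n",
              f(x$ci_loa_lower[1]), f(x$ci_loa_lower[2]),
              f(x$ci_loa_upper[1]), f(x$ci_loa_upper[2])))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, xlab = "Mean of methods (kg)",
                              ylab = "Difference (kg)", ...) {
  graphics::plot(x$means, x$diffs, xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = x$mean_bias, lty = 1)
  graphics::abline(h = c(x$loa_lower, x$loa_upper), lty = 2)
  invisible(x)
}

#' Bland-Altman agreement report for several estimators
#'
#' Runs [bland_altman()] for each named estimate series against a
#' common reference and tabulates bias, limits of agreement and their
#' confidence intervals, one row per estimator (row order follows the
#' input order).
#'
#' @param estimates named list of numeric series, all aligned to the
#'   same subjects as `reference`.
#' @param reference numeric reference series (e.g. DEXA FFM, kg).
#' @param z normal quantile for the limits of agreement.
#' @return A data.frame with columns `model`, `n`, `bias`,
#'   `loa_lower`, `loa_upper`, `ci_bias_lo`, `ci_bias_hi`,
#'   `ci_loa_lower_lo`, `ci_loa_lower_hi`, `ci_loa_upper_lo`,
#'   `ci_loa_upper_hi`, `sd_diff`. The underlying `bland_altman`
#'   objects (with per-subject plot data) are in `attr(, "results")`.
#' @export
agreement_report <- function(estimates, reference, z = 1.96) {
  stopifnot(is.list(estimates), length(estimates) >= 1, is.numeric(reference))
  if (is.null(names(estimates)) || any(names(estimates) == ""))
    stop("estimates must be a fully named list")
  bad <- names(estimates)[vapply(estimates, length, 1L) != length(reference)]
  if (length(bad))
    stop("series not aligned to reference: ", paste(bad, collapse = ", "))
  res <- lapply(estimates, bland_altman, y = reference, z = z)
  out <- do.call(rbind, lapply(names(res), function(nm) {
    r <- res[[nm]]
    data.frame(model = nm, n = r$n, bias = r$mean_bias,
               loa_lower = r$loa_lower, loa_upper = r$loa_upper,
               ci_bias_lo = r$ci_bias[1], ci_bias_hi = r$ci_bias[2],
               ci_loa_lower_lo = r$ci_loa_lower[1],
               ci_loa_lower_hi = r$ci_loa_lower[2],
               ci_loa_upper_lo = r$ci_loa_upper[1],
               ci_loa_upper_hi = r$ci_loa_upper[2],
               sd_diff = r$sd_diff, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "results") <- res
  out
}
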