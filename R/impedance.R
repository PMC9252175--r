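#' Resistance of a circular frustum conductor
#'
#' DC resistance of a homogeneous conductor shaped as a circular
#' frustum with linearly varying radius, in circumference terms:
#' \deqn{R = \frac{4\pi \rho h}{C_1 C_2},}
#' the integral of thin-slab resistances \eqn{\rho\,dz / (\pi r(z)^2)}
#' along the height. Reduces to \eqn{\rho h / (\pi r^2)} for a cylinder.
#' Used as the ground-truth physics of the hand-to-hand measurement in
#' the synthetic cohort generator.
#'
#' @param c_base,c_top end-circle circumferences, cm.
#' @param h conductor length, cm.
#' @param resistivity specific resistivity, Ohm cm.
#' @return Resistance in Ohm. Vectorised.
#' @export
frustum_resistance <- function(c_base, c_top, h, resistivity) {
  stopifnot(is.numeric(c_base), is.numeric(c_top), is.numeric(h),
            is.numeric(resistivity))
  if (any(c_base <= 0) || any(c_top <= 0))
    stop("end circumferences must be strictly positive")
  if (any(h < 0) || any(resistivity <= 0))
    stop("length must be non-negative and resistivity strictly positive")
  4 * pi * resistivity * h / (c_base * c_top)
}

#' Series hand-to-hand resistance of a chain of segment conductors
#'
#' The hand-to-hand current path is modelled as arm segments in series;
#' the torso contribution is neglected by default because its large
#' cross-sectional area makes its resistance small relative to the arms.
#'
#' @param segments a list of segments, each a list with elements
#'   `c_base`, `c_top`, `length`, `resistivity` (an `arm_geometry` plus
#'   `resistivity` also works when named accordingly).
#' @param torso_resistance additional series resistance in Ohm
#'   (default 0, the torso-neglect assumption).
#' @return Total resistance in Ohm.
#' @export
hand_to_hand_resistance <- function(segments, torso_resistance = 0) {
  if (!is.list(segments) || length(segments) == 0)
    stop("segments must be a non-empty list")
  stopifnot(is.numeric(torso_resistance), torso_resistance >= 0)
  r <- vapply(segments, function(s) {
    frustum_resistance(s$c_base, s$c_top, s$length, s$resistivity)
  }, numeric(1))
  sum(r) + torso_resistance
}

#' Arm-volume impedance proxy
#'
#' The quantity `total arm volume x TBM/FFM`, which tracks the measured
#' hand-to-hand resistance across subjects: arm volume sets the
#' conductor geometry while the TBM/FFM ratio absorbs the dependence of
#' effective resistivity on body composition (fat conducts poorly, so
#' fatter subjects at a given geometry present higher resistance).
#'
#' @param total_arm_volume total arm volume, cm^3.
#' @param tbm total body mass, kg.
#' @param ffm fat-free mass, kg.
#' @return Proxy value in cm^3.
#' @export
impedance_proxy <- function(total_arm_volume, tbm, ffm) {
  stopifnot(is.numeric(total_arm_volume), is.numeric(tbm), is.numeric(ffm))
  if (any(total_arm_volume <= 0) || any(tbm <= 0) || any(ffm <= 0))
    stop("all inputs must be strictly positive")
  if (any(ffm >= tbm))
    stop("ffm must be strictly less than tbm")
  total_arm_volume * tbm / ffm
}

#' Fit the resistance-on-proxy approximation line
#'
#' Ordinary least-squares regression of measured resistance on the
#' arm-volume proxy, quantifying how well limb geometry scaled by body
#' composition explains hand-to-hand resistance.
#'
#' @param proxy numeric vector of proxy values (cm^3).
#' @param resistance numeric vector of measured resistances (Ohm).
#' @return An object of class `proxy_fit` with elements `slope`,
#'   `intercept`, `r_squared`, `n`.
#' @export
fit_proxy <- function(proxy, resistance) {
  stopifnot(is.numeric(proxy), is.numeric(resistance),
            length(proxy) == length(resistance))
  if (length(proxy) < 3)
    stop("need at least 3 (proxy, resistance) pairs")
  if (stats::var(proxy) == 0)
    stop("degenerate design: proxy values are all equal")
  fit <- stats::lm(resistance ~ proxy)
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((resistance - mean(resistance))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, n = length(proxy)),
            class = "proxy_fit")
}

#' @export
print.proxy_fit <- function(x, ...) {
  cat("Resistance ~ arm-volume proxy (OLS)\n")
  cat(sprintf("  n = %d, slope = %.4g Ohm/cm^3, intercept = %.4g Ohm\n",
              x$n, x$slope, x$intercept))
  cat(sprintf("  r^2 = %.3f\n", x$r_squared))
  invisible(x)
}
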