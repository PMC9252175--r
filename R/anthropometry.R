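#' Arm geometry: a single arm as a circular frustum
#'
#' Describes one arm as a truncated cone (frustum): the shoulder
#' circumference is the circumference of the base circle, the wrist
#' circumference that of the top circle, and the arm length is the
#' frustum height.
#'
#' @param shoulder_circ shoulder circumference in cm (base circle).
#' @param wrist_circ wrist circumference in cm (top circle).
#' @param arm_length arm length in cm (frustum height).
#' @return An object of class `arm_geometry`.
#' @examples
#' arm_geometry(36, 16, 55)
#' @export
arm_geometry <- function(shoulder_circ, wrist_circ, arm_length) {
  stopifnot(is.numeric(shoulder_circ), is.numeric(wrist_circ),
            is.numeric(arm_length))
  if (any(shoulder_circ <= 0) || any(wrist_circ <= 0) || any(arm_length <= 0))
    stop("arm geometry measurements must be strictly positive")
  if (any(shoulder_circ < wrist_circ))
    stop("shoulder circumference must be >= wrist circumference")
  structure(list(shoulder_circ = shoulder_circ, wrist_circ = wrist_circ,
                 arm_length = arm_length),
            class = "arm_geometry")
}

#' @export
print.arm_geometry <- function(x, ...) {
  cat(sprintf("Arm frustum: shoulder %.1f cm, wrist %.1f cm, length %.1f cm\n",
              x$shoulder_circ, x$wrist_circ, x$arm_length))
  cat(sprintf("  volume %.1f cm^3\n",
              frustum_volume(x$shoulder_circ, x$wrist_circ, x$arm_length)))
  invisible(x)
}

#' Volume of a circular frustum from its end circumferences
#'
#' Volume of a truncated cone whose radius varies linearly along its
#' height, parameterised by the circumferences of the two end circles
#' (the quantities actually measured with a tape):
#' \deqn{V = \frac{h (C_1^2 + C_1 C_2 + C_2^2)}{12\pi}.}
#' The formula is symmetric in the two circumferences and reduces to the
#' cylinder volume \eqn{\pi r^2 h} when they are equal.
#'
#' @param c_base,c_top circumferences of the end circles, cm.
#' @param h frustum height, cm.
#' @return Volume in cm^3. Vectorised over all arguments.
#' @examples
#' frustum_volume(10 * pi, 10 * pi, 10) # cylinder, pi * 5^2 * 10
#' @export
frustum_volume <- function(c_base, c_top, h) {
  stopifnot(is.numeric(c_base), is.numeric(c_top), is.numeric(h))
  if (any(c_base < 0) || any(c_top < 0) || any(h < 0))
    stop("frustum dimensions must be non-negative")
  h * (c_base^2 + c_base * c_top + c_top^2) / (12 * pi)
}

#' Total arm volume of a subject
#'
#' Sum of the left and right arm frustum volumes.
#'
#' @param left,right `arm_geometry` objects.
#' @return Total volume in cm^3.
#' @export
total_arm_volume <- function(left, right) {
  stopifnot(inherits(left, "arm_geometry"), inherits(right, "arm_geometry"))
  frustum_volume(left$shoulder_circ, left$wrist_circ, left$arm_length) +
    frustum_volume(right$shoulder_circ, right$wrist_circ, right$arm_length)
}

#' Body mass index
#'
#' @param tbm total body mass, kg.
#' @param height height, cm.
#' @return BMI in kg/m^2.
#' @export
compute_bmi <- function(tbm, height) {
  stopifnot(is.numeric(tbm), is.numeric(height))
  if (any(tbm <= 0) || any(height <= 0))
    stop("tbm and height must be strictly positive")
  tbm / (height / 100)^2
}

#' Bioimpedance index (height squared over resistance)
#'
#' The classic single-cylinder BIA predictor \eqn{BI = height^2 / R},
#' where R is the real part (resistance) of the measured hand-to-hand
#' impedance. Under the cylinder-conductor approximation BI is
#' proportional to conductive body volume.
#'
#' @param height height, cm.
#' @param r resistance, Ohm.
#' @return BI in cm^2/Ohm.
#' @export
bioimpedance_index <- function(height, r) {
  stopifnot(is.numeric(height), is.numeric(r))
  if (any(height <= 0))
    stop("height must be strictly positive")
  if (any(r <= 0))
    stop("resistance must be strictly positive (open-circuit or invalid reading?)")
  height^2 / r
}
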