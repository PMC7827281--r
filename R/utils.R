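# internal numeric helpers

DEG <- 180 / pi

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * DEG

# Round half away from zero at `digits` decimals (base round() rounds half to
# even, which would not reproduce the fixed 5-decimal convention of the
# measurement records).
round_away <- function(x, digits = 5) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Round to the 5-decimal measurement precision
#'
#' Measured angles and goal coordinates are recorded with a precision of five
#' decimal places, rounding halves away from zero.
#'
#' @param x A numeric vector.
#' @return `x` rounded to 5 decimals.
#' @export
#' @examples
#' round5(95.000005)
round5 <- function(x) round_away(x, 5)

# Angle in degrees between the rows of two n x 3 matrices.
# atan2(||u x v||, u.v) is numerically stable near 0 and 180 degrees,
# where acos of a clamped dot product loses precision.
angle_between_rows <- function(u, v) {
  dot <- rowSums(u * v)
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  as.numeric(rad2deg(atan2(sqrt(cx^2 + cy^2 + cz^2), dot)))
}

row_norms <- function(m) as.numeric(sqrt(rowSums(m^2)))

`%||%` <- function(a, b) if (is.null(a)) b else a
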