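#' Wrap orientations into the half-open interval [0, 180)
#'
#' Grating orientation is 180-degree periodic; every orientation in the
#' package is stored on \code{[0, 180)}.
#'
#' @param theta Numeric vector of orientations in degrees (any real values).
#' @return Numeric vector of the same length with values in \code{[0, 180)}.
#' @examples
#' wrapOrientation(c(-10, 0, 185, 360))
#' @export
wrapOrientation <- function(theta) {
  theta %% 180
}

#' Signed relative orientation between two orientations
#'
#' Computes \code{a - b} on the 180-degree circle, wrapped into the half-open
#' interval \code{(-90, 90]}. Positive values are counterclockwise, negative
#' values clockwise; the boundary case of exactly 90 degrees maps to +90.
#'
#' @param a,b Numeric vectors of orientations in degrees (recycled).
#' @return Numeric vector of signed differences in \code{(-90, 90]} degrees.
#'   \code{NA} where either input is missing.
#' @examples
#' relativeOrientation(10, 170)  # 20
#' relativeOrientation(0, 90)    # +90 (boundary convention)
#' @export
relativeOrientation <- function(a, b) {
  d <- (a - b) %% 180
  ifelse(d > 90, d - 180, d)
}
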