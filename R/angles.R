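#' Circular angle utilities
#'
#' All internal model computations are carried out in radians on the response
#' circle; file I/O and reported summaries use degrees-on-the-circle. These
#' helpers centralise wrapping and unit conversion so that angular arithmetic
#' is always performed on the circle.
#'
#' `wrap_angle()` maps any angle to the half-open interval (-pi, pi];
#' `wrap_deg()` is the degree analogue with range (-180, 180].
#' `circ_dist()` returns the signed circular difference `a - b`, wrapped.
#'
#' @param theta numeric vector of angles in radians.
#' @param deg numeric vector of angles in degrees.
#' @param rad numeric vector of angles in radians.
#' @param a,b numeric vectors of angles in radians.
#' @return numeric vector of the same length as the input.
#' @examples
#' wrap_angle(3 * pi)        # pi
#' circ_dist(pi - 0.1, -pi + 0.1)  # -0.2, the short way round
#' @name angles
NULL

#' @rdname angles
#' @export
wrap_angle <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  w[w <= -pi] <- pi  # range is (-pi, pi]
  w
}

#' @rdname angles
#' @export
wrap_deg <- function(deg) {
  w <- (deg + 180) %% 360 - 180
  w[w <= -180] <- 180
  w
}

#' @rdname angles
#' @export
deg2rad <- function(deg) deg * pi / 180

#' @rdname angles
#' @export
rad2deg <- function(rad) rad * 180 / pi

#' @rdname angles
#' @export
circ_dist <- function(a, b) wrap_angle(a - b)
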