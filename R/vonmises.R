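# von Mises density and sampler. The observer model parameterises the von
# Mises by "precision" P, used directly as the concentration kappa: at the
# concentrations typical of localization data the von Mises is numerically
# indistinguishable from a Gaussian with variance 1/P.

# log I0(kappa), stable for large kappa via the exponentially scaled Bessel
.log_bessel_i0 <- function(kappa) {
  log(besselI(kappa, nu = 0, expon.scaled = TRUE)) + kappa
}

#' von Mises density and random generation
#'
#' Density and sampler for the von Mises (circular normal) distribution with
#' mean direction `mu` and concentration `kappa`, on the support (-pi, pi].
#' `kappa = 0` gives the uniform distribution on the circle. Sampling uses the
#' Best-Fisher (1979) wrapped-Cauchy rejection algorithm, valid for all
#' `kappa`.
#'
#' @param x numeric vector of angles (radians).
#' @param n number of draws.
#' @param mu mean direction (radians); recycled.
#' @param kappa concentration (>= 0); recycled. In this package the observer's
#'   precision (rad^-2) is used directly as `kappa`.
#' @param log logical; return log-density?
#' @return `dvonmises` a numeric vector of (log-)densities; `rvonmises` a
#'   numeric vector of `n` angles in (-pi, pi].
#' @examples
#' integrate(dvonmises, -pi, pi, kappa = 5)  # 1
#' @export
dvonmises <- function(x, mu = 0, kappa = 1, log = FALSE) {
  if (any(!is.finite(x)) || any(!is.finite(mu)) || any(!is.finite(kappa)))
    stop("non-finite arguments to dvonmises()")
  if (any(kappa < 0)) stop("kappa must be >= 0")
  ld <- kappa * cos(x - mu) - log(2 * pi) - .log_bessel_i0(kappa)
  if (log) ld else exp(ld)
}

#' @rdname dvonmises
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (any(!is.finite(mu)) || any(!is.finite(kappa)) || any(kappa < 0))
    stop("invalid mu/kappa in rvonmises()")
  mu <- rep_len(mu, n)
  kappa <- rep_len(kappa, n)
  out <- numeric(n)
  unif <- kappa < 1e-10
  out[unif] <- stats::runif(sum(unif), -pi, pi)
  idx <- which(!unif)
  if (length(idx)) {
    k <- kappa[idx]
    a <- 1 + sqrt(1 + 4 * k^2)
    b <- (a - sqrt(2 * a)) / (2 * k)
    r <- (1 + b^2) / (2 * b)
    th <- numeric(length(idx))
    todo <- seq_along(idx)
    while (length(todo)) {
      m <- length(todo)
      u1 <- stats::runif(m)
      u2 <- stats::runif(m)
      u3 <- stats::runif(m)
      z <- cos(pi * u1)
      f <- (1 + r[todo] * z) / (r[todo] + z)
      cc <- k[todo] * (r[todo] - f)
      ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
      acc <- todo[ok]
      th[acc] <- sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
      todo <- todo[!ok]
    }
    out[idx] <- th
  }
  wrap_angle(out + mu)
}
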