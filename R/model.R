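#' Allocentric precision as a function of landmark distance
#'
#' The precision of the landmark-relative (allocentric) location estimate
#' declines exponentially with the circular distance `d` between the target
#' and the landmark:
#' \deqn{P_{allo}(d) = A_{max} \, e^{-A_{scale} \cdot d}.}
#' The egocentric precision, by contrast, does not depend on `d`.
#'
#' @param d non-negative circular distance (radians); vectorised.
#' @param a_max peak precision at `d = 0` (rad^-2), `>= 0`.
#' @param a_scale decay rate (rad^-1), `>= 0`.
#' @return precision (rad^-2), same length as `d`. `a_max = 0` returns 0
#'   everywhere (landmark absent / reduced model).
#' @examples
#' allocentric_precision(log(2) / 8, a_max = 180, a_scale = 8)  # 90, half-life
#' @export
allocentric_precision <- function(d, a_max, a_scale) {
  if (any(!is.finite(d)) || any(d < 0)) stop("d must be finite and >= 0")
  if (!is.finite(a_max) || a_max < 0) stop("a_max must be >= 0")
  if (!is.finite(a_scale) || a_scale < 0) stop("a_scale must be >= 0")
  a_max * exp(-a_scale * d)
}

#' Cue estimates and precision-weighted integration
#'
#' `cue_estimate()` packages a single cue's mean direction and precision;
#' precision 0 encodes an uninformative cue. `integrate_cues()` combines an
#' egocentric and an allocentric estimate by precision weighting:
#' \deqn{\mu = \frac{P_1 \mu_1 + P_2 \mu_2}{P_1 + P_2}, \qquad P = P_1 + P_2.}
#' The weighted mean is computed on the circle's local chart: the second mean
#' is expressed as a signed deviation from the first before averaging, and the
#' result re-wrapped, so cues near the +/-pi seam integrate correctly.
#'
#' @param mu mean direction (radians).
#' @param precision cue precision (rad^-2), `>= 0`.
#' @param ego,allo `cue_estimate` objects.
#' @return a `cue_estimate` (list with `mu`, `precision`).
#' @examples
#' ego <- cue_estimate(0, 30)
#' allo <- cue_estimate(0.1047, 90)
#' integrate_cues(ego, allo)  # mu ~ 0.0785, precision 120
#' @export
cue_estimate <- function(mu, precision) {
  if (!is.finite(mu) || !is.finite(precision) || precision < 0)
    stop("cue_estimate needs a finite mean and precision >= 0")
  structure(list(mu = wrap_angle(mu), precision = precision),
            class = "cue_estimate")
}

#' @rdname cue_estimate
#' @export
integrate_cues <- function(ego, allo) {
  stopifnot(inherits(ego, "cue_estimate"), inherits(allo, "cue_estimate"))
  ptot <- ego$precision + allo$precision
  if (ptot <= 0) stop("degenerate cues: both precisions are zero")
  delta <- circ_dist(allo$mu, ego$mu)
  cue_estimate(wrap_angle(ego$mu + allo$precision * delta / ptot), ptot)
}

#' Mean of the allocentric estimate under a landmark shift
#'
#' The allocentric estimate is anchored to the landmark, so when the landmark
#' reappears displaced by `shift` the allocentric mean follows it:
#' `mu_allo = wrap(target + shift)`. In all other conditions `shift = 0` and
#' the allocentric mean equals the true target location.
#'
#' @param target true target angle (radians); vectorised.
#' @param shift signed landmark displacement (radians).
#' @return wrapped angle(s).
#' @export
allo_mean <- function(target, shift = 0) wrap_angle(target + shift)

# Integrated-estimate geometry for one trial: allocentric weight, response
# mean offset from the target, and total precision.
.integration_weights <- function(p_ego, p_allo) {
  ptot <- p_ego + p_allo
  w <- ifelse(ptot > 0, p_allo / ptot, 0)
  list(w = w, p_mle = ptot)
}

#' Log-density of an observer response
#'
#' The response distribution is a lapse-contaminated von Mises centred on the
#' integrated estimate:
#' \deqn{p(\hat x) = (1 - \lambda)\,\phi(\hat x;\, \mu_{MLE}, P_{MLE}) +
#'   \lambda \frac{1}{2\pi},}
#' where \eqn{\mu_{MLE}} is the precision-weighted combination of the
#' egocentric mean (the true target) and the allocentric mean (the target plus
#' any landmark shift), \eqn{P_{MLE}} is the summed precision, and
#' \eqn{\lambda} is the lapse probability.
#'
#' @param resp response angle(s), radians.
#' @param target true target angle(s), radians.
#' @param params an [model_params()] object.
#' @param d target-landmark circular distance(s), radians; `NA` (or
#'   `allo_active = FALSE`) disables the allocentric component.
#' @param shift signed landmark displacement(s), radians.
#' @param allo_active logical; is the allocentric cue available on this trial?
#' @return log-density, vectorised over trials.
#' @export
response_logpdf <- function(resp, target, params, d = NA_real_, shift = 0,
                            allo_active = TRUE) {
  stopifnot(inherits(params, "observer_params"))
  n <- max(length(resp), length(target), length(d), length(shift),
           length(allo_active))
  resp <- rep_len(resp, n); target <- rep_len(target, n)
  d <- rep_len(d, n); shift <- rep_len(shift, n)
  allo_active <- rep_len(allo_active, n)
  if (any(!is.finite(resp)) || any(!is.finite(target)))
    stop("non-finite response or target angle")
  on <- allo_active & !is.na(d)
  p_allo <- numeric(n)
  if (any(on))
    p_allo[on] <- allocentric_precision(d[on], params$a_max, params$a_scale)
  iw <- .integration_weights(params$p_ego, p_allo)
  dev <- circ_dist(resp, wrap_angle(target + shift * iw$w))
  .lapse_mix_logpdf(dev, iw$p_mle, params$p_lapse)
}

# log of (1 - lapse) * vonmises(dev; 0, kappa) + lapse / (2*pi), stable
.lapse_mix_logpdf <- function(dev, kappa, p_lapse) {
  if (p_lapse >= 1) return(rep_len(-log(2 * pi), length(dev)))
  lv <- log1p(-p_lapse) + dvonmises(dev, 0, kappa, log = TRUE)
  if (p_lapse <= 0) return(lv)
  lu <- log(p_lapse) - log(2 * pi)
  hi <- pmax(lv, lu)
  hi + log1p(exp(pmin(lv, lu) - hi))
}

#' Predicted response bias under a landmark shift
#'
#' Closed-form consequence of precision weighting: the integrated estimate is
#' pulled toward the shifted landmark by the allocentric weight, so the
#' response distribution is centred at
#' \deqn{b(d) = s \cdot \frac{P_{allo}(d)}{P_{ego} + P_{allo}(d)}.}
#' Because both mixture components are symmetric about this centre, `b(d)` is
#' also the median signed deviation of responses from the target.
#'
#' @param d target-landmark distance(s), radians.
#' @param shift signed landmark displacement, radians.
#' @param params an [model_params()] object.
#' @return predicted signed deviation (radians), vectorised over `d`.
#' @export
predicted_bias <- function(d, shift, params) {
  stopifnot(inherits(params, "observer_params"))
  p_allo <- allocentric_precision(d, params$a_max, params$a_scale)
  shift * .integration_weights(params$p_ego, p_allo)$w
}

# median of |theta| where theta ~ (1-lapse) VM(0, kappa) + lapse * uniform
.fold_median <- function(kappa, p_lapse) {
  if (p_lapse >= 1) return(pi / 2)
  if (kappa < 1e-10) return(pi / 2)  # both components uniform
  # truncate the von Mises integral far beyond the bulk of its mass
  upper_bulk <- min(pi, max(0.5, 30 / sqrt(kappa)))
  vm_cdf_half <- function(m) {  # P(0 < VM < m)
    if (m <= 0) return(0)
    stats::integrate(function(t) dvonmises(t, 0, kappa),
                     0, min(m, upper_bulk),
                     rel.tol = 1e-10, abs.tol = 1e-13)$value
  }
  f <- function(m) (1 - p_lapse) * 2 * vm_cdf_half(m) + p_lapse * m / pi - 0.5
  stats::uniroot(f, interval = c(1e-12, pi), tol = 1e-11)$root
}

#' Predicted response variability (median absolute deviation)
#'
#' Median absolute deviation of the response around the target at
#' target-landmark distance `d`. When the landmark is shifted, the systematic
#' bias is subtracted before taking absolute deviations, so the statistic
#' isolates variability (matching how shifted-landmark variability curves are
#' plotted). Two methods are provided: deterministic quadrature on the mixture
#' distribution (default; root-finds the median of the folded density), and
#' Monte-Carlo forward simulation.
#'
#' @param d target-landmark distance(s), radians.
#' @param shift signed landmark displacement, radians (affects only whether a
#'   bias is present to subtract; the centred MAD itself is shift-invariant).
#' @param params an [model_params()] object.
#' @param method `"quadrature"` or `"mc"`.
#' @param n_mc Monte-Carlo sample size per distance.
#' @param seed optional integer seed for the Monte-Carlo method.
#' @return MAD in radians, vectorised over `d`.
#' @export
predicted_mad <- function(d, shift = 0, params, method = c("quadrature", "mc"),
                          n_mc = 1e5, seed = NULL) {
  stopifnot(inherits(params, "observer_params"))
  method <- match.arg(method)
  p_allo <- allocentric_precision(d, params$a_max, params$a_scale)
  kappa <- params$p_ego + p_allo
  if (method == "quadrature") {
    return(vapply(kappa, .fold_median, numeric(1), p_lapse = params$p_lapse))
  }
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_along(d), function(i) {
    b <- predicted_bias(d[i], shift, params)
    x <- .sample_mixture(n_mc, mu = b, kappa = kappa[i],
                         p_lapse = params$p_lapse)
    if (shift != 0) x <- wrap_angle(x - stats::median(x))
    stats::median(abs(x))
  }, numeric(1))
}

# forward-sample the lapse-contaminated von Mises
.sample_mixture <- function(n, mu, kappa, p_lapse) {
  lapse <- stats::runif(n) < p_lapse
  x <- rvonmises(n, mu = mu, kappa = kappa)
  if (any(lapse)) x[lapse] <- stats::runif(sum(lapse), -pi, pi)
  x
}
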