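#' Observer model parameters
#'
#' Bundle the generative parameters of the cue-integration observer:
#' \describe{
#'   \item{p_ego}{egocentric precision (rad^-2), independent of landmark
#'     distance; `>= 0`.}
#'   \item{a_max}{peak allocentric precision (rad^-2), attained when the target
#'     coincides with the landmark; `>= 0`. `a_max = 0` switches the
#'     allocentric cue off (landmark-absent / reduced model).}
#'   \item{a_scale}{exponential decay rate (rad^-1) of allocentric precision
#'     with target-landmark distance; `>= 0`.}
#'   \item{p_lapse}{probability of a lapse trial, on which the response is
#'     uniform on the circle; in `[0, 1]`. Swap errors are absorbed here and
#'     not modelled separately.}
#'   \item{cost}{proportional reduction of egocentric precision when a landmark
#'     is present (cost-model variant): effective landmark-trial precision is
#'     `p_ego * (1 - cost)`. With `cost = 0` the cost model coincides with the
#'     base model. Normally in `[0, 1]`; negative values (a landmark benefit)
#'     are permitted down to -1 for meta-analytic use.}
#' }
#'
#' @param p_ego,a_max,a_scale,p_lapse,cost see Details above.
#' @return an object of class `observer_params` (a named list).
#' @examples
#' model_params(p_ego = 45, a_max = 180, a_scale = 8, p_lapse = 0.05)
#' @export
model_params <- function(p_ego, a_max = 0, a_scale = 0, p_lapse = 0, cost = 0) {
  stopifnot(length(p_ego) == 1, length(a_max) == 1, length(a_scale) == 1,
            length(p_lapse) == 1, length(cost) == 1)
  v <- c(p_ego = p_ego, a_max = a_max, a_scale = a_scale,
         p_lapse = p_lapse, cost = cost)
  if (any(!is.finite(v))) stop("model parameters must be finite")
  if (p_ego < 0) stop("p_ego must be >= 0")
  if (a_max < 0) stop("a_max must be >= 0")
  if (a_scale < 0) stop("a_scale must be >= 0")
  if (p_lapse < 0 || p_lapse > 1) stop("p_lapse must lie in [0, 1]")
  if (cost < -1 || cost > 1) stop("cost must lie in [-1, 1]")
  structure(as.list(v), class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat("Observer parameters:\n")
  cat(sprintf("  p_ego   %8.3f rad^-2\n", x$p_ego))
  cat(sprintf("  a_max   %8.3f rad^-2\n", x$a_max))
  cat(sprintf("  a_scale %8.3f rad^-1\n", x$a_scale))
  cat(sprintf("  p_lapse %8.4f\n", x$p_lapse))
  if (x$cost != 0) cat(sprintf("  cost    %8.4f\n", x$cost))
  invisible(x)
}

#' Default generative parameters by set size
#'
#' Reference parameter values used as simulation defaults. Egocentric
#' precision declines roughly linearly with set size (~ -18 rad^-2 per item),
#' peak allocentric precision declines steeply, the decay scale is shared
#' across set sizes, and the lapse rate grows slightly (~0.014 per item). At
#' set size 4, `a_max = 4 * p_ego`, so the predicted peak bias under a
#' landmark shift is 80% of the shift, and `a_scale = 8` rad^-1 confines the
#' allocentric benefit to within roughly 45 degrees of the landmark.
#'
#' @param set_size 1, 2 or 4.
#' @return an [model_params()] object.
#' @export
default_params <- function(set_size = 4) {
  tab <- list(`1` = c(100, 800, 8, 0.010),
              `2` = c(72, 500, 8, 0.025),
              `4` = c(45, 180, 8, 0.050))
  key <- as.character(set_size)
  if (!key %in% names(tab)) stop("set_size must be 1, 2 or 4")
  v <- tab[[key]]
  model_params(p_ego = v[1], a_max = v[2], a_scale = v[3], p_lapse = v[4])
}

#' Default per-cell parameter map for an experiment
#'
#' Returns a named list of [model_params()] keyed by `"condition:set_size"`,
#' covering every design cell of the requested experiment, suitable for
#' [simulate_responses()]. All conditions at a given set size share the same
#' generating parameters; whether the allocentric component is active on a
#' trial is decided by the condition (see [simulate_responses()]), not here.
#'
#' @param experiment one of `"E1"`, `"E2"`, `"E3"`, `"E2B"`.
#' @return named list of `observer_params`.
#' @export
default_cell_params <- function(experiment = c("E1", "E2", "E3", "E2B")) {
  experiment <- match.arg(experiment)
  spec <- .design_spec(experiment)
  cells <- unique(spec$cells[, c("condition", "set_size")])
  out <- list()
  for (i in seq_len(nrow(cells))) {
    key <- paste(cells$condition[i], cells$set_size[i], sep = ":")
    out[[key]] <- default_params(cells$set_size[i])
  }
  out
}
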