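# Forward simulation of observer responses from the generative model.

.cell_key <- function(condition, set_size) paste(condition, set_size, sep = ":")

# resolve a per-trial parameter table from a single observer_params or a
# named list keyed "condition:set_size"
.trial_params <- function(design, params) {
  keys <- .cell_key(design$condition, design$set_size)
  if (inherits(params, "observer_params"))
    params <- stats::setNames(rep(list(params), length(unique(keys))),
                              unique(keys))
  missing <- setdiff(unique(keys), names(params))
  if (length(missing))
    stop("no parameters supplied for cell(s): ",
         paste(missing, collapse = ", "))
  bad <- !vapply(params, inherits, logical(1), "observer_params")
  if (any(bad)) stop("params must be observer_params objects")
  get <- function(field) vapply(params[keys], `[[`, numeric(1), field)
  data.frame(p_ego = get("p_ego"), a_max = get("a_max"),
             a_scale = get("a_scale"), p_lapse = get("p_lapse"),
             cost = get("cost"))
}

# per-trial geometry in radians: target-landmark distance (NA when no
# landmark), shift, target. shift_reference selects whether the allocentric
# memory distance uses the pre-shift (encoding-time, default) or post-shift
# landmark position.
.trial_geometry <- function(data, shift_reference = c("pre", "post")) {
  shift_reference <- match.arg(shift_reference)
  target <- deg2rad(data$target_deg)
  lm <- deg2rad(data$landmark_deg)
  shift <- deg2rad(data$shift_deg)
  lm_ref <- if (shift_reference == "post") wrap_angle(lm + shift) else lm
  d <- abs(circ_dist(target, lm_ref))
  list(target = target, d = d, shift = shift)
}

#' Simulate observer responses for a trial schedule
#'
#' Samples one response per trial from the generative model: with probability
#' `p_lapse` the response is uniform on the circle; otherwise it is von Mises
#' distributed around the integrated (egocentric + allocentric) estimate with
#' precision equal to the summed cue precisions. The allocentric cue is active
#' only in `allo_conditions` (by default those with a landmark visible at both
#' encoding and test: LM_PRESENT, LM_GAP, LM_SHIFT). If a parameter set
#' carries a nonzero `cost`, egocentric precision on trials of
#' `cost_conditions` (default: every condition with a landmark) is reduced to
#' `p_ego * (1 - cost)`.
#'
#' @param design trial schedule from [generate_design()] or
#'   [generate_cell_design()].
#' @param params a single [model_params()] applied to every cell, or a named
#'   list keyed `"condition:set_size"` (see [default_cell_params()]).
#' @param seed integer seed; responses are reproducible given the seed.
#' @param participant participant identifier recorded in the dataset.
#' @param allo_conditions conditions in which the allocentric cue is active.
#' @param cost_conditions conditions subject to the egocentric cost; `NULL`
#'   means all conditions except LM_ABSENT.
#' @param shift_reference `"pre"` (default) or `"post"`: landmark position
#'   used for the allocentric distance in LM_SHIFT.
#' @return the design data frame with `participant` and `response_deg`
#'   columns appended (degrees, 4 decimals).
#' @examples
#' d <- generate_design("E3", seed = 1)
#' dat <- simulate_responses(d, default_cell_params("E3"), seed = 2)
#' @export
simulate_responses <- function(design, params, seed = NULL,
                               participant = "S01",
                               allo_conditions = .ALLO_CONDITIONS,
                               cost_conditions = NULL,
                               shift_reference = c("pre", "post")) {
  shift_reference <- match.arg(shift_reference)
  if (!is.null(seed)) set.seed(seed)
  pt <- .trial_params(design, params)
  geom <- .trial_geometry(design, shift_reference)
  n <- nrow(design)

  if (is.null(cost_conditions)) cost_conditions <- setdiff(.CONDITIONS,
                                                           "LM_ABSENT")
  p_ego <- pt$p_ego
  costed <- design$condition %in% cost_conditions & pt$cost != 0
  p_ego[costed] <- p_ego[costed] * (1 - pt$cost[costed])

  allo_on <- design$condition %in% allo_conditions & !is.na(geom$d)
  p_allo <- numeric(n)
  p_allo[allo_on] <- pt$a_max[allo_on] * exp(-pt$a_scale[allo_on] *
                                               geom$d[allo_on])
  iw <- .integration_weights(p_ego, p_allo)
  mu <- wrap_angle(geom$target + geom$shift * iw$w)

  resp <- rvonmises(n, mu = mu, kappa = iw$p_mle)
  lapse <- stats::runif(n) < pt$p_lapse
  if (any(lapse)) resp[lapse] <- stats::runif(sum(lapse), -pi, pi)

  out <- design
  out$participant <- participant
  out$response_deg <- round(rad2deg(wrap_angle(resp)), 4)
  out
}

#' Simulate a cohort of synthetic participants
#'
#' Convenience wrapper: generates one schedule and one response set per
#' participant, with per-participant seeds derived from `seed`.
#'
#' @param experiment experiment id passed to [generate_design()].
#' @param n_participants number of synthetic participants.
#' @param params as in [simulate_responses()]; optionally a function of the
#'   participant index returning a params object/list, for heterogeneous
#'   cohorts.
#' @param seed integer base seed.
#' @param ... further arguments passed to [simulate_responses()].
#' @return row-bound dataset for all participants, ids `"S01"`, `"S02"`, ...
#' @export
simulate_cohort <- function(experiment, n_participants, params, seed = 1,
                            ...) {
  sets <- lapply(seq_len(n_participants), function(i) {
    p <- if (is.function(params)) params(i) else params
    des <- generate_design(experiment, seed = seed + 1000L * i)
    simulate_responses(des, p, seed = seed + 1000L * i + 1L,
                       participant = sprintf("S%02d", i), ...)
  })
  out <- do.call(rbind, sets)
  rownames(out) <- NULL
  out
}
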