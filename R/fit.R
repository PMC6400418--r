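# Maximum-likelihood fitting of tying variants and AICc model comparison.

# per-trial log-likelihood under a tying variant; geometry precomputed
.loglik_trials <- function(data, tying, values, geom = NULL) {
  if (is.null(geom)) geom <- .trial_geometry(data, tying$shift_reference)
  cp <- .resolve_cell_params(tying, values)
  keys <- .cell_key(data$condition, data$set_size)
  missing <- setdiff(unique(keys), names(cp))
  if (length(missing))
    stop("tying does not cover cell(s): ", paste(missing, collapse = ", "))
  dev <- circ_dist(deg2rad(data$response_deg), geom$target)
  ll <- numeric(nrow(data))
  allo_on <- data$condition %in% tying$allo_conditions & !is.na(geom$d)
  for (key in unique(keys)) {
    idx <- which(keys == key)
    p <- cp[[key]]
    p_allo <- numeric(length(idx))
    on <- allo_on[idx]
    if (any(on))
      p_allo[on] <- allocentric_precision(geom$d[idx][on], p$a_max, p$a_scale)
    iw <- .integration_weights(p$p_ego, p_allo)
    x <- wrap_angle(dev[idx] - geom$shift[idx] * iw$w)
    ll[idx] <- .lapse_mix_logpdf(x, iw$p_mle, p$p_lapse)
  }
  ll
}

#' Negative log-likelihood of a dataset under a tying variant
#'
#' Sums the per-trial response log-density over all trials, with trial-level
#' parameters resolved through the tying map. Invariant to trial order.
#'
#' @param data dataset with responses (see [simulate_responses()] /
#'   [read_dataset()]).
#' @param tying a [param_tying()] variant covering every cell in `data`.
#' @param values numeric vector of free-slot values (length `tying$k`).
#' @return the negative log-likelihood (a single number).
#' @export
neg_loglik <- function(data, tying, values) {
  -sum(.loglik_trials(data, tying, values))
}

#' Small-sample corrected Akaike Information Criterion
#'
#' `aicc = -2 loglik + 2k + 2k(k+1) / (n - k - 1)` (Hurvich-Tsai correction).
#'
#' @param loglik maximized log-likelihood.
#' @param k number of free parameters.
#' @param n number of observations; must exceed `k + 1`.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# randomized interior starting values: precisions log-uniform over
# [1, 1e3] rad^-2, decay scale log-uniform over [0.5, 50] rad^-1, lapse and
# cost uniform over a plausible interior range
.draw_start <- function(slots) {
  vapply(seq_len(nrow(slots)), function(i) {
    switch(slots$param[i],
           p_ego   = 10^stats::runif(1, 0, 3),
           a_max   = 10^stats::runif(1, 0, 3),
           a_scale = 10^stats::runif(1, log10(0.5), log10(50)),
           p_lapse = stats::runif(1, 0.005, 0.2),
           cost    = stats::runif(1, max(0.01, slots$lower[i] + 0.01), 0.3))
  }, numeric(1))
}

#' Fit the observer model by constrained maximum likelihood
#'
#' Minimizes [neg_loglik()] with box constraints (via [stats::nlminb()]) from
#' `n_starts` randomized interior starting points and keeps the best
#' optimum. Deterministic given `seed`. Bounds are taken from the tying's
#' slot table: precisions in [0, 1e6] (a large finite stand-in for an
#' unbounded precision), decay scale in [0, 500], lapse in [0, 1], cost in
#' [0, 1] (or [-1, 1] when negative costs are allowed).
#'
#' @param data dataset for a single participant (fitting is always per
#'   participant; a `participant` column, if present, must be constant).
#' @param tying a [param_tying()] variant; default [tying_full()] on the
#'   cells present in `data`.
#' @param n_starts number of randomized starts.
#' @param seed integer seed for the starts.
#' @param control passed to [stats::nlminb()]; defaults set
#'   `rel.tol = 1e-8`, `eval.max = 1000`, `iter.max = 500`.
#' @return an object of class `observer_fit`: `tying`, `values` (named slot
#'   estimates), `loglik`, `k`, `n`, `aicc`, `n_starts`, `converged`,
#'   `participant`.
#' @examples
#' \donttest{
#' des <- generate_cell_design("LM_PRESENT", 4, 200, seed = 1)
#' dat <- simulate_responses(des, default_params(4), seed = 2)
#' fit_observer(dat, n_starts = 5, seed = 3)
#' }
#' @export
fit_observer <- function(data, tying = NULL, n_starts = 20, seed = NULL,
                         control = list()) {
  if (is.null(tying)) tying <- tying_full(dataset_cells(data))
  stopifnot(inherits(tying, "param_tying"))
  n <- nrow(data)
  if (n <= tying$k + 1)
    stop("too few trials (n = ", n, ") for k = ", tying$k, " parameters")
  participant <- if ("participant" %in% names(data)) {
    u <- unique(data$participant)
    if (length(u) > 1)
      stop("fit_observer() expects one participant; see fit_cohort()")
    u
  } else NA_character_

  geom <- .trial_geometry(data, tying$shift_reference)
  obj <- function(v) {
    nll <- -sum(.loglik_trials(data, tying, v, geom))
    if (!is.finite(nll)) 1e12 else nll
  }
  ctrl <- utils::modifyList(list(rel.tol = 1e-8, eval.max = 1000,
                                 iter.max = 500), control)
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  converged <- FALSE
  failures <- character(0)
  for (s in seq_len(n_starts)) {
    start <- .draw_start(tying$slots)
    res <- tryCatch(
      stats::nlminb(start, obj, lower = tying$slots$lower,
                    upper = tying$slots$upper, control = ctrl),
      error = function(e) e)
    if (inherits(res, "error")) { failures <- c(failures, conditionMessage(res)); next }
    if (is.null(best) || res$objective < best$objective) best <- res
    if (res$convergence == 0) converged <- TRUE
  }
  if (is.null(best))
    stop("all ", n_starts, " starts failed: ",
         paste(unique(failures), collapse = "; "))
  values <- stats::setNames(best$par,
                            paste0(tying$slots$param, "[",
                                   tying$slots$group, "]"))
  structure(list(tying = tying, values = values, loglik = -best$objective,
                 k = tying$k, n = n, aicc = aicc(-best$objective, tying$k, n),
                 n_starts = n_starts, converged = converged,
                 participant = participant),
            class = "observer_fit")
}

#' @export
print.observer_fit <- function(x, ...) {
  cat(sprintf("Observer model fit%s: logLik %.2f, k = %d, n = %d, AICc %.2f\n",
              if (!is.na(x$participant)) paste0(" (", x$participant, ")")
              else "", x$loglik, x$k, x$n, x$aicc))
  print(round(x$values, 4))
  if (!x$converged) cat("  warning: no start reported clean convergence\n")
  invisible(x)
}

#' @export
coef.observer_fit <- function(object, ...) object$values

#' Per-cell parameters implied by a fit
#'
#' @param fit an `observer_fit`.
#' @return named list of [model_params()] per cell.
#' @export
cell_params <- function(fit) {
  stopifnot(inherits(fit, "observer_fit"))
  .resolve_cell_params(fit$tying, unname(fit$values))
}

#' Fit the egocentric-cost model variant
#'
#' Convenience wrapper around [fit_observer()] with the five-parameter cost
#' tying ([tying_cost()]): shared `p_ego` (landmark-absent value), `a_max`,
#' `a_scale`, `p_lapse`, plus a cost `C` such that landmark-trial egocentric
#' precision is `p_ego * (1 - C)`. `C` is bounded in [0, 1] by default;
#' `allow_negative_cost = TRUE` widens the bound to [-1, 1].
#'
#' @inheritParams fit_observer
#' @param allow_negative_cost logical.
#' @param ... further arguments to [tying_cost()].
#' @export
fit_cost_model <- function(data, n_starts = 20, seed = NULL,
                           allow_negative_cost = FALSE, control = list(),
                           ...) {
  tying <- tying_cost(dataset_cells(data),
                      allow_negative_cost = allow_negative_cost, ...)
  fit_observer(data, tying, n_starts = n_starts, seed = seed,
               control = control)
}

#' Fit every participant of a dataset
#'
#' @param data multi-participant dataset.
#' @param tying a `param_tying`, or `NULL` for [tying_full()] per participant.
#' @param ... passed to [fit_observer()].
#' @return named list of `observer_fit`, one per participant.
#' @export
fit_cohort <- function(data, tying = NULL, ...) {
  ids <- unique(data$participant)
  fits <- lapply(ids, function(id)
    fit_observer(data[data$participant == id, , drop = FALSE], tying, ...))
  stats::setNames(fits, ids)
}

#' Compare two fitted model variants by summed AICc
#'
#' Computes `sum(AICc_A - AICc_B)` over participants (or the mean, if
#' requested). Positive values favour variant B (lower AICc is better). Both
#' fit lists must cover the same participants fitted on the same data.
#'
#' @param fits_a,fits_b lists of `observer_fit` (e.g. from [fit_cohort()]).
#' @param method `"sum"` (default) or `"mean"` across participants.
#' @return list with `delta_aicc`, `method`, `favours` (`"A"`/`"B"`/`"tie"`),
#'   and the per-participant differences.
#' @export
compare_fits <- function(fits_a, fits_b, method = c("sum", "mean")) {
  method <- match.arg(method)
  if (inherits(fits_a, "observer_fit")) fits_a <- list(fits_a)
  if (inherits(fits_b, "observer_fit")) fits_b <- list(fits_b)
  pa <- vapply(fits_a, `[[`, character(1), "participant")
  pb <- vapply(fits_b, `[[`, character(1), "participant")
  if (length(pa) != length(pb) || !setequal(pa, pb))
    stop("fit lists cover different participants")
  fits_b <- fits_b[match(pa, pb)]
  na <- vapply(fits_a, `[[`, numeric(1), "n")
  nb <- vapply(fits_b, `[[`, numeric(1), "n")
  if (!all(na == nb))
    stop("variants were fitted on different trial counts")
  per <- vapply(fits_a, `[[`, numeric(1), "aicc") -
    vapply(fits_b, `[[`, numeric(1), "aicc")
  delta <- if (method == "sum") sum(per) else mean(per)
  list(delta_aicc = delta, method = method,
       favours = if (delta > 0) "B" else if (delta < 0) "A" else "tie",
       per_participant = stats::setNames(per, pa))
}

#' Linear trend of a fitted parameter across set sizes
#'
#' Fits an ordinary least-squares slope of parameter value against set size
#' for each participant, then tests the cohort of slopes against zero with a
#' two-sided one-sample t-test (`df = n_participants - 1`).
#'
#' @param estimates data frame with columns `participant`, `set_size`,
#'   `value`.
#' @return list with per-participant `slopes`, `mean`, `se`, `t`, `df`, `p`.
#'   With zero slope variance the t statistic is undefined and flagged via
#'   `t = NaN`.
#' @examples
#' est <- data.frame(participant = rep(1:3, each = 3),
#'                   set_size = rep(c(1, 2, 4), 3),
#'                   value = c(9, 8, 5, 10, 8, 4, 11, 9, 5))
#' setsize_trend(est)
#' @export
setsize_trend <- function(estimates) {
  stopifnot(all(c("participant", "set_size", "value") %in% names(estimates)))
  ids <- unique(estimates$participant)
  if (length(ids) < 2) stop("need at least 2 participants")
  slopes <- vapply(ids, function(id) {
    e <- estimates[estimates$participant == id, ]
    if (length(unique(e$set_size)) < 2)
      stop("participant ", id, " has fewer than 2 set sizes")
    unname(stats::coef(stats::lm(value ~ set_size, data = e))["set_size"])
  }, numeric(1))
  m <- mean(slopes)
  se <- stats::sd(slopes) / sqrt(length(slopes))
  t <- if (se > 0) m / se else NaN
  df <- length(slopes) - 1
  p <- if (is.finite(t)) 2 * stats::pt(-abs(t), df) else NaN
  list(slopes = stats::setNames(slopes, ids), mean = m, se = se,
       t = t, df = df, p = p)
}

#' Predicted egocentric cost implied by set-size doubling
#'
#' Under the hypothesis that allocentric and egocentric location codes share a
#' common memory resource, adding a landmark should cost as much precision as
#' doubling the number of memory items. That predicted cost is computed per
#' participant as `1 - p_ego(2N) / p_ego(N)` for each available doubling, with
#' cohort mean and standard error.
#'
#' @param estimates data frame with columns `participant`, `set_size`,
#'   `p_ego`.
#' @param pairs list of `c(N, 2N)` set-size pairs; default `(1, 2)` and
#'   `(2, 4)`.
#' @return data frame with one row per pair: `from`, `to`, `mean`, `se`, and
#'   an attribute `"per_participant"` holding the individual costs.
#' @export
predicted_cost <- function(estimates, pairs = list(c(1, 2), c(2, 4))) {
  stopifnot(all(c("participant", "set_size", "p_ego") %in% names(estimates)))
  per <- list()
  rows <- lapply(pairs, function(pr) {
    ids <- unique(estimates$participant)
    costs <- vapply(ids, function(id) {
      e <- estimates[estimates$participant == id, ]
      p1 <- e$p_ego[e$set_size == pr[1]]
      p2 <- e$p_ego[e$set_size == pr[2]]
      if (length(p1) != 1 || length(p2) != 1)
        stop("participant ", id, " lacks set size ", pr[1], " or ", pr[2])
      if (p1 == 0) stop("zero p_ego at set size ", pr[1], " (participant ",
                        id, ")")
      1 - p2 / p1
    }, numeric(1))
    per[[paste(pr, collapse = "_")]] <<- stats::setNames(costs, ids)
    data.frame(from = pr[1], to = pr[2], mean = mean(costs),
               se = stats::sd(costs) / sqrt(length(costs)))
  })
  out <- do.call(rbind, rows)
  attr(out, "per_participant") <- per
  out
}
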