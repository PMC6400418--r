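# Binned circular summaries: median signed deviation (bias) and median
# absolute deviation (variability) versus target-landmark distance, in
# partially overlapping bins (half-width 15 deg, spaced every 15 deg), plus
# Monte-Carlo and quadrature model curves.

.bin_centers <- function(fold, spacing = 15) {
  if (fold) seq(0, 180, by = spacing) else seq(-180 + spacing, 180,
                                               by = spacing)
}

# membership of distances (deg) in the bin [center - hw, center + hw)
.in_bin <- function(dist, center, fold, hw = 15) {
  if (fold) dist >= center - hw & dist < center + hw
  else {
    delta <- wrap_deg(dist - center)
    delta >= -hw & delta < hw
  }
}

.median_or_na <- function(x) if (length(x)) stats::median(x) else NA_real_

# bias / MAD of a set of signed deviations; MAD optionally centred on the
# median bias first (used when a landmark shift induces a systematic bias)
.bin_stats <- function(dev, center_bias) {
  b <- .median_or_na(dev)
  m <- if (!length(dev)) NA_real_
  else stats::median(abs(dev - if (center_bias) b else 0))
  c(bias = b, mad = m)
}

#' Binned bias and variability of localization responses
#'
#' For every condition/set-size cell, computes the median signed angular
#' deviation (bias) and the median absolute angular deviation (variability)
#' of responses from targets, as a function of target-landmark distance, in
#' partially overlapping bins of half-width 15 degrees spaced every 15
#' degrees (24 bins on the signed circle; 13 on the folded [0, 180] axis).
#' A trial whose distance falls in two overlapping bins contributes to both.
#' Landmark-absent cells have no distance axis and are summarized as a single
#' pooled row (`bin_center_deg = NA`).
#'
#' @param data dataset with responses.
#' @param fold collapse signed distance to [0, 180] degrees?
#' @param shift_align sign each deviation by the direction of the landmark
#'   shift, and subtract the per-bin median bias before computing the MAD
#'   (use for shifted-landmark data).
#' @param pool `"trials"`: pool trials across participants per bin;
#'   `"participants"`: per-participant medians averaged across participants.
#' @param boot number of bootstrap resamples for interval estimates on bias
#'   and MAD per bin (0 = none).
#' @param seed seed for the bootstrap.
#' @param conf bootstrap interval coverage.
#' @param ci_method `"percentile"` (default) or `"normal"`
#'   (estimate +/- z * bootstrap SE; use for extreme `conf` levels, where
#'   percentile endpoints of a few hundred resamples are unreliable).
#' @return data frame of class `binned_summary`: `condition`, `set_size`,
#'   `bin_center_deg`, `n`, `bias_deg`, `mad_deg`, and with `boot > 0` the
#'   interval columns `bias_lo`, `bias_hi`, `mad_lo`, `mad_hi`. Empty bins
#'   hold `NA` statistics.
#' @export
binned_summary <- function(data, fold = TRUE, shift_align = FALSE,
                           pool = c("trials", "participants"), boot = 0,
                           seed = NULL, conf = 0.95,
                           ci_method = c("percentile", "normal")) {
  pool <- match.arg(pool)
  ci_method <- match.arg(ci_method)
  if (!nrow(data)) stop("empty dataset")
  if (!is.null(seed)) set.seed(seed)
  if (!"participant" %in% names(data)) data$participant <- "S01"
  dev <- wrap_deg(data$response_deg - data$target_deg)
  if (shift_align) {
    sgn <- sign(data$shift_deg)
    sgn[sgn == 0] <- 1
    dev <- dev * sgn
  }
  dist <- wrap_deg(data$target_deg - data$landmark_deg)
  if (fold) dist <- abs(dist)
  cells <- dataset_cells(data)
  qs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)

  summarize_bin <- function(idx) {
    if (pool == "trials") {
      est <- .bin_stats(dev[idx], shift_align)
    } else {
      by_p <- split(dev[idx], data$participant[idx])
      mat <- vapply(by_p, .bin_stats, numeric(2), center_bias = shift_align)
      est <- c(bias = mean(mat["bias", ]), mad = mean(mat["mad", ]))
    }
    row <- data.frame(n = length(idx), bias_deg = est[["bias"]],
                      mad_deg = est[["mad"]])
    if (boot > 0) {
      if (length(idx)) {
        if (pool == "trials") {
          bs <- replicate(boot, .bin_stats(sample(dev[idx], replace = TRUE),
                                           shift_align))
        } else {
          ids <- unique(data$participant[idx])
          bs <- replicate(boot, {
            take <- sample(ids, replace = TRUE)
            mat <- vapply(take, function(id)
              .bin_stats(dev[idx][data$participant[idx] == id], shift_align),
              numeric(2))
            c(mean(mat["bias", ]), mean(mat["mad", ]))
          })
        }
        if (ci_method == "normal") {
          z <- stats::qnorm(qs[2])
          row$bias_lo <- row$bias_deg - z * stats::sd(bs[1, ])
          row$bias_hi <- row$bias_deg + z * stats::sd(bs[1, ])
          row$mad_lo <- row$mad_deg - z * stats::sd(bs[2, ])
          row$mad_hi <- row$mad_deg + z * stats::sd(bs[2, ])
        } else {
          row$bias_lo <- stats::quantile(bs[1, ], qs[1], na.rm = TRUE)
          row$bias_hi <- stats::quantile(bs[1, ], qs[2], na.rm = TRUE)
          row$mad_lo <- stats::quantile(bs[2, ], qs[1], na.rm = TRUE)
          row$mad_hi <- stats::quantile(bs[2, ], qs[2], na.rm = TRUE)
        }
      } else row[c("bias_lo", "bias_hi", "mad_lo", "mad_hi")] <- NA_real_
    }
    row
  }

  out <- list()
  for (ci in seq_len(nrow(cells))) {
    in_cell <- data$condition == cells$condition[ci] &
      data$set_size == cells$set_size[ci]
    if (all(is.na(dist[in_cell]))) {  # no landmark: one pooled row
      row <- summarize_bin(which(in_cell))
      out[[length(out) + 1]] <- cbind(
        data.frame(condition = cells$condition[ci],
                   set_size = cells$set_size[ci],
                   bin_center_deg = NA_real_), row)
      next
    }
    for (ctr in .bin_centers(fold)) {
      idx <- which(in_cell & .in_bin(dist, ctr, fold))
      row <- summarize_bin(idx)
      out[[length(out) + 1]] <- cbind(
        data.frame(condition = cells$condition[ci],
                   set_size = cells$set_size[ci], bin_center_deg = ctr), row)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("binned_summary", class(out))
  out
}

#' Monte-Carlo model prediction of the binned summary curves
#'
#' Simulates `n_mc` responses from the generative model at targets uniform on
#' the circle around a landmark, then summarizes them exactly as
#' [binned_summary()] does. This mirrors how model curves are generated for
#' overlay on empirical bias/variability plots.
#'
#' @param params an [model_params()] object.
#' @param shift_deg landmark displacement in degrees (0 for no-conflict
#'   conditions); signs are balanced and deviations sign-aligned when nonzero.
#' @param n_mc number of simulated trials.
#' @param seed integer seed.
#' @param fold fold the distance axis to [0, 180]?
#' @param ... further arguments passed to [binned_summary()].
#' @return a `binned_summary` data frame for one synthetic cell.
#' @export
model_curves <- function(params, shift_deg = 0, n_mc = 1e5, seed = NULL,
                         fold = TRUE, ...) {
  stopifnot(inherits(params, "observer_params"))
  if (!is.null(seed)) set.seed(seed)
  condition <- if (shift_deg != 0) "LM_SHIFT" else "LM_PRESENT"
  design <- data.frame(
    experiment = "MC", condition = condition, set_size = 4L, block = 1L,
    trial = seq_len(n_mc), item_angles = "", target_index = 0L,
    target_deg = wrap_deg(stats::runif(n_mc, -180, 180)),
    landmark_deg = 0,
    shift_deg = if (shift_deg != 0)
      sample(c(-1, 1), n_mc, replace = TRUE) * abs(shift_deg) else 0)
  dat <- simulate_responses(design, params, participant = "MC")
  binned_summary(dat, fold = fold, shift_align = shift_deg != 0, ...)
}

# pooled response-deviation distribution over a window of distances:
# grid log-density -> CDF, used for deterministic bin predictions
.pooled_bin_quadrature <- function(params, shift_rad, d_lo, d_hi,
                                   n_d = 32, n_grid = 8192) {
  d <- seq(d_lo, d_hi, length.out = n_d)
  p_allo <- allocentric_precision(d, params$a_max, params$a_scale)
  iw <- .integration_weights(params$p_ego, p_allo)
  theta <- seq(-pi, pi, length.out = n_grid + 1)[-1]
  dens <- rowMeans(vapply(seq_len(n_d), function(i)
    exp(.lapse_mix_logpdf(wrap_angle(theta - shift_rad * iw$w[i]),
                          iw$p_mle[i], params$p_lapse)),
    numeric(n_grid)))
  step <- 2 * pi / n_grid
  # midpoint-corrected CDF on the grid (plain cumsum is half a cell late)
  cdf <- (cumsum(dens) - dens / 2) * step
  cdf <- cdf / ((cumsum(dens)[n_grid]) * step)
  b <- stats::approx(cdf, theta, xout = 0.5, ties = "ordered")$y
  # MAD around the median: weighted quantile of the folded distances
  u <- abs(wrap_angle(theta - b))
  o <- order(u)
  du <- dens[o]
  cum <- (cumsum(du) - du / 2) * step
  cum <- cum / (sum(du) * step)
  m <- stats::approx(cum, u[o], xout = 0.5, ties = "ordered")$y
  c(bias = b, mad = m)
}

#' Deterministic quadrature prediction of the binned summary curves
#'
#' For each bin, pools the model's response-deviation distribution over
#' distances spanning the bin window (targets are uniform relative to the
#' landmark, so distances within a bin are weighted uniformly) and extracts
#' the distribution's median (bias) and the median absolute deviation around
#' it. This is the deterministic counterpart of [model_curves()].
#'
#' @param params an [model_params()] object.
#' @param shift_deg landmark displacement, degrees.
#' @param fold folded distance axis?
#' @param centers_deg bin centres; default matches [binned_summary()].
#' @param bin_halfwidth bin half-width in degrees.
#' @param n_d distances per bin window for the pooling quadrature.
#' @param n_grid angular grid resolution for the pooled density.
#' @return data frame: `bin_center_deg`, `bias_deg`, `mad_deg`.
#' @export
predicted_curves <- function(params, shift_deg = 0, fold = TRUE,
                             centers_deg = NULL, bin_halfwidth = 15,
                             n_d = 32, n_grid = 8192) {
  stopifnot(inherits(params, "observer_params"))
  if (is.null(centers_deg)) centers_deg <- .bin_centers(fold)
  shift_rad <- deg2rad(abs(shift_deg))
  rows <- lapply(centers_deg, function(ctr) {
    # distance window of the bin on the folded axis
    lo <- max(0, abs(ctr) - bin_halfwidth)
    hi <- min(180, abs(ctr) + bin_halfwidth)
    st <- .pooled_bin_quadrature(params, shift_rad, deg2rad(lo), deg2rad(hi),
                                 n_d = n_d, n_grid = n_grid)
    data.frame(bin_center_deg = ctr, bias_deg = rad2deg(st[["bias"]]),
               mad_deg = rad2deg(st[["mad"]]))
  })
  do.call(rbind, rows)
}
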