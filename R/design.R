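# Trial-schedule generators for the four landmark experiments.
#
# Common structure: conditions interleaved within blocks; in every
# landmark condition the target's angular position relative to the landmark is
# stratified over 12 thirty-degree bins within each block, the landmark itself
# is uniform on the circle, non-target items are placed uniformly subject to a
# minimum pairwise separation of 15 degrees (no such constraint involves the
# landmark), and in the shifted-landmark condition the landmark reappears
# displaced 6 degrees clockwise or counter-clockwise, balanced within block.

.CONDITIONS <- c("LM_ABSENT", "LM_PRESENT", "LM_GAP", "LM_ENCODE",
                 "LM_RETRIEVE", "LM_SHIFT")

# conditions in which a landmark visible at both encoding and test supports an
# allocentric estimate (the best-fitting model configuration)
.ALLO_CONDITIONS <- c("LM_PRESENT", "LM_GAP", "LM_SHIFT")

.SHIFT_DEG <- 6
.MIN_SEP_DEG <- 15
.N_TARGET_BINS <- 12

.design_spec <- function(experiment) {
  cells <- switch(experiment,
    E1 = data.frame(
      condition = rep(c("LM_PRESENT", "LM_ABSENT"), each = 3),
      set_size  = rep(c(1L, 2L, 4L), 2),
      n         = c(216L, 216L, 216L, 36L, 36L, 36L)),
    E2 = data.frame(
      condition = c("LM_PRESENT", "LM_GAP", "LM_ENCODE", "LM_ABSENT"),
      set_size  = 4L,
      n         = c(216L, 216L, 216L, 72L)),
    E3 = data.frame(
      condition = c("LM_PRESENT", "LM_GAP", "LM_SHIFT", "LM_ABSENT"),
      set_size  = 4L,
      n         = c(216L, 216L, 216L, 36L)),
    E2B = data.frame(
      condition = c("LM_PRESENT", "LM_RETRIEVE", "LM_ABSENT"),
      set_size  = 4L,
      n         = c(210L, 210L, 105L)),
    stop("unknown experiment: ", experiment)
  )
  n_blocks <- if (experiment == "E2B") 5L else 6L
  stopifnot(all(cells$n %% n_blocks == 0))
  list(cells = cells, n_blocks = n_blocks)
}

# balanced (as equal as possible) target-bin assignment for n trials
.assign_bins <- function(n) {
  base <- rep(seq_len(.N_TARGET_BINS), n %/% .N_TARGET_BINS)
  rem <- n %% .N_TARGET_BINS
  if (rem > 0) base <- c(base, sample.int(.N_TARGET_BINS, rem))
  sample(base)
}

# bin k (1..12) covers signed target-landmark separations
# [k*30 - 195, k*30 - 165) degrees, i.e. centres -165, -135, ..., 180
.bin_center_deg <- function(k) wrap_deg(k * 30 - 180)

# place set_size - 1 non-target items uniformly with >= 15 deg pairwise
# separation from all already-placed items; returns all item angles (deg)
.place_items <- function(target_deg, set_size, max_tries = 1e4) {
  items <- target_deg
  while (length(items) < set_size) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- stats::runif(1, -180, 180)
      if (all(abs(wrap_deg(cand - items)) >= .MIN_SEP_DEG)) {
        items <- c(items, cand)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("item placement failed after ", max_tries, " tries")
  }
  items
}

.make_cell_trials <- function(experiment, condition, set_size, n, block) {
  has_lm <- condition != "LM_ABSENT"
  if (has_lm) {
    landmark <- wrap_deg(stats::runif(n, -180, 180))
    centers <- .bin_center_deg(.assign_bins(n))
    target <- wrap_deg(landmark + centers + stats::runif(n, -15, 15))
  } else {
    landmark <- rep(NA_real_, n)
    target <- wrap_deg(stats::runif(n, -180, 180))
  }
  shift <- rep(0, n)
  if (condition == "LM_SHIFT") {
    stopifnot(n %% 2 == 0)
    shift <- sample(rep(c(-.SHIFT_DEG, .SHIFT_DEG), n / 2))
  }
  item_str <- character(n)
  tidx <- integer(n)
  tdeg <- numeric(n)
  for (i in seq_len(n)) {
    items <- .place_items(target[i], set_size)
    ord <- sample.int(set_size)
    items <- round(wrap_deg(items[ord]), 4)
    ti <- which(ord == 1L)
    item_str[i] <- paste(sprintf("%.4f", items), collapse = ";")
    tidx[i] <- ti - 1L
    tdeg[i] <- items[ti]
  }
  data.frame(
    experiment = experiment, condition = condition, set_size = set_size,
    block = block, item_angles = item_str, target_index = tidx,
    target_deg = tdeg, landmark_deg = round(landmark, 4),
    shift_deg = shift, stringsAsFactors = FALSE)
}

#' Generate a trial schedule for one of the landmark experiments
#'
#' Reproduces the published designs:
#' * **E1** — set sizes 1, 2, 4 interleaved; per set size 216 LM_PRESENT and
#'   36 LM_ABSENT trials; 6 blocks of 126 (756 trials).
#' * **E2** — set size 4; 216 each of LM_PRESENT, LM_GAP, LM_ENCODE and 72
#'   LM_ABSENT; 6 blocks of 120 (720 trials).
#' * **E3** — set size 4; 216 each of LM_PRESENT, LM_GAP, LM_SHIFT and 36
#'   LM_ABSENT; 6 blocks of 114 (684 trials).
#' * **E2B** — set size 4; 210 each of LM_PRESENT, LM_RETRIEVE and 105
#'   LM_ABSENT; 5 blocks of 105 (525 trials).
#'
#' Within each block, targets of landmark conditions are stratified as equally
#' as possible over 12 angular bins of target-landmark separation; the
#' landmark position is uniform; non-target items are uniform subject to a
#' 15-degree minimum separation between items (none for the landmark); in
#' LM_SHIFT the landmark displacement is 6 degrees, sign balanced within
#' block. All angles are degrees on the circle in (-180, 180], rounded to 4
#' decimals; `target_index` is 0-based into the `item_angles` list.
#'
#' @param experiment `"E1"`, `"E2"`, `"E3"` or `"E2B"`.
#' @param seed integer seed; the schedule is reproducible given the seed.
#' @return a data frame with one row per trial: `experiment`, `condition`,
#'   `set_size`, `block`, `item_angles` (semicolon-joined degrees),
#'   `target_index`, `target_deg`, `landmark_deg` (`NA` when absent),
#'   `shift_deg`.
#' @examples
#' d <- generate_design("E3", seed = 1)
#' nrow(d)               # 684
#' table(d$condition)
#' @export
generate_design <- function(experiment = c("E1", "E2", "E3", "E2B"),
                            seed = NULL) {
  experiment <- match.arg(experiment)
  if (!is.null(seed)) set.seed(seed)
  spec <- .design_spec(experiment)
  blocks <- lapply(seq_len(spec$n_blocks), function(b) {
    cell_trials <- lapply(seq_len(nrow(spec$cells)), function(i) {
      .make_cell_trials(experiment, spec$cells$condition[i],
                        spec$cells$set_size[i],
                        spec$cells$n[i] %/% spec$n_blocks, b)
    })
    blk <- do.call(rbind, cell_trials)
    blk[sample.int(nrow(blk)), , drop = FALSE]
  })
  out <- do.call(rbind, blocks)
  out$trial <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("experiment", "condition", "set_size", "block", "trial",
          "item_angles", "target_index", "target_deg", "landmark_deg",
          "shift_deg")]
}

#' Generate a custom single-cell trial schedule
#'
#' Builds `n_trials` trials of one condition/set-size cell using the same
#' placement rules as [generate_design()] (bin-stratified targets, uniform
#' landmark, 15-degree item separation). Intended for simulation harnesses
#' that need cell compositions outside the four published designs.
#'
#' @param condition one of the six landmark conditions.
#' @param set_size number of memory items.
#' @param n_trials number of trials.
#' @param seed optional integer seed.
#' @param block block label attached to the trials.
#' @return a trial data frame in the same format as [generate_design()].
#' @export
generate_cell_design <- function(condition, set_size = 4L, n_trials = 100L,
                                 seed = NULL, block = 1L) {
  condition <- match.arg(condition, .CONDITIONS)
  if (condition == "LM_SHIFT" && n_trials %% 2 != 0)
    stop("LM_SHIFT needs an even trial count to balance shift signs")
  if (!is.null(seed)) set.seed(seed)
  out <- .make_cell_trials("CUSTOM", condition, as.integer(set_size),
                           as.integer(n_trials), as.integer(block))
  out$trial <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("experiment", "condition", "set_size", "block", "trial",
          "item_angles", "target_index", "target_deg", "landmark_deg",
          "shift_deg")]
}
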