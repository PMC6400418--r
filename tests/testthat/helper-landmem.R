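# shared fixtures and oracles, built in code at test time

# random valid observer parameters in a realistic range
rparams <- function(allow_lapse = TRUE) {
  model_params(
    p_ego = 10^runif(1, log10(20), log10(200)),
    a_max = 10^runif(1, log10(50), log10(800)),
    a_scale = 10^runif(1, log10(2), log10(20)),
    p_lapse = if (allow_lapse) runif(1, 0, 0.15) else 0)
}

# trapezoid integral of the response density over a fine periodic grid
grid_density_integral <- function(params, d = NA, shift = 0,
                                  allo_active = TRUE, n_grid = 8192) {
  th <- seq(-pi, pi, length.out = n_grid + 1)[-1]
  f <- exp(response_logpdf(th, 0, params, d = d, shift = shift,
                           allo_active = allo_active))
  sum(f) * 2 * pi / n_grid
}

# single-participant recovery harness: set size 4, 648 landmark-present and
# 108 landmark-absent trials (three seeded E1 schedules restricted to ss 4)
recovery_data <- function(rep_seed, truth = default_params(4)) {
  des <- do.call(rbind, lapply(0:2, function(j) {
    d <- generate_design("E1", seed = rep_seed + j)
    d[d$set_size == 4, ]
  }))
  simulate_responses(des, truth, seed = rep_seed + 10L, participant = "R")
}

# balanced landmark-present / landmark-absent data for cost estimation
cost_data <- function(seed, truth, n_each = 1200L, id = "S01") {
  des <- rbind(
    generate_cell_design("LM_PRESENT", 4, n_each, seed = seed),
    generate_cell_design("LM_ABSENT", 4, n_each, seed = seed + 1L))
  simulate_responses(des, truth, seed = seed + 2L, participant = id)
}

# draw deviations from the lapse-contaminated von Mises mixture
.sample_dev <- function(n, kappa, p_lapse, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapse <- runif(n) < p_lapse
  x <- rvonmises(n, 0, kappa)
  if (any(lapse)) x[lapse] <- runif(sum(lapse), -pi, pi)
  x
}

# bootstrap standard error of the median
boot_se_median <- function(x, n_boot = 200) {
  stats::sd(replicate(n_boot, stats::median(sample(x, replace = TRUE))))
}

# minimum pairwise circular separation (degrees) of an item_angles string
min_item_sep <- function(item_str) {
  a <- as.numeric(strsplit(item_str, ";", fixed = TRUE)[[1]])
  if (length(a) < 2) return(Inf)
  prs <- utils::combn(a, 2)
  min(abs(wrap_deg(prs[1, ] - prs[2, ])))
}
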