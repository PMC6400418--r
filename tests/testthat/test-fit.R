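make_small_data <- function(n = 60, seed = 1, cond = "LM_PRESENT") {
  des <- generate_cell_design(cond, 4, n, seed = seed)
  simulate_responses(des, default_params(4), seed = seed + 1,
                     participant = "S01")
}

test_that("tying variants expose the expected free-parameter counts", {
  cells <- data.frame(condition = c("LM_PRESENT", "LM_GAP", "LM_ABSENT"),
                      set_size = 4)
  expect_equal(tying_full(cells)$k, 4)           # p_ego, a_max, a_scale, lapse
  expect_equal(tying_reduced(cells)$k, 2)        # allocentric slots freed
  expect_equal(tying_cost(cells)$k, 5)
  ty <- param_tying(cells, a_max = "by_condition", a_scale = "by_condition")
  expect_equal(ty$k, 6)  # separate allocentric parameters per landmark cond
  # allocentric parameters never free in landmark-absent cells
  i_abs <- which(ty$cells$condition == "LM_ABSENT")
  expect_true(is.na(ty$assign[i_abs, "a_max"]))
  expect_equal(ty$fixed_values[i_abs, "a_max"], c(a_max = 0))
})

test_that("the negative log-likelihood matches direct per-trial summation", {
  dat <- make_small_data(5, seed = 2)
  ty <- tying_full(dataset_cells(dat))
  v <- c(45, 180, 8, 0.05)
  p <- model_params(45, 180, 8, 0.05)
  direct <- -sum(response_logpdf(
    deg2rad(dat$response_deg), deg2rad(dat$target_deg), p,
    d = abs(deg2rad(wrap_deg(dat$target_deg - dat$landmark_deg))),
    shift = deg2rad(dat$shift_deg)))
  expect_equal(neg_loglik(dat, ty, v), direct, tolerance = 1e-12)
  # single pure-lapse trial
  one <- dat[1, ]
  expect_equal(neg_loglik(one, ty, c(45, 180, 8, 1)), log(2 * pi))
  # permuting trials leaves the likelihood unchanged
  perm <- dat[sample(nrow(dat)), ]
  expect_equal(neg_loglik(perm, ty, v), neg_loglik(dat, ty, v))
  expect_error(neg_loglik(make_small_data(5, 3, "LM_GAP"), ty, v),
               "does not cover")
})

test_that("landmark-absent trials contribute independently of allocentrics", {
  dat <- rbind(make_small_data(30, seed = 4),
               make_small_data(30, seed = 5, cond = "LM_ABSENT"))
  ty <- tying_full(dataset_cells(dat))
  base <- neg_loglik(dat, ty, c(45, 180, 8, 0.05))
  moved <- neg_loglik(dat, ty, c(45, 300, 2, 0.05))
  # changing a_max / a_scale shifts only the landmark-trial term
  lm_only <- dat[dat$condition == "LM_PRESENT", ]
  ty_lm <- tying_full(dataset_cells(lm_only))
  expect_equal(base - moved,
               neg_loglik(lm_only, ty_lm, c(45, 180, 8, 0.05)) -
                 neg_loglik(lm_only, ty_lm, c(45, 300, 2, 0.05)))
})

test_that("with zero cost the cost model reproduces the base likelihood", {
  dat <- rbind(make_small_data(40, seed = 6),
               make_small_data(20, seed = 7, cond = "LM_ABSENT"))
  cells <- dataset_cells(dat)
  base <- param_tying(cells, p_ego = "shared", a_max = "shared",
                      a_scale = "shared", p_lapse = "shared")
  cost <- tying_cost(cells)
  v <- c(45, 180, 8, 0.05)
  expect_equal(neg_loglik(dat, cost, c(v, 0)), neg_loglik(dat, base, v))
})

test_that("the fitted optimum dominates the generating parameters", {
  dat <- rbind(make_small_data(300, seed = 8),
               make_small_data(60, seed = 9, cond = "LM_ABSENT"))
  ty <- tying_full(dataset_cells(dat))
  fit <- fit_observer(dat, ty, n_starts = 6, seed = 10)
  expect_s3_class(fit, "observer_fit")
  expect_lte(-fit$loglik, neg_loglik(dat, ty, c(45, 180, 8, 0.05)))
  # AICc identity on the result
  expect_equal(fit$aicc, -2 * fit$loglik + 2 * fit$k +
                 2 * fit$k * (fit$k + 1) / (fit$n - fit$k - 1))
  # deterministic given the seed
  fit2 <- fit_observer(dat, ty, n_starts = 6, seed = 10)
  expect_identical(fit$values, fit2$values)
  # p_ego recovered to first order on this modest sample
  expect_lt(abs(fit$values[["p_ego[ss4]"]] / 45 - 1), 0.35)
})

test_that("model nesting: the full model attains at least the reduced fit", {
  dat <- make_small_data(250, seed = 11)
  cells <- dataset_cells(dat)
  f_full <- fit_observer(dat, tying_full(cells), n_starts = 6, seed = 12)
  f_red <- fit_observer(dat, tying_reduced(cells), n_starts = 6, seed = 13)
  expect_gte(f_full$loglik, f_red$loglik - 1e-4)
  expect_lt(f_red$k, f_full$k)
})

test_that("a reduced fit on allocentric-free data recovers p_ego", {
  des <- generate_cell_design("LM_PRESENT", 4, 500, seed = 14)
  dat <- simulate_responses(des, model_params(45, 0, 0, 0.05), seed = 15,
                            participant = "S01")
  fit <- fit_observer(dat, tying_reduced(dataset_cells(dat)),
                      n_starts = 6, seed = 16)
  # +/- 3 asymptotic SE of a concentration estimate, sqrt(2/n) relative
  expect_lt(abs(fit$values[["p_ego[ss4]"]] / 45 - 1), 3 * sqrt(2 / 500))
})

test_that("AICc comparison is consistent across participants and variants", {
  dat <- make_small_data(150, seed = 17)
  cells <- dataset_cells(dat)
  f1 <- fit_observer(dat, tying_full(cells), n_starts = 4, seed = 18)
  f2 <- fit_observer(dat, tying_reduced(cells), n_starts = 4, seed = 19)
  expect_equal(compare_fits(list(f1), list(f1))$delta_aicc, 0)
  cmp <- compare_fits(list(f1), list(f2))
  # algebraic identity for nested variants on the same data
  expect_equal(cmp$delta_aicc,
               (-2 * f1$loglik + 2 * f1$k +
                  2 * f1$k * (f1$k + 1) / (f1$n - f1$k - 1)) -
                 (-2 * f2$loglik + 2 * f2$k +
                    2 * f2$k * (f2$k + 1) / (f2$n - f2$k - 1)))
  other <- fit_observer(
    transform(make_small_data(150, seed = 20), participant = "S02"),
    tying_full(cells), n_starts = 4, seed = 21)
  expect_error(compare_fits(list(f1), list(other)), "different participants")
  expect_equal(compare_fits(list(f1, other), list(f1, other),
                            method = "mean")$delta_aicc, 0)
})

test_that("set-size slopes and their t-test match hand-computed values", {
  est <- data.frame(participant = rep(1:3, each = 2),
                    set_size = rep(c(1, 2), 3),
                    value = c(0, 1, 0, 2, 0, 3))  # slopes 1, 2, 3
  tr <- setsize_trend(est)
  expect_equal(unname(tr$slopes), c(1, 2, 3))
  expect_equal(tr$mean, 2)
  expect_equal(tr$se, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(tr$t, 2 * sqrt(3), tolerance = 1e-12)  # 3.464
  expect_equal(tr$df, 2)
  expect_equal(tr$p, 2 * pt(-2 * sqrt(3), 2), tolerance = 1e-12)
  flat <- data.frame(participant = rep(1:3, each = 2),
                     set_size = rep(c(1, 2), 3), value = 5)
  tr0 <- setsize_trend(flat)
  expect_equal(tr0$mean, 0)
  expect_true(is.nan(tr0$t))
})

test_that("a declining precision trend is detected in a noisy cohort", {
  set.seed(22)
  est <- do.call(rbind, lapply(1:10, function(i)
    data.frame(participant = i, set_size = c(1, 2, 4),
               value = 100 - 18 * c(1, 2, 4) + rnorm(3, 0, 6))))
  tr <- setsize_trend(est)
  expect_lt(tr$p, 0.05)
  expect_lt(tr$mean, 0)
})

test_that("predicted cost is the proportional precision loss per doubling", {
  est <- data.frame(participant = rep(1:2, each = 3),
                    set_size = rep(c(1, 2, 4), 2),
                    p_ego = c(100, 80, 64, 100, 100, 100))
  pc <- predicted_cost(est)
  expect_equal(pc$mean, c(0.1, 0.1))  # mean of (0.2, 0) per pair
  expect_equal(pc$from, c(1, 2)); expect_equal(pc$to, c(2, 4))
  est$p_ego[1] <- 0
  expect_error(predicted_cost(est), "zero p_ego")
  expect_error(predicted_cost(est[est$set_size != 2, ]), "lacks set size")
})
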