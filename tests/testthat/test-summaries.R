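perfect_data <- function(n = 200, seed = 1, cond = "LM_PRESENT",
                         offset = 0) {
  des <- generate_cell_design(cond, 1, n, seed = seed)
  des$participant <- "S01"
  des$response_deg <- wrap_deg(des$target_deg + offset)
  des
}

test_that("on-target responses give zero bias and MAD in occupied bins", {
  s <- binned_summary(perfect_data(300, seed = 2))
  occ <- s[s$n > 0, ]
  expect_true(all(occ$bias_deg == 0))
  expect_true(all(occ$mad_deg == 0))
  expect_equal(nrow(s), 13)  # folded axis: centres 0, 15, ..., 180
})

test_that("a constant offset appears as pure bias under shift alignment", {
  dat <- perfect_data(300, seed = 3, cond = "LM_SHIFT", offset = 0)
  dat$response_deg <- wrap_deg(dat$target_deg + 5 * sign(dat$shift_deg))
  s <- binned_summary(dat, shift_align = TRUE)
  occ <- s[s$n > 0, ]
  expect_true(all(occ$bias_deg == 5))
  expect_true(all(occ$mad_deg == 0))
})

test_that("overlapping bins each count a trial twice on the folded axis", {
  dat <- perfect_data(500, seed = 4)
  s <- binned_summary(dat, fold = TRUE)
  expect_equal(sum(s$n), 2 * nrow(dat))
  s24 <- binned_summary(dat, fold = FALSE)
  expect_equal(nrow(s24), 24)
  expect_equal(sum(s24$n), 2 * nrow(dat))
})

test_that("landmark-absent data collapse to one pooled summary row", {
  dat <- rbind(perfect_data(60, seed = 5),
               perfect_data(60, seed = 6, cond = "LM_ABSENT"))
  s <- binned_summary(dat)
  ab <- s[s$condition == "LM_ABSENT", ]
  expect_equal(nrow(ab), 1)
  expect_true(is.na(ab$bin_center_deg))
  expect_equal(ab$n, 60)
})

test_that("empty bins are reported as missing values, not errors", {
  dat <- perfect_data(4, seed = 7)
  s <- binned_summary(dat)
  expect_true(any(s$n == 0))
  expect_true(all(is.na(s$bias_deg[s$n == 0])))
})

test_that("the shift-aligned bias curve is invariant to mirroring", {
  des <- generate_cell_design("LM_SHIFT", 4, 600, seed = 8)
  dat <- simulate_responses(des, default_params(4), seed = 9,
                            participant = "S01")
  s1 <- binned_summary(dat, shift_align = TRUE)
  flipped <- dat
  flipped$shift_deg <- -dat$shift_deg
  flipped$response_deg <- wrap_deg(dat$target_deg -
                                     wrap_deg(dat$response_deg -
                                                dat$target_deg))
  s2 <- binned_summary(flipped, shift_align = TRUE)
  expect_equal(s1$bias_deg, s2$bias_deg)
  expect_equal(s1$mad_deg, s2$mad_deg)
})

test_that("bootstrap intervals bracket the point estimates", {
  des <- generate_cell_design("LM_PRESENT", 4, 400, seed = 10)
  dat <- simulate_responses(des, default_params(4), seed = 11,
                            participant = "S01")
  s <- binned_summary(dat, boot = 200, seed = 12)
  occ <- s[s$n >= 20, ]
  expect_true(all(occ$bias_lo <= occ$bias_deg & occ$bias_deg <= occ$bias_hi))
  expect_true(all(occ$mad_lo <= occ$mad_deg & occ$mad_deg <= occ$mad_hi))
  expect_true(all(occ$mad_deg >= 0))
})

test_that("per-participant pooling averages participant medians", {
  dat <- rbind(perfect_data(100, seed = 13),
               transform(perfect_data(100, seed = 14), participant = "S02",
                         response_deg = wrap_deg(target_deg + 4)))
  s <- binned_summary(dat, pool = "participants")
  occ <- s[s$n > 0 & !is.na(s$bias_deg), ]
  # one participant unbiased, one biased by 4 degrees -> mean 2 where both
  both <- occ[occ$n >= 8, ]
  expect_true(all(abs(both$bias_deg) <= 4))
})

test_that("flat-model curves match the landmark-free prediction", {
  p0 <- model_params(45, 0, 0, 0.05)
  mc <- model_curves(p0, n_mc = 3e4, seed = 15)
  q <- rad2deg(predicted_mad(0, 0, p0))
  expect_lt(max(abs(mc$mad_deg - q)), 0.6)        # flat at the quadrature MAD
  mc0 <- model_curves(default_params(4), shift_deg = 0, n_mc = 3e4, seed = 16)
  expect_lt(max(abs(mc0$bias_deg), na.rm = TRUE), 0.6)  # no shift, no bias
})
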