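test_that("allocentric precision decays exponentially with distance", {
  expect_equal(allocentric_precision(0, 180, 8), 180)          # peak at d = 0
  expect_equal(allocentric_precision(2.2, 180, 0), 180)        # flat decay
  expect_equal(allocentric_precision(log(2) / 8, 180, 8), 90)  # half-life
  expect_equal(allocentric_precision(c(0, 1), 0, 8), c(0, 0))  # landmark off
  expect_error(allocentric_precision(-0.1, 180, 8), ">= 0")
  expect_error(allocentric_precision(1, -1, 8), "a_max")
})

test_that("cue integration weights by precision and sums precisions", {
  ego <- cue_estimate(0, 30)
  # single-cue identity
  r <- integrate_cues(ego, cue_estimate(1, 0))
  expect_equal(r$mu, 0); expect_equal(r$precision, 30)
  # equal-weight midpoint
  r <- integrate_cues(ego, cue_estimate(0.3, 30))
  expect_equal(r$mu, 0.15); expect_equal(r$precision, 60)
  # direct evaluation of the weighted-mean formulas
  r <- integrate_cues(cue_estimate(0, 30), cue_estimate(0.1047, 90))
  expect_equal(r$mu, 0.1047 * 90 / 120, tolerance = 1e-12)
  expect_equal(r$precision, 120)
  expect_error(integrate_cues(cue_estimate(0, 0), cue_estimate(1, 0)),
               "degenerate")
})

test_that("integration happens on the circle's local chart near the seam", {
  r <- integrate_cues(cue_estimate(pi - 0.05, 50), cue_estimate(-pi + 0.05, 50))
  expect_equal(r$mu, pi)  # midpoint across the seam, not the long way
})

test_that("fusion never hurts: integrated precision dominates both cues", {
  set.seed(3)
  for (i in 1:50) {
    p1 <- runif(1, 0, 100); p2 <- runif(1, 0, 100)
    r <- integrate_cues(cue_estimate(runif(1, -pi, pi), p1),
                        cue_estimate(runif(1, -pi, pi), max(p2, 1e-9)))
    expect_gte(r$precision, max(p1, p2))
  }
  r <- integrate_cues(cue_estimate(0.4, 25), cue_estimate(0, 0))
  expect_equal(r$precision, 25)  # equality iff the other precision is zero
})

test_that("the allocentric mean follows a shifted landmark and wraps", {
  expect_equal(allo_mean(1.1, 0), 1.1)
  expect_equal(allo_mean(0.5, deg2rad(6)), 0.5 + 0.1047198, tolerance = 1e-6)
  expect_equal(allo_mean(pi - 0.01, 0.02), -pi + 0.01)
})

test_that("the response density is a normalized lapse-contaminated mixture", {
  p <- model_params(45, 180, 8, p_lapse = 1)
  expect_equal(response_logpdf(c(-2, 0, 3), 0, p, d = 0.2),
               rep(log(1 / (2 * pi)), 3))
  set.seed(11)
  for (i in 1:20) {
    expect_equal(grid_density_integral(rparams(), d = runif(1, 0, pi),
                                       shift = runif(1, -0.2, 0.2)),
                 1, tolerance = 1e-6)
  }
  expect_error(response_logpdf(NA, 0, rparams()), "non-finite")
})

test_that("at high precision the von Mises approaches the Gaussian", {
  gap_at_mode <- sapply(c(50, 200, 1e4), function(P) {
    p <- model_params(P, 0, 0, 0)
    abs(response_logpdf(0, 0, p, allo_active = FALSE) -
          dnorm(0, 0, 1 / sqrt(P), log = TRUE))
  })
  expect_true(all(diff(gap_at_mode) < 0))   # shrinks with precision
  expect_lt(gap_at_mode[3], 1e-4)
  p <- model_params(50, 0, 0, 0)
  x <- seq(-3 / sqrt(50), 3 / sqrt(50), length.out = 9)
  expect_lt(max(abs(response_logpdf(x, 0, p, allo_active = FALSE) -
                      dnorm(x, 0, 1 / sqrt(50), log = TRUE))), 0.1)
})

test_that("predicted bias equals the precision-weighted share of the shift", {
  p <- model_params(50, 50, 5, 0.05)
  s <- deg2rad(6)
  expect_equal(predicted_bias(0.7, 0, p), 0)
  expect_equal(predicted_bias(0, s, p), s / 2)  # equal weights at d = 0
  d <- seq(0, pi, length.out = 20)
  b <- predicted_bias(d, s, p)
  expect_true(all(b >= 0 & b <= s))
  expect_true(all(diff(b) <= 0))        # non-increasing in distance
  expect_equal(sign(predicted_bias(0.3, -s, p)), -1)
})

test_that("predicted MAD is monotone in distance with the landmark-free limit", {
  p <- model_params(45, 180, 8, 0.05)
  d <- c(0, 0.3, 0.8, 2, pi)
  m <- predicted_mad(d, 0, p)
  expect_true(all(diff(m) > -1e-12))
  # allocentric-free limit: pure von Mises MAD, independent of d
  p0 <- model_params(45, 0, 0, 0)
  m0 <- predicted_mad(c(0.1, 2.5), 0, p0)
  expect_equal(m0[1], m0[2])
  psteep <- model_params(45, 180, 60, 0.05)
  expect_equal(predicted_mad(pi, 0, psteep),
               predicted_mad(pi, 0, model_params(45, 0, 0, 0.05)),
               tolerance = 1e-6)
})

test_that("Monte-Carlo and quadrature MAD agree within sampling error", {
  set.seed(21)
  for (i in 1:5) {
    p <- rparams()
    d <- runif(1, 0, pi)
    q <- predicted_mad(d, 0, p)
    mc <- predicted_mad(d, 0, p, method = "mc", n_mc = 4e4, seed = 100 + i)
    kap <- p$p_ego + allocentric_precision(d, p$a_max, p$a_scale)
    x <- abs(.sample_dev(4e4, kap, p$p_lapse, seed = 200 + i))
    expect_lt(abs(q - mc), 3 * boot_se_median(x))
  }
})
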