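test_that("correlation curve basics: straight traces and right angles", {
  tr <- trace_result(cbind(seq(0, 80, 8), 0), 8, FALSE)
  cc <- tangent_correlation(list(tr), 40)
  expect_identical(cc$mean_corr[1], 1)
  expect_true(all(abs(cc$mean_corr - 1) < 1e-12))
  # open trace: pair counts non-increasing with separation
  expect_true(all(diff(cc$n_pairs) <= 0))
  sq <- trace_result(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)), 10, TRUE)
  cs <- tangent_correlation(list(sq), 20)
  expect_equal(cs$mean_corr[cs$sep_nm == 10], 0, tolerance = 1e-12)
  expect_error(tangent_correlation(list(), 40), "no traces")
  tr2 <- trace_result(cbind(seq(0, 80, 10), 0), 10, FALSE)
  expect_error(tangent_correlation(list(tr, tr2), 40), "same step")
})

test_that("noiseless exponential curves invert exactly", {
  L <- seq(0, 120, 8)
  cv <- correlation_curve(L, exp(-L / 112), step_nm = 8)
  fit <- fit_persistence_length(cv, c(8, 120))
  expect_equal(fit$lp, 56, tolerance = 1e-6)
  expect_lt(fit$residual_rms, 1e-9)
  # scale consistency: rescaling separations rescales Lp
  cv2 <- correlation_curve(3 * L, exp(-L / 112), step_nm = 24)
  fit2 <- fit_persistence_length(cv2, c(24, 360))
  expect_equal(fit2$lp, 3 * 56, tolerance = 1e-6)
})

test_that("a constant offset shows up in the fit residuals", {
  L <- seq(0, 120, 8)
  y <- pmin(1, exp(-L / 112) + 0.01)
  fit <- fit_persistence_length(correlation_curve(L, y, 8), c(8, 120))
  # oracle: grid search over lp for the least-squares residual RMS
  idx <- L >= 8
  rms_or <- function(lp) sqrt(mean((y[idx] - exp(-L[idx] / (2 * lp)))^2))
  grid <- seq(40, 80, by = 0.01)
  best <- min(vapply(grid, rms_or, numeric(1)))
  expect_equal(fit$residual_rms, best, tolerance = 1e-3)
  expect_lt(fit$residual_rms, 0.01)   # bounded by the perturbation
  expect_gt(fit$residual_rms, 0.001)  # but clearly nonzero
})

test_that("the fit validates its inputs", {
  L <- seq(0, 120, 8)
  cv <- correlation_curve(L, exp(-L / 112), 8)
  expect_error(fit_persistence_length(cv, c(8, 20)), ">= 4")
})

test_that("generated ensembles recover Lp through the correlation fit", {
  traces <- native_wlc_traces(n_chains = 300, n_segments = 114, seg_len = 8,
                              lp = 56)
  fit <- fit_persistence_length(tangent_correlation(traces, 112), c(8, 112))
  expect_lt(abs(fit$lp - 56) / 56, 0.05)
})

test_that("bending angle distributions are signed, normalized and sharp for kinks", {
  straight <- trace_result(cbind(seq(0, 80, 8), 0), 8, FALSE)
  ad <- bending_angle_distribution(list(straight), 8)
  expect_true(all(ad$angles == 0))
  # histogram integrates to 1
  expect_equal(sum(ad$density * diff(ad$breaks)), 1, tolerance = 1e-12)
  # kinked fixture: two straight arms joined at 90 degrees
  kink <- trace_result(rbind(cbind(seq(-40, 0, 8), 0),
                             cbind(0 * seq(8, 40, 8), seq(8, 40, 8))),
                       8, FALSE)
  adk <- bending_angle_distribution(list(kink), 8)
  expect_true(any(abs(abs(adk$angles) - pi / 2) < 1e-9))
  # the right-angle mass is essentially absent from a WLC ensemble at Lp 56
  traces <- native_wlc_traces(300, 114, 8, 56)
  adw <- bending_angle_distribution(traces, 8)
  near_right <- function(a) mean(abs(abs(a) - pi / 2) < 0.05)
  expect_lt(near_right(adw$angles), 1e-3)
  expect_gt(near_right(adk$angles), 0.1)
})

test_that("non-multiple separations are handled by re-resampling", {
  traces <- native_wlc_traces(300, 114, 8, 56)
  ad <- bending_angle_distribution(traces[1:50], separation_nm = 10)
  expect_equal(ad$separation_nm, 10)
  expect_gt(length(ad$angles), 1000)
  # variance close to the chord-tangent expectation (L - step/3)/Lp
  expect_equal(var(ad$angles), (10 - 10 / 3) / 56, tolerance = 0.15)
})

test_that("contour statistics match hand arithmetic", {
  t1 <- trace_result(cbind(seq(0, 328, 8), 0), 8, FALSE)
  s2 <- 332 / 41
  t2 <- trace_result(cbind(seq(0, 332, by = s2), 0), s2, FALSE)
  cls <- contour_length_stats(list(t1, t2))
  expect_equal(cls$mean_nm, 330, tolerance = 1e-9)
  expect_equal(cls$sd_nm, sd(c(328, 332)), tolerance = 1e-9)
  expect_error(contour_length_stats(list(t1)), ">= 2")
  expect_equal(percent_change(347, 328), 5.79, tolerance = 0.01)
  expect_equal(round(percent_change(347, 328)), 6)
  expect_equal(percent_change(330, 2 * 165), 0)
})

test_that("bootstrap CI is degenerate for identical traces and validates n_boot", {
  tr <- native_wlc_traces(300, 114, 8, 56)[[1]]
  same <- replicate(6, tr, simplify = FALSE)
  bs <- bootstrap_lp(same, n_boot = 20, seed = 1, max_sep_nm = 112)
  expect_equal(diff(bs$ci), 0, tolerance = 1e-9)
  expect_error(bootstrap_lp(same, n_boot = 1), ">= 10")
  expect_error(bootstrap_lp(same[1:3], n_boot = 20), ">= 5")
})

test_that("bootstrap CI covers the true Lp across repeated experiments", {
  traces <- native_wlc_traces(600, 114, 8, 56, seed = 900)
  hits <- 0L; meta <- 20L
  for (r in seq_len(meta)) {
    sub <- traces[((r - 1) * 30 + 1):(r * 30)]
    bs <- bootstrap_lp(sub, n_boot = 25, fit_range = c(8, 112), seed = r,
                       max_sep_nm = 112)
    if (bs$ci[1] <= 56 && 56 <= bs$ci[2]) hits <- hits + 1L
  }
  expect_gte(hits / meta, 0.9)
})
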