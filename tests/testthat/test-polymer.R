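test_that("open WLC sampler honours its construction invariants", {
  p <- sample_wlc_2d(164, 2, 56, seed = 11)
  g <- afmwlc:::segment_geometry(p$vertices)
  expect_equal(nrow(p$vertices), 165)
  # uniform segment length and exact contour
  expect_lt(diff(range(g$len)) / 2, 1e-9)
  expect_equal(sum(g$len), p$true_contour, tolerance = 1e-9)
  expect_equal(p$true_contour, 328)
  # deterministic under the seed
  p2 <- sample_wlc_2d(164, 2, 56, seed = 11)
  expect_identical(p$vertices, p2$vertices)
  p3 <- sample_wlc_2d(164, 2, 56, seed = 12)
  expect_false(identical(p$vertices, p3$vertices))
})

test_that("infinite-stiffness limit gives a straight chain", {
  p <- sample_wlc_2d(100, 2, 1e12, seed = 3)
  ee <- sqrt(sum((p$vertices[101, ] - p$vertices[1, ])^2))
  expect_equal(ee, 200, tolerance = 1e-6)
})

test_that("sampler rejects bad parameters", {
  expect_error(sample_wlc_2d(10, 2, -5, 1), "positive")
  expect_error(sample_wlc_2d(10, -1, 56, 1), "positive")
  expect_error(sample_wlc_2d(10, 20, 56, 1), "seg_len <= lp / 4")
  expect_error(sample_closed_wlc_2d(8, 2, 56, 1), ">= 16")
})

test_that("tangent correlation of the generated ensemble follows exp(-L/2Lp)", {
  traces <- native_wlc_traces(n_chains = 300, n_segments = 114, seg_len = 8,
                              lp = 56)
  curve <- tangent_correlation(traces, max_sep_nm = 112)
  for (i in seq_along(curve$sep_nm)) {
    L <- curve$sep_nm[i]
    if (L == 0) { expect_identical(curve$mean_corr[i], 1); next }
    expect_lt(abs(curve$mean_corr[i] - exp(-L / 112)), 3 * curve$se[i])
  }
})

test_that("net bending-angle variance over separation L equals L/Lp", {
  traces <- native_wlc_traces(n_chains = 300, n_segments = 114, seg_len = 8,
                              lp = 56)
  for (L in c(8, 16, 24)) {
    # mean-square angle about the known zero mean, per molecule: unbiased
    # despite overlapping windows; the CLT across molecules gives the s.e.
    vs <- vapply(traces, function(tr)
      mean(bending_angle_distribution(list(tr), separation_nm = L)$angles^2),
      numeric(1))
    se_v <- sd(vs) / sqrt(length(vs))
    expect_lt(abs(mean(vs) - L / 56), 3 * se_v)
  }
})

test_that("closed WLC sampler yields uniform, exactly closed simple chains", {
  p <- sample_closed_wlc_2d(428, 2, 56, seed = 5)
  g <- afmwlc:::segment_geometry(p$vertices)
  expect_true(p$closed)
  # first and last vertices coincide; spacings uniform; contour exact
  expect_lt(max(abs(p$vertices[1, ] - p$vertices[429, ])), 1e-6)
  expect_lt(diff(range(g$len[g$len > 1e-9])) / 2, 1e-9 * 2)
  expect_equal(p$true_contour, 856)
  expect_equal(sum(g$len), 856, tolerance = 1e-6)
  # turning angles of a simple closed curve sum to +/- 2*pi
  expect_equal(abs(sum(polymer_turning_angles(p))), 2 * pi, tolerance = 1e-6)
  # deterministic
  p2 <- sample_closed_wlc_2d(428, 2, 56, seed = 5)
  expect_identical(p$vertices, p2$vertices)
})

test_that("stiff-limit closed chain is a regular polygon", {
  p <- sample_closed_wlc_2d(16, 2, 1e12, seed = 2)
  g <- afmwlc:::segment_geometry(p$vertices)
  ta <- polymer_turning_angles(p)
  expect_equal(unname(ta), rep(2 * pi / 16, 16), tolerance = 1e-4)
  expect_lt(diff(range(g$len)) / 2, 1e-6)
})

test_that("closed-chain ensemble preserves the constructed contour length", {
  lens <- vapply(1:25, function(i)
    polymer_contour_length(sample_closed_wlc_2d(107, 8, 56, seed = 400 + i)),
    numeric(1))
  expect_lt(abs(mean(lens) - 856) / 856, 0.005)
})
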