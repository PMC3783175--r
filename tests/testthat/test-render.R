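test_that("rendered straight ridge matches the analytic blurred Gaussian", {
  img <- straight_rod_image(328, noise = 0)
  pr <- render_params(ridge_height_nm = preblur_ridge_height(0.6),
                      noise_sd_nm = 0)
  eff <- effective_ridge_height(pr)
  expect_equal(eff, 0.6, tolerance = 1e-12)
  # transverse profile through an interior column is Gaussian with width
  # sqrt(sigma_r^2 + sigma_t^2) about the rendered (translated) line
  y0 <- attr(img, "vertices_nm")[1, 2]
  sig <- sqrt(pr$ridge_sigma_nm^2 + pr$tip_sigma_nm^2)
  j <- ncol(img$heights) %/% 2
  col <- img$heights[, j]
  i0 <- which.max(col)
  for (i in (i0 - 3):(i0 + 3)) {
    off <- (i - 0.5) * img$pixel_nm - y0
    expected <- eff * exp(-off^2 / (2 * sig^2))
    expect_equal(col[i], expected, tolerance = 0.02 * eff)
  }
  # maximum of the image equals the effective peak sampled at the pixel
  # nearest the ridge center, within 1%
  d0 <- min(abs((seq_len(nrow(img$heights)) - 0.5) * img$pixel_nm - y0))
  expect_lt(abs(max(img$heights) - eff * exp(-d0^2 / (2 * sig^2))) / eff,
            0.01)
})

test_that("rendering is deterministic and validates its inputs", {
  pr <- bare_params()
  p <- sample_wlc_2d(100, 2, 56, seed = 4)
  a <- render_afm(p, pr, seed = 9)
  b <- render_afm(p, pr, seed = 9)
  expect_identical(a$heights, b$heights)
  c <- render_afm(p, pr, seed = 10)
  expect_false(identical(a$heights, c$heights))
  expect_error(render_afm(matrix(numeric(0), 0, 2), pr, 1), "2 vertices")
  big <- rbind(c(0, 0), c(5000, 0))   # longer than the 1024 nm field
  expect_error(render_afm(big, pr, 1), "does not fit")
})

test_that("noise and background particles behave as configured", {
  pr <- render_params(ridge_height_nm = 0.85, noise_sd_nm = 0.05,
                      image_shape = c(256L, 256L))
  img <- render_afm(rbind(c(0, 0), c(100, 0)), pr, seed = 3)
  corner <- img$heights[1:60, 1:60]   # far from the ridge
  expect_equal(sd(as.numeric(corner)), 0.05, tolerance = 0.1)
  prb <- render_params(ridge_height_nm = 0.85, noise_sd_nm = 0,
                       background_particles = 5, image_shape = c(256L, 256L))
  imgb <- render_afm(rbind(c(0, 0), c(100, 0)), prb, seed = 3)
  img0 <- render_afm(rbind(c(0, 0), c(100, 0)),
                     render_params(ridge_height_nm = 0.85, noise_sd_nm = 0,
                                   image_shape = c(256L, 256L)), seed = 3)
  expect_gt(sum(imgb$heights - img0$heights), 0)  # dots add height
})

test_that("render parameter validation enforces the physical ranges", {
  expect_error(render_params(ridge_height_nm = 0.1), "\\[0.3, 3\\]")
  expect_error(render_params(ridge_height_nm = 5), "\\[0.3, 3\\]")
  expect_error(render_params(pixel_nm = -1), "positive")
  expect_error(render_params(noise_sd_nm = -0.1), "non-negative")
})
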