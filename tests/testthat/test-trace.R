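test_that("a straight rod traces to its true length with subpixel accuracy", {
  img <- straight_rod_image(328, noise = 0)
  rg <- segment_molecules(img, height_band = c(0.6, 0.6))[[1]]
  tr <- trace_backbone(img, rg, 8)
  expect_lt(abs(measure_contour_length(tr) - 328) / 328, 0.02)
  # points lie on the true line to < 0.2 px RMS (subpixel refinement)
  y0 <- mean(tr$points[, 2])
  rms <- sqrt(mean((tr$points[, 2] - y0)^2))
  expect_lt(rms, 0.2 * img$pixel_nm)
  # spacings uniform within 5% (final partial segment excepted)
  sp <- sqrt(rowSums(diff(tr$points)^2))
  expect_true(all(abs(sp[-length(sp)] - 8) / 8 < 0.05))
})

test_that("a quarter-circle arc traces to the right curvature", {
  R <- 100
  th <- seq(0, pi / 2, length.out = 200)
  arc <- cbind(R * cos(th), R * sin(th))
  pr <- bare_params(noise = 0)
  img <- render_afm(arc, pr, seed = 1)
  rg <- segment_molecules(img, height_band = c(0.6, 0.6))[[1]]
  tr <- trace_backbone(img, rg, 8)
  # mean turning angle per 8-nm step = step / R
  g <- afmwlc:::segment_geometry(tr$points)
  phi <- atan2(g$vec[, 2], g$vec[, 1])
  kappa <- mean(abs(diff(phi))) / 8
  expect_lt(abs(kappa - 1 / R) * R, 0.05)
})

test_that("traced length is rotation-invariant and skeleton-consistent", {
  p <- sample_wlc_2d_clear(164, 2, 56, seed = 21, min_clearance_nm = 12)
  img <- render_afm(p, bare_params(noise = 0), seed = 2)
  rg <- segment_molecules(img, height_band = c(0.6, 0.6))[[1]]
  L1 <- measure_contour_length(trace_backbone(img, rg, 8))
  rot <- afm_image(t(img$heights)[ncol(img$heights):1, ], img$pixel_nm)
  rgr <- segment_molecules(rot, height_band = c(0.6, 0.6))[[1]]
  L2 <- measure_contour_length(trace_backbone(rot, rgr, 8))
  expect_lt(abs(L1 - L2) / L1, 0.01)
  # traced length never exceeds the skeletal path length by more than 5%
  expect_lt(L1, 1.05 * rg$skel_len_nm + 16)
})

test_that("tracing is idempotent under re-rendering", {
  p <- sample_wlc_2d_clear(164, 2, 56, seed = 31, min_clearance_nm = 12)
  pr <- bare_params(noise = 0)
  img <- render_afm(p, pr, seed = 3)
  rg <- segment_molecules(img, height_band = c(0.6, 0.6))[[1]]
  tr <- trace_backbone(img, rg, 8)
  img2 <- render_afm(tr$points, pr, seed = 3)
  rg2 <- segment_molecules(img2, height_band = c(0.6, 0.6))[[1]]
  tr2 <- trace_backbone(img2, rg2, 8)
  # lateral RMS of the retrace about the rendered input polyline < 1 px
  # (render recenters, so compare against the translated vertices)
  v2 <- attr(img2, "vertices_nm")
  pt_polyline_dist <- function(q, poly) {
    a <- poly[-nrow(poly), , drop = FALSE]
    v <- diff(poly)
    t <- pmin(1, pmax(0, ((q[1] - a[, 1]) * v[, 1] +
                          (q[2] - a[, 2]) * v[, 2]) / rowSums(v^2)))
    min(sqrt((a[, 1] + t * v[, 1] - q[1])^2 +
             (a[, 2] + t * v[, 2] - q[2])^2))
  }
  d <- vapply(seq_len(nrow(tr2$points)), function(i)
    pt_polyline_dist(tr2$points[i, ], v2), numeric(1))
  expect_lt(sqrt(mean(d^2)), img$pixel_nm)
})

test_that("contour length measures simple figures exactly", {
  sq <- trace_result(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)), 10, TRUE)
  expect_equal(measure_contour_length(sq), 40)
  line <- trace_result(cbind(seq(0, 24, 8), 0), 8, FALSE)
  expect_equal(measure_contour_length(line), 24)
})

test_that("height profiling recovers rendered heights and their ratio", {
  img <- straight_rod_image(328, noise = 0)
  rg <- segment_molecules(img, height_band = c(0.6, 0.6))[[1]]
  tr <- trace_backbone(img, rg, 8)
  hp <- height_profile(img, tr, n_positions = 50, seed = 5)
  expect_lt(abs(hp$mean_nm - 0.6) / 0.6, 0.02)
  expect_error(height_profile(img, tr, n_positions = 0), ">= 1")
  # deterministic under the seed
  hp2 <- height_profile(img, tr, n_positions = 50, seed = 5)
  expect_identical(hp$samples, hp2$samples)
  # coated filament images ~1.67x higher than bare DNA
  imgc <- straight_rod_image(328, noise = 0, height_nm = 1.0)
  rgc <- segment_molecules(imgc, height_band = c(1.0, 1.0))[[1]]
  trc <- trace_backbone(imgc, rgc, 8)
  hpc <- height_profile(imgc, trc, n_positions = 50, seed = 5)
  expect_equal(hpc$mean_nm / hp$mean_nm, 1.0 / 0.6, tolerance = 0.05)
})

test_that("tracing rejects branched and too-short regions", {
  pr <- bare_params(noise = 0)
  a <- render_afm(rbind(c(-100, 0), c(100, 0)), pr, seed = 1)
  b <- render_afm(rbind(c(0, -100), c(0, 100)), pr, seed = 1)
  x <- afm_image(pmax(a$heights, b$heights), a$pixel_nm)
  rg <- segment_molecules(x, height_band = c(0.6, 0.6))[[1]]
  expect_error(trace_backbone(x, rg, 8), "linear or circular")
  rg$class_hint <- "linear"
  expect_error(trace_backbone(x, rg, 8), "endpoints")
})
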