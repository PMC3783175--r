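test_that("segmentation finds and classes single molecules", {
  img <- straight_rod_image(328, noise = 0.05)
  regs <- segment_molecules(img, height_band = c(0.6, 0.6))
  expect_length(regs, 1)
  expect_equal(regs[[1]]$class_hint, "linear")
  expect_equal(regs[[1]]$n_endpoints, 2)
  expect_equal(regs[[1]]$area_nm2, sum(regs[[1]]$mask) * 4)

  pc <- sample_closed_wlc_2d(428, 2, 56, seed = 5, min_clearance_nm = 12)
  imgc <- render_afm(pc, bare_params(), seed = 6)
  regc <- segment_molecules(imgc, height_band = c(0.6, 0.6))
  expect_length(regc, 1)
  expect_equal(regc[[1]]$class_hint, "circular")
  expect_equal(regc[[1]]$n_endpoints, 0)
})

test_that("compacted particles are classed compact, crossings rejected", {
  cp <- generate_compact(seed = 3, params = bare_params())
  regs <- segment_molecules(cp$image, height_band = c(0.6, 0.6))
  expect_length(regs, 1)
  expect_equal(regs[[1]]$class_hint, "compact")
  expect_gt(regs[[1]]$mean_height_nm, 1.2)

  # two crossing rods merge into one branched component -> reject
  pr <- bare_params(noise = 0)
  a <- render_afm(rbind(c(-100, 0), c(100, 0)), pr, seed = 1)
  b <- render_afm(rbind(c(0, -100), c(0, 100)), pr, seed = 1)
  x <- afm_image(pmax(a$heights, b$heights), a$pixel_nm)
  regs <- segment_molecules(x, height_band = c(0.6, 0.6))
  expect_length(regs, 1)
  expect_equal(regs[[1]]$class_hint, "reject")
  expect_gt(regs[[1]]$n_endpoints, 2)
})

test_that("blank images and border-touching molecules yield no regions", {
  blank <- afm_image(matrix(0.01, 128, 128), 2)
  expect_length(segment_molecules(blank, height_band = c(0.6, 0.6)), 0)
  pr <- render_params(ridge_height_nm = 0.85, noise_sd_nm = 0,
                      image_shape = c(64L, 64L))
  # rod rendered then shifted to touch the border
  img <- render_afm(rbind(c(0, 0), c(100, 0)), pr, seed = 1)
  shifted <- afm_image(img$heights[, c(33:64, 1:32)], img$pixel_nm)
  H <- shifted$heights
  H[, 1] <- pmax(H[, 1], 0.5)       # force border contact
  expect_length(segment_molecules(afm_image(H, 2),
                                  height_band = c(0.6, 0.6),
                                  thresh_nm = 0.3), 0)
})

test_that("thinning reduces a thick band to a unit-width skeleton", {
  m <- matrix(FALSE, 40, 40)
  m[18:22, 5:35] <- TRUE
  S <- skeletonize_mask(m)
  expect_true(all(which(S, arr.ind = TRUE)[, 1] %in% 18:22))
  # one path: two endpoints, no branch pixels
  expect_equal(sum(S & afmwlc:::skel_degree(S) == 1), 2)
  expect_equal(sum(afmwlc:::skel_crossing(S) >= 3), 0)
  # skeletal length: the band length minus blunt-end erosion of at most
  # one band half-width per end
  expect_gte(afmwlc:::skel_length_px(S), 31 - 6)
  expect_lte(afmwlc:::skel_length_px(S), 31)
})
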