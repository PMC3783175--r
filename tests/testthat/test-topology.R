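test_that("the four morphology classes are recognized", {
  pr <- bare_params()
  p <- sample_wlc_2d_clear(164, 2, 56, seed = 9, min_clearance_nm = 12)
  img <- render_afm(p, pr, seed = 1)
  tp <- classify_topology(img, segment_molecules(img,
                          height_band = c(0.6, 0.6))[[1]], 0.6)
  expect_equal(tp$class, "linear")
  expect_false(is.na(tp$contour_nm))

  pc <- sample_closed_wlc_2d(428, 2, 56, seed = 5, min_clearance_nm = 12)
  imgc <- render_afm(pc, pr, seed = 2)
  tpc <- classify_topology(imgc, segment_molecules(imgc,
                           height_band = c(0.6, 0.6))[[1]], 0.6)
  expect_equal(tpc$class, "open_circle")

  pl <- generate_plectoneme(860, 0.42, seed = 4,
                            params = bare_params())
  tpp <- classify_topology(pl$image, segment_molecules(pl$image,
                           height_band = c(0.6, 0.6))[[1]], 0.6,
                           contour_nm = 860)
  expect_equal(tpp$class, "plectoneme")
  expect_lt(abs(tpp$axis_nm - pl$axis_nm) / pl$axis_nm, 0.1)
  expect_equal(tpp$axis_ratio, round(tpp$axis_nm / 860, 2))

  cp <- generate_compact(seed = 3, params = bare_params())
  tpk <- classify_topology(cp$image, segment_molecules(cp$image,
                           height_band = c(0.6, 0.6))[[1]], 0.6)
  expect_equal(tpk$class, "compact")
})

test_that("superhelical axis measurement is accurate and guarded", {
  pr <- bare_params(noise = 0)
  rod <- render_afm(rbind(c(0, 0), c(100, 0)), pr, seed = 2,
                    height_scale = 2)
  rg <- segment_molecules(rod, height_band = c(0.6, 0.6))[[1]]
  rg$class_hint <- "plectoneme"
  expect_equal(measure_superhelical_axis(rod, rg, 0.6), 100,
               tolerance = 0.05)
  rg$class_hint <- "circular"
  expect_error(measure_superhelical_axis(rod, rg, 0.6), "plectoneme")
  # construction truth: 860 * 0.42 = 361.2
  pl <- generate_plectoneme(860, 0.42, seed = 1)
  expect_equal(pl$axis_nm, 361.2)
  expect_error(generate_plectoneme(860, 0.1), "0.2, 0.5")
})

test_that("axis-to-contour ratio is exact arithmetic and scale invariant", {
  expect_identical(axis_to_contour_ratio(360, 860), 0.42)
  expect_identical(axis_to_contour_ratio(7, 7), 1)
  for (c_ in c(1, 13.7, 1e4))
    expect_identical(axis_to_contour_ratio(0.41 * c_, c_), 0.41)
  expect_error(axis_to_contour_ratio(-1, 10), "positive")
  expect_error(axis_to_contour_ratio(10, 0), "positive")
})

test_that("unwinding bookkeeping obeys White's relation exactly", {
  # no binding: all changes zero
  z <- unwinding_model(1000)
  expect_true(z$linking$d_tw == 0)
  expect_true(z$linking$wr == 0)
  expect_true(z$extension_fraction == 0)
  # near-full occupancy of 1000 bp: 111 dimers x 9 bp; a 0.02 nm/bp rise
  # change gives the ~6% contour extension
  m <- unwinding_model(1000, n_bound_dimers = 111, unwind_deg_per_dimer = 12,
                       d_rise_nm_per_bound_bp = 0.02)
  expect_equal(m$extension_fraction, 0.999 * 0.02 / 0.34, tolerance = 1e-12)
  expect_equal(round(100 * m$extension_fraction), 6)
  # closed chain: dLk = 0 and twist converts to writhe with positive sign
  expect_true(m$linking$d_lk == 0)
  expect_equal(m$linking$wr, -m$linking$d_tw, tolerance = 0)
  expect_gt(m$linking$wr, 0)
  # White's identity to machine precision over a parameter grid
  for (nd in c(0, 10, 50, 111)) for (deg in c(0, 5, 26)) for (cl in c(TRUE, FALSE)) {
    s <- unwinding_model(1000, n_bound_dimers = nd,
                         unwind_deg_per_dimer = deg, closed = cl)$linking
    expect_true(s$d_lk - s$d_tw - s$wr == 0)
  }
  expect_error(unwinding_model(1000, n_bound_dimers = 150), "occupancy")
  expect_error(linking_state(1000, 10.5, d_tw = -1, wr = 0.5, d_lk = 0),
               "White")
})

test_that("extension is linear in occupancy and rise change", {
  base <- unwinding_model(2686, n_bound_dimers = 100,
                          d_rise_nm_per_bound_bp = 0.02)$extension_fraction
  expect_equal(unwinding_model(2686, n_bound_dimers = 200,
                               d_rise_nm_per_bound_bp = 0.02)$extension_fraction,
               2 * base, tolerance = 1e-12)
  expect_equal(unwinding_model(2686, n_bound_dimers = 100,
                               d_rise_nm_per_bound_bp = 0.04)$extension_fraction,
               2 * base, tolerance = 1e-12)
  # relaxed circle bookkeeping: Lk0 = n_bp / pitch
  expect_equal(unwinding_model(2686)$linking$lk0, 2686 / 10.5)
})
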