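test_that("slit wall shear reproduces the device estimates", {
  ## 6 eta Q / (w h^2): the experimental 0.10 / 0.20 Pa anchors
  expect_equal(slit_wall_shear(0.5, 200, 50, 1e-3), 0.10, tolerance = 1e-9)
  expect_equal(slit_wall_shear(1.0, 200, 50, 1e-3), 0.20, tolerance = 1e-9)
  expect_equal(slit_wall_shear(0, 200, 50, 1e-3), 0)
  expect_error(slit_wall_shear(0.5, -200, 50, 1e-3), "positive")
  expect_warning(slit_wall_shear(0.5, 60, 50, 1e-3), "aspect")
})

test_that("rectangular-duct series has the expected integral properties", {
  p <- rect_duct_profile(0.5, 200, 50)
  ## mean velocity from unit conversion: 0.5 uL/min over 200x50 um^2
  expect_equal(attr(p, "mean_mm_s"), 0.83333, tolerance = 1e-4)
  ## profile symmetric about the channel center
  expect_equal(p$v_mm_s, rev(p$v_mm_s), tolerance = 1e-10)
  ## series truncation is reported and tiny
  expect_lt(attr(p, "truncation"), 1e-6)
  ## slit limit: centerline/mean -> 3/2 as w/h grows
  ps <- rect_duct_profile(0.5, 25000, 50)
  expect_equal(attr(ps, "centerline_mid") / attr(ps, "mean_mm_s"), 1.5,
               tolerance = 5e-3)
  ## depth-averaged variant integrates to the same flow rate
  pd <- rect_duct_profile(0.5, 200, 50, n_bins = 400, at = "depth_averaged")
  flux <- mean(pd$v_mm_s) * 1e-3 * (200e-6 * 50e-6) / (1e-9 / 60) # uL/min
  expect_equal(flux, 0.5, tolerance = 2e-3)
})

test_that("wall-gradient shear estimator is exact on a parabola", {
  prof <- slit_depth_profile(0.5, 200, 50)
  expect_equal(shear_from_profile(prof, 1e-3), 0.10, tolerance = 1e-9)
  expect_equal(shear_from_profile(slit_depth_profile(1.0, 200, 50), 1e-3),
               0.20, tolerance = 1e-9)
  ## doubling Q doubles tau for a Newtonian fluid (linearity)
  expect_equal(shear_from_profile(slit_depth_profile(0.7, 200, 50), 1e-3) /
                 shear_from_profile(slit_depth_profile(0.35, 200, 50), 1e-3),
               2, tolerance = 1e-9)
  ## uniform plug profile has zero wall gradient
  plug <- vesselflow:::velocity_profile_obj((1:25 - 0.5) * 2, rep(1, 25),
                                            span = 50, axis = "depth")
  expect_equal(shear_from_profile(plug, 1e-3), 0, tolerance = 1e-12)
  ## too-sparse profiles are refused
  sparse <- vesselflow:::velocity_profile_obj(c(24, 25), c(1, 1), span = 50)
  expect_error(shear_from_profile(sparse, 1e-3), "sparse")
})
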