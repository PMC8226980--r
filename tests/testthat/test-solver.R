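test_that("planform solve conserves flux through every cross-section", {
  f <- fx_straight_field()
  set.seed(7)
  s0 <- runif(10, 50, 550)
  flux <- vapply(s0, function(s) section_flux(f, s), 0)
  expect_true(all(abs(flux / 0.5 - 1) < 0.005))
})

test_that("Newtonian planform profile matches the duct series", {
  f <- fx_fine_field()
  prof <- field_profile(f)
  ref <- rect_duct_profile(0.5, 200, 50, n_bins = nrow(prof),
                           at = "depth_averaged")
  ## centerline within 2% (the ~1.4% deficit is the known Brinkman model
  ## error plus discretization)
  expect_lt(abs(max(prof$v_mm_s) / attr(ref, "centerline_davg") - 1), 0.02)
  ## bins over the central 60% of the width within 2%
  cen <- abs(prof$pos_um - 100) <= 60
  expect_true(all(abs(prof$v_mm_s[cen] / ref$v_mm_s[cen] - 1) < 0.02))
  ## spanwise symmetry of the solved profile
  expect_equal(prof$v_mm_s, rev(prof$v_mm_s), tolerance = 1e-6)
})

test_that("velocities scale linearly with Q and refine under the grid", {
  f1 <- fx_straight_field()
  f2 <- solve_planform(fx_straight_grid(), preset_fluid("pbs"), 1.0)
  sel <- f1$grid$mask
  expect_equal(f2$speed[sel], 2 * f1$speed[sel], tolerance = 1e-8)
  ## halving the pixel changes the centerline speed by < 1%
  fhalf <- fx_fine_field()  # 2.5 um
  g5 <- rasterize(build_serpentine(segment_length = 800, n_segments = 1), 5)
  f5 <- solve_planform(g5, preset_fluid("pbs"), 0.5)
  expect_lt(abs(max(field_profile(f5)$v_mm_s) /
                  max(field_profile(fhalf)$v_mm_s) - 1), 0.01)
})

test_that("Carreau solver with eta0 = etaInf reproduces the Newtonian run", {
  gr <- fx_straight_grid()
  fn <- solve_planform(gr, preset_fluid("pbs"), 0.5)
  degen <- fluid_model("degen", 1000, "carreau", eta0 = 1e-3,
                       etaInf = 1e-3, lambda = 3.313, n = 0.3568)
  fc <- solve_planform(gr, degen, 0.5)
  sel <- gr$mask
  expect_lt(max(abs(fc$speed[sel] - fn$speed[sel]) /
                  pmax(fn$speed[sel], 1e-12)), 1e-10)
})

test_that("the bend carries faster flow on its inner side", {
  ba <- bend_speed_asymmetry(fx_baseline()$field)
  expect_true(ba$inner_mm_s > ba$outer_mm_s)
  expect_gt(ba$ratio, 1)
})

test_that("clot constrictions speed the flow up by mass conservation", {
  ## half-width clot: approximately twofold
  cs <- constriction_speedup(fx_thrombus()$field)
  expect_gt(cs$ratio, 1.8)
  expect_lt(cs$ratio, 2.2)

  ## 75% clot: ratio ~ 1/(1 - 0.75) = 4 by the flux-conservation oracle
  g75 <- add_defect(build_serpentine(segment_length = 800, n_segments = 1),
                    defect("clot", path_position = 0.4,
                           spanwise_extent = 0.75))
  f75 <- solve_planform(rasterize(g75, 5), preset_fluid("pbs"), 0.5)
  expect_lt(abs(constriction_speedup(f75)$ratio / 4 - 1), 0.1)

  ## small clot: the speed-up shrinks toward the no-defect limit of 1
  ## (a local jet around the sharp clot tip keeps it above the 1D flux
  ## estimate 1/(1 - extent), but well below the half-blockage ratio)
  g20 <- add_defect(build_serpentine(segment_length = 800, n_segments = 1),
                    defect("clot", path_position = 0.4,
                           spanwise_extent = 0.2))
  f20 <- solve_planform(rasterize(g20, 10), preset_fluid("pbs"), 0.5)
  r20 <- constriction_speedup(f20)$ratio
  expect_gt(r20, 1)
  expect_lt(r20, cs$ratio)

  ## asking for a clot that is not there fails
  expect_error(constriction_speedup(fx_straight_field()), "clot")
})

test_that("degenerate grids are rejected", {
  g <- build_serpentine(segment_length = 400, n_segments = 1)
  gr0 <- rasterize(g, 5, margin = 0)
  expect_error(solve_planform(gr0, preset_fluid("pbs"), 0.5), "border")
  expect_error(solve_planform(fx_straight_grid(), preset_fluid("pbs"), 0),
               "positive")
})
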