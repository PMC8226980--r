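test_that("the thrombus scene shows the twofold constriction speed-up", {
  sc <- fx_thrombus()
  cs <- constriction_speedup(sc$field)
  expect_gt(cs$ratio, 1.8)
  expect_lt(cs$ratio, 2.2)
  ## the measured field is faster inside the constriction in absolute terms
  expect_gt(cs$constricted_mm_s, cs$reference_mm_s)
})

test_that("the hemorrhage gap bleeds slowly compared to the main flow", {
  f <- fx_hemorrhage_field()
  gs <- gap_flow_stats(f)
  ## nonzero extravasation flux through the 20 um aperture
  expect_gt(gs$gap_flux_uL_min, 0.001)
  ## but only a small fraction of the perfusion flow
  expect_lt(gs$gap_flux_uL_min, 0.25 * f$Q)
  ## transit across the bleed is slower than the main channel flow
  expect_lt(gs$gap_mean_speed_mm_s, gs$main_mean_speed_mm_s)
  ## asking for gap statistics without a gap fails
  expect_error(gap_flow_stats(fx_straight_field()), "gap")
})

test_that("scenes are complete and reproducible", {
  sc <- fx_baseline()
  expect_s3_class(sc$field, "flow_field")
  expect_s3_class(sc$trajectories, "trajectory_set")
  expect_s3_class(sc$frames, "image_sequence")
  ## blood at these shear rates is mid-way between its Carreau plateaus
  eta <- sc$field$eta[sc$grid$mask]
  expect_true(all(eta > 0.0035 & eta < 0.056))
  ## the solved mean speed matches Q / (w h) to the expected order
  expect_equal(mean(sc$field$speed, na.rm = TRUE),
               duct_mean_velocity(0.5, 200, 50), tolerance = 0.15)
})

test_that("frame stacks and tables round-trip through files", {
  sc <- fx_baseline()
  td <- withr::local_tempdir()
  p <- file.path(td, "frames.tif")
  write_frames(sc$frames, p)
  back <- read_frames(p)
  expect_equal(length(back$frames), length(sc$frames$frames))
  expect_equal(back$pixel_size_um, sc$frames$pixel_size_um)
  expect_equal(back$origin_um, sc$frames$origin_um)
  ## 16-bit quantization only
  expect_lt(max(abs(back$frames[[1]] - sc$frames$frames[[1]])), 1 / 65535)

  tp <- file.path(td, "tracks.csv")
  write_tracks_csv(sc$trajectories, tp)
  tback <- read_tracks_csv(tp)
  expect_equal(tback$x_um, sc$trajectories$x_um)
  expect_equal(attr(tback, "dt_ms"), 2)

  ## mask export is a valid single-page binary image
  mp <- file.path(td, "mask.tif")
  write_mask_tiff(sc$grid, mp)
  m <- tiff::readTIFF(mp)
  expect_equal(sort(unique(as.vector(m))), c(0, 1))
  expect_equal(sum(m > 0), sum(sc$grid$mask))
})
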