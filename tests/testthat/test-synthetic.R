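test_that("deflection-free particles follow streamlines", {
  spec <- scene_spec(n_particles = 20, n_frames = 40,
                     scatter = scatter_model(collision_rate = 0),
                     seed = 4, s_range = c(0.1, 0.5))
  tr <- advect_particles(fx_straight_field(), spec)
  st <- track_steps(tr, grid = fx_straight_grid())
  ## lateral drift of each track stays far below one pixel (5 um)
  drift <- tapply(st$lat_um, st$particle, function(l) abs(sum(l)))
  expect_lt(max(drift), 1)
  expect_lt(max(abs(st$lat_um)), 0.5)
})

test_that("advection is reproducible and conserves particles", {
  spec <- scene_spec(n_particles = 25, n_frames = 30, seed = 9)
  t1 <- advect_particles(fx_straight_field(), spec)
  t2 <- advect_particles(fx_straight_field(), spec)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  ## every particle starts at frame 1 and runs contiguously until it
  ## leaves (outlet exit) or the acquisition ends
  expect_equal(sort(unique(t1$particle)), 1:25)
  for (p in split(t1$frame, t1$particle))
    expect_identical(p, seq.int(1L, length(p)))
})

test_that("the realized per-step deflections match the configured model", {
  ## large-sample realization on a straight channel at Q = 0.5
  spec <- scene_spec(n_particles = 400, n_frames = 90, seed = 12,
                     s_range = c(0.1, 0.8))
  tr <- advect_particles(fx_straight_field(), spec)
  st <- track_steps(tr, grid = fx_straight_grid())
  keep <- !is.na(st$s_um) & st$s_um > 200 & st$s_um < 400 &
    abs(st$lateral_um) <= 80
  signed <- asin(pmin(abs(st$lat_um[keep]) / st$delta_um[keep], 1)) *
    sign(st$lat_um[keep]) * 180 / pi
  expect_gt(length(signed), 1e4)

  ## calibration anchor: the mean |angle| realizes ~1.2 degrees
  expect_lt(abs(mean(abs(signed)) - 1.2), 0.08)

  ## the collided fraction matches the Poisson collision probability
  ## (non-collided steps carry only numerical-noise angles << 0.05 deg)
  sm <- spec$scatter
  p <- 1 - exp(-sm$collision_rate * 2 / 1000)
  thr <- 0.05
  p_eff <- p * (1 - (stats::pnorm(thr / sm$deflection_sd) -
                       stats::pnorm(-thr / sm$deflection_sd)))
  frac <- mean(abs(signed) > thr)
  se <- sqrt(p_eff * (1 - p_eff) / length(signed))
  expect_lt(abs(frac - p_eff), 5 * se)

  ## two-sample KS: collided deflections vs the configured Gaussian
  ## (both truncated at the same threshold)
  hits <- signed[abs(signed) > thr]
  set.seed(99)
  oracle <- rnorm(5 * length(hits), 0, sm$deflection_sd)
  oracle <- oracle[abs(oracle) > thr]
  ks <- suppressWarnings(stats::ks.test(hits, oracle))
  expect_gt(ks$p.value, 0.01)
})

test_that("rendering is pure and spots land where the particles are", {
  ## static particle: identical frames without noise
  tr <- traj_from_xy(rep(50, 5), rep(20, 5))
  spec <- scene_spec(n_particles = 1, n_frames = 5,
                     optics = list(noise_sd = 0, speckle_contrast = 0),
                     seed = 3)
  fr <- render_frames(tr, spec, window = c(0, 100, 0, 40))
  expect_identical(fr$frames[[1]], fr$frames[[3]])

  ## bead centroid recovered within 0.3 px of the generating position
  d <- detect_spots(fr$frames[[1]])
  expect_equal(nrow(d), 1)
  truth_px <- (50 - 0) / 1 + 0.5   # um -> pixel-index coordinate
  expect_lt(abs(d$x_px - truth_px), 0.3)
  expect_lt(abs(d$y_px - ((20 - 0) / 1 + 0.5)), 0.3)

  ## byte-identical rerun with the same seed, including noise and speckle
  spec2 <- scene_spec(n_particles = 1, n_frames = 5, seed = 3)
  f1 <- render_frames(tr, spec2, flow = fx_straight_field(),
                      window = c(0, 100, 0, 40))
  f2 <- render_frames(tr, spec2, flow = fx_straight_field(),
                      window = c(0, 100, 0, 40))
  expect_identical(f1$frames, f2$frames)
})

test_that("speckle pairs carry an exact known shift for PIV validation", {
  sp <- synth_speckle_pair(n = c(96, 96), shift = c(3, 0), seed = 5)
  ## frame B is frame A translated: interior columns agree exactly
  expect_equal(sp$b[10:90, ], sp$a[7:87, ], tolerance = 1e-12)
})

test_that("scene and optics parameters are validated", {
  expect_error(scene_spec(dt_ms = 0), "positive")
  expect_error(scene_spec(optics = list(spot_sigma_px = -1)), "positive")
  expect_error(scatter_model(collision_rate = -5), "collision_rate")
  expect_error(make_scene("aneurysm"))
})
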