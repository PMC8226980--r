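test_that("spot detection finds subpixel centroids", {
  ## blank frame: nothing to detect
  expect_equal(nrow(detect_spots(matrix(0.05, 60, 60))), 0)

  ## five rendered Gaussian spots recovered within 0.3 px
  cx <- c(15.3, 40.7, 70.2, 95.5, 120.8)
  cy <- c(12.1, 30.6, 18.4, 35.9, 22.3)
  fr <- spot_frame(140, 48, cx, cy)
  d <- detect_spots(fr)
  expect_equal(nrow(d), 5)
  d <- d[order(d$x_px), ]
  expect_true(all(abs(d$x_px - sort(cx)) < 0.3))
  expect_true(all(abs(d$y_px - cy[order(cx)]) < 0.3))

  ## two resolvable spots closer than min_separation are merged, counted
  fr2 <- spot_frame(60, 40, c(30, 38), c(20, 20))
  d2 <- detect_spots(fr2, threshold = 0.3, min_separation = 10)
  expect_equal(nrow(d2), 1)
  expect_gte(attr(d2, "merged"), 1)
  ## the merged centroid sits between the two generating spots
  expect_gt(d2$x_px, 30); expect_lt(d2$x_px, 38)

  ## saturated frames warn
  expect_warning(detect_spots(spot_frame(40, 40, 20, 20, amp = 1.2)),
                 "saturated")
})

test_that("greedy mutual-nearest-neighbour linking is correct and gated", {
  ## one particle at constant velocity: a single full-length track
  det <- lapply(0:9, function(f)
    data.frame(x_px = 10 + 3 * f, y_px = 20, mass = 1))
  tr <- link_tracks(det, max_disp = 8, min_length = 5, dt_ms = 2)
  expect_equal(length(unique(tr$particle)), 1)
  expect_equal(nrow(tr), 10)

  ## a jump beyond max_disp terminates the track
  det2 <- det
  det2[[6]]$x_px <- det2[[6]]$x_px + 50
  tr2 <- link_tracks(det2, max_disp = 8, min_length = 3, dt_ms = 2)
  expect_gt(length(unique(tr2$particle)), 1)

  ## 20 advected, non-crossing particles: >= 95% of links correct
  spec <- scene_spec(n_particles = 20, n_frames = 30,
                     scatter = scatter_model(collision_rate = 0), seed = 6,
                     s_range = c(0.1, 0.6))
  truth <- advect_particles(fx_straight_field(), spec)
  det3 <- lapply(sort(unique(truth$frame)), function(f) {
    d <- truth[truth$frame == f, ]
    data.frame(x_px = d$x_um, y_px = d$y_um, x_um = d$x_um, y_um = d$y_um,
               truth_id = d$particle)
  })
  lk <- link_tracks(det3, max_disp = 5, min_length = 5, dt_ms = 2,
                    pixel_size_um = 1)
  ## reconstruct which truth particle each detection belonged to
  good <- 0; total <- 0
  for (f in seq_along(det3)[-1]) {
    prev <- det3[[f - 1]]; cur <- det3[[f]]
    lprev <- lk[lk$frame == f - 1, ]; lcur <- lk[lk$frame == f, ]
    m0 <- match(round(lprev$x_um, 9), round(prev$x_um, 9))
    m1 <- match(round(lcur$x_um, 9), round(cur$x_um, 9))
    common <- intersect(lprev$particle, lcur$particle)
    for (id in common) {
      t0 <- prev$truth_id[m0[lprev$particle == id]]
      t1 <- cur$truth_id[m1[lcur$particle == id]]
      total <- total + 1
      if (isTRUE(t0 == t1)) good <- good + 1
    }
  }
  expect_gt(total, 100)
  expect_gte(good / total, 0.95)
})

test_that("mean speed implements the average of instantaneous speeds", {
  ## hand-computed: steps of 2 and 4 um at 2 ms -> (1 + 2)/2 = 1.5 mm/s
  tr <- traj_from_xy(c(0, 2, 6), c(0, 0, 0))
  expect_equal(mean_speed(tr), 1.5)
  ## single step (0,0) -> (3,4): delta = 5 um, speed 2.5 mm/s
  tr2 <- traj_from_xy(c(0, 3), c(0, 4))
  expect_equal(mean_speed(tr2), 2.5)
  ## constant motion returns the constant
  tr3 <- traj_from_xy(seq(0, 18, by = 2), rep(5, 10))
  expect_equal(mean_speed(tr3), 1)
  ## single-point tracks are rejected
  expect_error(mean_speed(traj_from_xy(1, 1)), "single-point")
})

test_that("mean speed is invariant to translation and rotation", {
  set.seed(8)
  x <- cumsum(runif(20, 1, 3)); y <- cumsum(rnorm(20, 0, 0.3))
  v0 <- mean_speed(traj_from_xy(x, y))
  expect_equal(mean_speed(traj_from_xy(x + 50, y - 20)), v0)
  th <- 0.7
  expect_equal(mean_speed(traj_from_xy(x * cos(th) - y * sin(th),
                                       x * sin(th) + y * cos(th))), v0)
})

test_that("step angles follow asin(|lateral| / delta)", {
  ## purely axial step
  expect_equal(scattering_angles(traj_from_xy(c(0, 5), c(0, 0)))$mean_deg, 0)
  ## purely lateral step
  expect_equal(scattering_angles(traj_from_xy(c(0, 0), c(0, 5)))$mean_deg, 90)
  ## lateral 1.0 um over delta 47.75 um: the 1.2-degree scale of the
  ## whole-blood measurements
  ax <- sqrt(47.75^2 - 1)
  s <- scattering_angles(traj_from_xy(c(0, ax), c(0, 1)))
  expect_equal(s$mean_deg, asin(1 / 47.75) * 180 / pi, tolerance = 1e-9)
  expect_equal(s$mean_deg, 1.2, tolerance = 0.01)
  ## zero-length steps are excluded and counted
  s2 <- scattering_angles(traj_from_xy(c(0, 0, 5), c(0, 0, 0)))
  expect_equal(s2$excluded, 1)
  expect_equal(s2$n_steps, 1)
})

test_that("interaction length reproduces the printed device values", {
  ## L = half-width / tan(phi): 1.2 deg -> 4.8 mm, 1.3 deg -> 4.4 mm
  expect_equal(signif(interaction_length(1.2, 100), 2), 4.8)
  expect_equal(signif(interaction_length(1.3, 100), 2), 4.4)
  ## tan(45 deg) = 1 -> 0.1 mm
  expect_equal(interaction_length(45, 100), 0.1, tolerance = 1e-9)
  expect_warning(L0 <- interaction_length(0, 100), "unbounded")
  expect_identical(L0, Inf)
})

test_that("tracked velocity profiles recover an analytic parabola", {
  ## advect on an exact parabolic spanwise profile (generator oracle)
  f <- fx_straight_field()
  grid <- fx_straight_grid()
  vbar <- duct_mean_velocity(0.5, 200, 50)
  pos <- grid$lateral + 100
  f$vx <- 6 * vbar * pos * (200 - pos) / 200^2
  f$vx[!grid$mask] <- NA
  f$vy[] <- 0; f$vy[!grid$mask] <- NA
  spec <- scene_spec(n_particles = 500, n_frames = 25,
                     scatter = scatter_model(collision_rate = 0), seed = 2,
                     s_range = c(0.2, 0.7))
  tr <- advect_particles(f, spec)
  prof <- velocity_profile(tr, grid, n_bins = 10)
  truth <- 6 * vbar * prof$pos_um * (200 - prof$pos_um) / 200^2
  ## interior bins (fully sampled) match the parabola within 5%; the
  ## outermost bins are excluded because particles are not seeded flush
  ## against the walls
  ok <- !is.na(prof$v_mm_s) & prof$n > 10 &
    prof$pos_um > 20 & prof$pos_um < 180
  expect_gt(sum(ok), 5)
  expect_true(all(abs(prof$v_mm_s[ok] / truth[ok] - 1) < 0.05))
  ## near-wall bins are slower than the central bins
  mid <- which.min(abs(prof$pos_um - 100))
  edges <- ok & (prof$pos_um < 40 | prof$pos_um > 160)
  expect_true(all(prof$v_mm_s[edges] < prof$v_mm_s[mid]))
  ## symmetric within sampling noise
  both <- ok & rev(ok)
  expect_true(all(abs(prof$v_mm_s[both] - rev(prof$v_mm_s)[both]) /
                    max(prof$v_mm_s, na.rm = TRUE) < 0.1))
  ## empty bins are NA, not zero
  spec1 <- scene_spec(n_particles = 3, n_frames = 10,
                      scatter = scatter_model(collision_rate = 0), seed = 1)
  pr1 <- velocity_profile(advect_particles(fx_straight_field(), spec1),
                          fx_straight_grid(), n_bins = 40)
  expect_true(any(is.na(pr1$v_mm_s)))
  expect_false(any(pr1$v_mm_s == 0, na.rm = TRUE))
})
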