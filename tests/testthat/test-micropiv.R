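test_that("NCC template matching recovers integer shifts exactly", {
  base <- synth_speckle_pair(c(200, 160), c(0, 0), seed = 2)$a
  shifted <- matrix(0.1, 200, 160)
  shifted[4:200, 2:160] <- base[1:197, 1:159]
  pv <- piv_pair(base, shifted)
  expect_true(all(pv$valid))
  expect_equal(unique(pv$u_px), 3)
  expect_equal(unique(pv$v_px), 1)
  ## a perfect integer match yields a correlation peak of exactly 1
  expect_equal(max(pv$peak), 1)
  ## all correlations bounded in [-1, 1]
  surf <- vesselflow:::ncc_surface(base[65:96, 65:96], base[49:112, 49:112])
  expect_true(all(surf >= -1 - 1e-12 & surf <= 1 + 1e-12))
  expect_equal(max(surf), 1)
})

test_that("self-correlation gives a zero displacement field", {
  a <- synth_speckle_pair(c(160, 160), c(0, 0), seed = 4)$a
  pv <- piv_pair(a, a)
  expect_true(all(pv$u_px == 0 & pv$v_px == 0))
})

test_that("subpixel shifts are recovered to a tenth of a pixel", {
  sp <- synth_speckle_pair(n = c(192, 128), shift = c(2.5, 0), seed = 3)
  pv <- piv_pair(sp$a, sp$b, dt_ms = 2, pixel_size_um = 1)
  expect_gt(sum(pv$valid), 20)
  expect_lt(abs(mean(pv$u_px[pv$valid]) - 2.5), 0.1)
  expect_lt(abs(mean(pv$v_px[pv$valid])), 0.1)
  ## velocity conversion: px / dt * pixel size
  expect_equal(pv$u_mm_s, pv$u_px * 1 / 2)
})

test_that("displacement estimates are shift-equivariant", {
  big <- synth_speckle_pair(c(260, 200), c(0, 0), seed = 7)$a
  crop <- function(ox, oy) big[(1 + ox):(160 + ox), (1 + oy):(128 + oy)]
  v1 <- piv_pair(crop(0, 0), crop(4, 2))
  v2 <- piv_pair(crop(30, 20), crop(34, 22))
  expect_equal(v1$u_px, v2$u_px)
  expect_equal(v1$v_px, v2$v_px)
})

test_that("featureless windows are flagged invalid, not fabricated", {
  flat <- matrix(0.5, 160, 160)
  pv <- piv_pair(flat, flat)
  expect_false(any(pv$valid))
  expect_true(all(is.na(pv$u_px)))
})

test_that("field filtering invalidates low SNR and repairs outliers", {
  sp <- synth_speckle_pair(n = c(224, 160), shift = c(2, 1), seed = 9)
  pv <- piv_pair(sp$a, sp$b)
  ## clean uniform field: vectors unchanged by the median filter
  pf <- filter_field(pv, snr_min = 0, median_tol = 2)
  expect_equal(pf$u_px, pv$u_px)
  expect_false(any(pf$interpolated))
  ## inject one outlier vector: replaced by the neighbourhood median
  k <- which(pv$ix_w == 4 & pv$iy_w == 4)
  pv$u_px[k] <- pv$u_px[k] + 9
  pv$u_mm_s[k] <- pv$u_px[k] * 0.5
  pf2 <- filter_field(pv, snr_min = 0, median_tol = 2)
  expect_true(pf2$interpolated[k])
  expect_lt(abs(pf2$u_px[k] - 2), 0.5)
  ## an all-invalid field warns and returns
  flatf <- piv_pair(matrix(0.5, 160, 160), matrix(0.5, 160, 160))
  expect_warning(filter_field(flatf), "no valid")
})

test_that("temporal projections behave as definitions", {
  f1 <- spot_frame(60, 40, 15, 20)
  expect_identical(temporal_projection(list(f1), "max"), f1)
  ## a moving spot leaves a continuous streak under max projection
  frames <- lapply(seq(10, 50, by = 4), function(cx)
    spot_frame(60, 40, cx, 20))
  mp <- temporal_projection(frames, "max")
  streak <- mp[10:50, 20]
  expect_true(all(streak > 0.5 * max(mp)))
  ## max projection is frame-order invariant
  expect_identical(mp, temporal_projection(rev(frames), "max"))
  ## mean projection averages
  expect_equal(temporal_projection(list(f1, f1 * 0), "mean"), f1 / 2)
})

test_that("PIV agrees with the simulation and the tracking estimates", {
  sc <- fx_baseline()
  pv <- filter_field(piv_sequence(sc$frames, pairs = 3))
  cmp <- compare_to_simulation(pv, sc$field)
  ## closure: PIV on frames rendered from the field itself
  expect_lt(cmp$summary$rms_relative, 0.10)
  ## independent measurement paths: PIV speeds vs tracked-bead speeds
  det <- suppressWarnings(detect_stack(sc$frames))
  tracks <- link_tracks(det, max_disp = 8, dt_ms = sc$frames$dt_ms)
  v_track <- mean_speed(tracks, by = "all")
  v_piv <- mean(sqrt(pv$u_mm_s^2 + pv$v_mm_s^2)[pv$valid])
  expect_lt(abs(v_piv / v_track - 1), 0.15)
})
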