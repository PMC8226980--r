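test_that("path length is additive over limbs and bends", {
  ## single straight limb: no-bend identity
  g1 <- build_serpentine(segment_length = 10000, n_segments = 1)
  expect_equal(g1$total_path_length, 10000)

  ## two 5 mm limbs joined by one semicircular bend of radius 0.5 mm
  g2 <- build_serpentine(segment_length = 5000, n_segments = 2,
                         bend_radius = 500)
  expect_equal(g2$total_path_length / 1000, 10 + pi * 0.5)

  ## default device configuration lands near the 200 mm physical length
  gd <- build_serpentine()
  expect_lt(abs(gd$total_path_length / 1000 - 200) / 200, 0.05)
})

test_that("non-physical dimensions are rejected", {
  expect_error(build_serpentine(width = 0), "positive")
  expect_error(build_serpentine(height = -5), "positive")
  expect_error(build_serpentine(n_segments = 2, bend_radius = 50),
               "width/2")
})

test_that("defects are validated and bounded", {
  g <- build_serpentine(segment_length = 2000, n_segments = 2,
                        bend_radius = 250)
  ## out of bounds
  expect_error(add_defect(g, defect("clot", path_position = 50)),
               "outside")
  expect_error(defect("clot", 1, spanwise_extent = 1.2), "spanwise")
  ## overlap along the path
  g1 <- add_defect(g, defect("clot", path_position = 1.0))
  expect_error(add_defect(g1, defect("clot", path_position = 1.05)),
               "overlap")
  ## a second, separated defect is fine
  expect_silent(add_defect(g1, defect("clot", path_position = 0.4)))
  ## wall gap needs a straight limb and an adjacent limb
  expect_error(add_defect(build_serpentine(n_segments = 1),
                          defect("wall_gap", path_position = 2)),
               "adjacent")
})

test_that("rasterization resolves the cross-section and is symmetric", {
  g <- build_serpentine(segment_length = 600, n_segments = 1)
  gr <- fx_straight_grid()
  ## 200 um width at 5 um pixels -> 40 cells across every column
  cols <- which(apply(gr$mask, 1, any))
  expect_true(all(rowSums(gr$mask[cols, , drop = FALSE]) == 40))
  ## mirror symmetry about the centerline
  expect_identical(gr$mask, gr$mask[, rev(seq_len(gr$dim[2]))])
  ## fluid area matches the analytic planform area within a pixel band
  area <- sum(gr$mask) * gr$pixel_size^2
  expect_lt(abs(area - 600 * 200), (2 * 600 + 2 * 200) * gr$pixel_size)
  ## too-coarse pixels are rejected
  expect_error(rasterize(g, 25), "coarse")
})

test_that("clot defects carve the expected constriction", {
  g <- add_defect(build_serpentine(segment_length = 2000, n_segments = 1),
                  defect("clot", path_position = 1.0,
                         spanwise_extent = 0.5))
  gr <- rasterize(g, 5)
  ## local fluid width at the clot center is half of 200 um -> 20 cells
  at <- which(!is.na(gr$s) & abs(gr$s - 1000) <= 2.5, arr.ind = TRUE)
  ix <- unique(at[, 1])
  expect_true(all(rowSums(gr$mask[ix, , drop = FALSE]) == 20))
  ## removing the defect restores the defect-free mask bit-exactly
  g0 <- g; g0$defects <- list()
  expect_identical(rasterize(g0, 5)$mask,
                   rasterize(build_serpentine(segment_length = 2000,
                                              n_segments = 1), 5)$mask)
})

test_that("wall gaps open a shortcut between adjacent limbs", {
  geom <- add_defect(
    build_serpentine(segment_length = 1000, n_segments = 2,
                     bend_radius = 250),
    defect("wall_gap", path_position = 0.75, gap_length = 20,
           wall_side = "inner"))
  gr <- rasterize(geom, 5)
  expect_gt(sum(gr$gap), 0)
  ## flood-fill oracle: with the aperture blocked, the two limbs connect
  ## only through the bend, so the grid distance from an inlet cell to the
  ## facing cell across the gap is much longer than with the gap open
  blocked <- gr$mask; blocked[gr$gap] <- FALSE
  start <- which(gr$inlet, arr.ind = TRUE)[1, , drop = FALSE]
  expect_true(all(flood_fill(gr$mask, start)[gr$mask]))   # fully connected
  reach_blocked <- flood_fill(blocked, start)
  expect_true(all(reach_blocked[blocked]))  # bend path still connects all
  ## the gap itself is unreachable when blocked
  expect_false(any(reach_blocked[gr$gap]))
  ## gap resolution guard
  expect_error(rasterize(geom, 10), "gap")
})
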