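## Shared fixtures, built once per test run and cached. All synthetic
## inputs are generated in code under fixed seeds.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (!exists(name, envir = .fx)) assign(name, maker(), envir = .fx)
  get(name, envir = .fx)
}

## straight 600 um channel, 5 um grid, water, Q = 0.5 uL/min
fx_straight_grid <- function()
  fixture("straight_grid", function()
    rasterize(build_serpentine(segment_length = 600, n_segments = 1), 5))

fx_straight_field <- function()
  fixture("straight_field", function()
    solve_planform(fx_straight_grid(), preset_fluid("pbs"), 0.5))

## finer straight channel for analytic-profile comparisons
fx_fine_field <- function()
  fixture("fine_field", function()
    solve_planform(
      rasterize(build_serpentine(segment_length = 800, n_segments = 1), 2.5),
      preset_fluid("pbs"), 0.5))

## long straight channel at Q = 5 uL/min: long per-step baselines for
## scattering-angle experiments
fx_fast_grid <- function()
  fixture("fast_grid", function()
    rasterize(build_serpentine(segment_length = 1500, n_segments = 1), 5))

fx_fast_field <- function()
  fixture("fast_field", function()
    solve_planform(fx_fast_grid(), preset_fluid("pbs"), 5))

## full scenes (blood, Q = 0.5)
fx_baseline <- function()
  fixture("baseline", function() make_scene("baseline", render = TRUE))

fx_thrombus <- function()
  fixture("thrombus", function() make_scene("thrombus", render = TRUE))

## ensemble PIV protocol for the constricted scene: dense window grid,
## 6-pair ensemble; the spatial median test guards outliers, so the
## per-pair SNR floor is relaxed (shear in the jet broadens the
## correlation peak and lowers SNR without displacing it)
fx_thrombus_piv <- function()
  fixture("thrombus_piv", function()
    filter_field(piv_sequence(fx_thrombus()$frames, pairs = 6,
                              overlap = 0.75),
                 snr_min = 1.1, median_tol = 2))

fx_hemorrhage_field <- function()
  fixture("hemorrhage_field", function()
    make_scene("hemorrhage", render = FALSE)$field)

## independent flood-fill oracle (4-connectivity BFS on a logical mask)
flood_fill <- function(mask, start) {
  nx <- nrow(mask); ny <- ncol(mask)
  seen <- matrix(FALSE, nx, ny)
  queue <- matrix(start, ncol = 2)
  seen[queue] <- TRUE
  while (nrow(queue)) {
    cur <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      p <- cur + d
      if (p[1] >= 1 && p[1] <= nx && p[2] >= 1 && p[2] <= ny &&
          mask[p[1], p[2]] && !seen[p[1], p[2]]) {
        seen[p[1], p[2]] <- TRUE
        queue <- rbind(queue, p)
      }
    }
  }
  seen
}

## render a frame with Gaussian spots at known pixel-index coordinates
spot_frame <- function(nx, ny, cx, cy, sigma = 2, amp = 0.6, bg = 0.05) {
  fr <- matrix(bg, nx, ny)
  for (k in seq_along(cx)) {
    gx <- exp(-((1:nx) - cx[k])^2 / (2 * sigma^2))
    gy <- exp(-((1:ny) - cy[k])^2 / (2 * sigma^2))
    fr <- fr + amp * outer(gx, gy)
  }
  fr
}

## hand-built trajectory set from a positions matrix (one particle)
traj_from_xy <- function(x, y, dt_ms = 2) {
  structure(data.frame(particle = 1L, frame = seq_along(x),
                       t_ms = (seq_along(x) - 1) * dt_ms,
                       x_um = x, y_um = y),
            dt_ms = dt_ms, class = c("trajectory_set", "data.frame"))
}
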