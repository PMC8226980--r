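## Label-free micro-PIV: displacement fields from frame pairs by
## normalized cross-correlation template matching (an interrogation window
## from frame A matched inside a larger search region of frame B), with
## 3-point parabolic subpixel refinement, SNR-based validation, and
## comparison against simulated flow fields.

# parabolic 3-point subpixel refinement along one axis
parabolic_peak <- function(ym, y0, yp) {
  den <- ym - 2 * y0 + yp
  if (!is.finite(den) || abs(den) < 1e-12) return(0)
  d <- 0.5 * (ym - yp) / den
  max(min(d, 0.5), -0.5)
}

#' PIV displacement field from a frame pair
#'
#' Tiles the frames with interrogation windows (template from frame A,
#' matched by normalized cross-correlation inside a larger search region
#' of frame B), locates the correlation peak with 3-point parabolic
#' subpixel refinement per axis, and converts displacements to velocities
#' via the pixel size and frame interval. Windows with a featureless
#' template or search region are flagged invalid rather than fabricated.
#' The SNR of a window is the ratio of the highest correlation peak to the
#' second-highest outside its immediate neighbourhood.
#'
#' @param a,b frames (matrices `[nx, ny]`, same shape).
#' @param window interrogation window size (px).
#' @param search search region size (px), `> window`.
#' @param overlap window overlap fraction in `[0, 0.75]`.
#' @param dt_ms frame interval (ms).
#' @param pixel_size_um pixel size (um).
#' @param origin_um coordinate origin of pixel (0.5, 0.5) (um).
#' @return A `displacement_field` data frame: window centers (`x_px`,
#'   `y_px`, `x_um`, `y_um`), displacements (`u_px`, `v_px`), velocities
#'   (`u_mm_s`, `v_mm_s`), `peak` correlation, `snr`, `valid` and
#'   `interpolated` flags; window-grid shape and parameters as attributes.
#' @export
piv_pair <- function(a, b, window = 32, search = 64, overlap = 0.5,
                     dt_ms = 2, pixel_size_um = 1, origin_um = c(0, 0)) {
  stopifnot(is.matrix(a), is.matrix(b))
  if (!all(dim(a) == dim(b))) stop("frames must have the same shape")
  if (search <= window) stop("search_size must exceed window_size")
  if (overlap < 0 || overlap > 0.75) stop("overlap must be in [0, 0.75]")
  nx <- nrow(a); ny <- ncol(a)
  s2 <- search / 2
  stride <- max(1, round(window * (1 - overlap)))
  if (nx < search + 2 || ny < search + 2)
    stop("frames smaller than the search region")
  cxs <- seq(s2, nx - s2, by = stride)       # block-corner offsets
  cys <- seq(s2, ny - s2, by = stride)
  off0 <- (search - window) / 2              # zero-displacement offset
  rows <- vector("list", length(cxs) * length(cys))
  k <- 0L
  for (jy in seq_along(cys)) {
    for (jx in seq_along(cxs)) {
      k <- k + 1L
      cx <- cxs[jx]; cy <- cys[jy]
      ti <- (cx - window / 2 + 1):(cx + window / 2)
      tj <- (cy - window / 2 + 1):(cy + window / 2)
      si <- (cx - s2 + 1):(cx + s2)
      sj <- (cy - s2 + 1):(cy + s2)
      tmpl <- a[ti, tj]
      surf <- ncc_surface(tmpl, b[si, sj])
      pk <- which(surf == max(surf), arr.ind = TRUE)[1, ]
      peak <- surf[pk[1], pk[2]]
      valid <- is.finite(peak) && peak > 0 && sd(tmpl) > 1e-6
      ## subpixel refinement (interior peaks only); a perfect peak means
      ## an exactly integer displacement, so no refinement is applied
      ddx <- ddy <- 0
      refine <- valid && peak < 1 - 1e-9
      if (refine && pk[1] > 1 && pk[1] < nrow(surf))
        ddx <- parabolic_peak(surf[pk[1] - 1, pk[2]], peak,
                              surf[pk[1] + 1, pk[2]])
      if (refine && pk[2] > 1 && pk[2] < ncol(surf))
        ddy <- parabolic_peak(surf[pk[1], pk[2] - 1], peak,
                              surf[pk[1], pk[2] + 1])
      ## SNR: first/second peak with a 2-px exclusion zone
      s2nd <- surf
      s2nd[max(1, pk[1] - 2):min(nrow(surf), pk[1] + 2),
           max(1, pk[2] - 2):min(ncol(surf), pk[2] + 2)] <- -Inf
      second <- suppressWarnings(max(s2nd))
      snr <- if (!is.finite(second) || second <= 0) 1e3
             else peak / second
      u_px <- pk[1] - 1 + ddx - off0
      v_px <- pk[2] - 1 + ddy - off0
      if (!valid) { u_px <- NA_real_; v_px <- NA_real_ }
      rows[[k]] <- data.frame(
        ix_w = jx, iy_w = jy,
        x_px = cx + 0.5, y_px = cy + 0.5,
        u_px = u_px, v_px = v_px,
        peak = peak, snr = snr, valid = valid)
    }
  }
  df <- do.call(rbind, rows)
  df$x_um <- origin_um[1] + (df$x_px - 0.5) * pixel_size_um
  df$y_um <- origin_um[2] + (df$y_px - 0.5) * pixel_size_um
  df$u_mm_s <- df$u_px * pixel_size_um / dt_ms
  df$v_mm_s <- df$v_px * pixel_size_um / dt_ms
  df$interpolated <- FALSE
  structure(df, window = window, search = search, overlap = overlap,
            dt_ms = dt_ms, pixel_size_um = pixel_size_um,
            origin_um = origin_um,
            grid_dim = c(length(cxs), length(cys)),
            class = c("displacement_field", "data.frame"))
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("PIV displacement field: %d x %d windows (%d valid)\n",
              attr(x, "grid_dim")[1], attr(x, "grid_dim")[2], sum(x$valid)))
  sp <- sqrt(x$u_mm_s^2 + x$v_mm_s^2)[x$valid]
  if (length(sp))
    cat(sprintf("  speed: mean %.3f mm/s, max %.3f mm/s; median SNR %.2f\n",
                mean(sp), max(sp), median(x$snr[x$valid])))
  invisible(x)
}

#' @export
plot.displacement_field <- function(x, scale = 10, ...) {
  ok <- x$valid & is.finite(x$u_px)
  graphics::plot(x$x_um, x$y_um, type = "n", asp = 1,
                 xlab = "x (um)", ylab = "y (um)", ...)
  graphics::arrows(x$x_um[ok], x$y_um[ok],
                   x$x_um[ok] + scale * x$u_mm_s[ok],
                   x$y_um[ok] + scale * x$v_mm_s[ok],
                   length = 0.03, col = "steelblue")
  invisible(x)
}

#' Ensemble PIV over an image sequence
#'
#' Runs [piv_pair()] on consecutive frame pairs and averages the valid
#' vectors per window (ensemble mean), which suppresses single-pair noise
#' in steady flows.
#'
#' @param seq an `image_sequence`.
#' @param pairs number of consecutive pairs to use (default all).
#' @param ... passed to [piv_pair()].
#' @return A `displacement_field` with ensemble-averaged vectors; `n_obs`
#'   counts the contributing pairs per window.
#' @export
piv_sequence <- function(seq, pairs = NULL, ...) {
  stopifnot(inherits(seq, "image_sequence"))
  nf <- length(seq$frames)
  if (nf < 2) stop("need at least two frames")
  np <- if (is.null(pairs)) nf - 1 else min(pairs, nf - 1)
  acc <- NULL
  for (p in seq_len(np)) {
    f <- piv_pair(seq$frames[[p]], seq$frames[[p + 1]],
                  dt_ms = seq$dt_ms, pixel_size_um = seq$pixel_size_um,
                  origin_um = seq$origin_um, ...)
    if (is.null(acc)) {
      acc <- f
      acc$su <- ifelse(f$valid, f$u_px, 0)
      acc$sv <- ifelse(f$valid, f$v_px, 0)
      acc$n_obs <- as.integer(f$valid)
    } else {
      acc$su <- acc$su + ifelse(f$valid, f$u_px, 0)
      acc$sv <- acc$sv + ifelse(f$valid, f$v_px, 0)
      acc$n_obs <- acc$n_obs + as.integer(f$valid)
      acc$peak <- pmax(acc$peak, f$peak)
      acc$snr <- acc$snr + (f$snr - acc$snr) / p  # running mean
    }
  }
  acc$valid <- acc$n_obs > 0
  acc$u_px <- ifelse(acc$valid, acc$su / pmax(acc$n_obs, 1), NA_real_)
  acc$v_px <- ifelse(acc$valid, acc$sv / pmax(acc$n_obs, 1), NA_real_)
  px <- attr(acc, "pixel_size_um"); dt <- attr(acc, "dt_ms")
  acc$u_mm_s <- acc$u_px * px / dt
  acc$v_mm_s <- acc$v_px * px / dt
  acc$su <- acc$sv <- NULL
  acc
}

#' Validate and smooth a displacement field
#'
#' Invalidates windows below an SNR floor, then compares each remaining
#' vector against the median of its 3x3 window-grid neighbourhood:
#' vectors deviating by more than `median_tol` px are replaced by that
#' median and flagged `interpolated`.
#'
#' @param field a `displacement_field`.
#' @param snr_min minimum acceptable first/second peak ratio.
#' @param median_tol neighbourhood-median deviation tolerance (px).
#' @return The filtered `displacement_field`; a warning (and unchanged
#'   vectors) if nothing remains valid.
#' @export
filter_field <- function(field, snr_min = 1.5, median_tol = 2) {
  stopifnot(inherits(field, "displacement_field"))
  field$valid <- field$valid & field$snr >= snr_min
  if (!any(field$valid)) {
    warning("no valid vectors after SNR filtering")
    return(field)
  }
  gd <- attr(field, "grid_dim")
  U <- matrix(NA_real_, gd[1], gd[2]); V <- U
  U[cbind(field$ix_w, field$iy_w)] <- ifelse(field$valid, field$u_px, NA)
  V[cbind(field$ix_w, field$iy_w)] <- ifelse(field$valid, field$v_px, NA)
  medU <- U; medV <- V
  for (j in seq_len(gd[2])) {
    for (i in seq_len(gd[1])) {
      ii <- max(1, i - 1):min(gd[1], i + 1)
      jj <- max(1, j - 1):min(gd[2], j + 1)
      nbU <- U[ii, jj]; nbV <- V[ii, jj]
      nbU[ii == i, jj == j] <- NA  # exclude self
      medU[i, j] <- median(nbU, na.rm = TRUE)
      medV[i, j] <- median(nbV, na.rm = TRUE)
    }
  }
  iw <- cbind(field$ix_w, field$iy_w)
  dev <- sqrt((field$u_px - medU[iw])^2 + (field$v_px - medV[iw])^2)
  out <- field$valid & is.finite(dev) & dev > median_tol &
    is.finite(medU[iw]) & is.finite(medV[iw])
  if (any(out)) {
    px <- attr(field, "pixel_size_um"); dt <- attr(field, "dt_ms")
    field$u_px[out] <- medU[iw][out]
    field$v_px[out] <- medV[iw][out]
    field$u_mm_s[out] <- field$u_px[out] * px / dt
    field$v_mm_s[out] <- field$v_px[out] * px / dt
    field$interpolated[out] <- TRUE
  }
  field
}

#' Min--max normalized speed magnitude of a displacement field
#'
#' @param field a `displacement_field`.
#' @return The field with a `mag_norm` column in `[0, 1]` (NA where
#'   invalid), as used for the normalized vector-magnitude plots.
#' @export
normalized_magnitude <- function(field) {
  sp <- sqrt(field$u_mm_s^2 + field$v_mm_s^2)
  sp[!field$valid] <- NA
  rng <- range(sp, na.rm = TRUE)
  field$mag_norm <- if (diff(rng) > 0) (sp - rng[1]) / diff(rng)
                    else sp * 0
  field
}

#' Compare a PIV field against a simulated flow field
#'
#' Samples the simulated velocity at each valid window center (bilinear)
#' and reports per-window residuals `PIV - simulation` plus summary
#' statistics. Windows whose centers fall outside the fluid or closer to a
#' wall than `wall_margin_um` are excluded (the window would straddle the
#' wall).
#'
#' @param field a `displacement_field`.
#' @param flow a `flow_field`.
#' @param wall_margin_um minimum wall distance of window centers; default
#'   half the interrogation window.
#' @return A `piv_comparison`: per-window data and a summary list with
#'   `n`, `rms_residual_mm_s`, `mean_sim_speed_mm_s` and
#'   `rms_relative`.
#' @export
compare_to_simulation <- function(field, flow, wall_margin_um = NULL) {
  stopifnot(inherits(field, "displacement_field"),
            inherits(flow, "flow_field"))
  if (is.null(wall_margin_um))
    wall_margin_um <- attr(field, "window") * attr(field, "pixel_size_um") / 2
  grid <- flow$grid
  ok <- field$valid & pos_is_fluid(grid, field$x_um, field$y_um)
  wd <- grid_interp(grid, grid$walldist, field$x_um, field$y_um)
  ok <- ok & wd >= wall_margin_um
  if (!any(ok)) stop("PIV and simulation domains do not overlap")
  us <- grid_interp(grid, flow$vx, field$x_um[ok], field$y_um[ok])
  vs <- grid_interp(grid, flow$vy, field$x_um[ok], field$y_um[ok])
  d <- data.frame(x_um = field$x_um[ok], y_um = field$y_um[ok],
                  u_piv = field$u_mm_s[ok], v_piv = field$v_mm_s[ok],
                  u_sim = us, v_sim = vs,
                  ru = field$u_mm_s[ok] - us, rv = field$v_mm_s[ok] - vs)
  rms <- sqrt(mean(d$ru^2 + d$rv^2))
  msim <- mean(sqrt(d$u_sim^2 + d$v_sim^2))
  structure(list(data = d,
                 summary = list(n = nrow(d),
                                mean_residual_u = mean(d$ru),
                                mean_residual_v = mean(d$rv),
                                rms_residual_mm_s = rms,
                                mean_sim_speed_mm_s = msim,
                                rms_relative = rms / msim)),
            class = "piv_comparison")
}

#' @export
print.piv_comparison <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "PIV vs simulation: %d windows, RMS residual %.3f mm/s (%.1f%% of mean)\n",
    s$n, s$rms_residual_mm_s, 100 * s$rms_relative))
  invisible(x)
}

#' Constriction speed-up measured by PIV
#'
#' PIV analogue of [constriction_speedup()]: the ratio of mean PIV speed
#' over windows inside the clot's along-path extent to that over an
#' unobstructed reference section, using the same core-region definition
#' so the two measurement paths are directly comparable.
#'
#' @param field a `displacement_field` (ideally ensemble-averaged and
#'   filtered).
#' @param grid the clot-bearing `planform_grid`.
#' @param which clot index.
#' @param core_margin_um exclude windows closer than this to a wall.
#' @param reference_offset reference-section separation in clot lengths.
#' @return A list: `ratio`, `constricted_mm_s`, `reference_mm_s`,
#'   `n_constricted`, `n_reference`.
#' @export
piv_constriction_ratio <- function(field, grid, which = 1,
                                   core_margin_um = 16,
                                   reference_offset = 2) {
  defs <- Filter(function(d) d$kind == "clot", grid$geometry$defects)
  if (length(defs) < which) stop("no such clot defect in the geometry")
  d <- defs[[which]]
  s0 <- d$path_position * 1000
  half <- d$clot_length / 2
  ref0 <- s0 - reference_offset * d$clot_length
  if (ref0 - half < 0) ref0 <- s0 + reference_offset * d$clot_length
  ok <- field$valid & pos_is_fluid(grid, field$x_um, field$y_um)
  sv <- grid_interp(grid, grid$s, field$x_um, field$y_um, fill = NA)
  wd <- grid_interp(grid, grid$walldist, field$x_um, field$y_um)
  sp <- sqrt(field$u_mm_s^2 + field$v_mm_s^2)
  inc <- ok & !is.na(sv) & wd >= core_margin_um &
    sv >= s0 - half & sv <= s0 + half
  inr <- ok & !is.na(sv) & wd >= core_margin_um &
    sv >= ref0 - half & sv <= ref0 + half
  if (!any(inc) || !any(inr))
    stop("no valid PIV windows in constricted or reference section")
  list(ratio = mean(sp[inc]) / mean(sp[inr]),
       constricted_mm_s = mean(sp[inc]), reference_mm_s = mean(sp[inr]),
       n_constricted = sum(inc), n_reference = sum(inr))
}

#' Temporal projection of an image sequence
#'
#' Per-pixel maximum or mean across frames; the max projection turns
#' moving particles into continuous streaks along their paths, the
#' visualization used to reveal trapped/accelerating cells between clots.
#'
#' @param seq an `image_sequence` (or list of matrices).
#' @param mode `"max"` or `"mean"`.
#' @return A single intensity matrix.
#' @export
temporal_projection <- function(seq, mode = c("max", "mean")) {
  mode <- match.arg(mode)
  frames <- if (inherits(seq, "image_sequence")) seq$frames else seq
  if (!length(frames)) stop("empty sequence")
  if (mode == "max") Reduce(pmax, frames)
  else Reduce(`+`, frames) / length(frames)
}
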