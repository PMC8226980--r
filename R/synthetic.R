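## Synthetic raw-data generation: stochastic bead/RBC trajectories advected
## through a solved flow field, and microscopy-like 16-bit frame rendering
## (Gaussian bead spots over advected band-limited RBC speckle).

#' Deflection scale that realizes a target mean scattering angle
#'
#' With Poisson collisions at `collision_rate` and Gaussian deflections of
#' standard deviation `sigma` (degrees), the realized per-step mean
#' absolute angle is `p * sigma * sqrt(2/pi)` with
#' `p = 1 - exp(-rate * dt)`. Inverts that relation.
#'
#' @param target_mean_deg desired per-step mean |deflection| (degrees);
#'   1.2 degrees is the whole-blood anchor at Q = 0.5 uL/min.
#' @param collision_rate collision events per second.
#' @param dt_ms frame interval (ms).
#' @return Deflection standard deviation in degrees.
#' @export
calibrate_deflection_sd <- function(target_mean_deg = 1.2,
                                    collision_rate = 500, dt_ms = 2) {
  p <- 1 - exp(-collision_rate * dt_ms / 1000)
  if (p <= 0) stop("collision_rate * dt too small to calibrate")
  target_mean_deg / (p * sqrt(2 / pi))
}

#' Bead--RBC scattering model
#'
#' Trajectory perturbations that emulate collisions of tracer beads with
#' red blood cells: collision events arrive as a Poisson process whose rate
#' scales linearly with hematocrit (45% whole-blood default); each event
#' deflects the step direction by a zero-mean Gaussian angle. By default
#' the deflection scale is calibrated so the realized per-step mean
#' |angle| is 1.2 degrees, the whole-blood measurement at Q = 0.5 uL/min.
#'
#' @param hematocrit RBC volume fraction, percent.
#' @param collision_rate events per second; default `500 * hematocrit/45`.
#' @param deflection_sd Gaussian deflection SD (degrees); default
#'   calibrated via [calibrate_deflection_sd()].
#' @param wall_interaction `"reflect"` (slide along the wall) or
#'   `"absorb"`.
#' @param capture_prob per-step capture probability inside wall-gap (bleed)
#'   cells, emulating the small fraction of cells trapped in the void
#'   region.
#' @param target_mean_angle calibration anchor (degrees) used when
#'   `deflection_sd` is not given.
#' @param dt_ms frame interval assumed for the calibration.
#' @return A `scatter_model` object.
#' @export
scatter_model <- function(hematocrit = 45, collision_rate = NULL,
                          deflection_sd = NULL,
                          wall_interaction = c("reflect", "absorb"),
                          capture_prob = 0.03, target_mean_angle = 1.2,
                          dt_ms = 2) {
  wall_interaction <- match.arg(wall_interaction)
  if (hematocrit < 0) stop("hematocrit must be >= 0")
  if (is.null(collision_rate)) collision_rate <- 500 * hematocrit / 45
  if (collision_rate < 0) stop("collision_rate must be >= 0")
  if (is.null(deflection_sd))
    deflection_sd <- if (collision_rate > 0)
      calibrate_deflection_sd(target_mean_angle, collision_rate, dt_ms)
    else 0
  if (deflection_sd < 0) stop("deflection_sd must be >= 0")
  structure(list(hematocrit = hematocrit, collision_rate = collision_rate,
                 deflection_sd = deflection_sd,
                 wall_interaction = wall_interaction,
                 capture_prob = capture_prob),
            class = "scatter_model")
}

default_optics <- function() {
  list(pixel_size_um = 1, spot_sigma_px = 2, bead_peak = 0.5,
       background = 0.08, noise_sd = 0.01, speckle_contrast = 0.2,
       speckle_corr_um = 6)
}

#' Synthetic acquisition specification
#'
#' Bundles everything needed to synthesize an acquisition: particle count,
#' frame interval (1 frame / 2 ms by default, the experimental rate),
#' frame count, optics (magnification-equivalent pixel size, bead spot
#' width and intensity, RBC speckle contrast and grain, camera noise), the
#' scattering model, and the RNG seed.
#'
#' @param n_particles number of tracer beads.
#' @param n_frames frames to synthesize.
#' @param dt_ms frame interval (ms).
#' @param optics named list merged over the defaults
#'   (`pixel_size_um = 1`, `spot_sigma_px = 2`, `bead_peak = 0.5`,
#'   `background = 0.08`, `noise_sd = 0.01`, `speckle_contrast = 0.2`,
#'   `speckle_corr_um = 6`); intensities are fractions of the 16-bit
#'   range.
#' @param scatter a [scatter_model()].
#' @param seed integer RNG seed; the same spec and seed reproduce
#'   byte-identical trajectories and frames.
#' @param seeding `"uniform"` (particles scattered over the channel) or
#'   `"inlet"`.
#' @param s_range path interval (fractions of total length) where
#'   particles are seeded.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(n_particles = 60, n_frames = 50, dt_ms = 2,
                       optics = list(), scatter = scatter_model(),
                       seed = 1L, seeding = c("uniform", "inlet"),
                       s_range = c(0.05, 0.6)) {
  seeding <- match.arg(seeding)
  if (dt_ms <= 0) stop("dt_ms must be positive")
  if (n_particles < 1 || n_frames < 2)
    stop("need at least 1 particle and 2 frames")
  optics <- modifyList(default_optics(), optics)
  with(optics, if (pixel_size_um <= 0 || spot_sigma_px <= 0 ||
                   bead_peak <= 0 || noise_sd < 0)
    stop("optics parameters must be positive (noise_sd >= 0)"))
  structure(list(n_particles = as.integer(n_particles),
                 n_frames = as.integer(n_frames), dt_ms = dt_ms,
                 optics = optics, scatter = scatter,
                 seed = as.integer(seed), seeding = seeding,
                 s_range = s_range),
            class = "scene_spec")
}

# nearest-cell fluid test for particle positions
pos_is_fluid <- function(grid, x, y) {
  inside <- x > grid$origin[1] & x < grid$origin[1] +
    grid$dim[1] * grid$pixel_size &
    y > grid$origin[2] & y < grid$origin[2] + grid$dim[2] * grid$pixel_size
  out <- logical(length(x))
  if (any(inside)) {
    ij <- grid_cell_index(grid, x[inside], y[inside])
    out[inside] <- grid$mask[ij]
  }
  out
}

#' Advect particles through a flow field
#'
#' Particles follow the local depth-averaged velocity each frame interval.
#' At Poisson collision events (the scattering model) the step direction is
#' deflected by a zero-mean Gaussian angle. Steps that would land in a
#' wall are handled per `wall_interaction`: `"reflect"` keeps the
#' along-flow component (slide), `"absorb"` terminates the particle.
#' Particles reaching the outlet are terminated; particles inside wall-gap
#' cells can be captured with the model's `capture_prob`.
#'
#' @param field a `flow_field`.
#' @param spec a `scene_spec`.
#' @return A `trajectory_set`: long data frame `(particle, frame, t_ms,
#'   x_um, y_um)` with the spec attached as attribute; reproducible given
#'   the seed.
#' @export
advect_particles <- function(field, spec) {
  stopifnot(inherits(field, "flow_field"), inherits(spec, "scene_spec"))
  grid <- field$grid
  set.seed(spec$seed)
  L <- grid$geometry$total_path_length
  px <- grid$pixel_size

  cand <- grid$mask & !grid$gap & !is.na(grid$s) &
    grid$walldist >= 2 * px
  cand <- cand & if (spec$seeding == "inlet")
    grid$s <= max(spec$s_range[1] * L, 6 * px)
  else (grid$s >= spec$s_range[1] * L & grid$s <= spec$s_range[2] * L)
  idx <- which(cand)
  if (!length(idx)) stop("no fluid cells available to seed particles")
  pick <- idx[sample.int(length(idx), spec$n_particles, replace = TRUE)]
  ci <- ((pick - 1L) %% grid$dim[1]) + 1L
  cj <- ((pick - 1L) %/% grid$dim[1]) + 1L
  x <- grid$origin[1] + (ci - 1 + runif(spec$n_particles)) * px
  y <- grid$origin[2] + (cj - 1 + runif(spec$n_particles)) * px

  n <- spec$n_particles
  nf <- spec$n_frames
  X <- matrix(NA_real_, n, nf); Y <- matrix(NA_real_, n, nf)
  X[, 1] <- x; Y[, 1] <- y
  alive <- rep(TRUE, n)
  sm <- spec$scatter
  pcol <- 1 - exp(-sm$collision_rate * spec$dt_ms / 1000)
  sdrad <- sm$deflection_sd * pi / 180

  for (f in seq_len(nf - 1)) {
    if (!any(alive)) break
    ia <- which(alive)
    vx <- grid_interp(grid, field$vx, X[ia, f], Y[ia, f])  # mm/s = um/ms
    vy <- grid_interp(grid, field$vy, X[ia, f], Y[ia, f])
    sx <- vx * spec$dt_ms; sy <- vy * spec$dt_ms
    hit <- runif(length(ia)) < pcol
    if (any(hit) && sdrad > 0) {
      th <- rnorm(sum(hit), 0, sdrad)
      ct <- cos(th); st <- sin(th)
      sx2 <- sx[hit] * ct - sy[hit] * st
      sy2 <- sx[hit] * st + sy[hit] * ct
      sx[hit] <- sx2; sy[hit] <- sy2
    }
    nxp <- X[ia, f] + sx; nyp <- Y[ia, f] + sy
    ok <- pos_is_fluid(grid, nxp, nyp)
    if (any(!ok)) {
      if (sm$wall_interaction == "absorb") {
        alive[ia[!ok]] <- FALSE
      } else {
        bad <- which(!ok)
        ij <- grid_cell_index(grid, X[ia[bad], f], Y[ia[bad], f])
        tx <- grid$tangent_x[ij]; ty <- grid$tangent_y[ij]
        proj <- sx[bad] * tx + sy[bad] * ty
        ax <- X[ia[bad], f] + proj * tx; ay <- Y[ia[bad], f] + proj * ty
        ok2 <- pos_is_fluid(grid, ax, ay)
        nxp[bad[ok2]] <- ax[ok2]; nyp[bad[ok2]] <- ay[ok2]
        nxp[bad[!ok2]] <- X[ia[bad[!ok2]], f]
        nyp[bad[!ok2]] <- Y[ia[bad[!ok2]], f]
        ok[bad] <- TRUE
      }
    }
    st_alive <- ia[ok]
    X[st_alive, f + 1] <- nxp[ok]; Y[st_alive, f + 1] <- nyp[ok]
    ## outlet exit
    ij <- grid_cell_index(grid, X[st_alive, f + 1], Y[st_alive, f + 1])
    sval <- grid$s[ij]
    gone <- !is.na(sval) & sval >= L - 3 * px
    alive[st_alive[gone]] <- FALSE
    ## gap capture
    ing <- grid$gap[ij]
    if (any(ing) && sm$capture_prob > 0) {
      cap <- ing & runif(length(st_alive)) < sm$capture_prob
      alive[st_alive[cap]] <- FALSE
      X[st_alive[cap], f + 1] <- NA; Y[st_alive[cap], f + 1] <- NA
    }
  }

  keep <- !is.na(X)
  df <- data.frame(
    particle = rep(seq_len(n), nf)[keep],
    frame = rep(seq_len(nf), each = n)[keep],
    t_ms = (rep(seq_len(nf), each = n)[keep] - 1) * spec$dt_ms,
    x_um = X[keep], y_um = Y[keep])
  df <- df[order(df$particle, df$frame), ]
  rownames(df) <- NULL
  structure(df, dt_ms = spec$dt_ms, spec = spec, ground_truth = TRUE,
            class = c("trajectory_set", "data.frame"))
}

#' @export
print.trajectory_set <- function(x, ...) {
  len <- table(x$particle)
  cat(sprintf("Trajectory set: %d tracks, %d points, dt = %g ms\n",
              length(len), nrow(x), attr(x, "dt_ms")))
  cat(sprintf("  track length: median %d frames (range %d-%d)\n",
              as.integer(median(len)), min(len), max(len)))
  invisible(x)
}

#' @export
plot.trajectory_set <- function(x, ...) {
  graphics::plot(x$x_um, x$y_um, type = "n", asp = 1,
                 xlab = "x (um)", ylab = "y (um)", ...)
  for (p in unique(x$particle)) {
    s <- x[x$particle == p, ]
    graphics::lines(s$x_um, s$y_um, col = grDevices::hcl.colors(
      max(x$particle), "Dark 3")[p])
  }
  invisible(x)
}

# bilinear sample of a plain matrix M[ix, iy] with given origin/pixel (um)
mat_bilinear <- function(M, origin, px, xq, yq) {
  fx <- (xq - origin[1]) / px - 0.5
  fy <- (yq - origin[2]) / px - 0.5
  i0 <- pmin(pmax(floor(fx), 0), nrow(M) - 2)
  j0 <- pmin(pmax(floor(fy), 0), ncol(M) - 2)
  ax <- pmin(pmax(fx - i0, 0), 1); ay <- pmin(pmax(fy - j0, 0), 1)
  M[cbind(i0 + 1L, j0 + 1L)] * (1 - ax) * (1 - ay) +
    M[cbind(i0 + 2L, j0 + 1L)] * ax * (1 - ay) +
    M[cbind(i0 + 1L, j0 + 2L)] * (1 - ax) * ay +
    M[cbind(i0 + 2L, j0 + 2L)] * ax * ay
}

#' Render microscopy-like frames from trajectories
#'
#' Each frame renders the live beads as 2D Gaussian spots; if a flow field
#' is supplied and the optics request speckle contrast, an RBC-like
#' band-limited speckle texture (filtered white noise, ~6 um grain)
#' advected by the flow is added as label-free PIV texture; Gaussian camera
#' noise tops it off. Intensities live in [0, 1] (written as 16-bit).
#' Rendering is pure: the same inputs and seed give byte-identical frames.
#'
#' @param trajectories a `trajectory_set`.
#' @param spec the `scene_spec` (optics, seed, dt).
#' @param flow optional `flow_field` for speckle advection and fluid
#'   masking.
#' @param window render window `c(xmin, xmax, ymin, ymax)` in um; default
#'   covers the trajectories (or the flow grid if given).
#' @return An `image_sequence`: list of `[nx, ny]` intensity matrices with
#'   pixel size, origin and frame interval attached.
#' @export
render_frames <- function(trajectories, spec, flow = NULL, window = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  op <- spec$optics
  px <- op$pixel_size_um
  if (is.null(window)) {
    window <- if (!is.null(flow)) {
      g <- flow$grid
      fl <- which(g$mask, arr.ind = TRUE)
      c(g$origin[1] + (range(fl[, 1]) + c(-2, 2)) * g$pixel_size,
        g$origin[2] + (range(fl[, 2]) + c(-2, 2)) * g$pixel_size)[c(1, 2, 3, 4)]
    } else {
      c(range(trajectories$x_um) + c(-20, 20),
        range(trajectories$y_um) + c(-20, 20))
    }
  }
  nxp <- ceiling((window[2] - window[1]) / px)
  nyp <- ceiling((window[4] - window[3]) / px)
  if (nxp < 8 || nyp < 8) stop("render window too small")
  org <- c(window[1], window[3])
  nf <- max(trajectories$frame)
  dt <- spec$dt_ms

  set.seed(spec$seed + 1L)
  xpix <- org[1] + (seq_len(nxp) - 0.5) * px
  ypix <- org[2] + (seq_len(nyp) - 0.5) * px
  XP <- rep(xpix, times = nyp); YP <- rep(ypix, each = nxp)

  fluidpix <- NULL; upix <- vpix <- NULL; S0 <- NULL; s0org <- NULL
  if (!is.null(flow)) {
    fluidpix <- pos_is_fluid(flow$grid, XP, YP)
    dim(fluidpix) <- c(nxp, nyp)
    if (op$speckle_contrast > 0) {
      upix <- grid_interp(flow$grid, flow$vx, XP, YP)
      vpix <- grid_interp(flow$grid, flow$vy, XP, YP)
      dim(upix) <- c(nxp, nyp); dim(vpix) <- c(nxp, nyp)
      pad <- ceiling(max(abs(c(upix, vpix))) * dt * nf / px) + 16L
      S0 <- matrix(rnorm((nxp + 2 * pad) * (nyp + 2 * pad)),
                   nxp + 2 * pad, nyp + 2 * pad)
      S0 <- as.matrix(EBImage::gblur(S0, sigma = op$speckle_corr_um / px / 2))
      S0 <- S0 / sd(S0)
      s0org <- org - pad * px
    }
  }

  rad <- ceiling(4 * op$spot_sigma_px)
  frames <- vector("list", nf)
  for (f in seq_len(nf)) {
    fr <- matrix(op$background, nxp, nyp)
    if (!is.null(S0)) {
      sx <- XP - (f - 1) * dt * as.vector(upix)
      sy <- YP - (f - 1) * dt * as.vector(vpix)
      tex <- mat_bilinear(S0, s0org, px, sx, sy)
      dim(tex) <- c(nxp, nyp)
      fr <- fr * (1 + op$speckle_contrast * tex)
    }
    if (!is.null(fluidpix)) fr[!fluidpix] <- op$background * 0.4
    pts <- trajectories[trajectories$frame == f, ]
    if (nrow(pts)) {
      cx <- (pts$x_um - org[1]) / px + 0.5
      cy <- (pts$y_um - org[2]) / px + 0.5
      for (k in seq_len(nrow(pts))) {
        i0 <- max(1L, floor(cx[k] - rad)); i1 <- min(nxp, ceiling(cx[k] + rad))
        j0 <- max(1L, floor(cy[k] - rad)); j1 <- min(nyp, ceiling(cy[k] + rad))
        if (i0 > i1 || j0 > j1) next
        ii <- i0:i1; jj <- j0:j1
        gx <- exp(-(ii - cx[k])^2 / (2 * op$spot_sigma_px^2))
        gy <- exp(-(jj - cy[k])^2 / (2 * op$spot_sigma_px^2))
        fr[ii, jj] <- fr[ii, jj] + op$bead_peak * outer(gx, gy)
      }
    }
    if (op$noise_sd > 0)
      fr <- fr + matrix(rnorm(nxp * nyp, 0, op$noise_sd), nxp, nyp)
    frames[[f]] <- pmin(pmax(fr, 0), 1)
  }
  structure(list(frames = frames, pixel_size_um = px, origin_um = org,
                 dt_ms = dt),
            class = "image_sequence")
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("Image sequence: %d frames of %d x %d px (%g um/px, %g ms)\n",
              length(x$frames), d[1], d[2], x$pixel_size_um, x$dt_ms))
  invisible(x)
}

#' Synthetic speckle frame pair with a known uniform shift
#'
#' Generates band-limited speckle and samples it twice, the second time
#' displaced by an exact (possibly subpixel) shift: ground truth for PIV
#' validation.
#'
#' @param n frame size `c(nx, ny)` in px.
#' @param shift true displacement `c(dx, dy)` in px of the pattern between
#'   frame A and frame B.
#' @param corr_px speckle grain scale (blur sigma, px).
#' @param noise_sd additive Gaussian noise.
#' @param seed RNG seed.
#' @return List with `a`, `b` (matrices) and `shift`.
#' @export
synth_speckle_pair <- function(n = c(128, 128), shift = c(2.5, 0),
                               corr_px = 3, noise_sd = 0, seed = 1) {
  set.seed(seed)
  pad <- ceiling(max(abs(shift))) + 8L
  S <- matrix(rnorm((n[1] + 2 * pad) * (n[2] + 2 * pad)),
              n[1] + 2 * pad, n[2] + 2 * pad)
  S <- as.matrix(EBImage::gblur(S, sigma = corr_px))
  S <- 0.5 + 0.2 * S / sd(S)
  xq <- rep(seq_len(n[1]), times = n[2]) + pad
  yq <- rep(seq_len(n[2]), each = n[1]) + pad
  samp <- function(dx, dy) {
    v <- mat_bilinear(S, c(0, 0), 1, xq - dx, yq - dy)
    dim(v) <- n
    v
  }
  a <- samp(0, 0); b <- samp(shift[1], shift[2])
  if (noise_sd > 0) {
    a <- a + matrix(rnorm(prod(n), 0, noise_sd), n[1], n[2])
    b <- b + matrix(rnorm(prod(n), 0, noise_sd), n[1], n[2])
  }
  list(a = pmin(pmax(a, 0), 1), b = pmin(pmax(b, 0), 1), shift = shift)
}
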