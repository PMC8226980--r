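#' Build a serpentine channel geometry
#'
#' Constructs the planform centerline of a serpentine microchannel:
#' `n_segments` straight limbs joined by 180-degree circular bends, with a
#' rectangular cross-section `width` x `height`. The default configuration
#' reproduces a device of ~200 mm total path length at 200 um x 50 um
#' cross-section; only these three quantities are constrained by the
#' physical device, so limb length, limb count and bend radius are free
#' design parameters.
#'
#' @param width channel width (um), spanwise.
#' @param height channel height (um), out-of-plane depth.
#' @param segment_length straight limb length (um).
#' @param n_segments number of straight limbs (>= 1).
#' @param bend_radius centerline radius of the 180-degree bends (um); must
#'   exceed `width / 2` when bends are present.
#' @return A `channel_geometry` object: the piecewise centerline (straight
#'   and arc pieces), cross-section dimensions, total path length (um) and
#'   an initially empty defect list.
#' @examples
#' g <- build_serpentine()
#' g$total_path_length / 1000  # mm, ~200
#' @export
build_serpentine <- function(width = 200, height = 50,
                             segment_length = 5000, n_segments = 34,
                             bend_radius = 300) {
  if (width <= 0 || height <= 0 || segment_length <= 0 || bend_radius <= 0)
    stop("channel dimensions must be positive")
  n_segments <- as.integer(n_segments)
  if (n_segments < 1) stop("n_segments must be >= 1")
  if (n_segments > 1 && bend_radius <= width / 2)
    stop("bend_radius must exceed width/2")

  pieces <- list()
  s0 <- 0
  for (i in seq_len(n_segments)) {
    y <- (i - 1) * 2 * bend_radius
    fwd <- i %% 2 == 1
    p0 <- c(if (fwd) 0 else segment_length, y)
    d <- c(if (fwd) 1 else -1, 0)
    pieces[[length(pieces) + 1L]] <-
      list(type = "straight", p0 = p0, dir = d, len = segment_length, s0 = s0)
    s0 <- s0 + segment_length
    if (i < n_segments) {
      cx <- if (fwd) segment_length else 0
      # forward limbs turn counter-clockwise at the right end, return limbs
      # clockwise at the left end; both sweep half a circle
      pieces[[length(pieces) + 1L]] <-
        list(type = "arc", c = c(cx, y + bend_radius), r = bend_radius,
             th0 = -pi / 2, dth = if (fwd) pi else -pi, s0 = s0)
      s0 <- s0 + pi * bend_radius
    }
  }
  structure(list(width = width, height = height,
                 segment_length = segment_length, n_segments = n_segments,
                 bend_radius = bend_radius, pieces = pieces,
                 total_path_length = s0, defects = list()),
            class = "channel_geometry")
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat("Serpentine channel geometry\n")
  cat(sprintf("  cross-section : %g um x %g um (width x height)\n",
              x$width, x$height))
  cat(sprintf("  limbs         : %d x %g um, bend radius %g um\n",
              x$n_segments, x$segment_length, x$bend_radius))
  cat(sprintf("  path length   : %.2f mm\n", x$total_path_length / 1000))
  if (length(x$defects))
    cat(sprintf("  defects       : %s\n",
                paste(vapply(x$defects, function(d)
                  sprintf("%s@%.2fmm", d$kind, d$path_position), ""),
                  collapse = ", ")))
  invisible(x)
}

#' Describe a channel defect
#'
#' A defect is either a clot-like wall-attached occlusion (`"clot"`)
#' blocking a fraction of the channel width, or a wall gap (`"wall_gap"`)
#' opening an aperture through the wall separating two adjacent serpentine
#' limbs, the "hemorrhage" scenario.
#'
#' @param kind `"clot"` or `"wall_gap"`.
#' @param path_position position along the centerline, in mm.
#' @param spanwise_extent clot only: blocked fraction of the width (0, 1).
#' @param gap_length wall gap only: aperture length along the wall (um);
#'   the device-relevant value is ~20 um.
#' @param wall_side `"inner"` (wall on the positive-lateral, left-of-travel
#'   side, facing the next limb on odd limbs) or `"outer"`.
#' @param clot_length clot extent along the flow direction (um).
#' @return A `channel_defect` object.
#' @export
defect <- function(kind = c("clot", "wall_gap"), path_position,
                   spanwise_extent = 0.5, gap_length = 20,
                   wall_side = c("inner", "outer"), clot_length = 200) {
  kind <- match.arg(kind)
  wall_side <- match.arg(wall_side)
  if (kind == "clot" && (spanwise_extent <= 0 || spanwise_extent >= 1))
    stop("spanwise_extent must be in (0, 1)")
  if (kind == "wall_gap" && gap_length <= 0)
    stop("gap_length must be positive")
  if (clot_length <= 0) stop("clot_length must be positive")
  structure(list(kind = kind, path_position = path_position,
                 spanwise_extent = spanwise_extent, gap_length = gap_length,
                 wall_side = wall_side, clot_length = clot_length),
            class = "channel_defect")
}

# extent of a defect along the path, um
defect_interval <- function(d) {
  s0 <- d$path_position * 1000
  half <- if (d$kind == "clot") d$clot_length / 2 else d$gap_length / 2
  c(s0 - half, s0 + half)
}

#' Add a defect to a channel geometry
#'
#' @param geometry a `channel_geometry`.
#' @param def a `channel_defect` from [defect()].
#' @return The geometry with the defect recorded. Defects may not overlap
#'   along the path, and a wall gap must sit on a straight limb of a
#'   multi-limb serpentine (it connects two adjacent limbs).
#' @export
add_defect <- function(geometry, def) {
  stopifnot(inherits(geometry, "channel_geometry"),
            inherits(def, "channel_defect"))
  s0 <- def$path_position * 1000
  if (s0 <= 0 || s0 >= geometry$total_path_length)
    stop("defect path_position outside the channel")
  iv <- defect_interval(def)
  for (d in geometry$defects)
    if (max(iv[1], defect_interval(d)[1]) < min(iv[2], defect_interval(d)[2]))
      stop("overlapping defects are not supported")
  pid <- piece_at(geometry, s0)
  if (def$kind == "wall_gap") {
    if (geometry$pieces[[pid]]$type != "straight")
      stop("a wall_gap must be placed on a straight limb")
    if (geometry$n_segments < 2)
      stop("a wall_gap needs an adjacent limb to connect to")
    if (2 * geometry$bend_radius <= geometry$width)
      stop("limb spacing leaves no wall to open a gap through")
  }
  geometry$defects <- c(geometry$defects, list(def))
  geometry
}

# index of the piece containing arclength s (um)
piece_at <- function(geometry, s) {
  s0s <- vapply(geometry$pieces, `[[`, 0, "s0")
  max(findInterval(s, s0s), 1L)
}

piece_len <- function(p) if (p$type == "straight") p$len else p$r * abs(p$dth)

#' Centerline point and tangent at a path position
#'
#' @param geometry a `channel_geometry`.
#' @param s arclength position(s) along the centerline (um).
#' @return A list with matrices `point` and `tangent` (one row per `s`),
#'   in um / unit vectors.
#' @export
path_point <- function(geometry, s) {
  pt <- matrix(NA_real_, length(s), 2)
  tg <- matrix(NA_real_, length(s), 2)
  for (k in seq_along(s)) {
    p <- geometry$pieces[[piece_at(geometry, s[k])]]
    ds <- s[k] - p$s0
    if (p$type == "straight") {
      pt[k, ] <- p$p0 + ds * p$dir
      tg[k, ] <- p$dir
    } else {
      th <- p$th0 + sign(p$dth) * ds / p$r
      pt[k, ] <- p$c + p$r * c(cos(th), sin(th))
      tg[k, ] <- if (p$dth > 0) c(-sin(th), cos(th)) else c(sin(th), -cos(th))
    }
  }
  list(point = pt, tangent = tg)
}

#' Rasterize a channel geometry onto a planform grid
#'
#' Produces the cell-centered occupancy mask and the coordinate maps used by
#' the flow solver and the measurement modules: arclength `s` along the
#' centerline, signed lateral offset (positive to the left of the travel
#' direction), unit tangent, piece index, wall distance (Euclidean distance
#' transform), and inlet/outlet/gap cell flags. Defects recorded on the
#' geometry are carved into the mask.
#'
#' @param geometry a `channel_geometry`.
#' @param pixel_size cell size (um); must resolve the width (<= width/10)
#'   and any wall gap (<= gap_length/4).
#' @param margin solid padding around the planform (um, default 2 pixels).
#' @return A `planform_grid` object.
#' @export
rasterize <- function(geometry, pixel_size = 5, margin = NULL) {
  stopifnot(inherits(geometry, "channel_geometry"))
  if (pixel_size > geometry$width / 10)
    stop("pixel_size too coarse: must be <= width/10")
  for (d in geometry$defects) {
    if (d$kind == "wall_gap" && pixel_size > d$gap_length / 4)
      stop("pixel_size too coarse to resolve the wall gap")
    if (d$kind == "clot" &&
        pixel_size > (1 - d$spanwise_extent) * geometry$width / 4)
      stop("pixel_size too coarse to resolve the constriction")
  }
  if (is.null(margin)) margin <- 2 * pixel_size
  w2 <- geometry$width / 2

  ## bounding box
  xr <- yr <- c(Inf, -Inf)
  grow <- function(r, v) c(min(r[1], min(v)), max(r[2], max(v)))
  for (p in geometry$pieces) {
    if (p$type == "straight") {
      p1 <- p$p0 + p$len * p$dir
      xr <- grow(xr, c(p$p0[1], p1[1]) + c(-1, 1) * w2)
      yr <- grow(yr, c(p$p0[2], p1[2]) + c(-1, 1) * w2)
    } else {
      xr <- grow(xr, p$c[1] + c(-1, 1) * (p$r + w2))
      yr <- grow(yr, p$c[2] + c(-1, 1) * (p$r + w2))
    }
  }
  x0 <- xr[1] - margin; y0 <- yr[1] - margin
  nx <- ceiling((xr[2] - xr[1] + 2 * margin) / pixel_size)
  ny <- ceiling((yr[2] - yr[1] + 2 * margin) / pixel_size)

  xc <- x0 + (seq_len(nx) - 0.5) * pixel_size
  yc <- y0 + (seq_len(ny) - 0.5) * pixel_size
  X <- rep(xc, times = ny); Y <- rep(yc, each = nx)
  n <- nx * ny

  mask <- logical(n)
  smap <- latmap <- tx <- ty <- rep(NA_real_, n)
  pidmap <- rep(NA_integer_, n)
  tol <- 1e-9
  for (k in seq_along(geometry$pieces)) {
    p <- geometry$pieces[[k]]
    if (p$type == "straight") {
      rx <- X - p$p0[1]; ry <- Y - p$p0[2]
      t <- rx * p$dir[1] + ry * p$dir[2]
      lat <- -rx * p$dir[2] + ry * p$dir[1]
      ins <- t >= -tol & t <= p$len + tol & abs(lat) <= w2
      new <- ins & !mask
      smap[new] <- p$s0 + t[new]
      latmap[new] <- lat[new]
      tx[new] <- p$dir[1]; ty[new] <- p$dir[2]
    } else {
      rx <- X - p$c[1]; ry <- Y - p$c[2]
      rp <- sqrt(rx^2 + ry^2)
      th <- atan2(ry, rx)
      frac <- if (p$dth > 0) ((th - p$th0) %% (2 * pi)) / p$dth
              else ((p$th0 - th) %% (2 * pi)) / abs(p$dth)
      ins <- frac >= 0 & frac <= 1 & abs(rp - p$r) <= w2
      new <- ins & !mask
      smap[new] <- p$s0 + frac[new] * p$r * abs(p$dth)
      latmap[new] <- if (p$dth > 0) p$r - rp[new] else rp[new] - p$r
      if (p$dth > 0) { tx[new] <- -sin(th[new]); ty[new] <- cos(th[new]) }
      else           { tx[new] <-  sin(th[new]); ty[new] <- -cos(th[new]) }
    }
    pidmap[ins & !mask] <- k
    mask <- mask | ins
  }

  gap <- logical(n)
  for (d in geometry$defects) {
    side <- if (d$wall_side == "inner") 1 else -1
    s0 <- d$path_position * 1000
    if (d$kind == "clot") {
      sel <- mask & !is.na(smap) & abs(smap - s0) <= d$clot_length / 2 &
        side * latmap >= w2 - d$spanwise_extent * geometry$width
      sel[is.na(sel)] <- FALSE
      mask[sel] <- FALSE
    } else {
      p <- geometry$pieces[[piece_at(geometry, s0)]]
      rx <- X - p$p0[1]; ry <- Y - p$p0[2]
      t <- rx * p$dir[1] + ry * p$dir[2]
      lat <- -rx * p$dir[2] + ry * p$dir[1]
      reach <- 2 * geometry$bend_radius - geometry$width
      sel <- abs(t - (s0 - p$s0)) <= d$gap_length / 2 &
        side * lat > w2 - pixel_size &
        side * lat < w2 + reach + pixel_size
      newly <- sel & !mask
      gap[newly] <- TRUE
      smap[newly] <- s0
      latmap[newly] <- side * w2
      tx[newly] <- side * -p$dir[2]; ty[newly] <- side * p$dir[1]
      pidmap[newly] <- NA_integer_
      mask <- mask | sel
    }
  }

  dim(mask) <- c(nx, ny); dim(smap) <- c(nx, ny); dim(latmap) <- c(nx, ny)
  dim(tx) <- c(nx, ny); dim(ty) <- c(nx, ny); dim(pidmap) <- c(nx, ny)
  dim(gap) <- c(nx, ny)

  lab <- EBImage::bwlabel(mask * 1)
  if (max(lab) > 1)
    stop("rasterized fluid domain is disconnected (", max(lab),
         " components); check defects and pixel_size")
  walldist <- as.matrix(EBImage::distmap(mask * 1)) * pixel_size

  band <- 2 * pixel_size
  inlet <- mask & !is.na(smap) & smap <= band & !gap
  outlet <- mask & !is.na(smap) &
    smap >= geometry$total_path_length - band & !gap
  inlet[is.na(inlet)] <- FALSE; outlet[is.na(outlet)] <- FALSE
  if (!any(inlet) || !any(outlet))
    stop("failed to locate inlet/outlet cells")

  structure(list(pixel_size = pixel_size, origin = c(x0, y0),
                 dim = c(nx, ny), mask = mask, s = smap, lateral = latmap,
                 tangent_x = tx, tangent_y = ty, piece = pidmap,
                 walldist = walldist, gap = gap, inlet = inlet,
                 outlet = outlet, geometry = geometry),
            class = "planform_grid")
}

#' @export
print.planform_grid <- function(x, ...) {
  cat("Planform grid\n")
  cat(sprintf("  %d x %d cells at %g um (%0.f fluid cells)\n",
              x$dim[1], x$dim[2], x$pixel_size, sum(x$mask)))
  cat(sprintf("  origin (%.1f, %.1f) um; inlet %d, outlet %d, gap %d cells\n",
              x$origin[1], x$origin[2], sum(x$inlet), sum(x$outlet),
              sum(x$gap)))
  invisible(x)
}

# cell-center coordinate vectors (um)
grid_xc <- function(grid) grid$origin[1] +
  (seq_len(grid$dim[1]) - 0.5) * grid$pixel_size
grid_yc <- function(grid) grid$origin[2] +
  (seq_len(grid$dim[2]) - 0.5) * grid$pixel_size

# bilinear interpolation of a cell-centered map at (x, y) um.
# Solid or out-of-domain cells contribute `fill` (0 for velocities keeps
# the no-slip behaviour near walls).
grid_interp <- function(grid, map, x, y, fill = 0) {
  px <- grid$pixel_size
  fx <- (x - grid$origin[1]) / px - 0.5
  fy <- (y - grid$origin[2]) / px - 0.5
  i0 <- floor(fx); j0 <- floor(fy)
  ax <- fx - i0; ay <- fy - j0
  m <- map
  m[!grid$mask] <- fill
  m[is.na(m)] <- fill
  get <- function(i, j) {
    ok <- i >= 0 & i <= grid$dim[1] - 1 & j >= 0 & j <= grid$dim[2] - 1
    v <- numeric(length(i))
    v[ok] <- m[cbind(i[ok] + 1L, j[ok] + 1L)]
    v[!ok] <- fill
    v
  }
  get(i0, j0) * (1 - ax) * (1 - ay) + get(i0 + 1, j0) * ax * (1 - ay) +
    get(i0, j0 + 1) * (1 - ax) * ay + get(i0 + 1, j0 + 1) * ax * ay
}

# nearest-cell lookup (list of index matrices clipped to the grid)
grid_cell_index <- function(grid, x, y) {
  i <- pmin(pmax(ceiling((x - grid$origin[1]) / grid$pixel_size), 1L),
            grid$dim[1])
  j <- pmin(pmax(ceiling((y - grid$origin[2]) / grid$pixel_size), 1L),
            grid$dim[2])
  cbind(i, j)
}

#' Export the fluid mask as an 8-bit TIFF
#'
#' Writes a single-page uint8 image (0 = solid, 255 = fluid) for visual
#' inspection; rows run from the top of the planform (decreasing y).
#'
#' @param grid a `planform_grid`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(grid, path) {
  img <- t(grid$mask * 1)[rev(seq_len(grid$dim[2])), , drop = FALSE]
  tiff::writeTIFF(img, path, bits.per.sample = 8)
  invisible(path)
}
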