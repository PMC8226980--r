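## File interfaces: multi-page TIFF stacks (16-bit), CSV trajectory and
## vector tables, JSON manifests. Internal frame orientation is [nx, ny]
## with y increasing upward; TIFFs are written in display orientation
## (row 1 = top).

frame_to_display <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
display_to_frame <- function(m) t(m[rev(seq_len(nrow(m))), , drop = FALSE])

#' Write an image sequence as a multi-page 16-bit TIFF
#'
#' A JSON sidecar (`<path>.json`) records pixel size, origin and frame
#' interval so the stack can be re-read without loss of geometry.
#'
#' @param seq an `image_sequence`.
#' @param path output TIFF path.
#' @param sidecar write the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_frames <- function(seq, path, sidecar = TRUE) {
  stopifnot(inherits(seq, "image_sequence"))
  tiff::writeTIFF(lapply(seq$frames, frame_to_display), path,
                  bits.per.sample = 16)
  if (sidecar)
    jsonlite::write_json(
      list(pixel_size_um = seq$pixel_size_um, origin_um = seq$origin_um,
           dt_ms = seq$dt_ms, n_frames = length(seq$frames)),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image sequence from a multi-page TIFF
#'
#' @param path TIFF path; geometry is restored from the `<path>.json`
#'   sidecar when present, else from the arguments.
#' @param pixel_size_um,origin_um,dt_ms fallback geometry.
#' @return An `image_sequence`.
#' @export
read_frames <- function(path, pixel_size_um = 1, origin_um = c(0, 0),
                        dt_ms = 2) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sc <- paste0(path, ".json")
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    pixel_size_um <- meta$pixel_size_um
    origin_um <- meta$origin_um
    dt_ms <- meta$dt_ms
  }
  structure(list(frames = lapply(pages, display_to_frame),
                 pixel_size_um = pixel_size_um,
                 origin_um = origin_um, dt_ms = dt_ms),
            class = "image_sequence")
}

#' Write / read trajectory tables
#'
#' CSV with columns `particle, frame, t_ms, x_um, y_um`.
#'
#' @param traj a `trajectory_set`.
#' @param path CSV path.
#' @return `path` (write) or a `trajectory_set` (read).
#' @export
write_tracks_csv <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory_set"))
  write.csv(as.data.frame(traj)[, c("particle", "frame", "t_ms",
                                    "x_um", "y_um")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  df <- read.csv(path)
  need <- c("particle", "frame", "t_ms", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("trajectory CSV must have columns ", paste(need, collapse = ", "))
  df <- df[order(df$particle, df$frame), need]
  rownames(df) <- NULL
  dt <- if (nrow(df) > 1) min(diff(sort(unique(df$t_ms)))) else NA_real_
  structure(df, dt_ms = dt, ground_truth = FALSE,
            class = c("trajectory_set", "data.frame"))
}

#' Export a solved flow field as CSV
#'
#' One row per fluid cell: position (um), velocity (mm/s), pressure (Pa)
#' and local viscosity (Pa s).
#'
#' @param field a `flow_field`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, path) {
  stopifnot(inherits(field, "flow_field"))
  grid <- field$grid
  sel <- which(grid$mask, arr.ind = TRUE)
  df <- data.frame(
    x_um = grid_xc(grid)[sel[, 1]], y_um = grid_yc(grid)[sel[, 2]],
    vx_mm_s = field$vx[sel], vy_mm_s = field$vy[sel],
    pressure_Pa = field$pressure[sel], viscosity_Pa_s = field$eta[sel])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a normalized speed-magnitude raster as 32-bit float TIFF
#'
#' Min--max normalized to `[0, 1]` (the convention of normalized
#' vector-magnitude plots); solid cells are written as 0.
#'
#' @param field a `flow_field`.
#' @param path TIFF path.
#' @return `path`, invisibly.
#' @export
write_magnitude_tiff <- function(field, path) {
  stopifnot(inherits(field, "flow_field"))
  m <- field$speed
  rng <- range(m, na.rm = TRUE)
  m <- (m - rng[1]) / max(diff(rng), 1e-300)
  m[is.na(m)] <- 0
  tiff::writeTIFF(frame_to_display(m), path, bits.per.sample = 32)
  invisible(path)
}

#' Export a PIV displacement field as CSV
#'
#' @param field a `displacement_field`.
#' @param path CSV path; PIV parameters are echoed into a `<path>.json`
#'   sidecar.
#' @return `path`, invisibly.
#' @export
write_piv_csv <- function(field, path) {
  stopifnot(inherits(field, "displacement_field"))
  cols <- c("x_um", "y_um", "u_mm_s", "v_mm_s", "peak", "snr",
            "valid", "interpolated")
  write.csv(as.data.frame(field)[, cols], path, row.names = FALSE)
  jsonlite::write_json(
    list(window_px = attr(field, "window"), search_px = attr(field, "search"),
         overlap = attr(field, "overlap"), dt_ms = attr(field, "dt_ms"),
         pixel_size_um = attr(field, "pixel_size_um")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
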