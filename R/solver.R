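## Depth-averaged planform flow solver.
##
## Momentum:  div(eta grad v) - (12 eta / h^2) v = grad p   (Stokes-Brinkman)
## Mass:      div v = 0
## on the rasterized planform, MAC staggered discretization (velocities on
## cell faces, pressure at cell centers). The 12 eta/h^2 drag is the
## Hele-Shaw closure for the out-of-plane parabolic profile; the in-plane
## viscous term restores no-slip at the side walls. Flow is driven by a
## source distributed over the inlet cells (fixed flow rate) and absorbed
## in the outlet cells, where the pressure is pinned to zero.
## Valid at vanishing Reynolds number (Re ~ 1e-2 for these channels).

# one linear Stokes-Brinkman solve for a given cell viscosity map (Pa s).
# Returns face velocities (m/s) and cell pressures (Pa).
stokes_brinkman_solve <- function(grid, eta_cells, Q) {
  nx <- grid$dim[1]; ny <- grid$dim[2]
  dx <- grid$pixel_size * 1e-6
  h <- grid$geometry$height * 1e-6
  mask <- grid$mask
  if (any(mask[1, ]) || any(mask[nx, ]) || any(mask[, 1]) || any(mask[, ny]))
    stop("fluid touches the grid border; rasterize with a larger margin")

  eta_ref <- mean(eta_cells[mask])
  EtaC <- eta_cells
  EtaC[!mask] <- eta_ref   # never used across walls, keeps arithmetic finite

  ufl <- mask[seq_len(nx - 1), , drop = FALSE] &
    mask[2:nx, , drop = FALSE]
  vfl <- mask[, seq_len(ny - 1), drop = FALSE] &
    mask[, 2:ny, drop = FALSE]
  uid <- matrix(0L, nx - 1, ny); uid[ufl] <- seq_len(sum(ufl))
  Nu <- sum(ufl)
  vid <- matrix(0L, nx, ny - 1); vid[vfl] <- Nu + seq_len(sum(vfl))
  Nv <- sum(vfl)
  pcell <- mask & !grid$outlet
  pid <- matrix(0L, nx, ny); pid[pcell] <- Nu + Nv + seq_len(sum(pcell))
  Np <- sum(pcell)
  N <- Nu + Nv + Np

  adx2 <- 12 * dx^2 / h^2   # times eta_f later
  II <- vector("list", 32); JJ <- II; XX <- II; kk <- 0L
  put <- function(r, c, x) {
    kk <<- kk + 1L; II[[kk]] <<- r; JJ[[kk]] <<- c; XX[[kk]] <<- x
  }

  ## ---- u-face momentum (face between cells (i,j) and (i+1,j)) ----
  fi <- which(ufl)
  i <- ((fi - 1L) %% (nx - 1L)) + 1L
  j <- ((fi - 1L) %/% (nx - 1L)) + 1L
  r <- uid[fi]
  etaL <- EtaC[cbind(i, j)]; etaR <- EtaC[cbind(i + 1L, j)]
  etaf <- (etaL + etaR) / 2
  cornU <- mask[cbind(i, pmin(j + 1L, ny))] &
    mask[cbind(i + 1L, pmin(j + 1L, ny))] & (j < ny)
  cornD <- mask[cbind(i, pmax(j - 1L, 1L))] &
    mask[cbind(i + 1L, pmax(j - 1L, 1L))] & (j > 1L)
  etaN <- ifelse(cornU,
                 (etaL + etaR + EtaC[cbind(i, pmin(j + 1L, ny))] +
                    EtaC[cbind(i + 1L, pmin(j + 1L, ny))]) / 4, etaf)
  etaS <- ifelse(cornD,
                 (etaL + etaR + EtaC[cbind(i, pmax(j - 1L, 1L))] +
                    EtaC[cbind(i + 1L, pmax(j - 1L, 1L))]) / 4, etaf)
  cen <- -(etaR + etaL) - adx2 * etaf
  hasE <- i + 1L <= nx - 1L & ufl[cbind(pmin(i + 1L, nx - 1L), j)]
  hasW <- i - 1L >= 1L & ufl[cbind(pmax(i - 1L, 1L), j)]
  hasN <- j + 1L <= ny & ufl[cbind(i, pmin(j + 1L, ny))]
  hasS <- j - 1L >= 1L & ufl[cbind(i, pmax(j - 1L, 1L))]
  put(r[hasE], uid[cbind(i[hasE] + 1L, j[hasE])], etaR[hasE] / eta_ref)
  put(r[hasW], uid[cbind(i[hasW] - 1L, j[hasW])], etaL[hasW] / eta_ref)
  put(r[hasN], uid[cbind(i[hasN], j[hasN] + 1L)], etaN[hasN] / eta_ref)
  put(r[hasS], uid[cbind(i[hasS], j[hasS] - 1L)], etaS[hasS] / eta_ref)
  ## tangential walls sit at dx/2: ghost value -u doubles the coefficient
  cen <- cen - ifelse(hasN, etaN, 2 * etaN) - ifelse(hasS, etaS, 2 * etaS)
  ## note: normal-direction wall (missing E/W unknown) keeps the same
  ## center coefficient (Dirichlet 0 at distance dx), already in cen
  put(r, r, cen / eta_ref)
  pR <- pid[cbind(i + 1L, j)]; pL <- pid[cbind(i, j)]
  put(r[pR > 0], pR[pR > 0], rep(-1, sum(pR > 0)))
  put(r[pL > 0], pL[pL > 0], rep(1, sum(pL > 0)))

  ## ---- v-face momentum (face between cells (i,j) and (i,j+1)) ----
  fi <- which(vfl)
  i <- ((fi - 1L) %% nx) + 1L
  j <- ((fi - 1L) %/% nx) + 1L
  r <- vid[fi]
  etaS2 <- EtaC[cbind(i, j)]; etaN2 <- EtaC[cbind(i, j + 1L)]
  etaf <- (etaS2 + etaN2) / 2
  cornE <- (i < nx) & mask[cbind(pmin(i + 1L, nx), j)] &
    mask[cbind(pmin(i + 1L, nx), j + 1L)]
  cornW <- (i > 1L) & mask[cbind(pmax(i - 1L, 1L), j)] &
    mask[cbind(pmax(i - 1L, 1L), j + 1L)]
  etaE <- ifelse(cornE,
                 (etaS2 + etaN2 + EtaC[cbind(pmin(i + 1L, nx), j)] +
                    EtaC[cbind(pmin(i + 1L, nx), j + 1L)]) / 4, etaf)
  etaW <- ifelse(cornW,
                 (etaS2 + etaN2 + EtaC[cbind(pmax(i - 1L, 1L), j)] +
                    EtaC[cbind(pmax(i - 1L, 1L), j + 1L)]) / 4, etaf)
  cen <- -(etaN2 + etaS2) - adx2 * etaf
  hasN <- j + 1L <= ny - 1L & vfl[cbind(i, pmin(j + 1L, ny - 1L))]
  hasS <- j - 1L >= 1L & vfl[cbind(i, pmax(j - 1L, 1L))]
  hasE <- i + 1L <= nx & vfl[cbind(pmin(i + 1L, nx), j)]
  hasW <- i - 1L >= 1L & vfl[cbind(pmax(i - 1L, 1L), j)]
  put(r[hasN], vid[cbind(i[hasN], j[hasN] + 1L)], etaN2[hasN] / eta_ref)
  put(r[hasS], vid[cbind(i[hasS], j[hasS] - 1L)], etaS2[hasS] / eta_ref)
  put(r[hasE], vid[cbind(i[hasE] + 1L, j[hasE])], etaE[hasE] / eta_ref)
  put(r[hasW], vid[cbind(i[hasW] - 1L, j[hasW])], etaW[hasW] / eta_ref)
  cen <- cen - ifelse(hasE, etaE, 2 * etaE) - ifelse(hasW, etaW, 2 * etaW)
  put(r, r, cen / eta_ref)
  pN <- pid[cbind(i, j + 1L)]; pS <- pid[cbind(i, j)]
  put(r[pN > 0], pN[pN > 0], rep(-1, sum(pN > 0)))
  put(r[pS > 0], pS[pS > 0], rep(1, sum(pS > 0)))

  ## ---- continuity at pressure cells ----
  fi <- which(pcell)
  i <- ((fi - 1L) %% nx) + 1L
  j <- ((fi - 1L) %/% nx) + 1L
  r <- pid[fi]
  hasE <- i <= nx - 1L & ufl[cbind(pmin(i, nx - 1L), j)]
  hasW <- i - 1L >= 1L & ufl[cbind(pmax(i - 1L, 1L), j)]
  hasN <- j <= ny - 1L & vfl[cbind(i, pmin(j, ny - 1L))]
  hasS <- j - 1L >= 1L & vfl[cbind(i, pmax(j - 1L, 1L))]
  put(r[hasE], uid[cbind(i[hasE], j[hasE])], rep(1, sum(hasE)))
  put(r[hasW], uid[cbind(i[hasW] - 1L, j[hasW])], rep(-1, sum(hasW)))
  put(r[hasN], vid[cbind(i[hasN], j[hasN])], rep(1, sum(hasN)))
  put(r[hasS], vid[cbind(i[hasS], j[hasS] - 1L)], rep(-1, sum(hasS)))

  ## inlet source: fixed flow rate distributed over the first inlet column
  ## with the Brinkman spanwise shape (fast profile development)
  rhs <- numeric(N)
  w <- grid$geometry$width
  src <- grid$inlet & grid$s <= grid$pixel_size & !grid$gap
  if (!any(src)) src <- grid$inlet
  lat <- grid$lateral[src]
  kk2 <- sqrt(12) / h
  shape <- 1 - cosh_ratio(kk2 * abs(lat) * 1e-6, kk2 * w / 2 * 1e-6)
  q <- (Q * UL_MIN_TO_M3S) * shape / sum(shape)
  rhs[pid[src]] <- q / (dx * h)

  A <- Matrix::sparseMatrix(i = unlist(II[seq_len(kk)]),
                            j = unlist(JJ[seq_len(kk)]),
                            x = unlist(XX[seq_len(kk)]),
                            dims = c(N, N))
  sol <- as.numeric(Matrix::solve(A, rhs))

  usol <- matrix(0, nx - 1, ny); usol[ufl] <- sol[uid[ufl]]
  vsol <- matrix(0, nx, ny - 1); vsol[vfl] <- sol[vid[vfl]]
  psol <- matrix(0, nx, ny); psol[pcell] <- sol[pid[pcell]] * eta_ref / dx
  list(u = usol, v = vsol, p = psol, ufl = ufl, vfl = vfl)
}

# cell-centered velocities (m/s) from face fields
face_to_cell <- function(grid, fc) {
  nx <- grid$dim[1]; ny <- grid$dim[2]
  uW <- rbind(rep(0, ny), fc$u); uE <- rbind(fc$u, rep(0, ny))
  vS <- cbind(rep(0, nx), fc$v); vN <- cbind(fc$v, rep(0, nx))
  vx <- (uW + uE) / 2; vy <- (vS + vN) / 2
  vx[!grid$mask] <- NA; vy[!grid$mask] <- NA
  list(vx = vx, vy = vy)
}

# characteristic shear rate (1/s): in-plane invariant plus the dominant
# depth-wise contribution sqrt(12) |v| / h
shear_rate_map <- function(grid, vx, vy) {
  dx <- grid$pixel_size * 1e-6
  h <- grid$geometry$height * 1e-6
  z <- function(m) { m[is.na(m)] <- 0; m }
  vx <- z(vx); vy <- z(vy)
  nx <- grid$dim[1]; ny <- grid$dim[2]
  ddx <- function(m) (rbind(m[-1, , drop = FALSE], 0) -
                        rbind(0, m[-nx, , drop = FALSE])) / (2 * dx)
  ddy <- function(m) (cbind(m[, -1, drop = FALSE], 0) -
                        cbind(0, m[, -ny, drop = FALSE])) / (2 * dx)
  gip <- sqrt(2 * ddx(vx)^2 + 2 * ddy(vy)^2 + (ddy(vx) + ddx(vy))^2)
  sp <- sqrt(vx^2 + vy^2)
  g <- sqrt(gip^2 + 12 * sp^2 / h^2)
  g[!grid$mask] <- NA
  g
}

#' Solve the depth-averaged planform flow
#'
#' Steady incompressible flow of a Newtonian or Carreau fluid through the
#' rasterized channel at fixed flow rate, using a staggered-grid
#' Stokes--Brinkman discretization (out-of-plane drag `12 eta/h^2`,
#' in-plane viscosity for side-wall no-slip). The flow rate is imposed as
#' a distributed source over the inlet cells; pressure is pinned to zero
#' over the outlet cells; all other boundaries are no-slip walls. For
#' Carreau fluids the viscosity map is updated from the local
#' characteristic shear rate by relaxed Picard iteration.
#'
#' @param grid a `planform_grid`.
#' @param fluid a `fluid_model`.
#' @param Q flow rate (uL/min).
#' @param tol Picard convergence threshold on the max relative viscosity
#'   update.
#' @param relax Picard relaxation factor.
#' @param maxit Picard iteration cap.
#' @param quiet suppress per-iteration messages.
#' @return A `flow_field`: cell-centered `vx`, `vy`, `speed` (mm/s),
#'   `pressure` (Pa), `shear_rate` (1/s), `eta` (Pa s), plus the staggered
#'   face velocities used for conservative flux queries.
#' @export
solve_planform <- function(grid, fluid, Q, tol = 1e-6, relax = 0.5,
                           maxit = 200, quiet = TRUE) {
  stopifnot(inherits(grid, "planform_grid"), inherits(fluid, "fluid_model"))
  if (Q <= 0) stop("Q must be positive")
  h <- grid$geometry$height * 1e-6
  vbar <- duct_mean_velocity(Q, grid$geometry$width,
                             grid$geometry$height) * 1e-3
  gchar <- sqrt(12) * vbar / h
  eta_cells <- matrix(viscosity(fluid, gchar), grid$dim[1], grid$dim[2])
  newtonian <- fluid$law == "newtonian" ||
    isTRUE(all.equal(fluid$eta0, fluid$etaInf))
  it <- 0L; dmax <- NA_real_
  repeat {
    it <- it + 1L
    fc <- stokes_brinkman_solve(grid, eta_cells, Q)
    cc <- face_to_cell(grid, fc)
    if (newtonian) break
    g <- shear_rate_map(grid, cc$vx, cc$vy)
    eta_new <- eta_cells
    eta_new[grid$mask] <- viscosity(fluid, g[grid$mask])
    dmax <- max(abs(eta_new[grid$mask] - eta_cells[grid$mask]) /
                  eta_cells[grid$mask])
    eta_cells <- eta_cells + relax * (eta_new - eta_cells)
    if (!quiet) message(sprintf("picard %d: max rel d(eta) = %.3g", it, dmax))
    if (dmax < tol) break
    if (it >= maxit) {
      warning("Picard iteration did not converge (", it,
              " iterations, last update ", signif(dmax, 3), ")")
      break
    }
  }
  g <- shear_rate_map(grid, cc$vx, cc$vy)
  eta_out <- eta_cells; eta_out[!grid$mask] <- NA
  vx <- cc$vx * 1e3; vy <- cc$vy * 1e3
  structure(list(grid = grid, fluid = fluid, Q = Q,
                 vx = vx, vy = vy, speed = sqrt(vx^2 + vy^2),
                 pressure = fc$p, shear_rate = g, eta = eta_out,
                 faces = fc[c("u", "v", "ufl", "vfl")],
                 iterations = it, eta_update = dmax),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("Flow field: %s at Q = %g uL/min\n", x$fluid$name, x$Q))
  cat(sprintf("  grid %d x %d at %g um; %d Picard iteration(s)\n",
              x$grid$dim[1], x$grid$dim[2], x$grid$pixel_size, x$iterations))
  cat(sprintf("  peak speed %.3f mm/s, mean %.3f mm/s, max pressure %.2f Pa\n",
              max(x$speed, na.rm = TRUE), mean(x$speed, na.rm = TRUE),
              max(x$pressure, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.flow_field <- function(object, ...) {
  g <- object$grid$geometry
  c(Q_uL_min = object$Q,
    mean_speed_mm_s = mean(object$speed, na.rm = TRUE),
    peak_speed_mm_s = max(object$speed, na.rm = TRUE),
    mean_shear_1_s = mean(object$shear_rate, na.rm = TRUE),
    tau_slit_Pa = slit_wall_shear(object$Q, g$width, g$height,
                                  if (object$fluid$law == "newtonian")
                                    object$fluid$eta
                                  else mean(object$eta, na.rm = TRUE)))
}

#' @export
plot.flow_field <- function(x, what = c("speed", "pressure", "eta",
                                        "shear_rate"), ...) {
  what <- match.arg(what)
  m <- x[[what]]
  graphics::image(grid_xc(x$grid), grid_yc(x$grid), m, asp = 1,
                  xlab = "x (um)", ylab = "y (um)",
                  col = grDevices::hcl.colors(64, "viridis"),
                  main = what, ...)
  invisible(x)
}

#' Volumetric flux through a cross-section
#'
#' Sums the tangential cell velocities over the one-pixel band of cells at
#' arclength `s0`; exact on straight, axis-aligned sections, approximate
#' (one-pixel band geometry) inside bends.
#'
#' @param field a `flow_field`.
#' @param s0 arclength position (um).
#' @return Flux in uL/min (compare with `field$Q`).
#' @export
section_flux <- function(field, s0) {
  grid <- field$grid
  px <- grid$pixel_size
  band <- grid$mask & !grid$gap & !is.na(grid$s) &
    grid$s > s0 - px / 2 & grid$s <= s0 + px / 2
  if (!any(band)) stop("no cells at s0 = ", s0)
  vt <- (field$vx * grid$tangent_x + field$vy * grid$tangent_y)[band] # mm/s
  sum(vt * 1e-3 * (px * 1e-6) * (grid$geometry$height * 1e-6)) /
    UL_MIN_TO_M3S
}

# mean speed over fluid cells in an s-band, away from walls
band_mean_speed <- function(field, s1, s2, core_margin = 0) {
  grid <- field$grid
  sel <- grid$mask & !grid$gap & !is.na(grid$s) &
    grid$s >= s1 & grid$s <= s2 & grid$walldist >= core_margin
  if (!any(sel)) return(NA_real_)
  mean(field$speed[sel])
}

#' Constriction speed-up across a clot defect
#'
#' Ratio of the mean speed in the constricted section (the clot's
#' along-path extent) to the mean speed in an unobstructed reference
#' section of the same length upstream. With half the width blocked, mass
#' conservation makes this ratio approximately two.
#'
#' @param field a `flow_field` solved on a clot-bearing grid.
#' @param which index of the clot among the geometry's clot defects.
#' @param core_margin exclude cells closer than this to a wall (um); use
#'   the same margin when comparing against PIV window statistics.
#' @param reference_offset separation (multiples of the clot length)
#'   between the clot center and the reference section center.
#' @return A list: `ratio`, `constricted_mm_s`, `reference_mm_s`.
#' @export
constriction_speedup <- function(field, which = 1, core_margin = 0,
                                 reference_offset = 2) {
  defs <- Filter(function(d) d$kind == "clot", field$grid$geometry$defects)
  if (length(defs) < which) stop("no such clot defect in the geometry")
  d <- defs[[which]]
  s0 <- d$path_position * 1000
  half <- d$clot_length / 2
  ref0 <- s0 - reference_offset * d$clot_length
  if (ref0 - half < 0) ref0 <- s0 + reference_offset * d$clot_length
  vc <- band_mean_speed(field, s0 - half, s0 + half, core_margin)
  vr <- band_mean_speed(field, ref0 - half, ref0 + half, core_margin)
  list(ratio = vc / vr, constricted_mm_s = vc, reference_mm_s = vr)
}

#' Inner/outer speed asymmetry in a serpentine bend
#'
#' Mean speed over the inner half of a bend (smaller radius) versus the
#' outer half. Pressure-driven flow through a curved channel is faster
#' along the shorter inner path.
#'
#' @param field a `flow_field`.
#' @param bend which bend (1 = first arc piece).
#' @return A list: `inner_mm_s`, `outer_mm_s`, `ratio` (inner/outer).
#' @export
bend_speed_asymmetry <- function(field, bend = 1) {
  grid <- field$grid
  arcs <- which(vapply(grid$geometry$pieces, function(p) p$type == "arc",
                       TRUE))
  if (length(arcs) < bend) stop("geometry has no bend ", bend)
  pidx <- arcs[bend]
  ccw <- grid$geometry$pieces[[pidx]]$dth > 0
  onarc <- !is.na(grid$piece) & grid$piece == pidx & grid$mask
  latsign <- if (ccw) grid$lateral else -grid$lateral
  inner <- onarc & latsign > 0
  outer <- onarc & latsign < 0
  vi <- mean(field$speed[inner], na.rm = TRUE)
  vo <- mean(field$speed[outer], na.rm = TRUE)
  list(inner_mm_s = vi, outer_mm_s = vo, ratio = vi / vo)
}

#' Spanwise velocity profile extracted from a solved field
#'
#' Bins the solved cell speeds by signed lateral coordinate over a section
#' of the path, for comparison with [rect_duct_profile()] (depth-averaged)
#' or with tracked-bead profiles.
#'
#' @param field a `flow_field`.
#' @param s_range path interval to pool (um); defaults to the middle half
#'   of the channel, away from inlet/outlet development regions.
#' @param n_bins number of spanwise bins.
#' @return A `velocity_profile` across `[0, w]`.
#' @export
field_profile <- function(field, s_range = NULL, n_bins = NULL) {
  grid <- field$grid
  w <- grid$geometry$width
  if (is.null(n_bins)) n_bins <- max(10, round(w / grid$pixel_size))
  L <- grid$geometry$total_path_length
  if (is.null(s_range)) s_range <- c(0.25, 0.75) * L
  sel <- grid$mask & !grid$gap & !is.na(grid$s) &
    grid$s >= s_range[1] & grid$s <= s_range[2]
  pos <- grid$lateral[sel] + w / 2
  sp <- field$speed[sel]
  bin <- pmin(pmax(ceiling(pos / (w / n_bins)), 1L), n_bins)
  v <- tapply(sp, factor(bin, levels = seq_len(n_bins)), mean)
  cnt <- tapply(sp, factor(bin, levels = seq_len(n_bins)), length)
  cnt[is.na(cnt)] <- 0L
  velocity_profile_obj((seq_len(n_bins) - 0.5) * w / n_bins, as.numeric(v),
                       span = w, counts = as.integer(cnt), Q = field$Q)
}
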