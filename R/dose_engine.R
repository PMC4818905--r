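## Simplified photon dose engine.
##
## This is a declared surrogate for a clinical convolution/superposition
## algorithm: per control point, the dose at a point is
##
##   D = calibration * MU * F(u, v) * exp(-mu_eff * depth) * (SAD/(SAD+w))^2
##
## where F is the aperture fluence per unit MU at the ray's isocenter-plane
## intersection with a Gaussian penumbra, depth is the path length inside the
## body along the beam direction (parallel-ray radiological depth, binary
## density), and w is the distance of the point beyond the isocenter plane
## along the beam axis. Dose is exactly linear in each control point's MU and
## zero outside the body. No scatter or buildup is modelled; this affects
## absolute dose values but not the optimization and evaluation logic built
## on top.

#' Dose engine configuration
#'
#' @param mu_eff effective linear attenuation (1/mm); default `0.005`
#'   approximates a 6 MV depth-dose falloff in water.
#' @param penumbra_sigma Gaussian penumbra width (mm) applied to the binary
#'   aperture fluence.
#' @param calib_gy_per_mu dose per MU (Gy) for an open ray at zero depth at
#'   the isocenter plane.
#' @param depth_step ray-marching step for the depth integral (mm).
#' @param fluence_cutoff per-unit-MU fluence below which a point is treated
#'   as unirradiated (speed optimization).
#' @return object of class `dose_engine_config`.
#' @export
dose_engine_config <- function(mu_eff = 0.005, penumbra_sigma = 3,
                               calib_gy_per_mu = 0.01, depth_step = 3,
                               fluence_cutoff = 1e-4) {
  cfg <- as.list(environment())
  stopifnot(mu_eff >= 0, penumbra_sigma >= 0, calib_gy_per_mu > 0, depth_step > 0)
  class(cfg) <- "dose_engine_config"
  cfg
}

## beam frame unit vectors for a gantry angle (degrees)
beam_frame <- function(gantry) {
  gr <- gantry * pi / 180
  list(e_u = c(cos(gr), -sin(gr), 0),   # in-plane, rotates with gantry
       e_v = c(0, 0, 1),                # leaf-row stacking axis
       e_w = c(-sin(gr), -cos(gr), 0))  # beam direction (source -> isocenter)
}

## smoothed interval indicator: P(u in (a,b)) under Gaussian blur sigma
blurred_interval <- function(u, a, b, sigma) {
  if (sigma <= 0) return(as.numeric(u > a & u < b))
  pnorm((b - u) / sigma) - pnorm((a - u) / sigma)
}

## per-unit-MU fluence of a control point at isocenter-plane coordinates
## (u, v) given in the *unrotated* beam frame; the collimator rotation is
## applied here
cp_fluence <- function(cp, machine, u, v, sigma) {
  cr <- cp$collimator * pi / 180
  uc <- cos(cr) * u + sin(cr) * v
  vc <- -sin(cr) * u + cos(cr) * v
  jf <- blurred_interval(uc, cp$jaws[1], cp$jaws[2], sigma) *
    blurred_interval(vc, cp$jaws[3], cp$jaws[4], sigma)
  f <- numeric(length(u))
  live <- jf > 1e-6
  if (any(live)) {
    edges <- leaf_row_edges(machine)
    vcl <- vc[live]
    ucl <- uc[live]
    fl <- numeric(length(ucl))
    # rows within 3 sigma + one row of the sample's v contribute
    reach <- 3 * sigma + machine$leaf_width_at_iso
    row0 <- findInterval(vcl, edges, all.inside = TRUE)
    for (dr in -2:2) {
      rr <- row0 + dr
      ok <- rr >= 1 & rr <= machine$n_leaf_pairs
      if (!any(ok)) next
      ok <- ok & abs((edges[pmax(rr, 1)] + machine$leaf_width_at_iso / 2) - vcl) <= reach
      if (!any(ok)) next
      r <- rr[ok]
      wv <- blurred_interval(vcl[ok], edges[r], edges[r + 1], sigma)
      wu <- blurred_interval(ucl[ok], cp$leaves[r, 1], cp$leaves[r, 2], sigma)
      fl[ok] <- fl[ok] + wv * wu
    }
    f[live] <- fl * jf[live]
  }
  f
}

#' Binary aperture fluence map of a control point
#'
#' Rasterizes the open aperture (leaf openings intersected with the jaw
#' rectangle, rotated by the collimator angle) on the isocenter plane and
#' scales it by the control point's MU. This is the unblurred fluence the
#' dose engine smooths with its penumbra model.
#'
#' @param cp a [control_point].
#' @param machine a [machine_model].
#' @param resolution pixel size (mm).
#' @param extent half-size of the map (mm); default covers the jaw rectangle.
#' @return list with pixel-center coordinate vectors `u`, `v` (unrotated beam
#'   frame) and matrix `map` (MU-scaled binary fluence).
#' @export
aperture_fluence <- function(cp, machine, resolution = 1, extent = NULL) {
  validate_control_point(cp, machine)
  if (is.null(extent)) extent <- max(abs(cp$jaws)) + 2 * resolution
  u <- seq(-extent + resolution / 2, extent - resolution / 2, by = resolution)
  v <- u
  uu <- matrix(u, nrow = length(u), ncol = length(v))
  vv <- matrix(v, nrow = length(u), ncol = length(v), byrow = TRUE)
  f <- cp_fluence(cp, machine, as.numeric(uu), as.numeric(vv), sigma = 0)
  list(u = u, v = v, map = matrix(f * cp$mu, nrow = length(u)))
}

## parallel-ray radiological depth (mm) of points inside the body along -e_w
ray_depth <- function(pts, e_w, body, step) {
  grid <- body$grid
  corners <- as.matrix(expand.grid(
    x = grid$origin[1] + c(0, (grid$dims[1] - 1)) * grid$spacing[1],
    y = grid$origin[2] + c(0, (grid$dims[2] - 1)) * grid$spacing[2],
    z = grid$origin[3] + c(0, (grid$dims[3] - 1)) * grid$spacing[3]))
  w_min <- min(corners %*% e_w)
  w_pts <- pts %*% e_w
  s_max <- max(w_pts - w_min)
  if (s_max <= 0) return(numeric(nrow(pts)))
  n_steps <- ceiling(s_max / step)
  depth <- numeric(nrow(pts))
  bodyv <- body$mask + 0
  for (m in seq_len(n_steps)) {
    s <- (m - 0.5) * step
    active <- s <= (w_pts - w_min)
    if (!any(active)) break
    q <- pts[active, , drop = FALSE] -
      matrix(e_w * s, nrow = sum(active), ncol = 3, byrow = TRUE)
    depth[active] <- depth[active] + sample_nearest(bodyv, grid, q) * step
  }
  depth
}

## per-unit-MU dose of one control point at arbitrary points (assumed inside
## the body); vectorized over points
cp_point_dose <- function(cp, machine, pts, body, engine) {
  fr <- beam_frame(cp$gantry)
  rel <- sweep(pts, 2, c(0, 0, 0))
  w <- as.numeric(rel %*% fr$e_w)
  sad <- machine$source_axis_distance
  mag <- sad / (sad + w)
  u_iso <- as.numeric(rel %*% fr$e_u) * mag
  v_iso <- as.numeric(rel %*% fr$e_v) * mag
  f <- cp_fluence(cp, machine, u_iso, v_iso, engine$penumbra_sigma)
  dose <- numeric(nrow(pts))
  live <- f > engine$fluence_cutoff
  if (any(live)) {
    depth <- ray_depth(pts[live, , drop = FALSE], fr$e_w, body, engine$depth_step)
    dose[live] <- engine$calib_gy_per_mu * f[live] *
      exp(-engine$mu_eff * depth) * mag[live]^2
  }
  dose
}

#' Dose influence matrix at sample points
#'
#' Per-unit-MU dose of every control point of a list of beams at a set of
#' points. Column order follows beams and their control points in sequence.
#'
#' @param beams list of [beam]s.
#' @param machine a [machine_model].
#' @param pts `n x 3` matrix of world positions (mm), inside the body.
#' @param body the body [structure_mask].
#' @param engine a [dose_engine_config].
#' @return `n x n_cp` dense matrix.
#' @export
dose_influence <- function(beams, machine, pts, body, engine = dose_engine_config()) {
  cps <- unlist(lapply(beams, function(b) b$control_points), recursive = FALSE)
  A <- matrix(0, nrow = nrow(pts), ncol = length(cps))
  for (j in seq_along(cps)) {
    A[, j] <- cp_point_dose(cps[[j]], machine, pts, body, engine)
  }
  A
}

#' Compute the 3D dose of a beam set
#'
#' Sums the per-control-point dose model over all control points of all
#' beams, on the voxels of `grid` inside the body; dose is zero outside the
#' body and exactly linear in every control point's MU.
#'
#' @param beams a [beam] or list of beams.
#' @param grid the dose [image_grid].
#' @param body the body [structure_mask] (any grid; sampled at dose voxel
#'   centers).
#' @param machine a [machine_model].
#' @param engine a [dose_engine_config].
#' @return a [scalar_volume] of kind `"dose"` (Gy).
#' @export
deposit_dose <- function(beams, grid, body, machine = machine_model(),
                         engine = dose_engine_config()) {
  if (inherits(beams, "beam")) beams <- list(beams)
  vals <- array(0, dim = grid$dims)
  in_body <- if (same_grid(grid, body$grid)) {
    which(body$mask)
  } else {
    which(sample_nearest(body$mask + 0, body$grid, grid_points(grid)) > 0.5)
  }
  if (!length(in_body)) return(scalar_volume(vals, grid, kind = "dose"))
  pts <- index_to_world(grid, arrayInd(in_body, grid$dims))
  acc <- numeric(length(in_body))
  for (b in beams) {
    for (cp in b$control_points) {
      if (cp$mu <= 0) next
      acc <- acc + cp$mu * cp_point_dose(cp, machine, pts, body, engine)
    }
  }
  vals[in_body] <- acc
  scalar_volume(vals, grid, kind = "dose")
}
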