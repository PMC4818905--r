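#' Axis-aligned image grid
#'
#' Defines the geometry shared by every volumetric object in the package:
#' voxel counts, isotropic or anisotropic spacing, and the world position of
#' the *center* of voxel `(1,1,1)` (R indexing; the first voxel). The world
#' position of voxel `(i,j,k)` is `origin + (i-1, j-1, k-1) * spacing`, in mm.
#' All modules (phantom generation, dose engine, warping, evaluation) use this
#' convention identically.
#'
#' @param dims integer length-3 vector of voxel counts, all `>= 1`.
#' @param spacing numeric length-3 voxel spacing in mm, all `> 0`.
#' @param origin numeric length-3 world position (mm) of the first voxel
#'   center. Default centers the grid on the world origin.
#' @return An object of class `image_grid`.
#' @examples
#' g <- image_grid(c(64, 64, 64), spacing = c(3, 3, 3))
#' grid_axes(g)$x[1:3]
#' @export
image_grid <- function(dims, spacing = c(1, 1, 1),
                       origin = -(dims - 1) / 2 * spacing) {
  dims <- as.integer(dims)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(dims) == 3L, length(spacing) == 3L, length(origin) == 3L)
  if (any(dims < 1L)) stop("all grid dims must be >= 1")
  if (any(spacing <= 0)) stop("all grid spacings must be > 0")
  structure(list(dims = dims, spacing = spacing, origin = origin),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("image_grid: %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%g, %g, %g) mm (center of first voxel)\n",
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
format.image_grid <- function(x, ...) {
  sprintf("%dx%dx%d @ (%g,%g,%g) mm", x$dims[1], x$dims[2], x$dims[3],
          x$spacing[1], x$spacing[2], x$spacing[3])
}

same_grid <- function(a, b, tol = 1e-6) {
  all(a$dims == b$dims) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Voxel-center coordinates along each axis
#'
#' @param grid an [image_grid].
#' @return list with numeric vectors `x`, `y`, `z` of voxel-center world
#'   coordinates (mm).
#' @export
grid_axes <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$dims[1]) - 1) * grid$spacing[1],
       y = grid$origin[2] + (seq_len(grid$dims[2]) - 1) * grid$spacing[2],
       z = grid$origin[3] + (seq_len(grid$dims[3]) - 1) * grid$spacing[3])
}

#' World coordinates of every voxel center
#'
#' @param grid an [image_grid].
#' @return an `n x 3` matrix of world positions (mm), in array (column-major)
#'   voxel order.
#' @export
grid_points <- function(grid) {
  ax <- grid_axes(grid)
  cbind(x = rep(ax$x, times = grid$dims[2] * grid$dims[3]),
        y = rep(rep(ax$y, each = grid$dims[1]), times = grid$dims[3]),
        z = rep(ax$z, each = grid$dims[1] * grid$dims[2]))
}

#' Convert world positions to continuous (1-based) voxel indices
#'
#' @param grid an [image_grid].
#' @param pts `n x 3` matrix of world positions in mm.
#' @return `n x 3` matrix of fractional voxel indices; `(1,1,1)` is the first
#'   voxel center.
#' @export
world_to_index <- function(grid, pts) {
  pts <- rbind(pts)
  cbind((pts[, 1] - grid$origin[1]) / grid$spacing[1] + 1,
        (pts[, 2] - grid$origin[2]) / grid$spacing[2] + 1,
        (pts[, 3] - grid$origin[3]) / grid$spacing[3] + 1)
}

#' Convert (1-based) voxel indices to world positions
#'
#' @param grid an [image_grid].
#' @param idx `n x 3` matrix of (possibly fractional) voxel indices.
#' @return `n x 3` matrix of world positions (mm).
#' @export
index_to_world <- function(grid, idx) {
  idx <- rbind(idx)
  cbind(grid$origin[1] + (idx[, 1] - 1) * grid$spacing[1],
        grid$origin[2] + (idx[, 2] - 1) * grid$spacing[2],
        grid$origin[3] + (idx[, 3] - 1) * grid$spacing[3])
}

#' Voxel volume in cm^3
#' @param grid an [image_grid].
#' @return scalar voxel volume in cm^3.
#' @export
voxel_volume_cm3 <- function(grid) prod(grid$spacing) / 1000

#' Trilinear interpolation of a 3D array at world positions
#'
#' Interpolates voxel-center values of `values` (laid out on `grid`) at
#' arbitrary world positions. Trilinear interpolation reproduces any field
#' that is linear in each coordinate and never produces values outside the
#' range of the eight surrounding voxels.
#'
#' @param values 3D numeric array with `dim(values) == grid$dims`.
#' @param grid an [image_grid].
#' @param pts `n x 3` matrix of world positions (mm).
#' @param outside one of `"error"` (default; any point outside the voxel-center
#'   hull aborts), `"zero"` (out-of-domain samples return 0; the number of such
#'   samples is attached as attribute `n_outside`), or `"nearest"` (clamp to
#'   the domain boundary).
#' @return numeric vector of interpolated values, length `nrow(pts)`.
#' @export
interp_trilinear <- function(values, grid, pts, outside = c("error", "zero", "nearest")) {
  outside <- match.arg(outside)
  stopifnot(all(dim(values) == grid$dims))
  ci <- world_to_index(grid, pts)
  n <- nrow(ci)
  d <- grid$dims
  eps <- 1e-9
  out_mask <- ci[, 1] < 1 - eps | ci[, 1] > d[1] + eps |
    ci[, 2] < 1 - eps | ci[, 2] > d[2] + eps |
    ci[, 3] < 1 - eps | ci[, 3] > d[3] + eps
  if (any(out_mask)) {
    if (outside == "error") {
      stop(sprintf("%d of %d sample positions lie outside the interpolation domain",
                   sum(out_mask), n))
    }
    if (outside == "nearest") out_mask[] <- FALSE
  }
  ci[, 1] <- pmin(pmax(ci[, 1], 1), d[1])
  ci[, 2] <- pmin(pmax(ci[, 2], 1), d[2])
  ci[, 3] <- pmin(pmax(ci[, 3], 1), d[3])
  i0 <- pmin(floor(ci[, 1]), d[1] - 1L); i0[d[1] == 1L] <- 1
  j0 <- pmin(floor(ci[, 2]), d[2] - 1L); j0[d[2] == 1L] <- 1
  k0 <- pmin(floor(ci[, 3]), d[3] - 1L); k0[d[3] == 1L] <- 1
  fx <- ci[, 1] - i0; fy <- ci[, 2] - j0; fz <- ci[, 3] - k0
  i1 <- pmin(i0 + 1, d[1]); j1 <- pmin(j0 + 1, d[2]); k1 <- pmin(k0 + 1, d[3])
  lin <- function(i, j, k) values[cbind(i, j, k)]
  v <- (1 - fx) * (1 - fy) * (1 - fz) * lin(i0, j0, k0) +
    fx * (1 - fy) * (1 - fz) * lin(i1, j0, k0) +
    (1 - fx) * fy * (1 - fz) * lin(i0, j1, k0) +
    fx * fy * (1 - fz) * lin(i1, j1, k0) +
    (1 - fx) * (1 - fy) * fz * lin(i0, j0, k1) +
    fx * (1 - fy) * fz * lin(i1, j0, k1) +
    (1 - fx) * fy * fz * lin(i0, j1, k1) +
    fx * fy * fz * lin(i1, j1, k1)
  if (outside == "zero") {
    v[out_mask] <- 0
    attr(v, "n_outside") <- sum(out_mask)
  }
  v
}

#' Nearest-neighbour lookup of a 3D array at world positions
#'
#' @inheritParams interp_trilinear
#' @param fill value returned for positions outside the grid.
#' @return numeric vector of sampled values.
#' @export
sample_nearest <- function(values, grid, pts, fill = 0) {
  ci <- round(world_to_index(grid, pts))
  d <- grid$dims
  ok <- ci[, 1] >= 1 & ci[, 1] <= d[1] &
    ci[, 2] >= 1 & ci[, 2] <= d[2] &
    ci[, 3] >= 1 & ci[, 3] <= d[3]
  v <- rep(fill, nrow(ci))
  if (any(ok)) {
    lin <- (ci[ok, 3] - 1) * d[1] * d[2] + (ci[ok, 2] - 1) * d[1] + ci[ok, 1]
    v[ok] <- values[lin]
  }
  v
}
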