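## Multi-phase dose accumulation on the pretreatment (reference) grid.

#' Warp a phase dose onto the reference grid
#'
#' Pull-back resampling: the value at each reference voxel is the trilinear
#' sample of the phase dose at `voxel center + displacement`. Samples that
#' fall outside the phase-dose domain return 0 and are counted
#' (`attr(, "n_outside")` on the returned volume's values). The warped
#' output never exceeds the source dose's range (trilinear convexity). No
#' energy- or mass-conserving correction is applied; this is plain
#' interpolating dose mapping.
#'
#' @param phase_dose a [scalar_volume] of kind `"dose"`.
#' @param dvf a [deformation_field] on the reference grid whose vectors map
#'   reference voxel centers into the phase image.
#' @return a [scalar_volume] on the reference grid.
#' @export
warp_dose <- function(phase_dose, dvf) {
  grid <- dvf$grid
  pts <- grid_points(grid)
  n <- nrow(pts)
  pts <- pts + cbind(as.numeric(dvf$displacement[, , , 1]),
                     as.numeric(dvf$displacement[, , , 2]),
                     as.numeric(dvf$displacement[, , , 3]))
  v <- interp_trilinear(phase_dose$values, phase_dose$grid, pts, outside = "zero")
  out <- scalar_volume(array(as.numeric(v), dim = grid$dims), grid, kind = "dose")
  attr(out$values, "n_outside") <- attr(v, "n_outside")
  out
}

#' Identity deformation field
#' @param grid reference [image_grid].
#' @return a zero-displacement [deformation_field].
#' @export
identity_dvf <- function(grid) {
  deformation_field(array(0, dim = c(grid$dims, 3)), grid)
}

#' Sum warped phase doses with fraction scaling
#'
#' Elementwise scaled sum of per-phase dose contributions already on the
#' reference grid. A plan optimized as a 30-fraction course and delivered
#' over a 10-fraction phase enters with scaling 10/30 of its total-course
#' dose (equivalently, 10 times its per-fraction dose).
#'
#' @param warped list of [scalar_volume]s on a common grid.
#' @param fraction_scaling numeric vector of positive per-phase factors
#'   (recycled).
#' @return object of class `summed_dose`: `dose` (a [scalar_volume]),
#'   `contributions`, `fraction_scaling`.
#' @export
sum_phase_doses <- function(warped, fraction_scaling = 1) {
  stopifnot(length(warped) >= 1)
  fraction_scaling <- rep(fraction_scaling, length.out = length(warped))
  if (any(fraction_scaling <= 0)) stop("fraction scaling factors must be > 0")
  grid <- warped[[1]]$grid
  vals <- array(0, dim = grid$dims)
  for (k in seq_along(warped)) {
    if (!same_grid(warped[[k]]$grid, grid)) {
      stop("all warped doses must share the reference grid")
    }
    vals <- vals + fraction_scaling[k] * warped[[k]]$values
  }
  structure(list(dose = scalar_volume(vals, grid, kind = "dose"),
                 contributions = warped, fraction_scaling = fraction_scaling),
            class = "summed_dose")
}

#' @export
print.summed_dose <- function(x, ...) {
  cat(sprintf("summed_dose: %d contributions, scaling %s, max %.2f Gy\n",
              length(x$contributions),
              paste(signif(x$fraction_scaling, 3), collapse = "/"),
              max(x$dose$values)))
  invisible(x)
}
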