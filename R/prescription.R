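## PET-intensity-to-dose prescription (dose painting by numbers).
##
## Dose is prescribed per fraction as a piecewise-linear function of PET
## signal intensity I:
##
##   D(I) = D_low                                          I <= I_low
##   D(I) = D_low + (I - I_low)/(I_high - I_low) (D_high - D_low)
##                                                  I_low <= I <= I_high
##   D(I) = D_high                                         I >= I_high
##
## with I_high = 95% of the maximum in-target intensity and I_low = 25% of
## I_high. The discrete PET data are extended to the continuum by trilinear
## interpolation at randomly seeded points inside the delineated volume, and
## the prescription is applied point by point.

#' Intensity window for dose painting
#'
#' @param I_low,I_high window bounds in PET intensity units,
#'   `0 <= I_low < I_high`.
#' @return object of class `intensity_window`.
#' @export
intensity_window <- function(I_low, I_high) {
  if (!(I_low >= 0 && I_low < I_high)) stop("need 0 <= I_low < I_high")
  structure(list(I_low = I_low, I_high = I_high), class = "intensity_window")
}

#' Compute the intensity window from a PET image and target
#'
#' `I_high` is 95% of the maximum PET intensity inside the target and
#' `I_low` is 25% of `I_high`.
#'
#' @param pet a [scalar_volume] holding PET uptake.
#' @param target a nonempty [structure_mask]; PET is sampled trilinearly on
#'   the target grid when the grids differ.
#' @param high_fraction,low_fraction the two defining fractions (defaults
#'   0.95 and 0.25).
#' @return an [intensity_window].
#' @export
compute_intensity_window <- function(pet, target, high_fraction = 0.95,
                                     low_fraction = 0.25) {
  if (!sum(target$mask)) stop("target is empty")
  if (same_grid(pet$grid, target$grid)) {
    vmax <- max(pet$values[target$mask])
  } else {
    idx <- which(target$mask)
    pts <- index_to_world(target$grid, arrayInd(idx, target$grid$dims))
    vmax <- max(interp_trilinear(pet$values, pet$grid, pts, outside = "nearest"))
  }
  if (vmax <= 0) stop("PET is non-positive everywhere inside the target")
  intensity_window(low_fraction * high_fraction * vmax, high_fraction * vmax)
}

#' Dose prescription parameters
#'
#' Per-fraction dose painting parameters. Defaults follow the adaptive
#' head-and-neck protocol the class solution was developed for: 2.2 to
#' 3.1 Gy per fraction, with at most 1.75 cm^3 of the primary tumor allowed
#' above 2.9 Gy per fraction (an allowance audited after prescription, not a
#' change to the mapping).
#'
#' @param D_low,D_high per-fraction dose bounds in Gy, `0 < D_low <= D_high`.
#' @param window an [intensity_window] (may be `NULL` until computed).
#' @param boost_cap Gy per fraction above which the boost-volume allowance
#'   applies.
#' @param max_boost_volume_cm3 maximum target volume allowed above
#'   `boost_cap`.
#' @return object of class `dose_prescription`.
#' @export
dose_prescription <- function(D_low = 2.2, D_high = 3.1, window = NULL,
                              boost_cap = 2.9, max_boost_volume_cm3 = 1.75) {
  if (!(D_low > 0 && D_low <= D_high)) stop("need 0 < D_low <= D_high")
  structure(list(D_low = D_low, D_high = D_high, window = window,
                 boost_cap = boost_cap,
                 max_boost_volume_cm3 = max_boost_volume_cm3),
            class = "dose_prescription")
}

#' Prescribed dose as a function of PET intensity
#'
#' The piecewise-linear, clamped intensity-to-dose mapping: `D_low` below the
#' window, a linear ramp inside it, `D_high` above. Continuous, monotone
#' non-decreasing, bounded by `[D_low, D_high]` for any real intensity.
#'
#' @param I numeric vector of intensities (any real values).
#' @param prescription a [dose_prescription] with a non-`NULL` window.
#' @return numeric vector of per-fraction doses in Gy.
#' @examples
#' p <- dose_prescription(window = intensity_window(25, 100))
#' prescribed_dose(c(10, 62.5, 150), p)
#' @export
prescribed_dose <- function(I, prescription) {
  w <- prescription$window
  if (is.null(w)) stop("prescription has no intensity window")
  f <- (I - w$I_low) / (w$I_high - w$I_low)
  f <- pmin(pmax(f, 0), 1)
  prescription$D_low + f * (prescription$D_high - prescription$D_low)
}

#' Trilinear PET intensity at arbitrary positions
#'
#' Extends the discrete PET data to the continuum. Positions outside the
#' voxel-center hull are an error (no extrapolation).
#'
#' @param pet a [scalar_volume].
#' @param positions `n x 3` matrix of world positions (mm).
#' @return numeric vector of interpolated intensities.
#' @export
trilinear_intensity <- function(pet, positions) {
  interp_trilinear(pet$values, pet$grid, positions, outside = "error")
}

#' Seed random prescription points inside a target
#'
#' Points are uniformly distributed over the target volume (rejection
#' sampling inside the mask bounding box; a point is accepted when the voxel
#' containing it belongs to the mask). Each point carries the trilinearly
#' interpolated PET intensity and its prescribed per-fraction dose.
#'
#' @param pet a [scalar_volume] (PET).
#' @param target a nonempty [structure_mask].
#' @param n_points number of points (> 0).
#' @param prescription a [dose_prescription]; when its window is `NULL` it is
#'   computed from `pet` and `target`.
#' @param seed integer seed; the point set is reproducible.
#' @param flat_dose optional Gy per fraction: when given, every point gets
#'   this flat prescription instead of the intensity mapping (used for nodal
#'   targets with insufficient PET signal, prescribed at their median level).
#' @return object of class `prescription_point_set`: data frame `points`
#'   (`x_mm`, `y_mm`, `z_mm`, `intensity`, `dose_Gy`), plus `target_name`,
#'   `prescription`, `seed`.
#' @export
seed_prescription_points <- function(pet, target, n_points = 5000,
                                     prescription = dose_prescription(),
                                     seed = 1, flat_dose = NULL) {
  if (n_points <= 0) stop("n_points must be > 0")
  if (!sum(target$mask)) stop("target is empty")
  if (is.null(prescription$window) && is.null(flat_dose)) {
    prescription$window <- compute_intensity_window(pet, target)
  }
  grid <- target$grid
  idx <- arrayInd(which(target$mask), grid$dims)
  lo <- index_to_world(grid, rbind(apply(idx, 2, min))) - grid$spacing / 2
  hi <- index_to_world(grid, rbind(apply(idx, 2, max))) + grid$spacing / 2
  pts <- with_seed(seed, {
    acc <- matrix(numeric(0), ncol = 3)
    while (nrow(acc) < n_points) {
      m <- max(2L * (n_points - nrow(acc)), 1000L)
      cand <- cbind(runif(m, lo[1], hi[1]), runif(m, lo[2], hi[2]),
                    runif(m, lo[3], hi[3]))
      inside <- sample_nearest(target$mask + 0, grid, cand) > 0.5
      acc <- rbind(acc, cand[inside, , drop = FALSE])
    }
    acc[seq_len(n_points), , drop = FALSE]
  })
  if (is.null(flat_dose)) {
    intensity <- interp_trilinear(pet$values, pet$grid, pts, outside = "nearest")
    dose <- prescribed_dose(intensity, prescription)
  } else {
    intensity <- rep(NA_real_, n_points)
    dose <- rep(flat_dose, n_points)
  }
  structure(list(points = data.frame(x_mm = pts[, 1], y_mm = pts[, 2],
                                     z_mm = pts[, 3], intensity = intensity,
                                     dose_Gy = dose),
                 target_name = target$name, prescription = prescription,
                 seed = seed),
            class = "prescription_point_set")
}

#' @export
print.prescription_point_set <- function(x, ...) {
  cat(sprintf("prescription_point_set '%s': %d points, dose %.3g-%.3g Gy/fx\n",
              x$target_name, nrow(x$points), min(x$points$dose_Gy),
              max(x$points$dose_Gy)))
  invisible(x)
}

#' Audit the boost-volume allowance
#'
#' Estimates the target volume prescribed above the boost cap (from the
#' fraction of seeded points above it times the target volume) and compares
#' it against the allowed maximum. This is a reporting audit; it does not
#' modify the prescription.
#'
#' @param point_set a `prescription_point_set`.
#' @param target the [structure_mask] the points were seeded in.
#' @return list with `boost_volume_cm3`, `allowed_cm3`, `within_allowance`.
#' @export
audit_boost_volume <- function(point_set, target) {
  p <- point_set$prescription
  frac <- mean(point_set$points$dose_Gy > p$boost_cap)
  vol <- frac * mask_volume_cm3(target)
  list(boost_volume_cm3 = vol, allowed_cm3 = p$max_boost_volume_cm3,
       within_allowance = vol <= p$max_boost_volume_cm3)
}

#' Write prescription points to CSV
#'
#' @param point_set a `prescription_point_set`.
#' @param path output CSV path; a sidecar JSON manifest with the window and
#'   dose parameters is written next to it.
#' @return `path`, invisibly.
#' @export
write_prescription_points <- function(point_set, path) {
  utils::write.csv(point_set$points, path, row.names = FALSE)
  p <- point_set$prescription
  manifest <- list(target = point_set$target_name, seed = point_set$seed,
                   D_low = p$D_low, D_high = p$D_high,
                   boost_cap = p$boost_cap,
                   max_boost_volume_cm3 = p$max_boost_volume_cm3,
                   I_low = if (is.null(p$window)) NULL else p$window$I_low,
                   I_high = if (is.null(p$window)) NULL else p$window$I_high)
  jsonlite::write_json(manifest, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
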