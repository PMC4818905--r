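## Plan-quality metrics: cumulative DVH and derived dose/volume indices,
## dose-painting quality factor, integral dose, detector-array sampling and
## global gamma analysis.

#' Cumulative dose-volume histogram of a structure
#'
#' Exact voxel-counting cumulative histogram: for each dose bin, the
#' fraction of the structure's voxels receiving at least that dose.
#'
#' @param dose a [scalar_volume] of kind `"dose"`.
#' @param structure a nonempty [structure_mask]; when grids differ the dose
#'   is sampled trilinearly at the structure's voxel centers.
#' @param bin_width_gy histogram bin width (Gy).
#' @return object of class `dvh_curve`: `structure`, `dose_bins`,
#'   `cum_volume_fraction` (starts at 1 at 0 Gy, monotone non-increasing,
#'   0 above the maximum dose), and the per-voxel `doses`.
#' @export
cumulative_dvh <- function(dose, structure, bin_width_gy = 0.1) {
  if (!sum(structure$mask)) stop("structure is empty")
  if (same_grid(dose$grid, structure$grid)) {
    d <- dose$values[structure$mask]
  } else {
    pts <- mask_points(structure)
    d <- interp_trilinear(dose$values, dose$grid, pts, outside = "nearest")
  }
  bins <- seq(0, max(d) + bin_width_gy, by = bin_width_gy)
  cvf <- vapply(bins, function(b) mean(d >= b), numeric(1))
  structure(list(structure = structure$name, dose_bins = bins,
                 cum_volume_fraction = cvf, doses = d),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("dvh_curve '%s': %d voxels, D2%%=%.2f D50%%=%.2f D98%%=%.2f Gy\n",
              x$structure, length(x$doses), dose_at_volume(x, 2),
              dose_at_volume(x, 50), dose_at_volume(x, 98)))
  invisible(x)
}

#' Dose received by the hottest x% of a structure (D_x%)
#'
#' Linear interpolation on the cumulative curve; `D2% >= D50% >= D98%` by
#' monotonicity.
#'
#' @param curve a `dvh_curve`.
#' @param x_percent volume percentage in (0, 100).
#' @return dose in Gy.
#' @export
dose_at_volume <- function(curve, x_percent) {
  if (x_percent <= 0 || x_percent >= 100) stop("x_percent must be in (0, 100)")
  as.numeric(stats::quantile(curve$doses, probs = 1 - x_percent / 100,
                             type = 7, names = FALSE))
}

#' Volume fraction receiving at least a dose (V_d)
#'
#' @param curve a `dvh_curve`.
#' @param d_gy dose level in Gy.
#' @return volume percentage in \[0, 100\].
#' @export
volume_at_dose <- function(curve, d_gy) {
  100 * mean(curve$doses >= d_gy)
}

#' Mean structure dose
#' @param curve a `dvh_curve`.
#' @return mean dose in Gy.
#' @export
mean_dose <- function(curve) mean(curve$doses)

#' Dose-painting quality factor
#'
#' The biologic-conformity metric: the mean deviation between prescribed and
#' planned dose over the dose-painted points, reported in percent. The
#' default normalizes each deviation by the point's prescribed dose (mean
#' relative absolute deviation), which makes the customary 5% planning goal
#' dimensionless; `normalization = "absolute"` returns the mean absolute
#' deviation in Gy instead.
#'
#' @param planned a [scalar_volume] of kind `"dose"` (sampled trilinearly at
#'   the points).
#' @param point_set a `prescription_point_set` (or any list with a `points`
#'   data frame carrying `x_mm`, `y_mm`, `z_mm`, `dose_Gy`).
#' @param fraction_scaling factor applied to the per-fraction prescribed
#'   doses before comparison (e.g. 30 when `planned` is a 30-fraction
#'   equivalent total dose).
#' @param normalization `"relative"` (percent of prescribed, default) or
#'   `"absolute"` (Gy).
#' @return object of class `qf_result`: `target`, `qf_percent` (or Gy),
#'   `n_points`, `deviations`.
#' @export
quality_factor <- function(planned, point_set, fraction_scaling = 1,
                           normalization = c("relative", "absolute")) {
  normalization <- match.arg(normalization)
  p <- point_set$points
  presc <- p$dose_Gy * fraction_scaling
  if (any(presc <= 0)) stop("prescribed doses must be positive")
  d <- interp_trilinear(planned$values, planned$grid,
                        as.matrix(p[, c("x_mm", "y_mm", "z_mm")]),
                        outside = "error")
  dev <- if (normalization == "relative") abs(d - presc) / presc * 100 else abs(d - presc)
  structure(list(target = point_set$target_name, qf_percent = mean(dev),
                 n_points = length(dev), deviations = dev,
                 normalization = normalization),
            class = "qf_result")
}

#' @export
print.qf_result <- function(x, ...) {
  cat(sprintf("qf_result '%s': QF = %.2f%s over %d points\n", x$target,
              x$qf_percent, if (x$normalization == "relative") "%" else " Gy",
              x$n_points))
  invisible(x)
}

#' Integral dose
#'
#' `ID[J] = D_mean[Gy] x V[cm^3] x rho[g/cm^3] x 1e-3` (energy imparted to
#' the body mass; 1 Gy = 1 J/kg). Tissue density defaults to 1 g/cm^3.
#'
#' @param dose a [scalar_volume] of kind `"dose"` on the body grid.
#' @param body a nonempty [structure_mask].
#' @param density_g_cm3 tissue density.
#' @return integral dose in Joules.
#' @export
integral_dose <- function(dose, body, density_g_cm3 = 1) {
  if (!sum(body$mask)) stop("body is empty")
  if (!same_grid(dose$grid, body$grid)) stop("dose and body must share a grid")
  d_mean <- mean(dose$values[body$mask])
  v_cm3 <- mask_volume_cm3(body)
  d_mean * v_cm3 * density_g_cm3 * 1e-3
}

#' Biplanar diode detector geometry
#'
#' Emulates a cross-plane silicon-diode array: diodes on two orthogonal
#' planes through the isocenter axis, spaced 5 mm inside a central 6 x 6 cm
#' region and 10 mm outside, 1069 diodes in total by default. The exact
#' board outline of the emulated device is not published, so the boards are
#' filled outward: candidate grid positions on both planes are kept in order
#' of increasing distance from the axis (deterministic tie-break) until
#' `n_points` diodes are placed.
#'
#' @param n_points total diode count.
#' @param extent_mm half-size of each detector board (mm).
#' @param central_mm half-size of the finely sampled central region (mm).
#' @param fine_mm,coarse_mm diode spacings (mm).
#' @return object of class `detector_geometry` with an `n x 3` matrix
#'   `positions` (first plane in y = 0, second in x = 0).
#' @export
detector_geometry <- function(n_points = 1069, extent_mm = 110,
                              central_mm = 30, fine_mm = 5, coarse_mm = 10) {
  coords_1d <- sort(unique(c(seq(-central_mm, central_mm, by = fine_mm),
                             seq(-extent_mm, extent_mm, by = coarse_mm))))
  g1 <- expand.grid(a = coords_1d, z = coords_1d)
  p1 <- cbind(g1$a, 0, g1$z)
  g2 <- g1[g1$a != 0, ]  # the shared axis column belongs to plane 1
  p2 <- cbind(0, g2$a, g2$z)
  pos <- rbind(p1, p2)
  plane <- rep(1:2, c(nrow(p1), nrow(p2)))
  r <- sqrt(rowSums(pos^2))
  ord <- order(r, plane, pos[, 1], pos[, 2], pos[, 3])
  if (n_points > nrow(pos)) {
    stop("n_points exceeds the candidate grid; increase extent_mm")
  }
  structure(list(positions = pos[ord[seq_len(n_points)], , drop = FALSE],
                 spacing_fine = fine_mm, spacing_coarse = coarse_mm),
            class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf("detector_geometry: %d diodes on two orthogonal planes\n",
              nrow(x$positions)))
  invisible(x)
}

#' Sample a dose volume at detector diode positions
#'
#' Trilinear dose at each diode position after an optional rigid placement
#' (translation) of the detector. Any diode outside the dose domain is an
#' error listing the offenders.
#'
#' @param dose a [scalar_volume] of kind `"dose"`.
#' @param geometry a [detector_geometry].
#' @param translation length-3 rigid offset of the detector (mm).
#' @return data frame with diode positions and sampled `dose_gy`.
#' @export
sample_detector <- function(dose, geometry, translation = c(0, 0, 0)) {
  pos <- sweep(geometry$positions, 2, -translation)
  ci <- world_to_index(dose$grid, pos)
  bad <- which(ci[, 1] < 1 | ci[, 1] > dose$grid$dims[1] |
                 ci[, 2] < 1 | ci[, 2] > dose$grid$dims[2] |
                 ci[, 3] < 1 | ci[, 3] > dose$grid$dims[3])
  if (length(bad)) {
    stop(sprintf("diodes outside the dose domain: %s%s",
                 paste(utils::head(bad, 10), collapse = ", "),
                 if (length(bad) > 10) sprintf(" (and %d more)", length(bad) - 10) else ""))
  }
  d <- interp_trilinear(dose$values, dose$grid, pos, outside = "error")
  data.frame(x_mm = pos[, 1], y_mm = pos[, 2], z_mm = pos[, 3], dose_gy = d)
}

#' Gamma analysis criteria
#'
#' @param dose_tolerance_pct dose-difference criterion as percent of the
#'   normalization dose (global gamma); default 3.
#' @param distance_tolerance_mm distance-to-agreement criterion; default 3.
#' @param normalization_dose_gy the normalization (prescribed) dose.
#' @param low_dose_cutoff_pct reference points below this percent of the
#'   normalization dose are excluded from pass statistics.
#' @return object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_tolerance_pct = 3, distance_tolerance_mm = 3,
                           normalization_dose_gy, low_dose_cutoff_pct = 20) {
  stopifnot(dose_tolerance_pct > 0, distance_tolerance_mm > 0,
            normalization_dose_gy > 0, low_dose_cutoff_pct >= 0)
  structure(as.list(environment()), class = "gamma_criteria")
}

#' Global gamma index of an evaluated dose against reference points
#'
#' For each reference point the gamma value is the minimum over candidate
#' positions within a search radius (3x the distance tolerance) of
#' `sqrt((|dx|/DTA)^2 + ((D_eval - D_ref)/(dD% x D_norm))^2)`, with the
#' evaluated dose trilinearly interpolated on a sub-voxel candidate grid.
#' The search proceeds over candidate shells of increasing radius and stops
#' per point once the distance term alone exceeds the current minimum, which
#' is equivalent to the exhaustive search. A point passes when `gamma <= 1`;
#' points below the low-dose cutoff are excluded from the pass fraction.
#'
#' @param reference data frame with `x_mm`, `y_mm`, `z_mm`, `dose_gy`
#'   (e.g. from [sample_detector()]).
#' @param evaluated a [scalar_volume] of kind `"dose"`.
#' @param criteria a [gamma_criteria].
#' @param step_mm candidate grid step (mm); smaller steps can only lower
#'   gamma values (minimization over a superset).
#' @return object of class `gamma_result`: `gamma` (per reference point,
#'   `NA` for cutoff-excluded points), `pass_fraction_percent`,
#'   `n_evaluated`.
#' @export
gamma_index <- function(reference, evaluated, criteria, step_mm = 0.5) {
  dta <- criteria$distance_tolerance_mm
  dd <- criteria$dose_tolerance_pct / 100 * criteria$normalization_dose_gy
  pos <- as.matrix(reference[, c("x_mm", "y_mm", "z_mm")])
  dref <- reference$dose_gy
  n <- nrow(pos)
  search_r <- 3 * dta
  offs <- as.matrix(expand.grid(
    x = seq(-search_r, search_r, by = step_mm),
    y = seq(-search_r, search_r, by = step_mm),
    z = seq(-search_r, search_r, by = step_mm)))
  r <- sqrt(rowSums(offs^2))
  keep <- r <= search_r + 1e-9
  offs <- offs[keep, , drop = FALSE]
  r <- r[keep]
  ord <- order(r)
  offs <- offs[ord, , drop = FALSE]
  r <- r[ord]
  # process in shells of increasing radius with per-point early termination
  shell_id <- floor(r / step_mm + 1e-9)
  g2 <- rep(Inf, n)
  active <- rep(TRUE, n)
  for (sid in unique(shell_id)) {
    shell_r <- sid * step_mm
    active <- active & g2 > (shell_r / dta)^2
    if (!any(active)) break
    so <- offs[shell_id == sid, , drop = FALSE]
    ai <- which(active)
    cand <- pos[rep(ai, each = nrow(so)), , drop = FALSE] +
      so[rep(seq_len(nrow(so)), times = length(ai)), , drop = FALSE]
    dv <- interp_trilinear(evaluated$values, evaluated$grid, cand, outside = "nearest")
    dist2 <- rowSums(so^2)[rep(seq_len(nrow(so)), times = length(ai))] / dta^2
    dose2 <- ((dv - dref[rep(ai, each = nrow(so))]) / dd)^2
    tot <- matrix(dist2 + dose2, nrow = nrow(so))
    g2[ai] <- pmin(g2[ai], apply(tot, 2, min))
  }
  gam <- sqrt(g2)
  excl <- dref < criteria$low_dose_cutoff_pct / 100 * criteria$normalization_dose_gy
  gam_out <- gam
  gam_out[excl] <- NA_real_
  n_eval <- sum(!excl)
  # a tiny tolerance keeps exactly-on-boundary points (gamma == 1) passing
  # despite floating-point round-off
  pass <- if (n_eval) 100 * sum(gam[!excl] <= 1 + 1e-9) / n_eval else NA_real_
  structure(list(gamma = gam_out, pass_fraction_percent = pass,
                 n_evaluated = n_eval, criteria = criteria),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("gamma_result: %.1f%% of %d points pass (gamma <= 1)\n",
              x$pass_fraction_percent, x$n_evaluated))
  invisible(x)
}

#' Per-structure dose metric table
#'
#' The standard reporting row set: D2%, D50%, D98%, mean dose and V at a
#' reference level (27 Gy by default, the parotid sparing level).
#'
#' @param dose a [scalar_volume] of kind `"dose"`.
#' @param structures list of [structure_mask]s.
#' @param v_level_gy dose level for the V_x metric (Gy).
#' @return data frame with one row per structure.
#' @export
dose_metric_table <- function(dose, structures, v_level_gy = 27) {
  rows <- lapply(structures, function(s) {
    cv <- cumulative_dvh(dose, s)
    data.frame(structure = s$name,
               D2 = dose_at_volume(cv, 2),
               D50 = dose_at_volume(cv, 50),
               D98 = dose_at_volume(cv, 98),
               Dmean = mean_dose(cv),
               V_level = volume_at_dose(cv, v_level_gy))
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "V_level"] <- sprintf("V%ggy_pct", v_level_gy)
  out
}
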