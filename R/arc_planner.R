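## IMAT class solution and s-IMRT comparator planner.
##
## Initial apertures come from beams-eye-view (BEV) projections of targets
## minus avoidance structures (anatomy-based segmentation), optionally
## subdivided into nested PET-intensity bands (biology-based segmentation).
## MU weights are then optimized by iterated non-negative least squares
## against the point prescriptions with DVH penalties, alternating with
## greedy local leaf moves. Delivery post-processing eliminates low-MU arc
## parts, refines control points to bounded inter-CP deltas, and links the
## surviving sub-arcs into one beam by shortest estimated delivery time.

#' Arc class-solution configuration
#'
#' The default is a two-arc template: an elective-neck arc collimated around
#' `PTV_EN` spanning gantry -176 to 176 degrees and a boost arc collimated
#' around `PTV_HR` spanning 144 to -144 degrees (descending through 0), with
#' control points every 8 degrees (45 and 37 CPs).
#'
#' @param arcs list of arc descriptions `list(target=, start=, stop=,
#'   direction=)` with `direction` +1 (increasing gantry) or -1.
#' @param cp_spacing control-point spacing in degrees; must divide each arc
#'   span.
#' @return object of class `class_solution_config`.
#' @export
class_solution_config <- function(
    arcs = list(list(target = "PTV_EN", start = -176, stop = 176, direction = 1),
                list(target = "PTV_HR", start = 144, stop = -144, direction = -1)),
    cp_spacing = 8) {
  stopifnot(cp_spacing > 0, length(arcs) >= 1)
  structure(list(arcs = arcs, cp_spacing = cp_spacing),
            class = "class_solution_config")
}

## control-point gantry sequence of one arc description
arc_angle_sequence <- function(arc, spacing) {
  span <- ((arc$stop - arc$start) * arc$direction) %% 360
  if (span == 0) span <- 360
  if (abs(span / spacing - round(span / spacing)) > 1e-9) {
    stop(sprintf("arc span %g deg is not divisible by CP spacing %g deg", span, spacing))
  }
  normalize_angle(arc$start + arc$direction * seq(0, span, by = spacing))
}

## project world points into unrotated-beam-frame isocenter-plane coordinates
project_bev <- function(pts, gantry, machine) {
  fr <- beam_frame(gantry)
  w <- as.numeric(pts %*% fr$e_w)
  mag <- machine$source_axis_distance / (machine$source_axis_distance + w)
  list(u = as.numeric(pts %*% fr$e_u) * mag,
       v = as.numeric(pts %*% fr$e_v) * mag)
}

## rotate BEV coordinates into the collimator (MLC) frame
to_mlc_frame <- function(u, v, collimator) {
  cr <- collimator * pi / 180
  list(u = cos(cr) * u + sin(cr) * v, v = -sin(cr) * u + cos(cr) * v)
}

## per-row [left, right] intervals of a projected point cloud; a positive
## margin dilates the cloud isotropically in the BEV plane before binning
row_intervals <- function(u, v, machine, margin = 0) {
  edges <- leaf_row_edges(machine)
  n <- machine$n_leaf_pairs
  if (margin > 0) {
    v <- c(v, v - margin, v + margin)
    u <- rep(u, 3)
  }
  left <- rep(NA_real_, n)
  right <- rep(NA_real_, n)
  row <- findInterval(v, edges, rightmost.closed = TRUE)
  ok <- row >= 1 & row <= n
  if (any(ok)) {
    f <- factor(row[ok], levels = 1:n)
    left <- as.numeric(tapply(u[ok], f, min)) - margin
    right <- as.numeric(tapply(u[ok], f, max)) + margin
  }
  list(left = left, right = right)
}

## subtract avoid intervals from target intervals row-wise; when the
## avoidance splits a row, one remaining segment is kept (a leaf pair forms
## a single opening). `prefer` picks which: the wider one, or the left/right
## one -- cycling the preference over a sequence of control points lets
## every target region be reached from some angles instead of shielding the
## same side everywhere.
subtract_intervals <- function(tgt, avd, prefer = c("wider", "left", "right")) {
  prefer <- match.arg(prefer)
  for (i in seq_along(tgt$left)) {
    if (is.na(tgt$left[i]) || is.na(avd$left[i])) next
    tl <- tgt$left[i]; tr <- tgt$right[i]
    al <- avd$left[i]; ar <- avd$right[i]
    if (ar <= tl || al >= tr) next
    left_seg <- c(tl, min(tr, al))
    right_seg <- c(max(tl, ar), tr)
    wl <- max(0, diff(left_seg)); wr <- max(0, diff(right_seg))
    take_left <- switch(prefer,
                        wider = wl >= wr,
                        left = wl > 0,
                        right = wr <= 0)
    if (wl <= 0 && wr <= 0) { tgt$left[i] <- NA; tgt$right[i] <- NA }
    else if (take_left && wl > 0) { tgt$left[i] <- left_seg[1]; tgt$right[i] <- left_seg[2] }
    else { tgt$left[i] <- right_seg[1]; tgt$right[i] <- right_seg[2] }
  }
  tgt
}

## turn row intervals into a constraint-satisfying control point
repair_aperture <- function(intervals, gantry, collimator, machine, mu = 0) {
  gap <- machine$min_opposing_gap
  n <- machine$n_leaf_pairs
  edges <- leaf_row_edges(machine)
  open_rows <- which(!is.na(intervals$left))
  flagged_empty <- length(open_rows) == 0
  if (flagged_empty) {
    # minimal gap-respecting aperture on the two central rows
    open_rows <- c(n %/% 2, n %/% 2 + 1)
    intervals$left[open_rows] <- -gap / 2
    intervals$right[open_rows] <- gap / 2
  }
  left <- intervals$left; right <- intervals$right
  # widen sub-gap openings symmetrically
  for (i in open_rows) {
    if (right[i] - left[i] < gap) {
      c0 <- (left[i] + right[i]) / 2
      left[i] <- c0 - gap / 2; right[i] <- c0 + gap / 2
    }
  }
  # jaws cover the rows meant to be open
  jy <- c(edges[min(open_rows)], edges[max(open_rows) + 1])
  jx <- c(min(left[open_rows]), max(right[open_rows]))
  # rows inside the jaw y-range with no desired opening cannot physically
  # close: give them the minimum gap at the local aperture center
  in_jaw <- seq(min(open_rows), max(open_rows))
  ctr_all <- mean((left[open_rows] + right[open_rows]) / 2)
  for (i in setdiff(in_jaw, open_rows)) {
    left[i] <- ctr_all - gap / 2; right[i] <- ctr_all + gap / 2
  }
  # park rows outside the jaws
  outside <- setdiff(1:n, in_jaw)
  left[outside] <- 0; right[outside] <- 0
  # enforce the diagonal-opposing gap by opening the violating pair
  for (iter in 1:100) {
    changed <- FALSE
    for (i in in_jaw) {
      for (j in intersect(i + (-1:1), in_jaw)) {
        viol <- gap - (right[j] - left[i])
        if (viol > 1e-9) {
          left[i] <- left[i] - viol / 2
          right[j] <- right[j] + viol / 2
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  jx <- c(min(jx[1], min(left[in_jaw])) - 1e-6, max(jx[2], max(right[in_jaw])) + 1e-6)
  cp <- control_point(gantry, collimator, jaws = c(jx, jy),
                      leaves = cbind(left, right), mu = mu)
  attr(cp, "flagged_empty") <- flagged_empty
  validate_control_point(cp, machine)
  cp
}

## structure mask -> world coordinates of its voxel centers
mask_points <- function(structure) {
  index_to_world(structure$grid, arrayInd(which(structure$mask), structure$grid$dims))
}

#' Anatomy-based aperture at one gantry angle
#'
#' Builds a per-leaf-pair opening covering the BEV projection of the target
#' minus the projections of avoidance structures, then repairs it to satisfy
#' `left <= right` and the minimum opposing/diagonal gap rule. An aperture
#' emptied by avoidance falls back to the minimal gap-respecting opening and
#' is flagged (`attr(cp, "flagged_empty")`).
#'
#' @param target a [structure_mask] (the PTV to conform to).
#' @param avoid list of [structure_mask]s to shield.
#' @param gantry,collimator angles in degrees.
#' @param machine a [machine_model].
#' @param margin_mm widening of the target projection to compensate the
#'   penumbra (mm).
#' @param mu initial monitor units for the control point.
#' @return a [control_point].
#' @export
abst_aperture <- function(target, avoid = list(), gantry, collimator = 0,
                          machine = machine_model(), margin_mm = 6, mu = 0,
                          avoid_side = "wider") {
  pts <- mask_points(target)
  if (!nrow(pts)) stop("target projects to an empty BEV region")
  bev <- project_bev(pts, gantry, machine)
  mc <- to_mlc_frame(bev$u, bev$v, collimator)
  tgt <- row_intervals(mc$u, mc$v, machine, margin = margin_mm)
  for (av in avoid) {
    ap <- mask_points(av)
    if (!nrow(ap)) next
    ab <- project_bev(ap, gantry, machine)
    am <- to_mlc_frame(ab$u, ab$v, collimator)
    tgt <- subtract_intervals(tgt, row_intervals(am$u, am$v, machine),
                              prefer = avoid_side)
  }
  repair_aperture(tgt, gantry, collimator, machine, mu = mu)
}

#' Biology-based nested apertures at one gantry angle
#'
#' Subdivides the anatomy-based aperture into nested sub-apertures by
#' thresholding the BEV-projected PET intensity: band 1 is the full
#' anatomy-based aperture, higher bands cover only the rows/extents of
#' target voxels whose intensity reaches increasing thresholds between
#' `I_low` and `I_high`. Higher-intensity bands are subsets of
#' lower-intensity bands by construction.
#'
#' @param pet a [scalar_volume] (PET uptake).
#' @param window an [intensity_window].
#' @param target,avoid,gantry,collimator,machine,margin_mm,mu as in
#'   [abst_aperture()].
#' @param n_bands number of nested bands (>= 1).
#' @return list of [control_point]s, one per band.
#' @export
bbst_aperture <- function(pet, window, target, avoid = list(), gantry,
                          collimator = 0, machine = machine_model(),
                          n_bands = 3, margin_mm = 6, mu = 0,
                          avoid_side = "wider") {
  stopifnot(n_bands >= 1)
  pts <- mask_points(target)
  if (!nrow(pts)) stop("target projects to an empty BEV region")
  intens <- interp_trilinear(pet$values, pet$grid, pts, outside = "nearest")
  bev <- project_bev(pts, gantry, machine)
  mc <- to_mlc_frame(bev$u, bev$v, collimator)
  avoid_iv <- lapply(avoid, function(av) {
    ap <- mask_points(av)
    if (!nrow(ap)) return(NULL)
    ab <- project_bev(ap, gantry, machine)
    am <- to_mlc_frame(ab$u, ab$v, collimator)
    row_intervals(am$u, am$v, machine)
  })
  thresholds <- c(-Inf, window$I_low + seq_len(n_bands - 1) / n_bands *
                    (window$I_high - window$I_low))
  lapply(thresholds, function(thr) {
    keep <- intens >= thr
    if (!any(keep)) keep <- intens >= max(intens)  # at least the hottest voxel
    iv <- row_intervals(mc$u[keep], mc$v[keep], machine, margin = margin_mm)
    for (ai in avoid_iv) if (!is.null(ai)) {
      iv <- subtract_intervals(iv, ai, prefer = avoid_side)
    }
    repair_aperture(iv, gantry, collimator, machine, mu = mu)
  })
}

#' Build the arc class solution
#'
#' One arc per configured entry, with control points at `start`,
#' `start + spacing`, ..., `stop` along the given direction. When structure
#' masks are supplied the initial apertures conform to the BEV of the arc's
#' target minus the avoidance structures; with a PET image and window,
#' nested intensity bands are cycled along the arc's control points to seed
#' intensity modulation. Without structures, open square apertures are used.
#'
#' @param config a [class_solution_config].
#' @param machine a [machine_model].
#' @param structures optional list of [structure_mask]s containing each
#'   arc's target.
#' @param avoid optional list of [structure_mask]s to shield.
#' @param pet,window optional PET image and [intensity_window] enabling
#'   intensity bands.
#' @param n_bands bands cycled over arc control points (used with `pet`).
#' @param margin_mm BEV margin (mm).
#' @param init_mu initial MU per control point.
#' @param open_field_mm side of the fallback square aperture.
#' @return list of [beam]s (one per arc).
#' @export
generate_class_solution <- function(config = class_solution_config(),
                                    machine = machine_model(),
                                    structures = NULL, avoid = list(),
                                    pet = NULL, window = NULL, n_bands = 3,
                                    margin_mm = 6, init_mu = 10,
                                    open_field_mm = 100) {
  lapply(config$arcs, function(arc) {
    angles <- arc_angle_sequence(arc, config$cp_spacing)
    target <- if (!is.null(structures)) get_structure(structures, arc$target) else NULL
    cps <- vector("list", length(angles))
    for (t in seq_along(angles)) {
      side <- c("wider", "left", "right")[(t - 1) %% 3 + 1]
      if (is.null(target)) {
        half <- open_field_mm / 2
        n <- machine$n_leaf_pairs
        edges <- leaf_row_edges(machine)
        lv <- cbind(rep(0, n), rep(0, n))
        rows <- which(edges[-length(edges)] < half & edges[-1] > -half)
        lv[rows, 1] <- -half; lv[rows, 2] <- half
        cps[[t]] <- control_point(angles[t], 0, c(-half, half, -half, half),
                                  lv, mu = init_mu)
      } else if (!is.null(pet) && !is.null(window)) {
        bands <- bbst_aperture(pet, window, target, avoid, angles[t],
                               machine = machine, n_bands = n_bands,
                               margin_mm = margin_mm, mu = init_mu,
                               avoid_side = side)
        cps[[t]] <- bands[[(t - 1) %% length(bands) + 1]]
      } else {
        cps[[t]] <- abst_aperture(target, avoid, angles[t], machine = machine,
                                  margin_mm = margin_mm, mu = init_mu,
                                  avoid_side = side)
      }
    }
    beam(cps, "arc", name = sprintf("arc_%s", arc$target))
  })
}

#' Build the six-beam step-and-shoot comparator plan
#'
#' Six non-opposing coplanar static beams at gantry 45, 75, 165, 195, 285
#' and 315 degrees, each carrying a configurable number of segments
#' (anatomy-based, or nested intensity bands when a PET image is given).
#'
#' @param machine a [machine_model].
#' @param gantry_angles the six beam angles (degrees).
#' @param structures,avoid,pet,window as in [generate_class_solution()].
#' @param target_name target the segments conform to.
#' @param n_segments segments per beam.
#' @param margin_mm,init_mu,open_field_mm as in [generate_class_solution()].
#' @return list of 6 static [beam]s.
#' @export
build_simrt_plan <- function(machine = machine_model(),
                             gantry_angles = c(45, 75, 165, 195, 285, 315),
                             structures = NULL, avoid = list(),
                             target_name = "PTV_HR", pet = NULL, window = NULL,
                             n_segments = 3, margin_mm = 6, init_mu = 10,
                             open_field_mm = 100) {
  target <- if (!is.null(structures)) get_structure(structures, target_name) else NULL
  lapply(gantry_angles, function(g) {
    gn <- normalize_angle(g)
    if (is.null(target)) {
      half <- open_field_mm / 2
      n <- machine$n_leaf_pairs
      edges <- leaf_row_edges(machine)
      lv <- cbind(rep(0, n), rep(0, n))
      rows <- which(edges[-length(edges)] < half & edges[-1] > -half)
      lv[rows, 1] <- -half; lv[rows, 2] <- half
      cps <- rep(list(control_point(gn, 0, c(-half, half, -half, half), lv,
                                    mu = init_mu)), n_segments)
    } else if (!is.null(pet) && !is.null(window)) {
      bands <- bbst_aperture(pet, window, target, avoid, gn, machine = machine,
                             n_bands = n_segments, margin_mm = margin_mm,
                             mu = init_mu)
      cps <- bands
    } else {
      cps <- rep(list(abst_aperture(target, avoid, gn, machine = machine,
                                    margin_mm = margin_mm, mu = init_mu)),
                 n_segments)
    }
    beam(cps, "static", name = sprintf("beam_%g", g %% 360))
  })
}
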