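## Machine model, control points and beams.
##
## Geometry conventions: patient axes x (lateral), y (anterior-posterior),
## z (cranio-caudal); the gantry rotates about z. At gantry 0 the source sits
## at +y (anterior); at gantry +90 at +x. Angles are kept in (-180, 180].
## Leaf and jaw positions are projected to the isocenter plane (mm); the MLC
## has `n_leaf_pairs` leaf pairs stacked along the (collimator-rotated) v
## axis, leaves travelling along u.

#' Normalize angles to (-180, 180]
#' @param a numeric vector of angles in degrees.
#' @return normalized angles.
#' @export
normalize_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a == -180] <- 180
  a
}

#' Treatment machine model
#'
#' Delivery capabilities of the linac surrogate. The MLC geometry (40 leaf
#' pairs, 1 cm minimum opening between opposing and diagonally opposing
#' leaves) follows the modelled machine; the speed and dose-rate limits are
#' assumptions with typical C-arm linac values, used only by the delivery
#' time estimate.
#'
#' @param n_leaf_pairs number of MLC leaf pairs.
#' @param leaf_width_at_iso leaf width projected to the isocenter plane (mm).
#' @param source_axis_distance source-axis distance (mm).
#' @param max_gantry_speed deg/s.
#' @param max_leaf_speed mm/s.
#' @param max_collimator_speed deg/s.
#' @param dose_rate_range MU/s, `c(min, max)`.
#' @param min_opposing_gap minimum opening between opposing (and diagonally
#'   opposing) leaves inside the jaw-open region (mm).
#' @return object of class `machine_model`.
#' @export
machine_model <- function(n_leaf_pairs = 40, leaf_width_at_iso = 10,
                          source_axis_distance = 1000,
                          max_gantry_speed = 6, max_leaf_speed = 25,
                          max_collimator_speed = 10,
                          dose_rate_range = c(0.5, 10),
                          min_opposing_gap = 10) {
  m <- as.list(environment())
  stopifnot(n_leaf_pairs >= 1, leaf_width_at_iso > 0, source_axis_distance > 0,
            max_gantry_speed > 0, max_leaf_speed > 0, max_collimator_speed > 0,
            all(dose_rate_range > 0), dose_rate_range[1] <= dose_rate_range[2],
            min_opposing_gap > 0)
  class(m) <- "machine_model"
  m
}

## v-interval boundaries of the leaf rows at the isocenter plane (centered)
leaf_row_edges <- function(machine) {
  half <- machine$n_leaf_pairs * machine$leaf_width_at_iso / 2
  seq(-half, half, by = machine$leaf_width_at_iso)
}

#' Control point
#'
#' A snapshot of machine state: gantry and collimator angle, jaw rectangle,
#' per-pair leaf positions, and the monitor units delivered in the segment it
#' terminates.
#'
#' @param gantry gantry angle in degrees (normalized to (-180, 180]).
#' @param collimator collimator angle in degrees.
#' @param jaws numeric length 4 `c(x1, x2, y1, y2)` at the isocenter plane
#'   (mm), `x1 < x2`, `y1 < y2`.
#' @param leaves `n_leaf_pairs x 2` matrix of `(left, right)` positions (mm),
#'   `left <= right` per pair.
#' @param mu monitor units, `>= 0`.
#' @return object of class `control_point`.
#' @export
control_point <- function(gantry, collimator = 0, jaws, leaves, mu = 0) {
  leaves <- as.matrix(leaves)
  stopifnot(length(jaws) == 4L, ncol(leaves) == 2L, mu >= 0)
  if (jaws[1] >= jaws[2] || jaws[3] >= jaws[4]) stop("jaws must satisfy x1 < x2, y1 < y2")
  structure(list(gantry = normalize_angle(gantry), collimator = collimator,
                 jaws = as.numeric(jaws), leaves = leaves, mu = mu),
            class = "control_point")
}

#' Validate a control point against machine constraints
#'
#' Checks `left <= right` for every pair and the minimum-gap rule for
#' opposing and diagonally opposing leaves of rows intersecting the jaw-open
#' y-range. Rows fully outside the jaws are exempt (parked pairs).
#'
#' @param cp a [control_point].
#' @param machine a [machine_model].
#' @param tol numeric tolerance (mm).
#' @return `TRUE` invisibly, or an error describing the violated constraint.
#' @export
validate_control_point <- function(cp, machine, tol = 1e-6) {
  lv <- cp$leaves
  if (nrow(lv) != machine$n_leaf_pairs) {
    stop(sprintf("control point has %d leaf pairs, machine has %d",
                 nrow(lv), machine$n_leaf_pairs))
  }
  if (any(lv[, 1] > lv[, 2] + tol)) stop("leaf constraint violated: left > right")
  edges <- leaf_row_edges(machine)
  in_jaw <- edges[-length(edges)] < cp$jaws[4] - tol & edges[-1] > cp$jaws[3] + tol
  gap <- machine$min_opposing_gap
  for (i in which(in_jaw)) {
    for (j in intersect(i + (-1:1), which(in_jaw))) {
      if (lv[j, 2] - lv[i, 1] < gap - tol) {
        stop(sprintf("minimum opposing-gap constraint violated at leaf pairs %d/%d", i, j))
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.control_point <- function(x, ...) {
  cat(sprintf("control_point: gantry %.1f deg, collimator %.1f deg, %.2f MU, %d leaf pairs\n",
              x$gantry, x$collimator, x$mu, nrow(x$leaves)))
  invisible(x)
}

#' Beam: an ordered control-point sequence
#'
#' @param control_points list of [control_point]s.
#' @param delivery_mode `"arc"` (gantry angles strictly monotone within each
#'   sub-arc) or `"static"` (all control points at one gantry angle).
#' @param name optional label.
#' @param subarc_breaks optional integer vector of control-point indices
#'   starting a new sub-arc (for beams created by linking sub-arcs); gantry
#'   monotonicity is then only required within each sub-arc.
#' @return object of class `beam`.
#' @export
beam <- function(control_points, delivery_mode = c("arc", "static"), name = NULL,
                 subarc_breaks = NULL) {
  delivery_mode <- match.arg(delivery_mode)
  stopifnot(length(control_points) >= 1)
  g <- vapply(control_points, function(cp) cp$gantry, numeric(1))
  if (delivery_mode == "static" && length(unique(g)) != 1L) {
    stop("static beam must have a single gantry angle")
  }
  if (delivery_mode == "arc" && length(g) > 1) {
    starts <- sort(unique(c(1L, subarc_breaks)))
    ends <- c(starts[-1] - 1L, length(g))
    for (s in seq_along(starts)) {
      gg <- g[starts[s]:ends[s]]
      if (length(gg) < 2) next
      dg <- diff(unwrap_angles(gg))
      if (any(dg == 0) || (any(dg > 0) && any(dg < 0))) {
        stop("arc gantry angles must be strictly monotone within a sub-arc")
      }
    }
  }
  structure(list(control_points = control_points, delivery_mode = delivery_mode,
                 name = name, subarc_breaks = subarc_breaks), class = "beam")
}

## unwrap a gantry sequence to a continuous (non-wrapping) angle track
unwrap_angles <- function(g) {
  out <- g
  for (i in seq_along(g)[-1]) {
    d <- g[i] - g[i - 1]
    d <- (d + 180) %% 360 - 180
    out[i] <- out[i - 1] + d
  }
  out
}

#' @export
print.beam <- function(x, ...) {
  g <- vapply(x$control_points, function(cp) cp$gantry, numeric(1))
  cat(sprintf("beam%s (%s): %d control points, gantry %.0f..%.0f deg, %.1f MU total\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              x$delivery_mode, length(x$control_points), g[1], g[length(g)],
              total_mu(x)))
  invisible(x)
}

#' Total monitor units of a beam or plan
#' @param x a [beam] or list of beams.
#' @return total MU.
#' @export
total_mu <- function(x) {
  if (inherits(x, "beam")) {
    sum(vapply(x$control_points, function(cp) cp$mu, numeric(1)))
  } else {
    sum(vapply(x, total_mu, numeric(1)))
  }
}

gantry_angles <- function(b) vapply(b$control_points, function(cp) cp$gantry, numeric(1))

## ---- plan JSON round-trip ---------------------------------------------

#' Write a plan (machine + beams) to JSON
#'
#' @param beams list of [beam]s.
#' @param machine a [machine_model].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plan <- function(beams, machine, path) {
  ser_cp <- function(cp) {
    list(gantry_deg = cp$gantry, collimator_deg = cp$collimator,
         jaws_mm = cp$jaws, leaves_mm = unclass(cp$leaves), mu = cp$mu)
  }
  obj <- list(schema = "dosepaint-plan/1",
              machine = unclass(machine),
              beams = lapply(beams, function(b) {
                list(name = b$name, delivery_mode = b$delivery_mode,
                     control_points = lapply(b$control_points, ser_cp))
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a plan written by [write_plan()]
#'
#' @param path JSON plan path.
#' @return list with elements `beams` and `machine`.
#' @export
read_plan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                             simplifyMatrix = TRUE)
  if (!identical(obj$schema, "dosepaint-plan/1")) stop("unrecognized plan schema")
  machine <- do.call(machine_model, obj$machine[names(formals(machine_model))])
  beams <- lapply(obj$beams, function(b) {
    cps <- lapply(b$control_points, function(cp) {
      control_point(cp$gantry_deg, cp$collimator_deg, cp$jaws_mm,
                    matrix(cp$leaves_mm, ncol = 2), cp$mu)
    })
    beam(cps, b$delivery_mode, name = b$name)
  })
  list(beams = beams, machine = machine)
}
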