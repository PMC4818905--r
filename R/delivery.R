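## Delivery post-processing: low-MU sub-arc pruning, control-point
## refinement, sub-arc linking and delivery-time estimation.

#' Eliminate low-MU arc parts, splitting arcs into sub-arcs
#'
#' Control points contributing fewer monitor units than the threshold are
#' removed; each maximal surviving contiguous run becomes one sub-arc beam.
#' Total output MU equals total input MU minus the pruned MU, control points
#' are never reordered, and no control point at or above the threshold is
#' removed.
#'
#' @param beams a [beam] or list of beams.
#' @param threshold MU threshold (default 2).
#' @return flat list of sub-arc [beam]s.
#' @export
prune_low_mu <- function(beams, threshold = 2) {
  if (inherits(beams, "beam")) beams <- list(beams)
  out <- list()
  for (b in beams) {
    keep <- vapply(b$control_points, function(cp) cp$mu, numeric(1)) >= threshold
    if (!any(keep)) next
    runs <- rle(keep)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    sub <- 0
    for (r in seq_along(runs$values)) {
      if (!runs$values[r]) next
      sub <- sub + 1
      nm <- if (sum(runs$values) > 1) {
        sprintf("%s_sub%d", b$name %||% "arc", sub)
      } else b$name
      out[[length(out) + 1]] <-
        beam(b$control_points[starts[r]:ends[r]], b$delivery_mode, name = nm)
    }
  }
  out
}

#' Control-point refinement limits
#'
#' @param mu maximum MU per inter-CP segment.
#' @param gantry,collimator maximum angle change between adjacent CPs (deg).
#' @param leaf,jaw maximum leaf/jaw travel between adjacent CPs (mm).
#' @return named list of limits.
#' @export
refinement_limits <- function(mu = 4, gantry = 2, collimator = 2,
                              leaf = 5, jaw = 5) {
  l <- as.list(environment())
  stopifnot(all(unlist(l) > 0))
  l
}

cp_deltas <- function(a, b) {
  c(gantry = abs(normalize_angle(b$gantry - a$gantry)),
    collimator = abs(b$collimator - a$collimator),
    leaf = max(abs(b$leaves - a$leaves)),
    jaw = max(abs(b$jaws - a$jaws)))
}

interp_cp <- function(a, b, f, mu, machine = NULL) {
  dg <- normalize_angle(b$gantry - a$gantry)
  leaves <- a$leaves + f * (b$leaves - a$leaves)
  jaws <- a$jaws + f * (b$jaws - a$jaws)
  if (!is.null(machine)) {
    # interpolating between a parked and an open row can undercut the
    # minimum gap while the interpolated jaws expose the row; widen such
    # rows symmetrically and settle the diagonal rule
    gap <- machine$min_opposing_gap
    edges <- leaf_row_edges(machine)
    in_jaw <- which(edges[-length(edges)] < jaws[4] & edges[-1] > jaws[3])
    for (i in in_jaw) {
      if (leaves[i, 2] - leaves[i, 1] < gap) {
        c0 <- mean(leaves[i, ])
        leaves[i, ] <- c(c0 - gap / 2, c0 + gap / 2)
      }
    }
    for (iter in 1:100) {
      changed <- FALSE
      for (i in in_jaw) {
        for (j in intersect(i + (-1:1), in_jaw)) {
          viol <- gap - (leaves[j, 2] - leaves[i, 1])
          if (viol > 1e-9) {
            leaves[i, 1] <- leaves[i, 1] - viol / 2
            leaves[j, 2] <- leaves[j, 2] + viol / 2
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
  }
  control_point(a$gantry + f * dg,
                a$collimator + f * (b$collimator - a$collimator),
                jaws, leaves, mu = mu)
}

#' Refine control points to bounded inter-CP deltas
#'
#' Inserts linearly interpolated control points inside any segment whose MU,
#' gantry/collimator angle change, or leaf/jaw travel exceeds the limits,
#' subdividing the segment MU equally so that every delta satisfies its
#' limit and the total beam MU is conserved; the opening control point,
#' which terminates no segment, is kept as-is. Applied after optimization so
#' the discretized arc meets the accuracy assumptions of treatment
#' verification. On a static (step-and-shoot) beam the beam is off between
#' segments, so only the MU limit applies and segments split over identical
#' apertures: the delivered dose is unchanged.
#'
#' @param b a [beam].
#' @param limits a [refinement_limits] list.
#' @return the refined [beam].
#' @export
refine_control_points <- function(b, limits = refinement_limits(),
                                  machine = machine_model()) {
  cps <- b$control_points
  out <- list()
  for (i in seq_along(cps)) {
    cp <- cps[[i]]
    if (i == 1) {
      # refinement only acts between adjacent pairs; the opening control
      # point is kept as-is
      out[[length(out) + 1]] <- cp
      next
    }
    prev <- cps[[i - 1]]
    if (b$delivery_mode == "static") {
      # step-and-shoot: the beam is off between segments, so only the MU
      # limit applies and the segment is split over identical apertures
      n_div <- max(ceiling(cp$mu / limits$mu - 1e-12), 1)
      for (s in seq_len(n_div)) {
        cc <- cp
        cc$mu <- cp$mu / n_div
        out[[length(out) + 1]] <- cc
      }
      next
    }
    dl <- cp_deltas(prev, cp)
    n_div <- max(ceiling(cp$mu / limits$mu - 1e-12),
                 ceiling(dl["gantry"] / limits$gantry - 1e-12),
                 ceiling(dl["collimator"] / limits$collimator - 1e-12),
                 ceiling(dl["leaf"] / limits$leaf - 1e-12),
                 ceiling(dl["jaw"] / limits$jaw - 1e-12), 1)
    for (s in seq_len(n_div)) {
      out[[length(out) + 1]] <- interp_cp(prev, cp, s / n_div, cp$mu / n_div,
                                          machine = machine)
    }
  }
  beam(out, b$delivery_mode, name = b$name, subarc_breaks = b$subarc_breaks)
}

#' Estimate the delivery time of a beam or plan
#'
#' Sum over inter-CP segments of the limiting ratio
#' `max(segment MU / max dose rate, gantry travel / max gantry speed,
#' max leaf travel / max leaf speed, collimator travel / max collimator
#' speed)`; the first control point contributes its MU at maximum dose rate.
#' For a list of beams, a fixed inter-beam overhead is added between beams.
#' Matching measured linac timings is out of scope; the estimate is monotone
#' non-decreasing in every segment delta, which is what sub-arc linking
#' needs.
#'
#' @param x a [beam] or list of beams.
#' @param machine a [machine_model].
#' @param interbeam_overhead_s seconds added between consecutive beams.
#' @return estimated delivery time in seconds.
#' @export
estimate_delivery_time <- function(x, machine = machine_model(),
                                   interbeam_overhead_s = 15) {
  if (!inherits(x, "beam")) {
    return(sum(vapply(x, estimate_delivery_time, numeric(1), machine = machine)) +
             interbeam_overhead_s * (length(x) - 1))
  }
  cps <- x$control_points
  t_total <- cps[[1]]$mu / machine$dose_rate_range[2]
  if (length(cps) > 1) {
    for (i in 2:length(cps)) {
      dl <- cp_deltas(cps[[i - 1]], cps[[i]])
      t_total <- t_total + max(cps[[i]]$mu / machine$dose_rate_range[2],
                               dl["gantry"] / machine$max_gantry_speed,
                               dl["leaf"] / machine$max_leaf_speed,
                               dl["collimator"] / machine$max_collimator_speed)
    }
  }
  unname(t_total)
}

reverse_beam <- function(b) {
  beam(rev(b$control_points), b$delivery_mode, name = b$name)
}

link_time <- function(subarcs, order, reversed, machine) {
  t_total <- 0
  prev_end <- NULL
  for (k in seq_along(order)) {
    b <- subarcs[[order[k]]]
    if (reversed[k]) b <- reverse_beam(b)
    g <- gantry_angles(b)
    if (!is.null(prev_end)) {
      t_total <- t_total + abs(normalize_angle(g[1] - prev_end)) / machine$max_gantry_speed
    }
    t_total <- t_total + estimate_delivery_time(b, machine)
    prev_end <- g[length(g)]
  }
  t_total
}

#' Link sub-arcs into one beam by shortest delivery time
#'
#' Chooses the sub-arc ordering and per-sub-arc direction minimizing the
#' estimated delivery time (gantry transit between sub-arc endpoints plus
#' per-sub-arc delivery): exhaustive search over all signed permutations for
#' up to 6 sub-arcs, a greedy nearest-endpoint heuristic above. The linked
#' beam contains exactly the input control points (as a multiset of
#' apertures and MUs) and its estimated time never exceeds that of the naive
#' input ordering.
#'
#' @param subarcs list of sub-arc [beam]s.
#' @param machine a [machine_model].
#' @return list with `beam` (the linked [beam]), `order`, `reversed`,
#'   `time_s` and `naive_time_s`.
#' @export
link_subarcs <- function(subarcs, machine = machine_model()) {
  stopifnot(length(subarcs) >= 1)
  n <- length(subarcs)
  naive <- link_time(subarcs, seq_len(n), rep(FALSE, n), machine)
  if (n <= 6) {
    perms <- permutations_of(n)
    best <- list(time = Inf)
    for (pi in seq_len(nrow(perms))) {
      for (mask in 0:(2^n - 1)) {
        rev_flags <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
        t_cand <- link_time(subarcs, perms[pi, ], rev_flags, machine)
        if (t_cand < best$time) {
          best <- list(time = t_cand, order = perms[pi, ], reversed = rev_flags)
        }
      }
    }
  } else {
    remaining <- seq_len(n)
    ord <- integer(0); rev_flags <- logical(0)
    prev_end <- NULL
    while (length(remaining)) {
      cost <- sapply(remaining, function(i) {
        g <- gantry_angles(subarcs[[i]])
        fwd <- if (is.null(prev_end)) 0 else abs(normalize_angle(g[1] - prev_end))
        bwd <- if (is.null(prev_end)) 0 else abs(normalize_angle(g[length(g)] - prev_end))
        c(fwd, bwd)
      })
      pick <- which.min(apply(cost, 2, min))
      use_rev <- cost[2, pick] < cost[1, pick]
      i <- remaining[pick]
      g <- gantry_angles(subarcs[[i]])
      prev_end <- if (use_rev) g[1] else g[length(g)]
      ord <- c(ord, i); rev_flags <- c(rev_flags, use_rev)
      remaining <- setdiff(remaining, i)
    }
    best <- list(time = link_time(subarcs, ord, rev_flags, machine),
                 order = ord, reversed = rev_flags)
    if (best$time > naive) {
      best <- list(time = naive, order = seq_len(n), reversed = rep(FALSE, n))
    }
  }
  cps <- list(); breaks <- integer(0)
  for (k in seq_along(best$order)) {
    b <- subarcs[[best$order[k]]]
    if (best$reversed[k]) b <- reverse_beam(b)
    if (k > 1) breaks <- c(breaks, length(cps) + 1L)
    cps <- c(cps, b$control_points)
  }
  list(beam = beam(cps, "arc", name = "linked_arcs", subarc_breaks = breaks),
       order = best$order, reversed = best$reversed,
       time_s = best$time, naive_time_s = naive)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- permutations_of(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}
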