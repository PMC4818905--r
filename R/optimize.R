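## MU-weight and leaf-position optimization against dose-painting
## objectives.
##
## The decision variables are the control-point MUs (non-negative) and the
## leaf positions. The algorithm alternates (a) an iterated non-negative
## least-squares MU solve over the point prescriptions plus one-sided
## dose-volume penalty rows, and (b) greedy local leaf-position moves
## accepted only on objective decrease. The attenuation/geometry part of the
## per-control-point dose is aperture-independent and cached, so a leaf move
## only re-evaluates the cheap fluence factor.

#' Optimization objectives
#'
#' @param targets list of dose-painting terms `list(points = <prescription
#'   point set>, weight = w)`; the squared deviation between planned and
#'   prescribed dose at the seeded points is minimized.
#' @param oars list of dose-volume penalty terms `list(structure = <mask>,
#'   dose_gy = level, volume_fraction = allowed fraction above the level,
#'   weight = w)`; the level is per fraction when optimizing per-fraction
#'   plans.
#' @return object of class `optimization_objectives`.
#' @export
optimization_objectives <- function(targets, oars = list()) {
  stopifnot(length(targets) >= 1)
  for (t in targets) stopifnot(inherits(t$points, "prescription_point_set"),
                               t$weight >= 0)
  for (o in oars) stopifnot(inherits(o$structure, "structure_mask"),
                            o$dose_gy >= 0, o$weight >= 0,
                            o$volume_fraction >= 0, o$volume_fraction <= 1)
  structure(list(targets = targets, oars = oars),
            class = "optimization_objectives")
}

#' Optimizer options
#'
#' @param max_iter iteration cap for the alternating scheme.
#' @param tol relative objective-change convergence tolerance.
#' @param n_mu_rounds inner rounds of the DVH-reweighted NNLS MU solve.
#' @param n_oar_sample voxel samples per OAR structure.
#' @param leaf_passes greedy leaf-move sweeps per outer iteration (0
#'   disables leaf optimization).
#' @param leaf_step leaf move proposal size (mm).
#' @param leaf_fraction fraction of (control point, row) pairs sampled per
#'   sweep.
#' @param seed integer seed controlling proposal sampling; the optimizer is
#'   deterministic for a fixed seed.
#' @return list of class `plan_options`.
#' @export
plan_options <- function(max_iter = 10, tol = 1e-4, n_mu_rounds = 6,
                         n_oar_sample = 300, leaf_passes = 1, leaf_step = 6,
                         leaf_fraction = 0.5, seed = 1) {
  structure(as.list(environment()), class = "plan_options")
}

## deterministic subsample of mask voxel centers
sample_structure_points <- function(structure, n) {
  idx <- which(structure$mask)
  if (!length(idx)) return(matrix(numeric(0), ncol = 3))
  if (length(idx) > n) idx <- idx[round(seq(1, length(idx), length.out = n))]
  index_to_world(structure$grid, arrayInd(idx, structure$grid$dims))
}

## objective-evaluation context: point groups with weights/levels
build_objective_groups <- function(objectives, options) {
  pts <- NULL
  groups <- list()
  for (t in objectives$targets) {
    p <- as.matrix(t$points$points[, c("x_mm", "y_mm", "z_mm")])
    groups[[length(groups) + 1]] <- list(
      kind = "target", name = t$points$target_name, weight = t$weight,
      rows = nrow(pts %||% matrix(0, 0, 3)) + seq_len(nrow(p)),
      d = t$points$points$dose_Gy)
    pts <- rbind(pts, p)
  }
  for (o in objectives$oars) {
    p <- sample_structure_points(o$structure, options$n_oar_sample)
    if (!nrow(p)) next
    groups[[length(groups) + 1]] <- list(
      kind = "oar", name = o$structure$name, weight = o$weight,
      rows = nrow(pts) + seq_len(nrow(p)),
      level = o$dose_gy, vf = o$volume_fraction)
    pts <- rbind(pts, p)
  }
  list(points = pts, groups = groups)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## composite objective value for a dose vector at the grouped points
objective_value <- function(D, groups) {
  val <- 0
  for (g in groups) {
    Dg <- D[g$rows]
    if (g$kind == "target") {
      val <- val + g$weight * mean((Dg - g$d)^2)
    } else {
      excess <- oar_excess(Dg, g$level, g$vf)
      val <- val + g$weight * mean(excess^2)
    }
  }
  val
}

## one-sided excess above the dose level, exempting the allowed hottest
## volume fraction
oar_excess <- function(D, level, vf) {
  ex <- pmax(D - level, 0)
  n_allow <- floor(vf * length(D))
  if (n_allow > 0 && any(ex > 0)) {
    exempt <- order(D, decreasing = TRUE)[seq_len(n_allow)]
    ex[exempt] <- 0
  }
  ex
}

## DVH-reweighted non-negative least-squares MU solve; returns the best MU
## vector found under the true objective (never worse than the input)
solve_mu <- function(A, groups, m0, options) {
  best_m <- m0
  best_obj <- objective_value(A %*% best_m, groups)
  m <- m0
  for (round in seq_len(options$n_mu_rounds)) {
    rows <- list(); rhs <- list(); wts <- list()
    D <- as.numeric(A %*% m)
    for (g in groups) {
      if (g$kind == "target") {
        rows[[length(rows) + 1]] <- g$rows
        rhs[[length(rhs) + 1]] <- g$d
        wts[[length(wts) + 1]] <- rep(sqrt(g$weight / length(g$rows)), length(g$rows))
      } else {
        ex <- oar_excess(D[g$rows], g$level, g$vf)
        sel <- which(ex > 0)
        if (length(sel)) {
          rows[[length(rows) + 1]] <- g$rows[sel]
          rhs[[length(rhs) + 1]] <- rep(g$level, length(sel))
          wts[[length(wts) + 1]] <- rep(sqrt(g$weight / length(g$rows)), length(sel))
        }
      }
    }
    r <- unlist(rows); w <- unlist(wts)
    C <- A[r, , drop = FALSE] * w
    d <- unlist(rhs) * w
    m <- tryCatch(pracma::lsqnonneg(C, as.numeric(d))$x,
                  error = function(e) m)
    obj <- objective_value(A %*% m, groups)
    if (obj < best_obj) { best_obj <- obj; best_m <- m }
  }
  list(m = best_m, obj = best_obj)
}

## recompute one influence column from cached geometry after a leaf change
column_from_cache <- function(cp, machine, cache, j, engine) {
  f <- cp_fluence(cp, machine, cache$u[, j], cache$v[, j], engine$penumbra_sigma)
  engine$calib_gy_per_mu * f * cache$att[, j]
}

## cache the aperture-independent per-CP factors at the sample points
build_influence_cache <- function(cps, machine, pts, body, engine) {
  n <- nrow(pts); k <- length(cps)
  u <- matrix(0, n, k); v <- matrix(0, n, k); att <- matrix(0, n, k)
  g_seen <- list()
  for (j in seq_len(k)) {
    gkey <- sprintf("%.6f", cps[[j]]$gantry)
    if (is.null(g_seen[[gkey]])) {
      fr <- beam_frame(cps[[j]]$gantry)
      w <- as.numeric(pts %*% fr$e_w)
      mag <- machine$source_axis_distance / (machine$source_axis_distance + w)
      depth <- ray_depth(pts, fr$e_w, body, engine$depth_step)
      g_seen[[gkey]] <- list(u = as.numeric(pts %*% fr$e_u) * mag,
                             v = as.numeric(pts %*% fr$e_v) * mag,
                             att = exp(-engine$mu_eff * depth) * mag^2)
    }
    gg <- g_seen[[gkey]]
    u[, j] <- gg$u; v[, j] <- gg$v; att[, j] <- gg$att
  }
  list(u = u, v = v, att = att)
}

#' Optimize MU weights and leaf positions of a plan
#'
#' Alternates a DVH-penalized non-negative least-squares MU solve with
#' greedy per-leaf local moves, accepting a step only when the composite
#' objective decreases; machine constraints are respected at every accepted
#' iterate and the objective trace is monotone non-increasing. Terminates at
#' the iteration cap or when the relative objective change drops below the
#' tolerance.
#'
#' @param beams list of [beam]s with initial apertures.
#' @param objectives an [optimization_objectives].
#' @param body the body [structure_mask].
#' @param machine a [machine_model].
#' @param engine a [dose_engine_config].
#' @param options a [plan_options].
#' @return object of class `plan_result`: `beams` (with optimized MU and
#'   leaves), `mu`, `objective_trace`, `achieved_qf` (percent, per target),
#'   `constraint_report`, `point_dose` and `groups` (sample-point diagnostics).
#' @export
optimize_plan <- function(beams, objectives, body, machine = machine_model(),
                          engine = dose_engine_config(),
                          options = plan_options()) {
  if (inherits(beams, "beam")) beams <- list(beams)
  cps <- unlist(lapply(beams, function(b) b$control_points), recursive = FALSE)
  for (cp in cps) validate_control_point(cp, machine)
  gobj <- build_objective_groups(objectives, options)
  pts <- gobj$points
  groups <- gobj$groups
  cache <- build_influence_cache(cps, machine, pts, body, engine)
  A <- matrix(0, nrow(pts), length(cps))
  for (j in seq_along(cps)) A[, j] <- column_from_cache(cps[[j]], machine, cache, j, engine)

  m <- vapply(cps, function(cp) cp$mu, numeric(1))
  trace <- objective_value(A %*% m, groups)
  sol <- solve_mu(A, groups, m, options)
  m <- sol$m
  trace <- c(trace, sol$obj)
  obj <- sol$obj
  gap <- machine$min_opposing_gap

  rng_stream <- with_seed(options$seed, sample.int(.Machine$integer.max, options$max_iter))
  for (iter in seq_len(options$max_iter)) {
    obj_before <- obj
    if (options$leaf_passes > 0) {
      proposals <- with_seed(rng_stream[iter], {
        nprop <- max(1L, round(options$leaf_fraction * length(cps) *
                                 machine$n_leaf_pairs))
        data.frame(j = sample.int(length(cps), nprop, replace = TRUE),
                   row = sample.int(machine$n_leaf_pairs, nprop, replace = TRUE),
                   side = sample(1:2, nprop, replace = TRUE),
                   dir = sample(c(-1, 1), nprop, replace = TRUE))
      })
      for (p in seq_len(nrow(proposals))) {
        j <- proposals$j[p]
        if (m[j] <= 0) next
        cp <- cps[[j]]
        lv <- cp$leaves
        lv[proposals$row[p], proposals$side[p]] <-
          lv[proposals$row[p], proposals$side[p]] +
          proposals$dir[p] * options$leaf_step
        if (lv[proposals$row[p], 1] > lv[proposals$row[p], 2] - gap) next
        cand <- cp
        cand$leaves <- lv
        ok <- tryCatch({ validate_control_point(cand, machine); TRUE },
                       error = function(e) FALSE)
        if (!ok) next
        a_new <- column_from_cache(cand, machine, cache, j, engine)
        D_new <- A %*% m + m[j] * (a_new - A[, j])
        obj_new <- objective_value(D_new, groups)
        if (obj_new < obj) {
          cps[[j]] <- cand
          A[, j] <- a_new
          obj <- obj_new
          trace <- c(trace, obj)
        }
      }
    }
    sol <- solve_mu(A, groups, m, options)
    if (sol$obj < obj) {
      m <- sol$m
      obj <- sol$obj
      trace <- c(trace, obj)
    }
    if (obj_before - obj <= options$tol * max(obj_before, 1e-12)) break
  }

  for (j in seq_along(cps)) cps[[j]]$mu <- m[j]
  out_beams <- list()
  off <- 0
  for (b in beams) {
    nb <- length(b$control_points)
    out_beams[[length(out_beams) + 1]] <-
      beam(cps[off + seq_len(nb)], b$delivery_mode, name = b$name)
    off <- off + nb
  }
  D <- as.numeric(A %*% m)
  qf <- numeric(0)
  for (g in groups) {
    if (g$kind == "target") {
      qf[g$name] <- mean(abs(D[g$rows] - g$d) / g$d) * 100
    }
  }
  constraint_report <- vapply(cps, function(cp) {
    tryCatch({ validate_control_point(cp, machine); TRUE },
             error = function(e) FALSE)
  }, logical(1))
  structure(list(beams = out_beams, mu = m, objective_trace = trace,
                 achieved_qf = qf, constraint_report = constraint_report,
                 point_dose = D, groups = groups, points = pts),
            class = "plan_result")
}

#' @export
print.plan_result <- function(x, ...) {
  cat(sprintf("plan_result: %d beams, %d control points, objective %.4g -> %.4g\n",
              length(x$beams), length(x$mu), x$objective_trace[1],
              x$objective_trace[length(x$objective_trace)]))
  for (n in names(x$achieved_qf)) {
    cat(sprintf("  QF %s: %.2f%%\n", n, x$achieved_qf[n]))
  }
  invisible(x)
}
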