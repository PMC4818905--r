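## Synthetic three-phase head-and-neck phantom cases.
##
## Geometry is deliberately schematic (cylinders/ellipsoids), but the
## structure-derivation rules are the clinical ones: GTV_T + 1 cm -> CTV_HR
## adjusted off air and uninvolved bone, + 3 mm -> PTV_HR, PRV expansions of
## 5 mm (cord) and 3 mm (brainstem), and a 50%-of-max uptake threshold for
## PET-based GTV segmentation.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## separable Gaussian smoothing, sigma in voxels (length 1 or 3)
smooth_gauss3 <- function(arr, sigma) {
  sigma <- rep(sigma, length.out = 3)
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- dnorm(seq(-r, r), sd = s)
    k <- k / sum(k)
    a <- if (ax == 1) arr else aperm(arr, switch(ax, NULL, c(2, 1, 3), c(3, 2, 1)))
    da <- dim(a)
    m <- matrix(a, nrow = da[1])
    # replicate-pad along the filtered axis
    mp <- rbind(m[rep(1, r), , drop = FALSE], m, m[rep(da[1], r), , drop = FALSE])
    out <- matrix(0, nrow = da[1], ncol = ncol(m))
    for (s_i in seq_along(k)) {
      out <- out + k[s_i] * mp[s_i:(s_i + da[1] - 1), , drop = FALSE]
    }
    a <- array(out, dim = da)
    arr <- if (ax == 1) a else aperm(a, switch(ax, NULL, c(2, 1, 3), c(3, 2, 1)))
  }
  arr
}

ellipsoid_mask <- function(grid, center, semiaxes) {
  ax <- grid_axes(grid)
  u2 <- ((ax$x - center[1]) / semiaxes[1])^2
  v2 <- ((ax$y - center[2]) / semiaxes[2])^2
  w2 <- ((ax$z - center[3]) / semiaxes[3])^2
  outer(outer(u2, v2, `+`), w2, `+`) <= 1
}

cylinder_mask <- function(grid, center_xy, radius, z_range = c(-Inf, Inf)) {
  ax <- grid_axes(grid)
  r2 <- outer((ax$x - center_xy[1])^2, (ax$y - center_xy[2])^2, `+`) <= radius^2
  zin <- ax$z >= z_range[1] & ax$z <= z_range[2]
  outer(r2, zin, `&`)
}

annulus_mask <- function(grid, center_xy, r_inner, r_outer, z_range = c(-Inf, Inf),
                         y_min = -Inf) {
  ax <- grid_axes(grid)
  r2 <- outer((ax$x - center_xy[1])^2, (ax$y - center_xy[2])^2, `+`)
  ring <- r2 <= r_outer^2 & r2 >= r_inner^2
  yok <- matrix(rep(ax$y >= y_min, each = length(ax$x)), nrow = length(ax$x))
  zin <- ax$z >= z_range[1] & ax$z <= z_range[2]
  outer(ring & yok, zin, `&`)
}

#' Isotropic Euclidean margin expansion of a structure mask
#'
#' Dilates the mask with a Euclidean ball of the given radius (measured
#' between voxel centers), then removes voxels belonging to the optional
#' exclusion structure. This implements the clinical margin recipes
#' (GTV to CTV, CTV to PTV, OAR to PRV) including the adjustment of CTVs off
#' air cavities and uninvolved bone, which is performed as a set subtraction.
#'
#' @param structure a [structure_mask].
#' @param margin_mm non-negative margin in mm. `0` returns the input
#'   (minus the exclusion, if given).
#' @param exclusion optional [structure_mask] on the same grid whose voxels
#'   are removed after dilation.
#' @param name label for the result; default appends the margin.
#' @return a [structure_mask]; always a superset of `structure` minus
#'   `exclusion`.
#' @export
expand_margin <- function(structure, margin_mm, exclusion = NULL, name = NULL) {
  if (margin_mm < 0) stop("margin_mm must be >= 0")
  grid <- structure$grid
  if (!is.null(exclusion) && !same_grid(grid, exclusion$grid)) {
    stop("exclusion mask must share the structure grid")
  }
  d <- grid$dims
  sp <- grid$spacing
  rv <- floor(margin_mm / sp + 1e-9)
  out <- array(FALSE, dim = d)
  m <- structure$mask
  for (di in seq(-rv[1], rv[1])) {
    for (dj in seq(-rv[2], rv[2])) {
      for (dk in seq(-rv[3], rv[3])) {
        if ((di * sp[1])^2 + (dj * sp[2])^2 + (dk * sp[3])^2 > margin_mm^2 + 1e-9) next
        si <- max(1, 1 - di):min(d[1], d[1] - di)
        sj <- max(1, 1 - dj):min(d[2], d[2] - dj)
        sk <- max(1, 1 - dk):min(d[3], d[3] - dk)
        out[si + di, sj + dj, sk + dk] <-
          out[si + di, sj + dj, sk + dk] | m[si, sj, sk]
      }
    }
  }
  if (!is.null(exclusion)) out <- out & !exclusion$mask
  if (is.null(name)) name <- sprintf("%s+%gmm", structure$name, margin_mm)
  structure_mask(name, out, grid)
}

#' Threshold-based PET segmentation inside a search region
#'
#' Segments the voxels of `search_roi` whose (trilinearly sampled) PET value
#' is at least `fraction` of the in-region maximum — the standard
#' 50%-of-SUVmax style auto-segmentation used to delineate FDG-avid tumor.
#'
#' @param pet a [scalar_volume] with PET uptake (any grid; values are sampled
#'   on the ROI grid by trilinear interpolation).
#' @param search_roi a nonempty [structure_mask].
#' @param fraction threshold as a fraction of the in-region maximum,
#'   `0 < fraction < 1`. Default `0.5`.
#' @param name label for the result.
#' @return a [structure_mask] on the ROI grid.
#' @export
segment_suv_threshold <- function(pet, search_roi, fraction = 0.5,
                                  name = "GTV_PET") {
  if (!sum(search_roi$mask)) stop("search_roi is empty")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  idx <- which(search_roi$mask)
  pts <- index_to_world(search_roi$grid, arrayInd(idx, search_roi$grid$dims))
  vals <- interp_trilinear(pet$values, pet$grid, pts, outside = "nearest")
  vmax <- max(vals)
  if (vmax <= 0) stop("PET has no positive signal inside the search region")
  out <- array(FALSE, dim = search_roi$grid$dims)
  out[idx[vals >= fraction * vmax]] <- TRUE
  structure_mask(name, out, search_roi$grid)
}

#' Smooth synthetic deformation vector field
#'
#' Generates a bounded, smooth random displacement field on a reference grid:
#' three independent Gaussian-smoothed noise components rescaled so the
#' maximum random displacement magnitude equals `amplitude_mm`, plus an
#' optional rigid translation. `amplitude_mm = 0` with zero translation gives
#' the identity field.
#'
#' @param grid reference [image_grid].
#' @param amplitude_mm maximum magnitude of the random component (mm).
#' @param smoothness_mm Gaussian smoothing length of the noise (mm).
#' @param seed integer seed; the field is reproducible bit-for-bit.
#' @param translation length-3 constant displacement (mm) added everywhere.
#' @return a [deformation_field].
#' @export
make_synthetic_dvf <- function(grid, amplitude_mm = 5, smoothness_mm = 25,
                               seed = 1, translation = c(0, 0, 0)) {
  d <- grid$dims
  disp <- array(0, dim = c(d, 3))
  if (amplitude_mm > 0) {
    comps <- with_seed(seed, {
      lapply(1:3, function(i) {
        smooth_gauss3(array(rnorm(prod(d)), dim = d),
                      smoothness_mm / grid$spacing)
      })
    })
    mag <- sqrt(comps[[1]]^2 + comps[[2]]^2 + comps[[3]]^2)
    scale <- amplitude_mm / max(mag, 1e-12)
    for (i in 1:3) disp[, , , i] <- comps[[i]] * scale
  }
  for (i in 1:3) disp[, , , i] <- disp[, , , i] + translation[i]
  deformation_field(disp, grid)
}

#' Default phantom configuration
#'
#' Parameters of the synthetic three-phase head-and-neck case. Grids are kept
#' at desk scale: a 64^3 CT surrogate at 3 mm and a 48^3 PET at 4 mm
#' isotropic (the PET voxel size of the emulated imaging protocol). The
#' primary tumor is a lateralized ellipsoid with a heterogeneous FDG-like
#' hotspot; phases II and III apply tumor shrinkage plus a small rigid shift,
#' mirroring re-imaging after fractions 8 and 18. Phase III carries no PET.
#'
#' @param ct_dims,ct_spacing CT surrogate grid (voxels, mm).
#' @param pet_dims,pet_spacing PET grid (voxels, mm).
#' @param body_semiaxes body ellipse semi-axes in x/y (mm); the body is an
#'   elliptic cylinder spanning the grid in z.
#' @param tumor_center,tumor_semiaxes primary tumor (GTV_T) ellipsoid (mm).
#' @param node_count number of pathological lymph nodes (0 or more).
#' @param node_center,node_radius first node sphere (mm); additional nodes
#'   are stacked 22 mm apart in z.
#' @param suv_max,node_suv,heterogeneity PET hotspot scaling: maximum tumor
#'   uptake, node uptake, and relative amplitude of the smoothed random
#'   heterogeneity inside the tumor.
#' @param pet_smoothness_mm smoothing length of the heterogeneity field (mm).
#' @param phase_shift_mm per-phase rigid shift applied to phases II/III (mm,
#'   applied once resp. twice).
#' @param phase_shrink tumor linear shrinkage factors for phases II and III.
#' @param ctv_margin_mm,ptv_margin_mm,en_margin_mm margin recipe (mm):
#'   GTV to CTV_HR, CTV to PTV, CTV_HR to elective CTV_EN.
#' @param prv_cord_mm,prv_brainstem_mm PRV expansions (mm).
#' @return a named list of class `phantom_config`.
#' @export
phantom_config <- function(ct_dims = c(64, 64, 64), ct_spacing = c(3, 3, 3),
                           pet_dims = c(48, 48, 48), pet_spacing = c(4, 4, 4),
                           body_semiaxes = c(80, 75),
                           tumor_center = c(25, -5, 0),
                           tumor_semiaxes = c(16, 14, 18),
                           node_count = 1,
                           node_center = c(42, -20, -25), node_radius = 8,
                           suv_max = 12, node_suv = 6, heterogeneity = 0.45,
                           pet_smoothness_mm = 10,
                           phase_shift_mm = c(2, -2, 0),
                           phase_shrink = c(0.85, 0.7),
                           ctv_margin_mm = 10, ptv_margin_mm = 3,
                           en_margin_mm = 12,
                           prv_cord_mm = 5, prv_brainstem_mm = 3) {
  cfg <- as.list(environment())
  if (any(cfg$ct_dims <= 0) || any(cfg$pet_dims <= 0) ||
      any(cfg$ct_spacing <= 0) || any(cfg$pet_spacing <= 0)) {
    stop("phantom configuration error: grid sizes and spacings must be positive")
  }
  if (cfg$node_count < 0) stop("phantom configuration error: node_count < 0")
  class(cfg) <- "phantom_config"
  cfg
}

## fixed anatomy of the schematic neck cross-section (mm, reference frame)
phantom_anatomy <- function() {
  list(cord_xy = c(0, -45), cord_r = 5,
       vertebra_r = c(8, 14),
       airway_xy = c(0, 10), airway_r = 8,
       brainstem_xy = c(0, -35), brainstem_r = 8, brainstem_zmin = 40,
       parotid_dx = 55, parotid_y = -18, parotid_z = 25,
       parotid_semi = c(12, 15, 20),
       swallow_r = c(8, 14),
       mandible_r = c(26, 32), mandible_ymin = 18, mandible_z = c(10, 45))
}

phantom_phase_structures <- function(cfg, shift, shrink) {
  an <- phantom_anatomy()
  grid <- image_grid(cfg$ct_dims, cfg$ct_spacing)
  sft <- function(c3) c3 + shift
  sft2 <- function(c2) c2 + shift[1:2]

  body <- structure_mask("body", {
    ax <- grid_axes(grid)
    e <- outer(((ax$x - shift[1]) / cfg$body_semiaxes[1])^2,
               ((ax$y - shift[2]) / cfg$body_semiaxes[2])^2, `+`) <= 1
    outer(e, rep(TRUE, grid$dims[3]), `&`)
  }, grid)

  air <- structure_mask("air", cylinder_mask(grid, sft2(an$airway_xy), an$airway_r), grid)
  vert <- annulus_mask(grid, sft2(an$cord_xy), an$vertebra_r[1], an$vertebra_r[2])
  mand <- annulus_mask(grid, sft2(an$airway_xy), an$mandible_r[1], an$mandible_r[2],
                       z_range = an$mandible_z + shift[3], y_min = an$mandible_ymin + shift[2])
  bone <- structure_mask("bone", vert | mand, grid)
  mandible <- structure_mask("mandible", mand, grid)

  cord <- structure_mask("spinal_cord",
                         cylinder_mask(grid, sft2(an$cord_xy), an$cord_r), grid)
  brainstem <- structure_mask("brainstem",
                              cylinder_mask(grid, sft2(an$brainstem_xy), an$brainstem_r,
                                            c(an$brainstem_zmin + shift[3], Inf)), grid)
  swallow <- structure_mask("swallowing",
                            annulus_mask(grid, sft2(an$airway_xy), an$swallow_r[1],
                                         an$swallow_r[2]) & !air$mask, grid)
  par_i <- structure_mask("parotid_ipsi",
                          ellipsoid_mask(grid, sft(c(an$parotid_dx, an$parotid_y, an$parotid_z)),
                                         an$parotid_semi), grid)
  par_c <- structure_mask("parotid_contra",
                          ellipsoid_mask(grid, sft(c(-an$parotid_dx, an$parotid_y, an$parotid_z)),
                                         an$parotid_semi), grid)

  gtv_t <- structure_mask("GTV_T",
                          ellipsoid_mask(grid, sft(cfg$tumor_center),
                                         cfg$tumor_semiaxes * shrink) & body$mask, grid)
  nodes <- list()
  if (cfg$node_count > 0) {
    for (n in seq_len(cfg$node_count)) {
      ctr <- sft(cfg$node_center + c(0, 0, (n - 1) * 22))
      nodes[[n]] <- structure_mask(sprintf("GTV_N%d", n),
                                   ellipsoid_mask(grid, ctr, rep(cfg$node_radius * shrink, 3)) &
                                     body$mask, grid)
    }
  }

  exclusion <- structure_mask("air_bone", air$mask | bone$mask, grid)
  ctv_hr <- expand_margin(gtv_t, cfg$ctv_margin_mm, exclusion = exclusion, name = "CTV_HR")
  nm <- ctv_hr$mask
  for (nd in nodes) nm <- nm | nd$mask
  ctv_hr <- structure_mask("CTV_HR", nm & body$mask, grid)
  ptv_hr <- expand_margin(ctv_hr, cfg$ptv_margin_mm, name = "PTV_HR")
  ptv_hr <- structure_mask("PTV_HR", ptv_hr$mask & body$mask, grid)
  ctv_en <- expand_margin(ctv_hr, cfg$en_margin_mm, exclusion = exclusion, name = "CTV_EN")
  ctv_en <- structure_mask("CTV_EN", (ctv_en$mask | ctv_hr$mask) & body$mask, grid)
  ptv_en <- expand_margin(ctv_en, cfg$ptv_margin_mm, name = "PTV_EN")
  ptv_en <- structure_mask("PTV_EN", ptv_en$mask & body$mask, grid)

  prv_cord <- expand_margin(cord, cfg$prv_cord_mm, name = "PRV_spinal_cord")
  prv_bs <- expand_margin(brainstem, cfg$prv_brainstem_mm, name = "PRV_brainstem")

  ct_vals <- array(-1000, dim = grid$dims)
  ct_vals[body$mask] <- 20
  ct_vals[bone$mask & body$mask] <- 700
  ct_vals[air$mask & body$mask] <- -950
  ct <- scalar_volume(ct_vals, grid, kind = "ct")

  structures <- c(list(body, gtv_t), nodes,
                  list(ctv_hr, ptv_hr, ctv_en, ptv_en,
                       cord, prv_cord, brainstem, prv_bs,
                       par_i, par_c, swallow, mandible, air, bone))
  list(ct = ct, structures = structures, body = body, gtv_t = gtv_t,
       nodes = nodes, grid = grid)
}

phantom_phase_pet <- function(cfg, shift, shrink, seed) {
  grid <- image_grid(cfg$pet_dims, cfg$pet_spacing)
  ax <- grid_axes(grid)
  body2d <- outer(((ax$x - shift[1]) / cfg$body_semiaxes[1])^2,
                  ((ax$y - shift[2]) / cfg$body_semiaxes[2])^2, `+`) <= 1
  body <- outer(body2d, rep(TRUE, grid$dims[3]), `&`)
  vals <- array(0.05, dim = grid$dims)
  vals[body] <- 1

  blob <- function(center, semi, peak, het_seed) {
    u2 <- ((ax$x - center[1]) / semi[1])^2
    v2 <- ((ax$y - center[2]) / semi[2])^2
    w2 <- ((ax$z - center[3]) / semi[3])^2
    r2 <- outer(outer(u2, v2, `+`), w2, `+`)
    profile <- exp(-1.5 * r2)
    het <- with_seed(het_seed, {
      smooth_gauss3(array(rnorm(prod(grid$dims)), dim = grid$dims),
                    cfg$pet_smoothness_mm / grid$spacing)
    })
    het <- het / max(abs(het))
    raw <- profile * pmax(1 + cfg$heterogeneity * het, 0.2)
    inside <- r2 <= 1
    if (!any(inside)) return(array(0, dim = grid$dims))
    raw * (peak - 1) / max(raw[inside]) * inside
  }

  vals <- vals + blob(cfg$tumor_center + shift, cfg$tumor_semiaxes * shrink,
                      cfg$suv_max, seed * 1000L + 11L)
  if (cfg$node_count > 0) {
    for (n in seq_len(cfg$node_count)) {
      ctr <- cfg$node_center + shift + c(0, 0, (n - 1) * 22)
      vals <- vals + blob(ctr, rep(cfg$node_radius * shrink, 3), cfg$node_suv,
                          seed * 1000L + 20L + n)
    }
  }
  scalar_volume(vals, grid, kind = "pet")
}

## analytic reference->phase displacement: rigid shift plus tumor-centred
## contraction weighted by a Gaussian falloff
phantom_phase_dvf <- function(cfg, grid, shift, shrink, falloff_mm = 40) {
  pts <- grid_points(grid)
  w <- exp(-rowSums(sweep(pts, 2, cfg$tumor_center)^2) / (2 * falloff_mm^2))
  disp <- array(0, dim = c(grid$dims, 3))
  for (i in 1:3) {
    d <- shift[i] + (shrink - 1) * (pts[, i] - cfg$tumor_center[i]) * w
    disp[, , , i] <- array(d, dim = grid$dims)
  }
  deformation_field(disp, grid)
}

#' Generate a synthetic three-phase dose-painting case
#'
#' Builds a complete seed-reproducible case: per phase a CT surrogate, the
#' full structure set (targets derived with the clinical margin rules, OARs,
#' PRVs, body, air/bone exclusion masks), PET for phases I and II only
#' (re-imaging stops before the last treatment phase), and analytic
#' deformation fields mapping the reference (phase I) grid into phases II and
#' III.
#'
#' @param config a [phantom_config].
#' @param seed integer seed; identical `(config, seed)` reproduce the case
#'   bit-for-bit.
#' @return An object of class `phantom_case` with fields `phases` (list of 3,
#'   each with `ct`, `pet` (or `NULL`), `structures`), `dvf_to_reference`
#'   (deformation fields for phases II and III), `config`, `seed`.
#' @examples
#' case <- generate_phantom(phantom_config(ct_dims = c(24, 24, 24),
#'                                         ct_spacing = c(8, 8, 8),
#'                                         pet_dims = c(24, 24, 24),
#'                                         pet_spacing = c(8, 8, 8)), seed = 7)
#' names(case$phases[[1]])
#' @export
generate_phantom <- function(config = phantom_config(), seed = 1) {
  cfg <- config
  grid <- image_grid(cfg$ct_dims, cfg$ct_spacing)
  ext <- (cfg$ct_dims - 1) * cfg$ct_spacing / 2
  if (any(abs(cfg$tumor_center) + cfg$tumor_semiaxes > ext + cfg$ct_spacing)) {
    stop("phantom configuration error: tumor extends outside the grid")
  }
  shifts <- list(c(0, 0, 0), cfg$phase_shift_mm, 2 * cfg$phase_shift_mm)
  shrinks <- c(1, cfg$phase_shrink)
  phases <- vector("list", 3)
  for (k in 1:3) {
    ph <- phantom_phase_structures(cfg, shifts[[k]], shrinks[k])
    pet <- if (k <= 2) phantom_phase_pet(cfg, shifts[[k]], shrinks[k], seed + k) else NULL
    if (!sum(ph$gtv_t$mask)) stop("phantom configuration error: empty GTV_T")
    if (any(ph$gtv_t$mask & !ph$body$mask)) {
      stop("phantom configuration error: tumor outside body")
    }
    phases[[k]] <- list(ct = ph$ct, pet = pet, structures = ph$structures)
  }
  dvfs <- list(phantom_phase_dvf(cfg, grid, shifts[[2]], shrinks[2]),
               phantom_phase_dvf(cfg, grid, shifts[[3]], shrinks[3]))
  structure(list(phases = phases, dvf_to_reference = dvfs,
                 config = cfg, seed = seed),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("phantom_case (seed %d): 3 phases on %s\n", x$seed,
              format(x$phases[[1]]$ct$grid)))
  for (k in 1:3) {
    cat(sprintf("  phase %d: PET %s, %d structures\n", k,
                if (is.null(x$phases[[k]]$pet)) "absent" else "present",
                length(x$phases[[k]]$structures)))
  }
  invisible(x)
}

#' Fetch a named structure from a phantom phase
#'
#' @param case a `phantom_case`.
#' @param name structure label (e.g. `"GTV_T"`, `"PRV_spinal_cord"`).
#' @param phase phase number (1-3).
#' @return the [structure_mask], or an error when absent.
#' @export
case_structure <- function(case, name, phase = 1) {
  s <- get_structure(case$phases[[phase]]$structures, name)
  if (is.null(s)) stop(sprintf("structure '%s' not present in phase %d", name, phase))
  s
}

#' Write a phantom case to disk
#'
#' Volumes go out as NIfTI; a JSON manifest lists phases, files and structure
#' names.
#'
#' @param case a `phantom_case`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_phantom_case <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = case$seed, phases = list())
  for (k in 1:3) {
    ph <- case$phases[[k]]
    pdir <- file.path(dir, sprintf("phase%d", k))
    dir.create(pdir, showWarnings = FALSE)
    write_volume(ph$ct, file.path(pdir, "ct.nii.gz"))
    entry <- list(ct = sprintf("phase%d/ct.nii.gz", k), structures = list())
    if (!is.null(ph$pet)) {
      write_volume(ph$pet, file.path(pdir, "pet.nii.gz"))
      entry$pet <- sprintf("phase%d/pet.nii.gz", k)
    }
    for (s in ph$structures) {
      fn <- sprintf("phase%d/%s.nii.gz", k, s$name)
      write_volume(s, file.path(dir, fn))
      entry$structures[[s$name]] <- fn
    }
    manifest$phases[[k]] <- entry
  }
  for (k in 1:2) {
    fn <- sprintf("dvf_phase%d_to_reference.nii.gz", k + 1)
    write_volume(case$dvf_to_reference[[k]], file.path(dir, fn))
    manifest$dvf_to_reference[[k]] <- fn
  }
  mf <- file.path(dir, "case.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(mf)
}

#' Read a phantom case directory written by [write_phantom_case()]
#'
#' @param dir case directory containing `case.json`.
#' @return a `phantom_case` (without the generating config).
#' @export
read_phantom_case <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "case.json"))
  phases <- lapply(manifest$phases, function(entry) {
    ct <- read_volume(file.path(dir, entry$ct), kind = "ct")
    pet <- if (!is.null(entry$pet)) {
      read_volume(file.path(dir, entry$pet), kind = "pet")
    } else NULL
    structures <- lapply(names(entry$structures), function(nm) {
      read_mask(file.path(dir, entry$structures[[nm]]), nm)
    })
    list(ct = ct, pet = pet, structures = structures)
  })
  dvfs <- lapply(manifest$dvf_to_reference, function(fn) {
    read_volume(file.path(dir, fn))
  })
  structure(list(phases = phases, dvf_to_reference = dvfs,
                 config = NULL, seed = manifest$seed),
            class = "phantom_case")
}
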