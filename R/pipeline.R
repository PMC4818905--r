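## End-to-end planning pipeline on synthetic cases: per-phase plan
## construction and optimization, multi-phase accumulation, evaluation.

mask_and_not <- function(a, bs, name) {
  m <- a$mask
  for (b in bs) if (!is.null(b)) m <- m & !b$mask
  structure_mask(name, m, a$grid)
}

#' Default organ-at-risk planning objectives
#'
#' Per-fraction dose-volume penalties for a 30-fraction course: at most 5%
#' of the spinal-cord PRV above 50 Gy and of the brainstem PRV above 60 Gy,
#' the mandible below 70 Gy, the parotids aimed below 27 Gy to half the
#' gland, and a soft constraint on the swallowing structures.
#'
#' @param structures list of [structure_mask]s of the phase being planned.
#' @param n_fractions total course fractions the levels are stated for.
#' @return list of OAR objective terms for [optimization_objectives()].
#' @export
default_oar_objectives <- function(structures, n_fractions = 30) {
  spec <- list(
    list(name = "PRV_spinal_cord", total_gy = 50, vf = 0.05, weight = 60),
    list(name = "PRV_brainstem", total_gy = 60, vf = 0.05, weight = 20),
    list(name = "mandible", total_gy = 70, vf = 0.05, weight = 10),
    list(name = "parotid_ipsi", total_gy = 27, vf = 0.5, weight = 8),
    list(name = "parotid_contra", total_gy = 27, vf = 0.5, weight = 8),
    list(name = "swallowing", total_gy = 45, vf = 0.3, weight = 4))
  out <- list()
  for (s in spec) {
    st <- get_structure(structures, s$name)
    if (is.null(st) || !sum(st$mask)) next
    out[[length(out) + 1]] <- list(structure = st,
                                   dose_gy = s$total_gy / n_fractions,
                                   volume_fraction = s$vf, weight = s$weight)
  }
  out
}

#' Build the dose-painting objectives for one treatment phase
#'
#' Phases I and II paint the primary tumor between `D_low` and `D_high` per
#' fraction from the phase PET, prescribe the nodal median level to lymph
#' node targets, and hold `PTV_HR` at the low painted level and `PTV_EN` at
#' its elective level. Phase III (no PET) prescribes a uniform 2 Gy per
#' fraction to `PTV_HR` only.
#'
#' @param case a `phantom_case`.
#' @param phase phase number (1-3).
#' @param n_points prescription points seeded in the painted target.
#' @param prescription a [dose_prescription].
#' @param node_flat_gy flat per-fraction nodal prescription (Gy).
#' @param elective_gy per-fraction elective-neck level (Gy).
#' @param phase3_gy per-fraction `PTV_HR` level in phase III (Gy).
#' @param seed integer seed for point seeding.
#' @return an [optimization_objectives].
#' @export
phase_objectives <- function(case, phase, n_points = 1500,
                             prescription = dose_prescription(),
                             node_flat_gy = 2.2, elective_gy = 2.0,
                             phase3_gy = 2.0, seed = 1) {
  st <- case$phases[[phase]]$structures
  pet <- case$phases[[phase]]$pet
  gtv <- get_structure(st, "GTV_T")
  ptv_hr <- get_structure(st, "PTV_HR")
  ptv_en <- get_structure(st, "PTV_EN")
  nodes <- Filter(function(s) grepl("^GTV_N", s$name), st)
  targets <- list()
  if (!is.null(pet)) {
    pts <- seed_prescription_points(pet, gtv, n_points, prescription,
                                    seed = seed)
    targets[[length(targets) + 1]] <- list(points = pts, weight = 100)
    for (nd in nodes) {
      npts <- seed_prescription_points(pet, nd, max(200L, n_points %/% 5),
                                       prescription, seed = seed + 1,
                                       flat_dose = node_flat_gy)
      targets[[length(targets) + 1]] <- list(points = npts, weight = 50)
    }
    hr_rest <- mask_and_not(ptv_hr, c(list(gtv), nodes), "PTV_HR_rest")
    hp <- seed_prescription_points(pet, hr_rest, max(400L, n_points %/% 2),
                                   prescription, seed = seed + 2,
                                   flat_dose = prescription$D_low)
    targets[[length(targets) + 1]] <- list(points = hp, weight = 30)
    en_rest <- mask_and_not(ptv_en, list(ptv_hr), "PTV_EN_rest")
    ep <- seed_prescription_points(pet, en_rest, max(400L, n_points %/% 2),
                                   prescription, seed = seed + 3,
                                   flat_dose = elective_gy)
    targets[[length(targets) + 1]] <- list(points = ep, weight = 20)
  } else {
    dummy_pet <- case$phases[[phase]]$ct  # geometry source only (flat doses)
    hp <- seed_prescription_points(dummy_pet, ptv_hr, n_points, prescription,
                                   seed = seed, flat_dose = phase3_gy)
    targets[[length(targets) + 1]] <- list(points = hp, weight = 100)
  }
  optimization_objectives(targets, default_oar_objectives(st))
}

#' Plan and optimize one treatment phase
#'
#' Builds the technique's beams (two-arc IMAT class solution or six-beam
#' step-and-shoot comparator) with anatomy/intensity-based initial
#' apertures avoiding the parotids, the swallowing structures and the
#' spinal-cord PRV, then optimizes MU and leaf positions against the phase
#' objectives.
#'
#' @param case a `phantom_case`.
#' @param phase phase number (1-3).
#' @param technique `"imat"` or `"simrt"`.
#' @param machine a [machine_model].
#' @param engine a [dose_engine_config].
#' @param options a [plan_options]; its seed is combined with the case seed
#'   and phase.
#' @param n_points painted-target prescription points for optimization.
#' @param n_bands intensity bands for the initial segments.
#' @return list with `result` (a `plan_result`), `objectives`, `window`,
#'   `technique`, `phase`.
#' @export
plan_phase <- function(case, phase, technique = c("imat", "simrt"),
                       machine = machine_model(),
                       engine = dose_engine_config(),
                       options = plan_options(), n_points = 1500,
                       n_bands = 3) {
  technique <- match.arg(technique)
  st <- case$phases[[phase]]$structures
  pet <- case$phases[[phase]]$pet
  body <- get_structure(st, "body")
  gtv <- get_structure(st, "GTV_T")
  avoid <- Filter(Negate(is.null),
                  lapply(c("parotid_ipsi", "parotid_contra", "swallowing",
                           "PRV_spinal_cord"),
                         function(n) get_structure(st, n)))
  window <- if (!is.null(pet)) compute_intensity_window(pet, gtv) else NULL
  seed <- case$seed * 100L + phase
  if (technique == "imat") {
    beams <- generate_class_solution(class_solution_config(), machine,
                                     structures = st, avoid = avoid,
                                     pet = pet, window = window,
                                     n_bands = n_bands)
  } else {
    beams <- build_simrt_plan(machine, structures = st, avoid = avoid,
                              pet = pet, window = window,
                              n_segments = max(n_bands, 3))
  }
  objectives <- phase_objectives(case, phase, n_points = n_points, seed = seed)
  options$seed <- seed
  result <- optimize_plan(beams, objectives, body, machine, engine, options)
  list(result = result, objectives = objectives, window = window,
       technique = technique, phase = phase)
}

#' Plan, accumulate and evaluate a full three-phase treatment
#'
#' Runs the complete study pipeline on a synthetic case: optimize a plan
#' per phase, compute each phase's per-fraction 3D dose, apply delivery
#' post-processing to the arcs (low-MU pruning, refinement, linking), warp
#' phases II and III onto the reference grid through the case's deformation
#' fields, sum at the per-phase fraction counts, and evaluate the
#' dose-painting quality factor (on freshly seeded points) and the standard
#' dose metrics on the summed dose.
#'
#' @param case a `phantom_case`.
#' @param technique `"imat"` or `"simrt"`.
#' @param fractions_per_phase fractions delivered per phase (default 10
#'   each, 30 in total).
#' @param n_qf_points points for the quality-factor evaluation.
#' @param machine,engine,options as in [plan_phase()].
#' @param n_points optimization points per painted target.
#' @return list with `phase_plans`, `phase_doses` (per-fraction),
#'   `summed` (a `summed_dose`, total course on the reference grid),
#'   `qf` (per painted phase `qf_result`s), `metrics` (summed-dose metric
#'   table), `delivery` (post-processed arcs and time estimates).
#' @export
run_treatment_course <- function(case, technique = c("imat", "simrt"),
                                 fractions_per_phase = c(10, 10, 10),
                                 n_qf_points = 5000,
                                 machine = machine_model(),
                                 engine = dose_engine_config(),
                                 options = plan_options(), n_points = 1500) {
  technique <- match.arg(technique)
  grid <- case$phases[[1]]$ct$grid
  phase_plans <- list()
  phase_doses <- list()
  for (ph in 1:3) {
    pp <- plan_phase(case, ph, technique, machine, engine, options,
                     n_points = n_points)
    body <- case_structure(case, "body", ph)
    dose <- deposit_dose(pp$result$beams, grid, body, machine, engine)
    phase_plans[[ph]] <- pp
    phase_doses[[ph]] <- dose
  }
  warped <- list(phase_doses[[1]],
                 warp_dose(phase_doses[[2]], case$dvf_to_reference[[1]]),
                 warp_dose(phase_doses[[3]], case$dvf_to_reference[[2]]))
  summed <- sum_phase_doses(warped, fractions_per_phase)

  qf <- list()
  for (ph in 1:2) {
    pet <- case$phases[[ph]]$pet
    gtv <- case_structure(case, "GTV_T", ph)
    pts <- seed_prescription_points(pet, gtv, n_qf_points,
                                    dose_prescription(),
                                    seed = case$seed * 100L + 50L + ph)
    qf[[ph]] <- quality_factor(phase_doses[[ph]], pts)
  }

  delivery <- lapply(phase_plans, function(pp) {
    beams <- pp$result$beams
    if (pp$technique == "imat") {
      subarcs <- prune_low_mu(beams, threshold = 2)
      if (length(subarcs)) {
        subarcs <- lapply(subarcs, refine_control_points, machine = machine)
        linked <- link_subarcs(subarcs, machine)
        list(beam = linked$beam, time_s = linked$time_s,
             n_subarcs = length(subarcs))
      } else list(beam = NULL, time_s = 0, n_subarcs = 0)
    } else {
      list(beam = beams,
           time_s = estimate_delivery_time(beams, machine),
           n_subarcs = NA_integer_)
    }
  })

  st <- case$phases[[1]]$structures
  report_names <- c("GTV_T", "CTV_HR", "PTV_HR", "PTV_EN", "PRV_spinal_cord",
                    "PRV_brainstem", "parotid_ipsi", "parotid_contra",
                    "swallowing", "mandible", "body")
  report_structs <- Filter(Negate(is.null),
                           lapply(report_names, function(n) get_structure(st, n)))
  metrics <- dose_metric_table(summed$dose, report_structs)

  list(phase_plans = phase_plans, phase_doses = phase_doses, summed = summed,
       qf = qf, metrics = metrics, delivery = delivery,
       technique = technique)
}
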