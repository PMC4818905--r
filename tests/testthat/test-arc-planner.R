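machine <- machine_model()

test_that("the default class solution has two arcs with 45 and 37 control points", {
  beams <- generate_class_solution(class_solution_config(), machine)
  expect_length(beams, 2)
  g_en <- sapply(beams[[1]]$control_points, function(cp) cp$gantry)
  g_hr <- sapply(beams[[2]]$control_points, function(cp) cp$gantry)
  expect_length(g_en, 45)     # -176 to 176 every 8 degrees
  expect_length(g_hr, 37)     # 144 to -144 every 8 degrees
  expect_equal(g_en[1], -176)
  expect_equal(g_en[45], 176)
  expect_equal(g_hr[1], 144)
  expect_equal(g_hr[37], -144)
  expect_true(all(diff(g_en) == 8))
  expect_true(all(diff(g_hr) == -8))   # descending through 0
})

test_that("arc spans must be divisible by the control-point spacing", {
  cfg <- class_solution_config(
    arcs = list(list(target = "PTV_HR", start = 0, stop = 16, direction = 1)),
    cp_spacing = 8)
  b <- generate_class_solution(cfg, machine)
  expect_equal(sapply(b[[1]]$control_points, function(cp) cp$gantry), c(0, 8, 16))
  bad <- class_solution_config(
    arcs = list(list(target = "PTV_HR", start = -176, stop = 176, direction = 1)),
    cp_spacing = 7)
  expect_error(generate_class_solution(bad, machine), "divisible")
})

test_that("the six-beam comparator uses the stated non-opposing coplanar angles", {
  beams <- build_simrt_plan(machine)
  ang <- sort(sapply(beams, function(b) b$control_points[[1]]$gantry) %% 360)
  expect_equal(ang, c(45, 75, 165, 195, 285, 315))
  # non-opposing: no pair 180 degrees apart
  for (a in ang) expect_false(any(abs((ang - a) %% 360 - 180) < 1e-9))
  # coplanar static beams: each beam has one gantry angle
  for (b in beams) {
    expect_equal(b$delivery_mode, "static")
    expect_length(unique(sapply(b$control_points, function(cp) cp$gantry)), 1)
  }
})

test_that("anatomy-based apertures conform to the brute-force BEV row rasterization", {
  case <- small_case()
  gtv <- case_structure(case, "GTV_T")   # off-axis target
  for (gantry in c(0, 52, -110)) {
    cp <- abst_aperture(gtv, list(), gantry, machine = machine, margin_mm = 0)
    # brute force: project every target voxel center, bin by leaf row
    pts <- dosepaint:::mask_points(gtv)
    bev <- dosepaint:::project_bev(pts, gantry, machine)
    edges <- dosepaint:::leaf_row_edges(machine)
    rows <- findInterval(bev$v, edges, rightmost.closed = TRUE)
    for (r in unique(rows)) {
      want <- range(bev$u[rows == r])
      expect_lte(cp$leaves[r, 1], want[1] + 1e-9)
      expect_gte(cp$leaves[r, 2], want[2] - 1e-9)
      # without margin and without gap-widening need, leaves touch the
      # projection bounds
      if (diff(want) >= machine$min_opposing_gap) {
        expect_equal(cp$leaves[r, ], want, ignore_attr = TRUE, tolerance = 1e-9)
      }
    }
  }
})

test_that("avoidance that swallows the target leaves a flagged minimal aperture", {
  case <- small_case()
  gtv <- case_structure(case, "GTV_T")
  blocker <- expand_margin(gtv, 12, name = "blocker")
  cp <- abst_aperture(gtv, list(blocker), gantry = 0, machine = machine,
                      margin_mm = 0)
  expect_true(attr(cp, "flagged_empty"))
  expect_silent(validate_control_point(cp, machine))
})

test_that("intensity bands are nested and collapse to the anatomy aperture for uniform PET", {
  case <- small_case()
  gtv <- case_structure(case, "GTV_T")
  pet <- case$phases[[1]]$pet
  w <- compute_intensity_window(pet, gtv)
  bands <- bbst_aperture(pet, w, gtv, list(), gantry = 40, machine = machine,
                         n_bands = 3)
  expect_length(bands, 3)
  for (k in 2:3) {
    # higher band opening lies within the lower band opening, row by row
    hi <- bands[[k]]$leaves
    lo <- bands[[k - 1]]$leaves
    open_hi <- which(hi[, 2] - hi[, 1] > machine$min_opposing_gap + 1e-6)
    jy <- bands[[k]]$jaws[3:4]
    edges <- dosepaint:::leaf_row_edges(machine)
    in_jaw <- which(edges[-length(edges)] < jy[2] & edges[-1] > jy[1])
    for (r in intersect(open_hi, in_jaw)) {
      expect_gte(hi[r, 1], lo[r, 1] - 1e-9)
      expect_lte(hi[r, 2], lo[r, 2] + 1e-9)
    }
  }
  upet <- scalar_volume(array(50, pet$grid$dims), pet$grid, kind = "pet")
  ub <- bbst_aperture(upet, intensity_window(10, 47.5), gtv, list(), gantry = 40,
                      machine = machine, n_bands = 2)
  ab <- abst_aperture(gtv, list(), gantry = 40, machine = machine)
  expect_equal(ub[[1]]$leaves, ab$leaves, ignore_attr = TRUE)
  # uniform intensity at the window top: every band keeps the full aperture
  expect_equal(ub[[2]]$leaves, ab$leaves, ignore_attr = TRUE)
})

test_that("band membership matches brute-force per-row intensity thresholding", {
  case <- small_case()
  gtv <- case_structure(case, "GTV_T")
  pet <- case$phases[[1]]$pet
  w <- compute_intensity_window(pet, gtv)
  n_bands <- 3
  bands <- bbst_aperture(pet, w, gtv, list(), gantry = 72, machine = machine,
                         n_bands = n_bands, margin_mm = 0)
  pts <- dosepaint:::mask_points(gtv)
  intens <- interp_trilinear(pet$values, pet$grid, pts, outside = "nearest")
  bev <- dosepaint:::project_bev(pts, 72, machine)
  edges <- dosepaint:::leaf_row_edges(machine)
  thr <- w$I_low + 1 / n_bands * (w$I_high - w$I_low)   # band-2 threshold
  keep <- intens >= thr
  rows <- findInterval(bev$v[keep], edges, rightmost.closed = TRUE)
  for (r in unique(rows)) {
    want <- range(bev$u[keep][rows == r])
    expect_lte(bands[[2]]$leaves[r, 1], want[1] + 1e-9)
    expect_gte(bands[[2]]$leaves[r, 2], want[2] - 1e-9)
  }
})

test_that("every generated control point satisfies machine constraints", {
  case <- small_case()
  st <- case$phases[[1]]$structures
  avoid <- list(case_structure(case, "PRV_spinal_cord"),
                case_structure(case, "parotid_ipsi"))
  pet <- case$phases[[1]]$pet
  w <- compute_intensity_window(pet, case_structure(case, "GTV_T"))
  beams <- generate_class_solution(class_solution_config(), machine,
                                   structures = st, avoid = avoid,
                                   pet = pet, window = w)
  for (b in beams) {
    for (cp in b$control_points) {
      expect_silent(validate_control_point(cp, machine))
    }
  }
  sb <- build_simrt_plan(machine, structures = st, avoid = avoid,
                         pet = pet, window = w)
  for (b in sb) {
    for (cp in b$control_points) expect_silent(validate_control_point(cp, machine))
  }
})
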