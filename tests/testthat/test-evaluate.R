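mk_dose <- function(vals, grid) scalar_volume(vals, grid, kind = "dose")

test_that("cumulative DVHs match brute-force threshold counting", {
  g <- image_grid(c(10, 10, 10), spacing = c(3, 3, 3))
  withr::with_seed(6, d <- array(runif(1000, 0, 70), g$dims))
  dose <- mk_dose(d, g)
  s <- structure_mask("s", array(runif(1000) > 0.4, g$dims), g)
  cv <- cumulative_dvh(dose, s, bin_width_gy = 0.5)
  inside <- d[s$mask]
  for (b in cv$dose_bins) {
    expect_equal(cv$cum_volume_fraction[which(cv$dose_bins == b)],
                 mean(inside >= b))
  }
  expect_equal(cv$cum_volume_fraction[1], 1)
  expect_true(all(diff(cv$cum_volume_fraction) <= 0))
  expect_equal(tail(cv$cum_volume_fraction, 1), 0)
  expect_error(cumulative_dvh(dose, structure_mask("e", array(FALSE, g$dims), g)),
               "empty")
})

test_that("DVH point metrics behave on uniform, two-voxel and ramp doses", {
  g <- image_grid(c(6, 6, 6), spacing = c(3, 3, 3))
  s <- structure_mask("s", array(TRUE, g$dims), g)
  u60 <- cumulative_dvh(mk_dose(array(60, g$dims), g), s)
  expect_equal(dose_at_volume(u60, 2), 60)
  expect_equal(dose_at_volume(u60, 98), 60)
  expect_equal(volume_at_dose(u60, 27), 100)
  u20 <- cumulative_dvh(mk_dose(array(20, g$dims), g), s)
  expect_equal(volume_at_dose(u20, 27), 0)

  g2 <- image_grid(c(2, 1, 1), spacing = c(3, 3, 3))
  s2 <- structure_mask("s", array(TRUE, g2$dims), g2)
  two <- cumulative_dvh(mk_dose(array(c(10, 20), g2$dims), g2), s2)
  expect_equal(two$cum_volume_fraction[two$dose_bins == 15], 0.5)

  # linear ramp 0..100 over the structure: D50 is 50 within a bin width
  g3 <- image_grid(c(101, 1, 1), spacing = c(1, 3, 3))
  s3 <- structure_mask("s", array(TRUE, g3$dims), g3)
  ramp <- cumulative_dvh(mk_dose(array(seq(0, 100, 1), g3$dims), g3), s3)
  expect_equal(dose_at_volume(ramp, 50), 50, tolerance = 1)
  d2 <- dose_at_volume(ramp, 2); d50 <- dose_at_volume(ramp, 50)
  d98 <- dose_at_volume(ramp, 98)
  expect_true(d2 >= d50 && d50 >= d98)
  # V at D_x is x% within a bin
  expect_equal(volume_at_dose(ramp, dose_at_volume(ramp, 30)), 30, tolerance = 1.1)
})

test_that("the quality factor is the mean relative deviation and is zero iff conformal", {
  g <- image_grid(c(12, 12, 12), spacing = c(4, 4, 4))
  interior <- array(FALSE, g$dims); interior[3:10, 3:10, 3:10] <- TRUE
  tgt <- structure_mask("GTV_T", interior, g)
  pet <- scalar_volume(array(1, g$dims), g, kind = "pet")
  ps <- seed_prescription_points(pet, tgt, 100, seed = 8, flat_dose = 2.5)
  perfect <- mk_dose(array(2.5, g$dims), g)
  expect_equal(quality_factor(perfect, ps)$qf_percent, 0)
  off5 <- mk_dose(array(2.5 * 1.05, g$dims), g)
  expect_equal(quality_factor(off5, ps)$qf_percent, 5, tolerance = 1e-9)
  # random planned field equals the brute-force per-point loop
  withr::with_seed(9, pl <- mk_dose(array(runif(prod(g$dims), 1, 4), g$dims), g))
  qf <- quality_factor(pl, ps)
  pts <- as.matrix(ps$points[, 1:3])
  brute <- 0
  for (i in seq_len(nrow(pts))) {
    di <- interp_trilinear(pl$values, g, pts[i, , drop = FALSE])
    brute <- brute + abs(as.numeric(di) - 2.5) / 2.5 * 100
  }
  expect_equal(qf$qf_percent, brute / nrow(pts), tolerance = 1e-12)
  # scale invariance: common factor on planned and prescribed cancels
  ps30 <- ps; ps30$points$dose_Gy <- ps$points$dose_Gy * 30
  pl30 <- mk_dose(pl$values * 30, g)
  expect_equal(quality_factor(pl30, ps30)$qf_percent, qf$qf_percent,
               tolerance = 1e-9)
  # 30-fraction scaling built in
  expect_equal(quality_factor(pl30, ps, fraction_scaling = 30)$qf_percent,
               qf$qf_percent, tolerance = 1e-9)
})

test_that("integral dose follows Dmean x V x rho and is additive", {
  g <- image_grid(c(10, 10, 10), spacing = c(10, 10, 10))  # 1 cm^3 voxels
  body <- structure_mask("body", array(TRUE, g$dims), g)   # 1000 cm^3
  expect_equal(integral_dose(mk_dose(array(1, g$dims), g), body), 1)  # 1 Gy x 1 kg
  expect_equal(integral_dose(mk_dose(array(0, g$dims), g), body), 0)
  withr::with_seed(10, d <- array(runif(1000, 0, 2), g$dims))
  id <- integral_dose(mk_dose(d, g), body, density_g_cm3 = 1.05)
  vox_mass_kg <- voxel_volume_cm3(g) * 1.05 / 1000
  expect_equal(id, sum(d * vox_mass_kg), tolerance = 1e-12)
  # additive over a disjoint partition of the body
  half1 <- structure_mask("a", array(c(TRUE, FALSE), g$dims), g)
  half2 <- structure_mask("b", !half1$mask, g)
  ia <- mean(d[half1$mask]) * mask_volume_cm3(half1) * 1e-3
  ib <- mean(d[half2$mask]) * mask_volume_cm3(half2) * 1e-3
  expect_equal(integral_dose(mk_dose(d, g), body), ia + ib, tolerance = 1e-12)
})

test_that("the detector geometry has 1069 diodes at the stated spacings", {
  geom <- detector_geometry()
  expect_equal(nrow(geom$positions), 1069)
  # diodes lie on two orthogonal planes through the axis
  on_p1 <- geom$positions[, 2] == 0
  on_p2 <- geom$positions[, 1] == 0
  expect_true(all(on_p1 | on_p2))
  # central-region spacing is 5 mm: successive transverse coordinates there
  p1 <- geom$positions[on_p1, ]
  ctr <- sort(unique(p1[abs(p1[, 1]) <= 30 & abs(p1[, 3]) <= 30, 1]))
  expect_equal(unique(diff(ctr)), 5)
  out <- sort(unique(p1[p1[, 1] > 35, 1]))
  if (length(out) > 1) expect_true(all(diff(out) == 10))
})

test_that("detector sampling is trilinear and rejects out-of-domain diodes", {
  g <- image_grid(c(60, 60, 60), spacing = c(4, 4, 4))
  ax <- grid_axes(g)
  ramp <- outer(outer(40 + 0.1 * ax$x, 0 * ax$y, `+`), 0.05 * ax$z, `+`)
  dose <- mk_dose(ramp, g)
  geom <- detector_geometry()
  s <- sample_detector(dose, geom)
  expect_equal(nrow(s), 1069)
  expect_equal(s$dose_gy, 40 + 0.1 * s$x_mm + 0.05 * s$z_mm, tolerance = 1e-9)
  uni <- mk_dose(array(3, g$dims), g)
  expect_true(all(sample_detector(uni, geom)$dose_gy == 3))
  small <- mk_dose(array(1, c(10, 10, 10)), image_grid(c(10, 10, 10)))
  expect_error(sample_detector(small, geom), "outside")
})

test_that("gamma analysis reproduces the analytic uniform-shift cases", {
  g <- image_grid(c(30, 30, 30), spacing = c(4, 4, 4))
  base <- array(2, g$dims)
  crit <- gamma_criteria(3, 3, normalization_dose_gy = 2, low_dose_cutoff_pct = 20)
  ref <- data.frame(x_mm = runif(50, -20, 20), y_mm = runif(50, -20, 20),
                    z_mm = runif(50, -20, 20), dose_gy = 2)
  # identical fields: gamma 0, 100% pass
  r0 <- gamma_index(ref, mk_dose(base, g), crit)
  expect_lt(max(r0$gamma), 1e-9)
  expect_equal(r0$pass_fraction_percent, 100)
  # uniform +3% of normalization: gamma exactly 1 everywhere, still passing
  r3 <- gamma_index(ref, mk_dose(base * 1.03, g), crit)
  expect_equal(unname(r3$gamma), rep(1, 50), tolerance = 1e-9)
  expect_equal(r3$pass_fraction_percent, 100)
  # uniform +4%: no spatial compensation possible, gamma 4/3, 0% pass
  r4 <- gamma_index(ref, mk_dose(base * 1.04, g), crit)
  expect_equal(unname(r4$gamma), rep(4 / 3, 50), tolerance = 1e-9)
  expect_equal(r4$pass_fraction_percent, 0)
})

test_that("a 2 mm ramp shift gives gamma at most 2/3 plus interpolation tolerance", {
  g <- image_grid(c(40, 15, 15), spacing = c(2, 4, 4))
  ax <- grid_axes(g)
  slope <- 0.02  # Gy/mm; dose ~2 Gy at center
  f <- function(x) 2 + slope * x
  ref_dose <- f(seq(-20, 20, by = 2))
  ref <- data.frame(x_mm = seq(-20, 20, by = 2), y_mm = 0, z_mm = 0,
                    dose_gy = ref_dose)
  shifted <- array(rep(f(ax$x - 2), times = 15 * 15), g$dims)
  crit <- gamma_criteria(3, 3, normalization_dose_gy = 2,
                         low_dose_cutoff_pct = 10)
  r <- gamma_index(ref, mk_dose(shifted, g), crit, step_mm = 0.5)
  expect_true(all(r$gamma <= 2 / 3 + 0.05))
})

test_that("gamma equals an exhaustive candidate search and is monotone in its knobs", {
  case <- small_case()
  body <- case_structure(case, "body")
  d <- deposit_dose(beam(list(open_cp(40, mu = 300)), "static"),
                    body$grid, body, machine_model(), dose_engine_config())
  withr::with_seed(12, {
    idx <- sample(which(body$mask & d$values > 0.5), 60)
  })
  pts <- index_to_world(body$grid, arrayInd(idx, body$grid$dims))
  # perturbed evaluated dose
  pert <- mk_dose(d$values * 1.02, body$grid)
  ref <- data.frame(x_mm = pts[, 1], y_mm = pts[, 2], z_mm = pts[, 3],
                    dose_gy = d$values[idx])
  crit <- gamma_criteria(3, 3, normalization_dose_gy = max(d$values),
                         low_dose_cutoff_pct = 10)
  r <- gamma_index(ref, pert, crit, step_mm = 1)
  # exhaustive oracle over the full cubic candidate set at the same step
  dta <- 3; dd <- 0.03 * max(d$values)
  offs <- as.matrix(expand.grid(x = seq(-9, 9, 1), y = seq(-9, 9, 1),
                                z = seq(-9, 9, 1)))
  offs <- offs[sqrt(rowSums(offs^2)) <= 9 + 1e-9, ]
  g_brute <- sapply(seq_len(nrow(pts)), function(i) {
    cand <- sweep(offs, 2, -pts[i, ])
    dv <- interp_trilinear(pert$values, pert$grid, cand, outside = "nearest")
    sqrt(min(rowSums(offs^2) / dta^2 + ((dv - ref$dose_gy[i]) / dd)^2))
  })
  expect_equal(unname(r$gamma), g_brute, tolerance = 1e-9)
  # loosening either tolerance never lowers the pass fraction
  r_loose_d <- gamma_index(ref, pert, gamma_criteria(5, 3, max(d$values), 10),
                           step_mm = 1)
  r_loose_x <- gamma_index(ref, pert, gamma_criteria(3, 5, max(d$values), 10),
                           step_mm = 1)
  expect_gte(r_loose_d$pass_fraction_percent, r$pass_fraction_percent)
  expect_gte(r_loose_x$pass_fraction_percent, r$pass_fraction_percent)
  # a denser candidate grid never increases gamma
  r_fine <- gamma_index(ref, pert, crit, step_mm = 0.5)
  expect_true(all(r_fine$gamma <= r$gamma + 1e-9))
})
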