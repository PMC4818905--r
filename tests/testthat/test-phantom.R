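test_that("phantom generation is bit-for-bit reproducible by seed", {
  a <- generate_phantom(small_config(), seed = 7)
  b <- generate_phantom(small_config(), seed = 7)
  expect_identical(a$phases[[1]]$pet$values, b$phases[[1]]$pet$values)
  expect_identical(a$phases[[2]]$ct$values, b$phases[[2]]$ct$values)
  expect_identical(lapply(a$phases[[3]]$structures, function(s) s$mask),
                   lapply(b$phases[[3]]$structures, function(s) s$mask))
  c2 <- generate_phantom(small_config(), seed = 8)
  expect_false(identical(a$phases[[1]]$pet$values, c2$phases[[1]]$pet$values))
})

test_that("phantom cases honor the three-phase imaging protocol and nesting rules", {
  case <- small_case()
  expect_length(case$phases, 3)
  expect_false(is.null(case$phases[[1]]$pet))
  expect_false(is.null(case$phases[[2]]$pet))
  expect_null(case$phases[[3]]$pet)       # no re-imaging before the last phase
  expect_length(case$dvf_to_reference, 2)
  for (ph in 1:3) {
    gtv <- case_structure(case, "GTV_T", ph)
    ctv <- case_structure(case, "CTV_HR", ph)
    ptv <- case_structure(case, "PTV_HR", ph)
    body <- case_structure(case, "body", ph)
    expect_gt(sum(gtv$mask), 0)
    expect_true(all(body$mask[gtv$mask]))         # tumor inside body
    expect_true(all(ctv$mask[gtv$mask]))          # GTV in CTV
    expect_true(all(ptv$mask[ctv$mask]))          # CTV in PTV
    en <- case_structure(case, "PTV_EN", ph)
    expect_true(all(en$mask[ctv$mask]))
  }
})

test_that("node count is honored and nodes can be disabled", {
  case0 <- generate_phantom(small_config(node_count = 0), seed = 3)
  nm <- vapply(case0$phases[[1]]$structures, function(s) s$name, character(1))
  expect_false(any(grepl("^GTV_N", nm)))
  case2 <- generate_phantom(small_config(node_count = 2), seed = 3)
  nm2 <- vapply(case2$phases[[1]]$structures, function(s) s$name, character(1))
  expect_setequal(intersect(nm2, c("GTV_N1", "GTV_N2")), c("GTV_N1", "GTV_N2"))
})

test_that("margin expansion matches an exhaustive Euclidean distance check", {
  g <- image_grid(c(15, 15, 15), spacing = c(1, 1, 1))
  seedmask <- array(FALSE, g$dims)
  seedmask[8, 8, 8] <- TRUE
  m <- structure_mask("seed", seedmask, g)
  out <- expand_margin(m, 3)
  # brute force: every voxel center within 3 mm of the seed voxel center
  pts <- grid_points(g)
  ctr <- index_to_world(g, cbind(8, 8, 8))
  want <- sqrt(rowSums(sweep(pts, 2, as.numeric(ctr))^2)) <= 3 + 1e-9
  expect_identical(as.logical(out$mask), as.logical(want))
})

test_that("margin expansion is an identity at zero, monotone, and honors exclusions", {
  case <- small_case()
  gtv <- case_structure(case, "GTV_T")
  expect_identical(expand_margin(gtv, 0)$mask, gtv$mask)
  e3 <- expand_margin(gtv, 3)
  e6 <- expand_margin(gtv, 6)
  expect_true(all(e3$mask[gtv$mask]))      # superset of input
  expect_true(all(e6$mask[e3$mask]))       # monotone in margin
  excl <- case_structure(case, "air")
  ex <- expand_margin(gtv, 6, exclusion = excl)
  expect_false(any(ex$mask & excl$mask))
  # still a superset of the input minus the exclusion
  expect_true(all(ex$mask[gtv$mask & !excl$mask]))
})

test_that("SUV thresholding matches a brute-force per-voxel scan and is monotone", {
  case <- small_case()
  pet <- case$phases[[1]]$pet
  gtv <- case_structure(case, "GTV_T")
  seg <- segment_suv_threshold(pet, gtv, 0.5)
  # brute force: interpolate PET at every ROI voxel center and threshold
  idx <- which(gtv$mask)
  pts <- index_to_world(gtv$grid, arrayInd(idx, gtv$grid$dims))
  vals <- interp_trilinear(pet$values, pet$grid, pts, outside = "nearest")
  want <- array(FALSE, gtv$grid$dims)
  want[idx[vals >= 0.5 * max(vals)]] <- TRUE
  expect_identical(seg$mask, want)
  # raising the fraction never enlarges the mask
  seg7 <- segment_suv_threshold(pet, gtv, 0.7)
  expect_true(all(seg$mask[seg7$mask]))
  expect_lte(sum(seg7$mask), sum(seg$mask))
})

test_that("SUV thresholding handles uniform and two-level fields as stated", {
  g <- image_grid(c(8, 8, 8), spacing = c(4, 4, 4))
  roi <- structure_mask("roi", array(TRUE, g$dims), g)
  uni <- scalar_volume(array(10, g$dims), g, kind = "pet")
  expect_equal(sum(segment_suv_threshold(uni, roi, 0.5)$mask), sum(roi$mask))
  two <- array(40, g$dims)
  core <- array(FALSE, g$dims); core[3:6, 3:6, 3:6] <- TRUE
  two[core] <- 100
  seg <- segment_suv_threshold(scalar_volume(two, g, kind = "pet"), roi, 0.5)
  expect_identical(seg$mask, core)
  expect_error(segment_suv_threshold(uni, structure_mask("e", array(FALSE, g$dims), g)),
               "empty")
  zero <- scalar_volume(array(0, g$dims), g, kind = "pet")
  expect_error(segment_suv_threshold(zero, roi, 0.5), "positive")
})

test_that("synthetic deformation fields honor amplitude, translation and identity", {
  g <- image_grid(c(10, 10, 10), spacing = c(4, 4, 4))
  id <- make_synthetic_dvf(g, amplitude_mm = 0, seed = 1)
  expect_true(all(id$displacement == 0))
  tr <- make_synthetic_dvf(g, amplitude_mm = 0, seed = 1, translation = c(3, -2, 1))
  expect_equal(unique(as.numeric(tr$displacement[, , , 1])), 3)
  expect_equal(unique(as.numeric(tr$displacement[, , , 3])), 1)
  rnd <- make_synthetic_dvf(g, amplitude_mm = 5, smoothness_mm = 12, seed = 2)
  mag <- sqrt(rnd$displacement[, , , 1]^2 + rnd$displacement[, , , 2]^2 +
                rnd$displacement[, , , 3]^2)
  expect_lte(max(mag), 5 + 1e-9)
  rnd2 <- make_synthetic_dvf(g, amplitude_mm = 5, smoothness_mm = 12, seed = 2)
  expect_identical(rnd$displacement, rnd2$displacement)
})

test_that("phantom cases serialize to a NIfTI + JSON case directory", {
  case <- small_case()
  dir <- tempfile("case")
  mf <- write_phantom_case(case, dir)
  expect_true(file.exists(file.path(dir, "case.json")))
  manifest <- jsonlite::read_json(file.path(dir, "case.json"))
  expect_length(manifest$phases, 3)
  pet <- read_volume(file.path(dir, "phase1/pet.nii.gz"), kind = "pet")
  expect_equal(as.numeric(pet$values), as.numeric(case$phases[[1]]$pet$values),
               tolerance = 1e-5)
  gtv <- read_mask(file.path(dir, "phase1/GTV_T.nii.gz"), "GTV_T")
  expect_identical(gtv$mask, case_structure(case, "GTV_T")$mask)
  unlink(dir, recursive = TRUE)
})
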