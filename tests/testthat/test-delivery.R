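machine <- machine_model()

mu_seq <- function(b) sapply(b$control_points, function(cp) cp$mu)

make_arc <- function(mus, start_gantry = 0) {
  cps <- lapply(seq_along(mus), function(i) {
    open_cp(50, gantry = normalize_angle(start_gantry + 8 * (i - 1)),
            mu = mus[i])
  })
  beam(cps, "arc", name = "arc")
}

test_that("low-MU pruning splits arcs exactly at the stated rule", {
  b <- make_arc(c(5, 1, 4, 0, 6))
  subs <- prune_low_mu(b, threshold = 2)
  expect_length(subs, 3)
  expect_equal(lapply(subs, mu_seq), list(5, 4, 6))
  expect_equal(sum(sapply(subs, total_mu)), total_mu(b) - 1 - 0)
  b2 <- make_arc(c(5, 3, 4))
  subs2 <- prune_low_mu(b2)
  expect_length(subs2, 1)
  expect_equal(mu_seq(subs2[[1]]), c(5, 3, 4))
})

test_that("pruning matches a brute-force contiguous-run scan on random MU sequences", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      mus <- round(runif(12, 0, 6), 2)
      b <- make_arc(mus)
      subs <- prune_low_mu(b, threshold = 2)
      # brute force: scan runs of indices with mu >= 2
      keep <- mus >= 2
      runs <- list(); cur <- c()
      for (i in seq_along(keep)) {
        if (keep[i]) cur <- c(cur, i)
        else { if (length(cur)) runs[[length(runs) + 1]] <- cur; cur <- c() }
      }
      if (length(cur)) runs[[length(runs) + 1]] <- cur
      expect_length(subs, length(runs))
      for (k in seq_along(runs)) {
        expect_equal(mu_seq(subs[[k]]), mus[runs[[k]]])   # order preserved
      }
    }
  })
})

test_that("refinement leaves compliant beams unchanged and subdivides violating segments", {
  lim <- refinement_limits(mu = 4, gantry = 2, collimator = 2, leaf = 5, jaw = 5)
  ok <- beam(list(open_cp(50, gantry = 0, mu = 3),
                  open_cp(50, gantry = 1.5, mu = 3)), "arc")
  expect_equal(mu_seq(refine_control_points(ok, lim)), c(3, 3))
  two <- beam(list(open_cp(50, gantry = 0, mu = 1),
                   open_cp(50, gantry = 8, mu = 2)), "arc")
  ref <- refine_control_points(two, lim)
  g <- sapply(ref$control_points, function(cp) cp$gantry)
  expect_equal(g, c(0, 2, 4, 6, 8))       # three inserted CPs at 2-degree steps
  expect_equal(total_mu(ref), total_mu(two), tolerance = 1e-12)
})

test_that("refined beams satisfy every limit under an exhaustive delta audit", {
  lim <- refinement_limits()
  withr::with_seed(17, {
    for (rep in 1:5) {
      b <- random_beam(8, seed = rep * 7)
      ref <- refine_control_points(b, lim)
      expect_equal(total_mu(ref), total_mu(b), tolerance = 1e-9)
      cps <- ref$control_points
      for (i in seq_along(cps)) {
        if (i > 1) {
          # the opening control point terminates no segment and is exempt
          expect_lte(cps[[i]]$mu, lim$mu + 1e-9)
          dl <- dosepaint:::cp_deltas(cps[[i - 1]], cps[[i]])
          expect_lte(dl[["gantry"]], lim$gantry + 1e-9)
          expect_lte(dl[["collimator"]], lim$collimator + 1e-9)
          expect_lte(dl[["leaf"]], lim$leaf + 1e-9)
          expect_lte(dl[["jaw"]], lim$jaw + 1e-9)
        }
      }
    }
  })
})

test_that("refining a static beam preserves per-aperture MU and therefore its dose", {
  b <- random_beam(4, seed = 3, static = TRUE)
  ref <- refine_control_points(b)
  expect_equal(total_mu(ref), total_mu(b), tolerance = 1e-12)
  # group MU by aperture signature: sums are unchanged
  sig <- function(cp) paste(signif(cp$leaves, 10), collapse = ",")
  mu_by_aperture <- function(bb) {
    tapply(sapply(bb$control_points, function(cp) cp$mu),
           sapply(bb$control_points, sig), sum)
  }
  a <- mu_by_aperture(b); r <- mu_by_aperture(ref)
  expect_equal(r[names(a)], a, tolerance = 1e-12)
})

test_that("delivery time follows the limiting-ratio model", {
  single <- beam(list(open_cp(50, gantry = 0, mu = 100)), "static")
  expect_equal(estimate_delivery_time(single, machine),
               100 / machine$dose_rate_range[2])   # 10 s at 10 MU/s
  two <- beam(list(open_cp(50, gantry = 0, mu = 0.1),
                   open_cp(50, gantry = 8, mu = 0.1)), "arc")
  expect_equal(estimate_delivery_time(two, machine),
               0.1 / 10 + 8 / machine$max_gantry_speed)
  # random beams vs brute-force per-segment max-of-ratios sum
  withr::with_seed(23, {
    for (rep in 1:5) {
      b <- random_beam(6, seed = rep)
      cps <- b$control_points
      t_brute <- cps[[1]]$mu / machine$dose_rate_range[2]
      for (i in 2:length(cps)) {
        t_brute <- t_brute +
          max(cps[[i]]$mu / machine$dose_rate_range[2],
              abs(normalize_angle(cps[[i]]$gantry - cps[[i - 1]]$gantry)) /
                machine$max_gantry_speed,
              max(abs(cps[[i]]$leaves - cps[[i - 1]]$leaves)) /
                machine$max_leaf_speed,
              abs(cps[[i]]$collimator - cps[[i - 1]]$collimator) /
                machine$max_collimator_speed)
      }
      expect_equal(estimate_delivery_time(b, machine), t_brute)
    }
  })
})

test_that("sub-arc linking matches exhaustive signed-permutation search for 3 sub-arcs", {
  subarcs <- list(make_arc(c(5, 5, 5), start_gantry = -100),
                  make_arc(c(4, 4), start_gantry = 60),
                  make_arc(c(6, 6, 6, 6), start_gantry = 150))
  linked <- link_subarcs(subarcs, machine)
  # independent oracle: enumerate all 3! orders x 2^3 directions
  best <- Inf
  ords <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (ord in ords) {
    for (m in 0:7) {
      rv <- as.logical(bitwAnd(m, c(1, 2, 4)))
      t_tot <- 0; prev <- NULL
      for (k in 1:3) {
        b <- subarcs[[ord[k]]]
        cps <- if (rv[k]) rev(b$control_points) else b$control_points
        g <- sapply(cps, function(cp) cp$gantry)
        if (!is.null(prev)) {
          t_tot <- t_tot + abs(normalize_angle(g[1] - prev)) / machine$max_gantry_speed
        }
        t_tot <- t_tot + estimate_delivery_time(
          beam(cps, "arc", subarc_breaks = NULL), machine)
        prev <- g[length(g)]
      }
      best <- min(best, t_tot)
    }
  }
  expect_equal(linked$time_s, best, tolerance = 1e-9)
  expect_lte(linked$time_s, linked$naive_time_s)
  # the linked beam holds exactly the input CPs as a multiset
  sig <- function(cp) paste(cp$gantry, cp$mu, paste(signif(cp$leaves, 8), collapse = ","))
  in_sigs <- sort(unlist(lapply(subarcs, function(b) sapply(b$control_points, sig))))
  out_sigs <- sort(sapply(linked$beam$control_points, sig))
  expect_identical(out_sigs, in_sigs)
})

test_that("linking a single sub-arc is the identity and greedy linking never beats naive badly", {
  one <- make_arc(c(5, 5))
  linked <- link_subarcs(list(one), machine)
  expect_equal(mu_seq(linked$beam), c(5, 5))
  many <- lapply(1:7, function(i) make_arc(c(4, 4), start_gantry = i * 40))
  l7 <- link_subarcs(many, machine)   # greedy branch (> 6 sub-arcs)
  expect_lte(l7$time_s, l7$naive_time_s + 1e-9)
  expect_length(l7$beam$control_points, 14)
})
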