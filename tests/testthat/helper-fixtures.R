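# Shared fixtures, all built in code at test time.

# small coarse phantom configuration (same 192 mm anatomy on coarser grids)
small_config <- function(...) {
  phantom_config(ct_dims = c(32, 32, 32), ct_spacing = c(6, 6, 6),
                 pet_dims = c(24, 24, 24), pet_spacing = c(8, 8, 8), ...)
}

small_case <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_phantom(small_config(), seed = 7)
    cache
  }
})

# a homogeneous box body (voxel centers within +/- half_mm) inside a larger
# grid, so rays enter the body strictly inside the marching range
box_body <- function(n = 21, spacing = 10, half_mm = 70) {
  g <- image_grid(rep(n, 3), rep(spacing, 3))
  ax <- grid_axes(g)
  inside <- abs(ax$x) <= half_mm
  m <- outer(outer(inside, inside, `&`), inside, `&`)
  structure_mask("body", m, g)
}

# an open square-field control point
open_cp <- function(half_mm = 50, gantry = 0, mu = 100,
                    machine = machine_model()) {
  n <- machine$n_leaf_pairs
  edges <- dosepaint:::leaf_row_edges(machine)
  lv <- cbind(rep(0, n), rep(0, n))
  rows <- which(edges[-length(edges)] < half_mm & edges[-1] > -half_mm)
  lv[rows, 1] <- -half_mm
  lv[rows, 2] <- half_mm
  control_point(gantry, 0, c(-half_mm, half_mm, -half_mm, half_mm), lv, mu = mu)
}

# random gap-respecting control point sequence for delivery tests
random_beam <- function(n_cp, seed, machine = machine_model(), static = FALSE) {
  withr::with_seed(seed, {
    cps <- lapply(seq_len(n_cp), function(i) {
      cp <- open_cp(half_mm = 40 + sample(0:4, 1) * 10,
                    gantry = if (static) 30 else normalize_angle(i * 8),
                    mu = round(runif(1, 0, 12), 2), machine = machine)
      cp
    })
    beam(cps, if (static) "static" else "arc")
  })
}

expect_same_volume <- function(a, b, tol = 1e-12) {
  expect_true(dosepaint:::same_grid(a$grid, b$grid))
  expect_lt(max(abs(as.numeric(a$values) - as.numeric(b$values))), tol)
}
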