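test_that("circumcircle is exact on analytic triangles", {
  # 3-4-5 right triangle: circumradius is half the hypotenuse
  expect_equal(circumcircle(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0))$radius, 2.5,
               tolerance = 1e-12)
  # equilateral side 1
  expect_equal(circumcircle(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))$radius,
               1 / sqrt(3), tolerance = 1e-12)
  # three points on a radius-20 circle in an arbitrary 3D plane
  set.seed(11)
  R <- trochlea:::rotation_about_axis(rnorm(3), runif(1, 0, 2 * pi))
  ctr <- c(4, -7, 11)
  pt <- function(th) as.numeric(ctr + R %*% c(20 * cos(th), 20 * sin(th), 0))
  ci <- circumcircle(pt(0), pt(40 * pi / 180), pt(110 * pi / 180))
  expect_equal(ci$radius, 20, tolerance = 1e-9)
  expect_equal(as.numeric(ci$center), ctr, tolerance = 1e-9)
  expect_error(circumcircle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), "collinear")
})

test_that("regional radii on a cylinder patch recover the cylinder radius", {
  g <- generate_cylinder_patch(20)
  m <- measure_trochlea(g$mesh, g$landmarks)
  expect_lt(max(abs(m$radii - 20)) / 20, 1e-3)
  expect_lt(abs(m$radii[["ma"]] - 20) / 20, 1e-3)
  expect_lt(abs(m$radii[["mp"]] - 20) / 20, 1e-3)
})

test_that("crest radii recover ground truth within 2% on the synthetic trochlea", {
  g <- generate_trochlea(trochlea_spec())  # default grid 200x200
  m <- measure_trochlea(g$mesh, g$landmarks)
  rel <- abs(m$radii - g$truth$radii) / g$truth$radii
  expect_lt(max(rel[c("am", "al", "pm", "pl")]), 0.02)
  expect_lt(max(rel[c("ma", "mp")]), 0.05)
})

test_that("measured radii are stable under mesh refinement", {
  m1 <- with(generate_trochlea(trochlea_spec(grid_nx = 100, grid_ny = 100)),
             measure_trochlea(mesh, landmarks))
  m2 <- with(generate_trochlea(trochlea_spec(grid_nx = 200, grid_ny = 200)),
             measure_trochlea(mesh, landmarks))
  expect_lt(max(abs(m2$radii - m1$radii) / m1$radii), 0.005)
})

test_that("posterior-heavier specs give r_mp > r_ma and mirrored twins agree", {
  spec <- trochlea_spec(grid_nx = 100, grid_ny = 100)  # posterior radii larger
  gr <- generate_trochlea(spec, side = "right")
  gl <- generate_trochlea(spec, side = "left")
  fr <- build_frame(gr$mesh, gr$landmarks)
  fl <- build_frame(gl$mesh, gl$landmarks)
  rr <- midsagittal_radii(apply_frame(fr, gr$mesh))
  rl <- midsagittal_radii(apply_frame(fl, gl$mesh))
  expect_gt(rr[["mp"]], rr[["ma"]])
  expect_lt(max(abs(rr - rl)), 1e-9)
})

test_that("patch extraction respects landmarks, normals and margin monotonicity", {
  g <- generate_trochlea(trochlea_spec(grid_nx = 100, grid_ny = 100))
  fr <- build_frame(g$mesh, g$landmarks)
  m <- apply_frame(fr, g$mesh)
  lm <- apply_frame(fr, g$landmarks)
  patch <- extract_trochlear_patch(m, lm)
  nz <- vertex_normals(m)[, 3]
  expect_true(all(nz[patch] > 0))
  expect_equal(attr(patch, "area"), g$truth$patch_area, tolerance = 0.1)
  shrunk <- extract_trochlear_patch(m, lm, margin = -5)
  expect_lt(length(shrunk), length(patch))
})

test_that("cylinder fitting is exact on noise-free data and matches the
           grid-search oracle under noise", {
  P <- cylinder_points(4000, 20, axis = c(1, 0, 0), span = 2 * pi / 3, seed = 2)
  f0 <- fit_cylinder(P)
  expect_lt(abs(f0$radius - 20), 1e-6)
  expect_lt(f0$rms, 1e-9)
  expect_gt(abs(f0$axis_direction[1]), 1 - 1e-9)
  # noisy cloud, oblique axis: agree with the independent coarse search
  set.seed(3)
  ax <- c(1, 0.15, -0.1); ax <- ax / sqrt(sum(ax^2))
  Pn <- cylinder_points(10000, 20, axis = ax, span = 2 * pi / 3, seed = 4) +
    matrix(rnorm(30000, sd = 0.1), ncol = 3)
  fn <- fit_cylinder(Pn, init_axis = c(1, 0, 0))
  expect_lt(abs(fn$radius - 20), 0.02)
  orc <- grid_cylinder_oracle(Pn, n_dir = 35)
  expect_lt(abs(fn$radius - orc$radius), 0.05)
  expect_gt(abs(sum(fn$axis_direction * orc$axis)), 0.99)
  # the optimum must be at least as good as the oracle's best grid point
  expect_lte(sum((fn$rms)^2) * nrow(Pn), orc$sse * (1 + 1e-9))
})

test_that("a sphere is underfit by a cylinder: finite radius below the sphere's", {
  set.seed(5)
  n <- 4000
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  f <- fit_cylinder(20 * u)
  expect_true(is.finite(f$radius))
  expect_gt(f$rms, 0.1)
  expect_lt(f$radius, 20)
})

test_that("fit_cylinder validates its input", {
  expect_error(fit_cylinder(matrix(rnorm(9), 3)), "at least 6")
})
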