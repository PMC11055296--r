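test_that("cutting a unit cube horizontally yields one closed square of length 4", {
  cu <- mesh_plane_intersection(cube_mesh(), plane3(c(0, 0, 1), offset = 0.5))
  expect_length(cu, 1)
  expect_true(cu[[1]]$closed)
  expect_equal(max(cu[[1]]$arclength), 4, tolerance = 1e-12)
  # every point on the plane
  expect_lt(max(abs(plane_distance(plane3(c(0, 0, 1), offset = 0.5),
                                   cu[[1]]$points))), 1e-9)
})

test_that("a plane above the mesh gives an empty intersection, not an error", {
  expect_length(mesh_plane_intersection(cube_mesh(), plane3(c(0, 0, 1), offset = 5)),
                0)
})

test_that("a plane containing the cylinder axis cuts the patch into two straight lines", {
  g <- generate_cylinder_patch(20, arc_span = 120, grid_nx = 21, grid_ny = 41)
  cu <- mesh_plane_intersection(g$mesh, plane3(c(0, 0, 1), offset = 20 * cos(pi / 6)))
  # z = R cos(span/4)... use a height cutting both sides of the arc
  expect_length(cu, 2)
  for (c1 in cu) {
    # each curve is a straight mediolateral line: constant y and z
    expect_lt(diff(range(c1$points[, 2])), 1e-9)
    expect_lt(diff(range(c1$points[, 3])), 1e-9)
    expect_equal(max(c1$arclength), 30, tolerance = 1e-9)
  }
})

test_that("section curves lie on their cutting planes on curved geometry", {
  g <- generate_trochlea(trochlea_spec(grid_nx = 60, grid_ny = 60))
  for (off in c(-5, 0, 4)) {
    pl <- plane3(c(0, 1, 0), offset = off)
    for (cu in mesh_plane_intersection(g$mesh, pl))
      expect_lt(max(abs(plane_distance(pl, cu$points))), 1e-9)
  }
})

test_that("station planes sit at the landmark anteroposterior positions", {
  g <- generate_trochlea(trochlea_spec(grid_nx = 40, grid_ny = 40))
  fr <- build_frame(g$mesh, g$landmarks)
  lm <- apply_frame(fr, g$landmarks)
  st <- station_planes(lm)
  expect_named(st, c("am", "mid_medial", "pm", "al", "mid_lateral", "pl"))
  for (pl in st) expect_equal(pl$normal, c(0, 1, 0))
  expect_equal(st$am$offset, lm$am_edge[2])
  expect_equal(st$mid_medial$offset, (lm$am_edge[2] + lm$pm_edge[2]) / 2)
  # mirrored left twin gives identical station offsets
  gl <- generate_trochlea(trochlea_spec(grid_nx = 40, grid_ny = 40), side = "left")
  lml <- apply_frame(build_frame(gl$mesh, gl$landmarks), gl$landmarks)
  stl <- station_planes(lml)
  for (nm in names(st))
    expect_equal(stl[[nm]]$offset, st[[nm]]$offset, tolerance = 1e-9)
  # degenerate wedge: corners at the same anteroposterior position
  bad <- unclass(lm)
  bad$pm_edge[2] <- bad$am_edge[2]
  expect_error(station_planes(trochlea:::matrix_landmarks(
    trochlea:::landmark_matrix(structure(bad, class = "landmark_set")))),
    "degenerate")
})

test_that("top points land on the crest and respect the half restriction", {
  g <- generate_trochlea(trochlea_spec(grid_nx = 120, grid_ny = 120))
  fr <- build_frame(g$mesh, g$landmarks)
  m <- apply_frame(fr, g$mesh)
  lm <- apply_frame(fr, g$landmarks)
  st <- station_planes(lm)
  cu <- trochlea:::pick_station_curve(m, st$mid_medial, "medial")
  tp <- top_point(cu, "medial")
  expect_lt(tp[1], 0)
  # the medial crest sits at x = -13 in generator coordinates; the frame
  # applies only an in-plane rotation, so compare against the transformed
  # crest line: distance to the crest curve below 0.1 mm
  crest_x <- -g$truth$spec$crest_halfwidth
  gen_pts <- g$mesh$vertices[abs(g$mesh$vertices[, 1] - crest_x) < 1e-9, ]
  gen_std <- apply_frame(fr, gen_pts[order(gen_pts[, 2]), ])
  crest_curve <- section_curve(gen_std, plane3(c(1, 0, 0), point = gen_std[1, ]))
  snap <- trochlea:::snap_to_curve(crest_curve, tp, max_snap = 0.1)
  expect_lt(sqrt(sum((snap$point - tp)^2)), 0.1)
  expect_error(top_point(cu, "lateral") -> tl, NA)
  expect_gt(tl[1], 0)
  # a curve living entirely on one half errors for the other
  half_curve <- section_curve(cbind(seq(1, 5), 0, 0), plane3(c(0, 1, 0), offset = 0))
  expect_error(top_point(half_curve, "medial"), "medial")
})

test_that("arc midpoints interpolate by arc length and converge with sampling", {
  # semicircle of radius 10: midpoint of the full arc is the apex
  for (n in c(51, 201, 801)) {
    th <- seq(0, pi, length.out = n)
    cu <- section_curve(cbind(10 * cos(th), 0, 10 * sin(th)),
                        plane3(c(0, 1, 0), offset = 0))
    m <- arc_midpoint(cu, cu$points[1, ], cu$points[n, ])
    expect_lt(sqrt(sum((m - c(0, 0, 10))^2)), 0.05)
  }
  # straight polyline: plain midpoint
  cu <- section_curve(rbind(c(0, 0, 0), c(0.5, 0, 0), c(2, 0, 0)),
                      plane3(c(0, 0, 1), offset = 0))
  expect_equal(arc_midpoint(cu, c(0, 0, 0), c(2, 0, 0)), c(1, 0, 0))
  expect_error(arc_midpoint(cu, c(0, 0, 0), c(0, 0, 0)), "same curve position")
  expect_error(arc_midpoint(cu, c(0, 5, 0), c(2, 0, 0)), "from the section curve")
})

test_that("mid-sagittal extremes are ordered anterior > superior > posterior in Y", {
  g <- generate_trochlea(trochlea_spec(grid_nx = 100, grid_ny = 100))
  fr <- build_frame(g$mesh, g$landmarks)
  m <- apply_frame(fr, g$mesh)
  cu <- mesh_plane_intersection(m, plane3(c(1, 0, 0), offset = 0))[[1]]
  ex <- midsagittal_extremes(cu)
  expect_gt(ex$anterior[2], ex$superior[2])
  expect_gt(ex$superior[2], ex$posterior[2])
  # superior point within 0.1 mm of the generator's groove apex height
  spec <- g$truth$spec
  apex_z <- -spec$groove_depth  # profile apex at x = 0 in generator coords
  gen_apex <- c(0, trochlea:::troch_geom(spec)$y_apex(0), apex_z)
  apex_std <- as.numeric(apply_frame(fr, rbind(gen_apex)))
  expect_lt(abs(ex$superior[3] - apex_std[3]), 0.1)
})
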