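test_that("STL round trips preserve geometry for binary and ASCII", {
  m <- tetra_mesh()
  for (binary in c(TRUE, FALSE)) {
    p <- withr::local_tempfile(fileext = ".stl")
    write_stl(m, p, binary = binary)
    m2 <- read_stl(p)
    expect_equal(nrow(m2$vertices), 4)
    expect_equal(nrow(m2$faces), 4)
    # vertex sets match up to ordering (float32 for binary)
    tol <- if (binary) 1e-6 else 1e-8
    d <- trochlea::mesh_point_distance(m, m2$vertices)
    expect_lt(max(d), tol)
  }
})

test_that("reading a generated patch recovers the generator's vertex count", {
  g <- generate_cylinder_patch(20, grid_nx = 21, grid_ny = 31)
  p <- withr::local_tempfile(fileext = ".stl")
  write_stl(g$mesh, p)
  m2 <- read_stl(p)
  expect_equal(nrow(m2$vertices), 21 * 31)
  expect_equal(nrow(m2$faces), nrow(g$mesh$faces))
})

test_that("degenerate mesh inputs are rejected", {
  p <- withr::local_tempfile(fileext = ".stl")
  file.create(p)
  expect_error(read_stl(p), "STL")
  expect_error(surface_mesh(matrix(0, 3, 3), rbind(c(1, 2, 3))), "4 vertices")
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_error(surface_mesh(v, rbind(c(1, 2, 5), c(1, 2, 3), c(1, 3, 4), c(2, 3, 4))),
               "invalid vertex index")
  vbad <- v; vbad[1, 1] <- NaN
  expect_error(surface_mesh(vbad, rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))),
               "non-finite")
})

test_that("validation drops zero-area faces", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(2, 0, 0))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4), c(1, 2, 5))  # last is collinear
  m <- surface_mesh(v, f)
  expect_equal(nrow(m$faces), 4)
})

test_that("landmark JSON round trip is bit-identical and errors are named", {
  g <- generate_trochlea(trochlea_spec(grid_nx = 30, grid_ny = 30))
  p <- withr::local_tempfile(fileext = ".json")
  write_landmarks(g$landmarks, p)
  lm2 <- read_landmarks(p)
  expect_identical(trochlea:::landmark_matrix(lm2),
                   trochlea:::landmark_matrix(g$landmarks))
  # missing key is named in the error
  obj <- jsonlite::read_json(p)
  obj$pl_edge <- NULL
  p2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj, p2, auto_unbox = TRUE, digits = NA)
  expect_error(read_landmarks(p2), "pl_edge")
})

test_that("collinear transverse-plane landmarks and off-surface landmarks fail fast", {
  lm <- list(am_edge = c(-10, 10, 0), pm_edge = c(-10, -10, 0),
             al_edge = c(10, 10, 0), pl_edge = c(10, -10, 0),
             ant_medial_edge = c(0, 0, 0), post_medial_edge = c(1, 0, 0),
             ant_lateral_edge = c(2, 0, 0))
  expect_error(landmark_set(lm), "collinear")
  g <- generate_trochlea(trochlea_spec(grid_nx = 40, grid_ny = 40))
  lm10 <- unclass(g$landmarks)
  lm10$am_edge <- lm10$am_edge + c(0, 0, 10)
  expect_error(landmark_set(lm10, mesh = g$mesh), "am_edge")
  # the honest set passes the on-surface check
  expect_s3_class(landmark_set(unclass(g$landmarks), mesh = g$mesh), "landmark_set")
})

test_that("records round-trip at 4-decimal precision with formatted cells", {
  rec <- data.frame(specimen_id = c("a", "b", "c"), sex = "male", age = 40,
                    side = "right", r_am = c(15.97, 16.12345, 18),
                    r_al = 22, r_pm = 34, r_pl = 28, r_ma = 17, r_mp = 22.4,
                    r_cyl = 20.52, cyl_rms = 0.31)
  p <- withr::local_tempfile(fileext = ".csv")
  write_records(rec, p)
  lines <- readLines(p)
  expect_length(lines, 4)             # header + 3 rows
  expect_match(lines[2], "15.9700")   # fixed 4-decimal formatting
  back <- read_records(p)
  expect_equal(back$r_am, round(rec$r_am, 4), tolerance = 1e-12)
  expect_equal(back$r_cyl, rec$r_cyl)
})

test_that("manifest validation enforces schema and file existence", {
  d <- withr::local_tempdir()
  g <- generate_trochlea(trochlea_spec(grid_nx = 30, grid_ny = 30))
  write_stl(g$mesh, file.path(d, "s1.stl"))
  write_landmarks(g$landmarks, file.path(d, "s1.json"))
  mf <- data.frame(specimen_id = "s1", sex = "male", age = 40, side = "right",
                   mesh_path = "s1.stl", landmark_path = "s1.json")
  write.csv(mf, file.path(d, "manifest.csv"), row.names = FALSE)
  man <- read_manifest(file.path(d, "manifest.csv"))
  expect_s3_class(man, "cohort_manifest")
  mf2 <- mf; mf2$mesh_path <- "missing.stl"
  write.csv(mf2, file.path(d, "bad.csv"), row.names = FALSE)
  expect_error(read_manifest(file.path(d, "bad.csv")), "missing file")
  mf3 <- mf; mf3$sex <- "other"
  write.csv(mf3, file.path(d, "bad2.csv"), row.names = FALSE)
  expect_error(read_manifest(file.path(d, "bad2.csv")), "sex")
})
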