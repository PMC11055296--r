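#' Specification for a synthetic trochlea surface
#'
#' Parameters of the analytic trochlea model used for validation. The surface
#' is a family of sagittal profiles: at mediolateral station `x`, the profile
#' is two circular arcs meeting tangentially at their apex, with the anterior
#' arc radius interpolated linearly from `r_med_ant` at the medial crest
#' (`x = -crest_halfwidth`) to `r_lat_ant` at the lateral crest, and likewise
#' for the posterior radii. The apex height dips by
#' `groove_depth * (1 - (x/crest_halfwidth)^2)` between the crests (the
#' central groove), and the apex sits at the anteroposterior midpoint of each
#' profile so that the measurement chain's arc-length midpoints stay on a
#' single arc. The anterior border is widened medially by
#' `anterior_halfwidth_extra` (a wedge), so the anterior border is not
#' parallel to a coordinate plane and the corner landmarks have distinct
#' anteroposterior positions. A thin skirt of width `skirt_width` falls from
#' each crest to a level rim (the articular margin), `rim_drop` mm below the
#' lowest crest point; the three border-extreme landmarks lie on this rim.
#'
#' @param r_med_ant,r_med_post,r_lat_ant,r_lat_post crest arc radii (mm).
#' @param crest_halfwidth half the mediolateral distance between crests (mm).
#' @param groove_depth depth of the central groove (mm).
#' @param anterior_halfwidth_extra medial-anterior wedge widening (mm).
#' @param ap_extent anteroposterior extent at the lateral crest (mm).
#' @param skirt_width width of the border skirt (mm).
#' @param rim_drop drop of the level rim below the lowest crest point (mm).
#' @param grid_nx,grid_ny sampling counts (mediolateral / anteroposterior).
#' @param noise_sd Gaussian vertex noise (mm).
#' @param seed RNG seed for the noise.
#' @return An object of class `"trochlea_spec"`.
#' @export
trochlea_spec <- function(r_med_ant = 16, r_med_post = 34,
                          r_lat_ant = 22, r_lat_post = 28,
                          crest_halfwidth = 13, groove_depth = 2.5,
                          anterior_halfwidth_extra = 2.5, ap_extent = 24,
                          skirt_width = 2.5, rim_drop = 1.5,
                          grid_nx = 200, grid_ny = 200,
                          noise_sd = 0, seed = 1L) {
  spec <- list(r_med_ant = r_med_ant, r_med_post = r_med_post,
               r_lat_ant = r_lat_ant, r_lat_post = r_lat_post,
               crest_halfwidth = crest_halfwidth, groove_depth = groove_depth,
               anterior_halfwidth_extra = anterior_halfwidth_extra,
               ap_extent = ap_extent, skirt_width = skirt_width,
               rim_drop = rim_drop, grid_nx = as.integer(grid_nx),
               grid_ny = as.integer(grid_ny), noise_sd = noise_sd,
               seed = as.integer(seed))
  radii <- c(r_med_ant, r_med_post, r_lat_ant, r_lat_post)
  if (any(!is.finite(unlist(spec[1:10]))))
    stop("trochlea_spec: all geometric parameters must be finite", call. = FALSE)
  if (any(radii <= 0)) stop("trochlea_spec: all radii must be > 0", call. = FALSE)
  if (groove_depth < 0) stop("trochlea_spec: groove_depth must be >= 0", call. = FALSE)
  if (spec$grid_nx < 16 || spec$grid_ny < 16)
    stop("trochlea_spec: grid counts must be >= 16", call. = FALSE)
  if (noise_sd < 0) stop("trochlea_spec: noise_sd must be >= 0", call. = FALSE)
  if (crest_halfwidth <= 0 || ap_extent <= 0 || skirt_width <= 0)
    stop("trochlea_spec: extents must be > 0", call. = FALSE)
  # arc feasibility: each crest arc must reach its profile terminus
  smax <- ap_extent / 2 + anterior_halfwidth_extra / 2 +
    anterior_halfwidth_extra * skirt_width / (2 * crest_halfwidth)
  if (min(radii) <= smax + 0.1)
    stop(sprintf(paste("trochlea_spec: arcs cannot meet tangentially over the",
                       "profile extent (min radius %.2f mm <= half-extent %.2f mm)"),
                 min(radii), smax), call. = FALSE)
  structure(spec, class = "trochlea_spec")
}

#' @export
print.trochlea_spec <- function(x, ...) {
  cat(sprintf(paste0("trochlea_spec: crest radii (mm) med %.1f/%.1f ant/post,",
                     " lat %.1f/%.1f ant/post\n"),
              x$r_med_ant, x$r_med_post, x$r_lat_ant, x$r_lat_post))
  cat(sprintf("  width 2x%.1f + skirt, AP %.1f, groove %.1f, grid %dx%d, noise sd %.3g\n",
              x$crest_halfwidth, x$ap_extent, x$groove_depth,
              x$grid_nx, x$grid_ny, x$noise_sd))
  invisible(x)
}

# profile machinery shared by the surface and the landmark constructions ------

troch_geom <- function(spec) {
  xc <- spec$crest_halfwidth
  ex <- spec$anterior_halfwidth_extra
  y_post <- -spec$ap_extent / 2
  y_ant <- function(x) spec$ap_extent / 2 + ex * (xc - x) / (2 * xc)
  clampx <- function(x) pmin(pmax(x, -xc), xc)
  ra <- function(x) {
    t <- (clampx(x) + xc) / (2 * xc)
    (1 - t) * spec$r_med_ant + t * spec$r_lat_ant
  }
  rp <- function(x) {
    t <- (clampx(x) + xc) / (2 * xc)
    (1 - t) * spec$r_med_post + t * spec$r_lat_post
  }
  y_apex <- function(x) (y_ant(clampx(x)) + y_post) / 2
  # two-arc profile height relative to the apex (tangent-continued past ends)
  arcz <- function(dy, r) {
    out <- numeric(length(dy))
    inside <- abs(dy) < r * 0.999999
    out[inside] <- sqrt(r[inside]^2 - dy[inside]^2) - r[inside]
    out[!inside] <- -r[!inside]  # degenerate guard; feasibility check prevents this
    out
  }
  z0 <- function(x) ifelse(abs(x) <= xc, -spec$groove_depth * (1 - (x / xc)^2), 0)
  # crest-profile height (params clamped at the crest) used by the skirt
  z_crest <- function(x, y) {
    dy <- y - y_apex(x)
    r <- ifelse(dy >= 0, ra(x), rp(x))
    arcz(dy, r)
  }
  zfun <- function(x, y) {
    z <- z_crest(x, y) + z0(x)
    u <- (abs(x) - xc) / spec$skirt_width
    sk <- u > 0
    if (any(sk)) {
      zc <- z_crest(x[sk], y[sk])
      z[sk] <- zc + pmin(u[sk], 1) * (zlevel(spec) - zc)
    }
    z
  }
  list(xc = xc, y_post = y_post, y_ant = y_ant, ra = ra, rp = rp,
       y_apex = y_apex, z0 = z0, zfun = zfun)
}

# rim level: below the lowest crest terminus
zlevel <- function(spec) {
  smax <- spec$ap_extent / 2 + spec$anterior_halfwidth_extra / 2 +
    spec$anterior_halfwidth_extra * spec$skirt_width / (2 * spec$crest_halfwidth)
  radii <- c(spec$r_med_ant, spec$r_med_post, spec$r_lat_ant, spec$r_lat_post)
  drops <- radii - sqrt(pmax(radii^2 - smax^2, 0))
  -(max(drops) + spec$rim_drop)
}

#' Generate a synthetic trochlea mesh with known ground truth
#'
#' Builds the analytic surface of [trochlea_spec()] as a structured triangle
#' mesh, places the seven landmarks exactly (corner edges at the crest arc
#' termini, border extremes at the extreme-anteroposterior rim points), and
#' returns the analytically known regional radii. The mid-sagittal radii are
#' the mediolateral blends `(r_med_ant + r_lat_ant)/2` and
#' `(r_med_post + r_lat_post)/2` by construction. Left-side specimens are
#' generated by mirroring across the sagittal plane.
#'
#' @param spec a [trochlea_spec()].
#' @param side `"right"` (canonical) or `"left"` (mirrored).
#' @param specimen_id identifier for the mesh.
#' @return A list with elements `mesh` (a [surface_mesh()]), `landmarks`
#'   (a [landmark_set()]) and `truth` (class `"trochlea_truth"`: named
#'   `radii` vector for AM/AL/PM/PL/MA/MP, `cylinder_equivalent_radius`
#'   (`NA` for a trochlea), and the analytic trochlear `patch_area` in mm^2).
#' @export
generate_trochlea <- function(spec, side = c("right", "left"),
                              specimen_id = "synthetic") {
  side <- match.arg(side)
  g <- troch_geom(spec)
  xc <- g$xc; sw <- spec$skirt_width
  ns <- max(3L, as.integer(round(spec$grid_nx * sw / (2 * (xc + sw)))))
  ngr <- max(16L, spec$grid_nx - 2L * (ns - 1L))
  xg <- c(seq(-(xc + sw), -xc, length.out = ns),
          seq(-xc, xc, length.out = ngr)[-1],
          seq(xc, xc + sw, length.out = ns)[-1])
  ny <- spec$grid_ny
  nx <- length(xg)
  X <- matrix(rep(xg, each = ny), nrow = ny)
  Y <- vapply(xg, function(x) seq(g$y_post, g$y_ant(x), length.out = ny), numeric(ny))
  Z <- matrix(g$zfun(as.vector(X), as.vector(Y)), nrow = ny)
  V <- cbind(as.vector(X), as.vector(Y), as.vector(Z))
  faces <- grid_faces(nx, ny)
  if (spec$noise_sd > 0) {
    V <- V + with_seed(spec$seed, matrix(stats::rnorm(length(V), sd = spec$noise_sd),
                                         ncol = 3))
  }
  mesh <- surface_mesh(V, faces, specimen_id, validate = TRUE)
  zl <- zlevel(spec)
  lm <- landmark_set(
    am_edge = c(-xc, g$y_ant(-xc), g$zfun(-xc, g$y_ant(-xc))),
    pm_edge = c(-xc, g$y_post, g$zfun(-xc, g$y_post)),
    al_edge = c(xc, g$y_ant(xc), g$zfun(xc, g$y_ant(xc))),
    pl_edge = c(xc, g$y_post, g$zfun(xc, g$y_post)),
    ant_medial_edge = c(-(xc + sw), g$y_ant(-(xc + sw)), zl),
    post_medial_edge = c(-(xc + sw), g$y_post, zl),
    ant_lateral_edge = c(xc + sw, g$y_ant(xc + sw), zl))
  if (side == "left") {
    mesh <- transform_mesh(mesh, rotation = diag(c(-1, 1, 1)))
    lm <- matrix_landmarks(landmark_matrix(lm) %*% diag(c(-1, 1, 1)))
  }
  truth <- structure(list(
    radii = c(am = spec$r_med_ant, al = spec$r_lat_ant,
              pm = spec$r_med_post, pl = spec$r_lat_post,
              ma = (spec$r_med_ant + spec$r_lat_ant) / 2,
              mp = (spec$r_med_post + spec$r_lat_post) / 2),
    landmarks = lm,
    cylinder_equivalent_radius = NA_real_,
    patch_area = troch_patch_area(spec),
    side = side, spec = spec), class = "trochlea_truth")
  list(mesh = mesh, landmarks = lm, truth = truth)
}

# analytic (dense-quadrature) area of the trochlear patch: the region between
# the crests bounded by the corner-landmark quadrilateral
troch_patch_area <- function(spec, n = 600) {
  g <- troch_geom(spec)
  xc <- g$xc
  xs <- seq(-xc, xc, length.out = n + 1)
  xm <- (xs[-1] + xs[-(n + 1)]) / 2
  h <- 1e-5
  total <- 0
  for (x in xm) {
    wy <- g$y_ant(x) - g$y_post
    ys <- seq(g$y_post, g$y_ant(x), length.out = n + 1)
    ym <- (ys[-1] + ys[-(n + 1)]) / 2
    zx <- (g$zfun(rep(x + h, n), ym) - g$zfun(rep(x - h, n), ym)) / (2 * h)
    zy <- (g$zfun(rep(x, n), ym + h) - g$zfun(rep(x, n), ym - h)) / (2 * h)
    total <- total + sum(sqrt(1 + zx^2 + zy^2)) * (wy / n) * (2 * xc / n)
  }
  total
}

# structured-grid triangulation (column-major vertex order, ny rows per column)
grid_faces <- function(nx, ny) {
  i <- rep(seq_len(nx - 1), each = ny - 1)
  j <- rep(seq_len(ny - 1), times = nx - 1)
  v00 <- (i - 1) * ny + j
  v10 <- i * ny + j
  v11 <- i * ny + j + 1
  v01 <- (i - 1) * ny + j + 1
  rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
}

# evaluate expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a right circular cylinder patch with known ground truth
#'
#' A patch of a cylinder with its axis along the mediolateral (x) direction
#' through the origin, spanning `arc_span` degrees centred on the apex.
#' All six regional radii of the ground truth equal `radius`, as does the
#' cylinder-equivalent radius, making the patch an exact end-to-end oracle
#' for the measurement chain.
#'
#' @param radius cylinder radius (mm), > 0.
#' @param axis_extent mediolateral extent of the patch (mm).
#' @param arc_span angular span in degrees (30 to 180).
#' @param grid_nx,grid_ny sampling counts along the axis / around the arc.
#'   The default arc sampling keeps three-point circle measurements within
#'   1e-4 relative of `radius`.
#' @param specimen_id identifier for the mesh.
#' @return As [generate_trochlea()]: list of `mesh`, `landmarks`, `truth`.
#' @export
generate_cylinder_patch <- function(radius, axis_extent = 30, arc_span = 120,
                                    grid_nx = 121, grid_ny = 361,
                                    specimen_id = "cylinder") {
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0", call. = FALSE)
  if (arc_span < 30 || arc_span > 180)
    stop("arc_span must be between 30 and 180 degrees", call. = FALSE)
  if (axis_extent <= 0) stop("axis_extent must be > 0", call. = FALSE)
  half <- arc_span / 2 * pi / 180
  th <- seq(-half, half, length.out = grid_ny)   # odd count puts the apex on the grid
  xg <- seq(-axis_extent / 2, axis_extent / 2, length.out = grid_nx)
  Y <- radius * sin(th)
  Z <- radius * cos(th)
  V <- cbind(rep(xg, each = grid_ny), rep(Y, times = grid_nx), rep(Z, times = grid_nx))
  mesh <- surface_mesh(V, grid_faces(grid_nx, grid_ny), specimen_id, validate = TRUE)
  ys <- radius * sin(half); zc <- radius * cos(half); L <- axis_extent / 2
  lm <- landmark_set(
    am_edge = c(-L, ys, zc), pm_edge = c(-L, -ys, zc),
    al_edge = c(L, ys, zc), pl_edge = c(L, -ys, zc),
    ant_medial_edge = c(-L, ys, zc), post_medial_edge = c(-L, -ys, zc),
    ant_lateral_edge = c(L, ys, zc))
  truth <- structure(list(
    radii = c(am = radius, al = radius, pm = radius,
              pl = radius, ma = radius, mp = radius),
    landmarks = lm,
    cylinder_equivalent_radius = radius,
    patch_area = axis_extent * radius * 2 * half,
    side = "right", spec = NULL), class = "trochlea_truth")
  list(mesh = mesh, landmarks = lm, truth = truth)
}

#' @export
print.trochlea_truth <- function(x, ...) {
  cat("trochlea ground truth (mm):\n  ")
  cat(paste(sprintf("%s=%.3f", toupper(names(x$radii)), x$radii), collapse = "  "), "\n")
  if (is.finite(x$cylinder_equivalent_radius))
    cat(sprintf("  cylinder-equivalent radius %.3f\n", x$cylinder_equivalent_radius))
  invisible(x)
}
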