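# ---- low-level vector helpers (3-vectors as numeric(3), point sets as n x 3) ----

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

as_point3 <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 3 || any(!is.finite(p)))
    stop(sprintf("%s must be a finite numeric 3-vector", what), call. = FALSE)
  p
}

as_points_matrix <- function(x, what = "points") {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 3, byrow = TRUE)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3) stop(sprintf("%s must have 3 columns", what), call. = FALSE)
  x
}

#' Construct a plane from a unit normal and offset
#'
#' A plane is stored as a unit normal `n` and scalar offset `d` such that a
#' point `x` lies on the plane when `sum(x * n) == d`. The offset is therefore
#' the signed distance of the plane from the coordinate origin, in mm.
#'
#' @param normal numeric 3-vector; need not be unit length on input.
#' @param offset scalar offset for the *unit* normal, or omit and supply
#'   `point`.
#' @param point a point on the plane (used instead of `offset` if given).
#' @return An object of class `"plane3"` with elements `normal` (unit) and
#'   `offset`.
#' @export
plane3 <- function(normal, offset = NULL, point = NULL) {
  n0 <- as_point3(normal, "normal")
  len <- vnorm(n0)
  if (len < 1e-12) stop("plane normal is zero", call. = FALSE)
  n <- n0 / len
  if (is.null(offset)) {
    if (is.null(point)) stop("supply either offset or point", call. = FALSE)
    offset <- sum(as_point3(point) * n)
  } else {
    # offset given for the raw normal: rescale to the unit normal
    offset <- offset / len
  }
  structure(list(normal = n, offset = as.numeric(offset)), class = "plane3")
}

#' @export
print.plane3 <- function(x, ...) {
  cat(sprintf("plane: %.6f x + %.6f y + %.6f z = %.6f\n",
              x$normal[1], x$normal[2], x$normal[3], x$offset))
  invisible(x)
}

#' Signed distances of points to a plane
#'
#' @param plane a [plane3()] object.
#' @param pts a point (length-3 vector) or an `n x 3` matrix.
#' @return Numeric vector of signed distances in mm (positive on the side the
#'   normal points to).
#' @export
plane_distance <- function(plane, pts) {
  pts <- as_points_matrix(pts)
  drop(pts %*% plane$normal) - plane$offset
}

#' Plane through three points
#'
#' @param p1,p2,p3 3D points (mm). The points must span a triangle of area
#'   greater than `1e-9` mm^2.
#' @return A [plane3()] containing all three points.
#' @export
plane_from_points <- function(p1, p2, p3) {
  p1 <- as_point3(p1); p2 <- as_point3(p2); p3 <- as_point3(p3)
  n <- cross3(p2 - p1, p3 - p1)
  if (vnorm(n) / 2 <= 1e-9)
    stop("points are collinear: no unique plane", call. = FALSE)
  plane3(n, point = p1)
}

#' Circumscribed circle through three points in 3D
#'
#' Returns the exact circumcircle of the triangle `p1 p2 p3`: the unique circle
#' through all three points, lying in their common plane. The radius follows
#' the closed form \eqn{R = abc / (4K)} with `a`, `b`, `c` the side lengths and
#' `K` the triangle area.
#'
#' @param p1,p2,p3 non-collinear 3D points (mm).
#' @return An object of class `"circle3"`: `center` (3-vector, mm), `radius`
#'   (mm), and `plane` (a [plane3()]).
#' @export
circumcircle <- function(p1, p2, p3) {
  p1 <- as_point3(p1); p2 <- as_point3(p2); p3 <- as_point3(p3)
  u <- p2 - p1
  v <- p3 - p1
  w <- cross3(u, v)
  w2 <- sum(w * w)
  if (sqrt(w2) / 2 <= 1e-9)
    stop("points are collinear: no circumcircle", call. = FALSE)
  # center = p1 + (|u|^2 (v x w) ... ) classic closed form
  center <- p1 + (sum(u * u) * cross3(w, -v) + sum(v * v) * cross3(w, u)) / (2 * w2)
  radius <- vnorm(center - p1)
  structure(list(center = center, radius = radius,
                 plane = plane3(w, point = p1)),
            class = "circle3")
}

#' @export
print.circle3 <- function(x, ...) {
  cat(sprintf("circle: radius %.4f mm, center (%.4f, %.4f, %.4f)\n",
              x$radius, x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

# rotation matrix about an arbitrary unit axis (Rodrigues)
rotation_about_axis <- function(axis, angle) {
  a <- unit(as_point3(axis, "axis"))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# deterministic random proper rotation (for property tests and pose scrambling)
random_rotation <- function() {
  repeat {
    a <- stats::rnorm(3)
    if (vnorm(a) > 1e-3) break
  }
  rotation_about_axis(a, stats::runif(1, 0, 2 * pi))
}

#' First intersection of a ray with a triangulated mesh
#'
#' Vectorized Moller-Trumbore over all faces; returns the hit closest to the
#' origin along the (normalized) direction, counting only `t > tol` hits.
#'
#' @param mesh a [surface_mesh()].
#' @param origin ray origin (mm).
#' @param direction ray direction; normalized internally.
#' @param tol minimum ray parameter counted as a hit.
#' @return The intersection point (3-vector) or `NULL` if the ray misses.
#' @export
ray_mesh_intersection <- function(mesh, origin, direction, tol = 1e-9) {
  origin <- as_point3(origin, "origin")
  d <- unit(as_point3(direction, "direction"))
  V <- mesh$vertices
  F <- mesh$faces
  p0 <- V[F[, 1], , drop = FALSE]
  e1 <- V[F[, 2], , drop = FALSE] - p0
  e2 <- V[F[, 3], , drop = FALSE] - p0
  # h = d x e2 per face
  h1 <- d[2] * e2[, 3] - d[3] * e2[, 2]
  h2 <- d[3] * e2[, 1] - d[1] * e2[, 3]
  h3 <- d[1] * e2[, 2] - d[2] * e2[, 1]
  a <- e1[, 1] * h1 + e1[, 2] * h2 + e1[, 3] * h3
  ok <- abs(a) > 1e-14
  s1 <- origin[1] - p0[, 1]; s2 <- origin[2] - p0[, 2]; s3 <- origin[3] - p0[, 3]
  u <- (s1 * h1 + s2 * h2 + s3 * h3) / a
  q1 <- s2 * e1[, 3] - s3 * e1[, 2]
  q2 <- s3 * e1[, 1] - s1 * e1[, 3]
  q3 <- s1 * e1[, 2] - s2 * e1[, 1]
  v <- (d[1] * q1 + d[2] * q2 + d[3] * q3) / a
  tt <- (e2[, 1] * q1 + e2[, 2] * q2 + e2[, 3] * q3) / a
  bt <- 1e-9  # barycentric slack: accept edge/vertex grazes
  hit <- ok & u >= -bt & v >= -bt & (u + v) <= 1 + bt & tt > tol
  if (!any(hit)) return(NULL)
  tmin <- min(tt[hit])
  origin + tmin * d
}
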