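#' Regional radius of curvature from a section plane
#'
#' Cuts the mesh with the region section plane, snaps the two station tops
#' onto the section curve, takes the arc-length midpoint between them, and
#' returns the radius of the circumcircle through the three points.
#'
#' @param mesh the standardized [surface_mesh()].
#' @param plane the region section plane (from [region_section_plane()]).
#' @param endA,endB the two station top points bounding the region.
#' @param max_snap endpoint snapping tolerance in mm.
#' @return The radius in mm, with attribute `circle` (the [circumcircle()]).
#' @export
region_radius <- function(mesh, plane, endA, endB, max_snap = 0.5) {
  curves <- mesh_plane_intersection(mesh, plane)
  if (length(curves) == 0) stop("region section plane misses the mesh", call. = FALSE)
  curve <- pick_curve(curves, rbind(endA, endB), max_snap)
  pa <- snap_to_curve(curve, endA, max_snap)$point
  pb <- snap_to_curve(curve, endB, max_snap)$point
  m <- arc_midpoint(curve, pa, pb, max_snap)
  circ <- circumcircle(pa, m, pb)
  structure(circ$radius, circle = circ)
}

# the longest section curve lying within snapping range of all probe points
pick_curve <- function(curves, probes, max_snap = 0.5) {
  probes <- as_points_matrix(probes)
  for (cu in curves) {   # curves arrive ordered by descending length
    ok <- all(apply(probes, 1, function(p) {
      min(rowSums(sweep(cu$points, 2, p)^2)) <= max_snap^2
    }))
    if (ok) return(cu)
  }
  stop("no section curve passes through the requested points", call. = FALSE)
}

#' Mid-anterior and mid-posterior radii from the mid-sagittal profile
#'
#' Cuts the standardized mesh with the mid-sagittal plane (X = 0), marks the
#' anterior, superior and posterior extreme points, and measures two
#' three-point circles: anterior extreme / arc midpoint / superior extreme
#' (mid-anterior), and superior / arc midpoint / posterior (mid-posterior).
#'
#' @param mesh the standardized [surface_mesh()].
#' @param max_snap snapping tolerance in mm.
#' @return Named numeric vector `c(ma = , mp = )` in mm.
#' @export
midsagittal_radii <- function(mesh, max_snap = 0.5) {
  curves <- mesh_plane_intersection(mesh, plane3(c(1, 0, 0), offset = 0))
  if (length(curves) == 0) stop("mid-sagittal plane misses the mesh", call. = FALSE)
  curve <- curves[[1]]  # longest: the trochlear profile for a trochlear patch
  ex <- midsagittal_extremes(curve)
  m_a <- arc_midpoint(curve, ex$anterior, ex$superior, max_snap)
  m_p <- arc_midpoint(curve, ex$superior, ex$posterior, max_snap)
  c(ma = circumcircle(ex$anterior, m_a, ex$superior)$radius,
    mp = circumcircle(ex$superior, m_p, ex$posterior)$radius)
}

#' Separate the trochlear surface patch
#'
#' Returns the indices of mesh vertices whose (X, Y) position falls inside
#' the quadrilateral of the four corner landmarks (optionally inflated by a
#' margin) and whose outward normal points superiorly (positive Z).
#'
#' @param mesh the standardized [surface_mesh()].
#' @param landmarks the standardized [landmark_set()].
#' @param margin signed inflation of the corner quadrilateral in mm
#'   (negative shrinks).
#' @return Integer vector of vertex indices (with attribute `area`, the
#'   summed area of faces whose vertices are all in the patch).
#' @export
extract_trochlear_patch <- function(mesh, landmarks, margin = 0) {
  quad <- rbind(landmarks$am_edge[1:2], landmarks$al_edge[1:2],
                landmarks$pl_edge[1:2], landmarks$pm_edge[1:2])
  ctr <- colMeans(quad)
  # a 1e-6 mm tolerance keeps vertices lying exactly on the quad boundary
  # robustly inside regardless of roundoff in the standardization
  margin <- margin + 1e-6
  dirs <- sweep(quad, 2, ctr)
  len <- sqrt(rowSums(dirs^2))
  quad <- sweep(dirs * (1 + margin / len), 2, -ctr)
  V <- mesh$vertices
  inq <- pracma::inpolygon(V[, 1], V[, 2], quad[, 1], quad[, 2], boundary = TRUE)
  nz <- vertex_normals(mesh)[, 3]
  idx <- which(inq & nz > 0)
  if (length(idx) == 0) stop("empty trochlear patch", call. = FALSE)
  inset <- logical(nrow(V)); inset[idx] <- TRUE
  ff <- inset[mesh$faces[, 1]] & inset[mesh$faces[, 2]] & inset[mesh$faces[, 3]]
  structure(idx, area = sum(face_areas(mesh)[ff]))
}

#' Least-squares cylinder fit
#'
#' Fits a right circular cylinder to a point cloud by minimizing
#' \eqn{\sum_i (d_i - r)^2}, where \eqn{d_i} is the distance of point i to
#' the axis line. The model has five parameters: the axis direction (two
#' spherical angles), the axis point (two coordinates in the plane through
#' the point centroid perpendicular to the axis), and the radius.
#' Levenberg-Marquardt iterations start from the supplied axis (mediolateral
#' X by default, reflecting the anatomy) with the radius at the mean
#' point-axis distance.
#'
#' @param points `n x 3` matrix of points (mm), e.g. the patch vertices.
#' @param init_axis initial axis direction.
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the relative reduction of the sum of
#'   squares and on the parameter step.
#' @return Object of class `"cylinder_fit"`: `axis_point`, `axis_direction`
#'   (unit), `radius` (mm), `rms` residual (mm), `iterations`, `converged`.
#' @export
fit_cylinder <- function(points, init_axis = c(1, 0, 0), max_iter = 200,
                         tol = 1e-15) {
  P <- as_points_matrix(points)
  if (nrow(P) < 6) stop("cylinder fit needs at least 6 points", call. = FALSE)
  ctr <- colMeans(P)
  Q <- sweep(P, 2, ctr)
  # normalize to unit scale so the optimization (and its stopping point)
  # is exactly scale-equivariant
  scl <- sqrt(mean(rowSums(Q^2)))
  if (scl <= 0) stop("degenerate point cloud", call. = FALSE)
  Q <- Q / scl
  a0 <- unit(as_point3(init_axis, "init_axis"))
  th0 <- acos(max(-1, min(1, a0[3])))
  ph0 <- atan2(a0[2], a0[1])
  axis_of <- function(th, ph) c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  dists <- function(par) {
    a <- axis_of(par[1], par[2])
    # orthonormal basis of the plane perpendicular to the axis
    e1 <- unit(if (abs(a[1]) < 0.9) cross3(a, c(1, 0, 0)) else cross3(a, c(0, 1, 0)))
    e2 <- cross3(a, e1)
    p0 <- par[3] * e1 + par[4] * e2
    W <- sweep(Q, 2, p0)
    cx <- W[, 2] * a[3] - W[, 3] * a[2]
    cy <- W[, 3] * a[1] - W[, 1] * a[3]
    cz <- W[, 1] * a[2] - W[, 2] * a[1]
    sqrt(cx^2 + cy^2 + cz^2)
  }
  resid <- function(par) dists(par) - par[5]
  par <- c(th0, ph0, 0, 0, mean(dists(c(th0, ph0, 0, 0, 0))))
  niter <- 0L
  # restart until the solution is stationary: Levenberg-Marquardt can stop
  # just short of the optimum in the flat axis/radius valley of shallow
  # patches, and the restarts polish it to machine precision
  for (round in 1:4) {
    fit <- minpack.lm::nls.lm(par = par, fn = resid,
                              control = minpack.lm::nls.lm.control(
                                maxiter = max_iter, ftol = tol, ptol = tol,
                                gtol = 0))
    niter <- niter + fit$niter
    step <- max(abs(fit$par - par))
    par <- fit$par
    if (step < 1e-12) break
  }
  if (!is.finite(par[5]) || par[5] <= 0 || fit$info == 0)
    stop("cylinder fit did not converge to a valid radius", call. = FALSE)
  a <- axis_of(par[1], par[2])
  e1 <- unit(if (abs(a[1]) < 0.9) cross3(a, c(1, 0, 0)) else cross3(a, c(0, 1, 0)))
  e2 <- cross3(a, e1)
  structure(list(axis_point = ctr + scl * (par[3] * e1 + par[4] * e2),
                 axis_direction = a, radius = scl * par[5],
                 rms = scl * sqrt(mean(resid(par)^2)),
                 iterations = niter,
                 converged = fit$info %in% 1:4),
            class = "cylinder_fit")
}

#' @export
print.cylinder_fit <- function(x, ...) {
  cat(sprintf("cylinder_fit: radius %.4f mm, rms %.6f mm (%d iterations%s)\n",
              x$radius, x$rms, x$iterations,
              if (x$converged) "" else ", NOT converged"))
  cat(sprintf("  axis point (%.3f, %.3f, %.3f), direction (%.4f, %.4f, %.4f)\n",
              x$axis_point[1], x$axis_point[2], x$axis_point[3],
              x$axis_direction[1], x$axis_direction[2], x$axis_direction[3]))
  invisible(x)
}

#' @export
coef.cylinder_fit <- function(object, ...) {
  c(radius = object$radius,
    axis_x = object$axis_direction[1], axis_y = object$axis_direction[2],
    axis_z = object$axis_direction[3])
}
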