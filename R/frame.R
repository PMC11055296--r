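#' Build the transverse and coronal datum planes from landmarks
#'
#' The transverse plane passes through the three border-extreme landmarks
#' (`ant_medial_edge`, `post_medial_edge`, `ant_lateral_edge`). The coronal
#' plane is perpendicular to it and passes through midpoint 1 (of the
#' anterior and posterior medial border extremes) and midpoint 2 (of the
#' anterior lateral border extreme and the posterolateral corner edge).
#'
#' @param landmarks a [landmark_set()].
#' @return List with elements `transverse` and `coronal`, both [plane3()].
#' @export
build_planes <- function(landmarks) {
  alpha <- plane_from_points(landmarks$ant_medial_edge,
                             landmarks$post_medial_edge,
                             landmarks$ant_lateral_edge)
  m1 <- (landmarks$ant_medial_edge + landmarks$post_medial_edge) / 2
  m2 <- (landmarks$ant_lateral_edge + landmarks$pl_edge) / 2
  if (vnorm(m2 - m1) < 1e-6)
    stop("coronal-plane midpoints coincide: degenerate landmark set", call. = FALSE)
  d <- m2 - m1
  n_beta <- cross3(alpha$normal, d)   # perpendicular to alpha and containing m1, m2
  if (vnorm(n_beta) < 1e-9)
    stop("coronal-plane chord is parallel to the transverse normal", call. = FALSE)
  beta <- plane3(n_beta, point = m1)
  list(transverse = alpha, coronal = beta)
}

#' Fit the talar centerpoint
#'
#' Midpoint 1 of the anteromedial/anterolateral corner edges and midpoint 2
#' of the posteromedial/posterolateral corner edges are joined; their chord
#' midpoint is projected onto the trochlear surface along the transverse
#' normal (superior sense), and the circumcenter of the three points is the
#' talar centerpoint (the world origin of the standardized frame).
#'
#' @param mesh a [surface_mesh()].
#' @param landmarks a [landmark_set()].
#' @param transverse the transverse plane (from [build_planes()]); used only
#'   for the projection direction.
#' @return The centerpoint as a 3-vector (mm), with attributes `points`
#'   (the three defining points) and `radius` (the fitted circle radius).
#' @export
fit_centerpoint <- function(mesh, landmarks, transverse = NULL) {
  if (is.null(transverse)) transverse <- build_planes(landmarks)$transverse
  p1 <- (landmarks$am_edge + landmarks$al_edge) / 2
  p2 <- (landmarks$pm_edge + landmarks$pl_edge) / 2
  mid <- (p1 + p2) / 2
  n <- transverse$normal
  # superior sense: toward the trochlear surface (the mesh lies on that side)
  if (mean(plane_distance(transverse, mesh$vertices)) < 0) n <- -n
  p3 <- ray_mesh_intersection(mesh, mid, n)
  if (is.null(p3))
    stop("centerpoint projection ray does not hit the mesh", call. = FALSE)
  circ <- tryCatch(circumcircle(p1, p2, p3), error = function(e)
    stop("centerpoint circle is degenerate (projection lands on the chord)",
         call. = FALSE))
  structure(circ$center, points = rbind(p1, p2, p3), radius = circ$radius)
}

#' Build the standardized anatomical frame
#'
#' Constructs the rigid (or, for left-side specimens, mirrored) map taking a
#' specimen from its native pose into the standardized frame: origin at the
#' fitted talar centerpoint, +Z superior along the transverse normal, +Y
#' anterior along the coronal normal, +X lateral completing a right-handed
#' system. Axis senses are resolved from the data (mesh side of the
#' transverse plane; anterior border-extreme side of the coronal plane), not
#' assumed from the input pose. With `side = "auto"`, a specimen whose
#' medial landmarks land at positive X is treated as a left talus and
#' mirrored across the sagittal plane so that medial is always at X < 0.
#'
#' @param mesh a [surface_mesh()].
#' @param landmarks a [landmark_set()].
#' @param side `"auto"` (default), `"right"` or `"left"`. For `"left"` the
#'   X axis is mirrored; `"right"` applies no mirror.
#' @return An object of class `"anatomical_frame"`: `rotation` (3x3, applied
#'   on the left; determinant -1 when a mirror is applied), `translation`
#'   (3-vector), `centerpoint` (in object coordinates), `side`, and
#'   `axes` (the axis convention record).
#' @export
build_frame <- function(mesh, landmarks, side = c("auto", "right", "left")) {
  side <- match.arg(side)
  planes <- build_planes(landmarks)
  ctr <- as.numeric(fit_centerpoint(mesh, landmarks, planes$transverse))
  zax <- planes$transverse$normal
  if (mean(plane_distance(planes$transverse, mesh$vertices)) < 0) zax <- -zax
  yax <- planes$coronal$normal
  if (sum(yax * (landmarks$ant_medial_edge - landmarks$post_medial_edge)) < 0)
    yax <- -yax
  # orthonormalize: Y exactly perpendicular to Z (they are by construction,
  # up to roundoff), then X = Y x Z for a right-handed system
  yax <- unit(yax - sum(yax * zax) * zax)
  xax <- cross3(yax, zax)
  R <- rbind(xax, yax, zax)
  dimnames(R) <- NULL
  mirrored <- FALSE
  if (side == "auto") {
    med <- R %*% (landmarks$ant_medial_edge - ctr)
    mirrored <- med[1] > 0
  } else mirrored <- (side == "left")
  if (mirrored) R <- diag(c(-1, 1, 1)) %*% R
  structure(list(rotation = R, translation = -as.numeric(R %*% ctr),
                 centerpoint = ctr,
                 side = if (mirrored) "left" else "right",
                 axes = c(X = "lateral", Y = "anterior", Z = "superior")),
            class = "anatomical_frame")
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat(sprintf("anatomical_frame (%s side%s)\n", x$side,
              if (det(x$rotation) < 0) ", mirrored" else ""))
  cat(sprintf("  centerpoint (object coords): (%.4f, %.4f, %.4f) mm\n",
              x$centerpoint[1], x$centerpoint[2], x$centerpoint[3]))
  cat("  axes: +X lateral, +Y anterior, +Z superior\n")
  invisible(x)
}

#' Apply an anatomical frame to a mesh, landmark set, or points
#'
#' @param frame an [build_frame()] result.
#' @param x a [surface_mesh()], [landmark_set()], or point matrix.
#' @return The standardized object, same class as the input.
#' @export
apply_frame <- function(frame, x) {
  R <- frame$rotation; tr <- frame$translation
  if (inherits(x, "surface_mesh")) return(transform_mesh(x, R, tr))
  if (inherits(x, "landmark_set")) {
    m <- landmark_matrix(x) %*% t(R)
    m <- sweep(m, 2, -tr)
    return(matrix_landmarks(m))
  }
  pts <- as_points_matrix(x)
  sweep(pts %*% t(R), 2, -tr)
}
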