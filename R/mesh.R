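#' Triangulated surface mesh
#'
#' The measurement substrate: a triangulated surface in mm. Vertices are an
#' `n x 3` matrix, faces an `m x 3` integer matrix of 1-based vertex indices.
#' Validation requires finite coordinates, valid indices, at least 4 vertices
#' and 4 faces, and drops zero-area faces.
#'
#' @param vertices `n x 3` numeric matrix (mm).
#' @param faces `m x 3` integer matrix of vertex indices.
#' @param specimen_id identifier carried through to records.
#' @param validate run [validate_mesh()] (default `TRUE`).
#' @return An object of class `"surface_mesh"`.
#' @export
surface_mesh <- function(vertices, faces, specimen_id = "unnamed", validate = TRUE) {
  vertices <- as_points_matrix(vertices, "vertices")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3) stop("faces must have 3 columns", call. = FALSE)
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  m <- structure(list(vertices = vertices, faces = faces,
                      specimen_id = as.character(specimen_id)),
                 class = "surface_mesh")
  if (validate) m <- validate_mesh(m) else m
}

#' Validate a surface mesh
#'
#' Checks finiteness, index validity and minimal size; removes zero-area
#' faces (area below `1e-12` mm^2).
#'
#' @param mesh a [surface_mesh()].
#' @return The validated mesh (possibly with degenerate faces dropped).
#' @export
validate_mesh <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  if (any(!is.finite(V))) stop("mesh validation: non-finite vertex coordinates", call. = FALSE)
  if (nrow(V) < 4) stop("mesh validation: fewer than 4 vertices", call. = FALSE)
  if (nrow(F) < 4) stop("mesh validation: fewer than 4 faces", call. = FALSE)
  if (any(F < 1L) || any(F > nrow(V)))
    stop("mesh validation: face references an invalid vertex index", call. = FALSE)
  a <- face_areas(mesh)
  keep <- a > 1e-12
  if (!all(keep)) {
    mesh$faces <- F[keep, , drop = FALSE]
    if (nrow(mesh$faces) < 4) stop("mesh validation: fewer than 4 non-degenerate faces", call. = FALSE)
  }
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("surface_mesh '%s': %d vertices, %d faces\n",
              x$specimen_id, nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  bbox x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

# per-face areas (mm^2)
face_areas <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# per-face unit normals, m x 3
face_normals <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len < 1e-15] <- 1
  n / len
}

#' Area-weighted vertex normals
#'
#' @param mesh a [surface_mesh()].
#' @return `n x 3` matrix of unit vertex normals (area-weighted average of
#'   incident face normals).
#' @export
vertex_normals <- function(mesh) {
  F <- mesh$faces
  fn <- face_normals(mesh) * face_areas(mesh)  # area weighting
  n <- matrix(0, nrow(mesh$vertices), 3)
  for (k in 1:3) {
    n[, 1] <- n[, 1] + rowsum_into(fn[, 1], F[, k], nrow(n))
    n[, 2] <- n[, 2] + rowsum_into(fn[, 2], F[, k], nrow(n))
    n[, 3] <- n[, 3] + rowsum_into(fn[, 3], F[, k], nrow(n))
  }
  len <- sqrt(rowSums(n^2))
  len[len < 1e-15] <- 1
  n / len
}

# accumulate values by index into a length-n vector
rowsum_into <- function(vals, idx, n) {
  out <- numeric(n)
  s <- rowsum(vals, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Merge duplicate vertices
#'
#' Vertices closer than `tol` (snapped to a grid of spacing `tol`) are merged
#' so that adjacent faces share indices; faces collapsing to fewer than three
#' distinct vertices are dropped.
#'
#' @param mesh a [surface_mesh()].
#' @param tol merge tolerance in mm.
#' @return The merged mesh.
#' @export
merge_vertices <- function(mesh, tol = 1e-6) {
  V <- mesh$vertices
  key <- paste(round(V[, 1] / tol), round(V[, 2] / tol), round(V[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  Vn <- V[first, , drop = FALSE]
  Fn <- matrix(map[mesh$faces], ncol = 3)
  ok <- Fn[, 1] != Fn[, 2] & Fn[, 2] != Fn[, 3] & Fn[, 1] != Fn[, 3]
  surface_mesh(Vn, Fn[ok, , drop = FALSE], mesh$specimen_id, validate = TRUE)
}

#' Apply an affine map to a mesh
#'
#' @param mesh a [surface_mesh()].
#' @param rotation 3x3 matrix applied on the left.
#' @param translation 3-vector added after rotation.
#' @return The transformed mesh. If `det(rotation) < 0` (a mirror), face
#'   orientation is flipped to keep outward normals outward.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  V <- mesh$vertices %*% t(rotation)
  V <- sweep(V, 2, -as_point3(translation, "translation"))
  F <- mesh$faces
  if (det(rotation) < 0) F <- F[, c(1, 3, 2), drop = FALSE]
  surface_mesh(V, F, mesh$specimen_id, validate = FALSE)
}

#' Distance from points to a mesh surface
#'
#' Exact point-triangle distance, vectorized over faces; used to check that
#' digitized landmarks lie on the surface.
#'
#' @param mesh a [surface_mesh()].
#' @param pts a point or `n x 3` matrix.
#' @return Numeric vector of unsigned distances (mm).
#' @export
mesh_point_distance <- function(mesh, pts) {
  pts <- as_points_matrix(pts)
  V <- mesh$vertices; F <- mesh$faces
  A <- V[F[, 1], , drop = FALSE]
  B <- V[F[, 2], , drop = FALSE]
  C <- V[F[, 3], , drop = FALSE]
  ab <- B - A; ac <- C - A
  # Gram matrix entries for the barycentric projection of p onto each plane
  aa <- rowSums(ab * ab); bb <- rowSums(ac * ac); cc <- rowSums(ab * ac)
  det <- pmax(aa * bb - cc * cc, 1e-30)
  out <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    ap <- sweep(-A, 2, -p)  # p - A rowwise
    d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
    u <- (bb * d1 - cc * d2) / det
    v <- (aa * d2 - cc * d1) / det
    q <- A + u * ab + v * ac  # in-plane projection
    bad <- u < 0 | v < 0 | (u + v) > 1
    if (any(bad)) {
      q[bad, ] <- closest_on_tri_edges(p, A[bad, , drop = FALSE],
                                       B[bad, , drop = FALSE], C[bad, , drop = FALSE])
    }
    dif <- sweep(q, 2, p)
    out[i] <- sqrt(min(rowSums(dif^2)))
  }
  out
}

# nearest point on the boundary (edges) of triangles to p
closest_on_tri_edges <- function(p, A, B, C) {
  seg <- function(P0, P1) {
    d <- P1 - P0
    w <- sweep(-P0, 2, -p)  # p - P0
    t <- rowSums(w * d) / pmax(rowSums(d * d), 1e-30)
    t <- pmin(pmax(t, 0), 1)
    P0 + t * d
  }
  q1 <- seg(A, B); q2 <- seg(B, C); q3 <- seg(A, C)
  d1 <- rowSums(sweep(q1, 2, p)^2)
  d2 <- rowSums(sweep(q2, 2, p)^2)
  d3 <- rowSums(sweep(q3, 2, p)^2)
  out <- q1
  w2 <- d2 < d1 & d2 <= d3
  w3 <- d3 < d1 & d3 < d2
  out[w2, ] <- q2[w2, ]
  out[w3, ] <- q3[w3, ]
  out
}
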