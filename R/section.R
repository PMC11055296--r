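#' Intersect a mesh with a plane
#'
#' Every triangle crossing the plane contributes a segment; segments are
#' chained into maximal polylines by shared endpoints (tolerance `1e-9` mm).
#' Vertices lying exactly on the plane are handled (a triangle edge lying in
#' the plane contributes that edge). Curves are returned ordered by
#' descending arc length.
#'
#' @param mesh a [surface_mesh()].
#' @param plane a [plane3()].
#' @param tol on-plane and endpoint-matching tolerance in mm.
#' @return A list of section curves (possibly empty), each of class
#'   `"section_curve"`: `points` (`k x 3` polyline), `arclength` (cumulative,
#'   strictly increasing), `closed` (logical), and the cutting `plane`.
#' @export
mesh_plane_intersection <- function(mesh, plane, tol = 1e-9) {
  V <- mesh$vertices
  F <- mesh$faces
  d <- plane_distance(plane, V)
  on <- abs(d) <= tol
  s <- sign(d)
  s[on] <- 0L
  s1 <- s[F[, 1]]; s2 <- s[F[, 2]]; s3 <- s[F[, 3]]
  smin <- pmin(s1, s2, s3); smax <- pmax(s1, s2, s3)
  crossing <- smin < 0 & smax > 0
  touch <- (s1 == 0) + (s2 == 0) + (s3 == 0)
  use <- crossing | touch == 2  # spanning triangles, or an edge in the plane
  if (!any(use)) return(list())
  segs <- vector("list", sum(use))
  k <- 0L
  edge_point <- function(i, j) {
    t <- d[i] / (d[i] - d[j])
    V[i, ] + t * (V[j, ] - V[i, ])
  }
  fi <- which(use)
  for (f in fi) {
    vv <- F[f, ]
    sv <- s[vv]
    z <- vv[sv == 0]
    if (length(z) == 2) {          # an edge lies in the plane
      seg <- rbind(V[z[1], ], V[z[2], ])
    } else if (length(z) == 1) {   # vertex on plane, other two must straddle
      o <- vv[sv != 0]
      if (s[o[1]] == s[o[2]]) next # grazing contact, no curve
      seg <- rbind(V[z, ], edge_point(o[1], o[2]))
    } else {                       # generic: two edges crossed
      # identify the vertex on its own side
      if (sv[1] == sv[2]) { a <- vv[3]; bc <- vv[1:2] }
      else if (sv[1] == sv[3]) { a <- vv[2]; bc <- vv[c(1, 3)] }
      else { a <- vv[1]; bc <- vv[2:3] }
      seg <- rbind(edge_point(a, bc[1]), edge_point(a, bc[2]))
    }
    k <- k + 1L
    segs[[k]] <- seg
  }
  segs <- segs[seq_len(k)]
  if (k == 0) return(list())
  chain_segments(segs, plane, tol = tol)
}

# chain loose segments into maximal polylines by endpoint identity
chain_segments <- function(segs, plane, tol = 1e-9) {
  P <- do.call(rbind, segs)  # 2k x 3, rows (start1, end1, start2, end2, ...)
  key <- paste(round(P[, 1] / tol), round(P[, 2] / tol), round(P[, 3] / tol))
  first <- !duplicated(key)
  id <- match(key, key[first])
  nodes <- P[first, , drop = FALSE]
  k <- nrow(P) / 2
  e1 <- id[seq(1, 2 * k, by = 2)]
  e2 <- id[seq(2, 2 * k, by = 2)]
  keep <- e1 != e2
  e1 <- e1[keep]; e2 <- e2[keep]
  # drop duplicate segments (edge-in-plane counted from both adjacent faces)
  ekey <- paste(pmin(e1, e2), pmax(e1, e2))
  kk <- !duplicated(ekey)
  e1 <- e1[kk]; e2 <- e2[kk]
  if (length(e1) == 0) return(list())
  # adjacency: node -> incident segment indices
  nseg <- length(e1)
  adj <- vector("list", nrow(nodes))
  for (i in seq_len(nseg)) {
    adj[[e1[i]]] <- c(adj[[e1[i]]], i)
    adj[[e2[i]]] <- c(adj[[e2[i]]], i)
  }
  used <- logical(nseg)
  curves <- list()
  walk <- function(start_node, seg0) {
    path <- start_node
    node <- start_node
    sg <- seg0
    repeat {
      used[sg] <<- TRUE
      node <- if (e1[sg] == node) e2[sg] else e1[sg]
      path <- c(path, node)
      nxt <- setdiff(adj[[node]][!used[adj[[node]]]], sg)
      if (length(nxt) == 0) break
      sg <- nxt[1]
    }
    path
  }
  deg <- lengths(adj)
  # open chains first: start from degree-1 nodes
  for (n0 in which(deg == 1)) {
    free <- adj[[n0]][!used[adj[[n0]]]]
    if (length(free) == 0) next
    curves[[length(curves) + 1]] <- walk(n0, free[1])
  }
  # remaining segments form closed loops
  repeat {
    left <- which(!used)
    if (length(left) == 0) break
    curves[[length(curves) + 1]] <- walk(e1[left[1]], left[1])
  }
  out <- lapply(curves, function(idx) {
    pts <- nodes[idx, , drop = FALSE]
    section_curve(pts, plane)
  })
  len <- vapply(out, function(cu) max(cu$arclength), numeric(1))
  out[order(len, decreasing = TRUE)]
}

#' Construct a section curve
#'
#' @param points ordered `k x 3` polyline on the cutting plane.
#' @param plane the cutting [plane3()].
#' @return Object of class `"section_curve"` with a cumulative arc-length
#'   table; consecutive duplicate points are removed.
#' @export
section_curve <- function(points, plane) {
  pts <- as_points_matrix(points)
  if (nrow(pts) >= 2) {
    step <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
    keep <- c(TRUE, step > 1e-12)
    pts <- pts[keep, , drop = FALSE]
  }
  if (nrow(pts) < 2) stop("section curve needs at least 2 distinct points", call. = FALSE)
  step <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  closed <- sqrt(sum((pts[1, ] - pts[nrow(pts), ])^2)) < 1e-9
  structure(list(points = pts, arclength = c(0, cumsum(step)),
                 closed = closed, plane = plane),
            class = "section_curve")
}

#' @export
print.section_curve <- function(x, ...) {
  cat(sprintf("section_curve: %d points, length %.4f mm%s\n",
              nrow(x$points), max(x$arclength), if (x$closed) " (closed)" else ""))
  invisible(x)
}

#' The six coronal station planes
#'
#' Stations are coronal planes (normal along the anteroposterior Y axis),
#' three per crest, positioned at the Y coordinates of the anteromedial
#' corner, the medial mid-station (midpoint of the AM and PM corners), the
#' posteromedial corner, and likewise laterally. Landmarks must already be
#' standardized.
#'
#' @param landmarks a standardized [landmark_set()].
#' @return Named list of six [plane3()] objects: `am`, `mid_medial`, `pm`,
#'   `al`, `mid_lateral`, `pl`.
#' @export
station_planes <- function(landmarks) {
  yn <- c(0, 1, 0)
  med <- c(landmarks$am_edge[2],
           (landmarks$am_edge[2] + landmarks$pm_edge[2]) / 2,
           landmarks$pm_edge[2])
  lat <- c(landmarks$al_edge[2],
           (landmarks$al_edge[2] + landmarks$pl_edge[2]) / 2,
           landmarks$pl_edge[2])
  if (min(abs(diff(med))) < 1e-6 || min(abs(diff(lat))) < 1e-6)
    stop("degenerate station positions: corner landmarks coincide anteroposteriorly",
         call. = FALSE)
  ys <- c(med, lat)
  names(ys) <- c("am", "mid_medial", "pm", "al", "mid_lateral", "pl")
  lapply(ys, function(y) plane3(yn, offset = y))
}

#' Top point of a section curve on one trochlear half
#'
#' The polyline point of maximal Z among points on the requested half
#' (X < 0 medial, X > 0 lateral, post-standardization); ties within `1e-9` mm
#' are broken toward smaller `|X|` (closer to the groove).
#'
#' @param curve a [section_curve()].
#' @param half `"medial"` or `"lateral"`.
#' @return The top point (3-vector).
#' @export
top_point <- function(curve, half = c("medial", "lateral")) {
  half <- match.arg(half)
  pts <- curve$points
  sel <- if (half == "medial") pts[, 1] < 0 else pts[, 1] > 0
  if (!any(sel))
    stop(sprintf("section curve has no points on the %s half", half), call. = FALSE)
  pts <- pts[sel, , drop = FALSE]
  zmax <- max(pts[, 3])
  cand <- which(pts[, 3] >= zmax - 1e-9)
  pts[cand[which.min(abs(pts[cand, 1]))], ]
}

#' Region section plane through two station tops
#'
#' The nearly sagittal section used for regional curvature: the plane through
#' `topA`, `topB` and the surface projection (along +Z) of their chord
#' midpoint. If the three points are collinear within tolerance (a locally
#' flat or perfectly cylindrical surface), the fallback is the vertical plane
#' through the chord.
#'
#' @param topA,topB station top points (3-vectors, mm).
#' @param mesh the standardized [surface_mesh()].
#' @return A [plane3()].
#' @export
region_section_plane <- function(topA, topB, mesh) {
  topA <- as_point3(topA, "topA"); topB <- as_point3(topB, "topB")
  if (vnorm(topB - topA) < 1e-9) stop("coincident top points", call. = FALSE)
  mid <- (topA + topB) / 2
  p3 <- ray_mesh_intersection(mesh, mid - c(0, 0, 1e-6), c(0, 0, 1))
  if (is.null(p3))
    stop("chord-midpoint projection ray does not hit the mesh", call. = FALSE)
  n <- cross3(topB - topA, p3 - topA)
  if (vnorm(n) / 2 <= 1e-9 * max(1, vnorm(topB - topA))) {
    # degenerate (flat) case: vertical plane containing the chord
    chord <- unit(topB - topA)
    n <- cross3(chord, c(0, 0, 1))
    if (vnorm(n) < 1e-9) stop("vertical chord: cannot build section plane", call. = FALSE)
    return(plane3(n, point = topA))
  }
  plane3(n, point = topA)
}

# snap a point onto the polyline (orthogonal projection onto its segments);
# returns the projected point and its arc-length position. Projection (rather
# than nearest-vertex) keeps the snap stable when a point falls midway
# between two polyline vertices.
snap_to_curve <- function(curve, p, max_snap = 0.5) {
  p <- as_point3(p)
  P <- curve$points
  n <- nrow(P)
  A <- P[-n, , drop = FALSE]
  D <- P[-1, , drop = FALSE] - A
  W <- sweep(-A, 2, -p)  # p - A rowwise
  t <- rowSums(W * D) / pmax(rowSums(D * D), 1e-30)
  t <- pmin(pmax(t, 0), 1)
  Q <- A + t * D
  d2 <- rowSums(sweep(Q, 2, p)^2)
  j <- which.min(d2)
  if (sqrt(d2[j]) > max_snap)
    stop(sprintf("point is %.3f mm from the section curve (max %.3f)",
                 sqrt(d2[j]), max_snap), call. = FALSE)
  seg <- sqrt(sum(D[j, ]^2))
  list(point = Q[j, ], s = curve$arclength[j] + t[j] * seg)
}

# point of the curve at a given cumulative arc length
point_at_arclength <- function(curve, target) {
  s <- curve$arclength
  j <- findInterval(target, s, rightmost.closed = TRUE)
  j <- min(max(j, 1), nrow(curve$points) - 1)
  t <- (target - s[j]) / (s[j + 1] - s[j])
  curve$points[j, ] + t * (curve$points[j + 1, ] - curve$points[j, ])
}

#' Arc-length midpoint between two points of a section curve
#'
#' `a` and `b` are snapped onto the polyline (they must lie within
#' `max_snap` mm of the curve); the returned point sits at half the
#' cumulative arc length between the snapped positions, linearly
#' interpolated within its segment.
#'
#' @param curve a [section_curve()].
#' @param a,b points on (or near) the curve.
#' @param max_snap snapping tolerance in mm.
#' @return The arc midpoint (3-vector).
#' @export
arc_midpoint <- function(curve, a, b, max_snap = 0.5) {
  sa <- snap_to_curve(curve, a, max_snap)
  sb <- snap_to_curve(curve, b, max_snap)
  if (abs(sa$s - sb$s) < 1e-9)
    stop("arc endpoints snap to the same curve position", call. = FALSE)
  point_at_arclength(curve, (sa$s + sb$s) / 2)
}

#' Anterior, superior and posterior extremes of the mid-sagittal profile
#'
#' @param curve the mid-sagittal [section_curve()] (cut at X = 0), restricted
#'   to the trochlear profile.
#' @return List of 3-vectors `anterior` (max Y), `superior` (max Z),
#'   `posterior` (min Y).
#' @export
midsagittal_extremes <- function(curve) {
  pts <- curve$points
  if (nrow(pts) < 3) stop("mid-sagittal profile has fewer than 3 points", call. = FALSE)
  list(anterior = pts[which.max(pts[, 2]), ],
       superior = pts[which.max(pts[, 3]), ],
       posterior = pts[which.min(pts[, 2]), ])
}
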