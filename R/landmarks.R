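LANDMARK_NAMES <- c("am_edge", "pm_edge", "al_edge", "pl_edge",
                    "ant_medial_edge", "post_medial_edge", "ant_lateral_edge")

#' Construct a landmark set
#'
#' The seven named anatomical points (mm) driving all constructions: the four
#' trochlear corner edges (`am_edge`, `pm_edge`, `al_edge`, `pl_edge`) and the
#' three border-extreme points (`ant_medial_edge`, `post_medial_edge`,
#' `ant_lateral_edge`) that define the transverse plane.
#'
#' @param ... the seven named points, each a numeric 3-vector (mm), or a
#'   single named list containing them.
#' @param mesh optional [surface_mesh()]; if given, every landmark must lie
#'   within `surface_tol` mm of the surface.
#' @param surface_tol landmark-to-surface tolerance in mm (digitization error
#'   is expected; gross mislabels must fail fast).
#' @return An object of class `"landmark_set"`: a named list of 3-vectors.
#' @export
landmark_set <- function(..., mesh = NULL, surface_tol = 2) {
  pts <- list(...)
  if (length(pts) == 1 && is.null(names(pts)) && is.list(pts[[1]])) pts <- pts[[1]]
  missing <- setdiff(LANDMARK_NAMES, names(pts))
  if (length(missing) > 0)
    stop(sprintf("landmark set is missing required point(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  pts <- lapply(pts[LANDMARK_NAMES], as_point3, what = "landmark")
  lm <- structure(pts, class = "landmark_set")
  validate_landmarks(lm, mesh = mesh, surface_tol = surface_tol)
}

validate_landmarks <- function(lm, mesh = NULL, surface_tol = 2) {
  tri <- rbind(lm$ant_medial_edge, lm$post_medial_edge, lm$ant_lateral_edge)
  area <- vnorm(cross3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])) / 2
  if (area <= 1e-9)
    stop("transverse-plane landmarks (ant_medial/post_medial/ant_lateral) are collinear",
         call. = FALSE)
  if (!is.null(mesh)) {
    d <- mesh_point_distance(mesh, landmark_matrix(lm))
    off <- d > surface_tol
    if (any(off))
      stop(sprintf("landmark(s) farther than %g mm from the mesh surface: %s",
                   surface_tol,
                   paste(sprintf("%s (%.2f mm)", LANDMARK_NAMES[off], d[off]),
                         collapse = ", ")), call. = FALSE)
  }
  lm
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("landmark_set (mm):\n")
  for (nm in LANDMARK_NAMES)
    cat(sprintf("  %-17s %9.4f %9.4f %9.4f\n", nm, x[[nm]][1], x[[nm]][2], x[[nm]][3]))
  invisible(x)
}

# 7 x 3 matrix in canonical order
landmark_matrix <- function(lm) {
  m <- do.call(rbind, lm[LANDMARK_NAMES])
  rownames(m) <- LANDMARK_NAMES
  m
}

matrix_landmarks <- function(m) {
  lm <- lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
  names(lm) <- rownames(m)
  structure(lm[LANDMARK_NAMES], class = "landmark_set")
}

#' Read landmarks from a JSON file
#'
#' The interchange format is a JSON object with the seven required landmark
#' names, each a 3-number array in mm.
#'
#' @param path path to a landmark JSON file.
#' @param mesh optional [surface_mesh()] for the on-surface check.
#' @param surface_tol landmark-to-surface tolerance in mm.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path, mesh = NULL, surface_tol = 2) {
  if (!file.exists(path)) stop(sprintf("landmark file not found: %s", path), call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  missing <- setdiff(LANDMARK_NAMES, names(obj))
  if (length(missing) > 0)
    stop(sprintf("landmark file %s is missing required key(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  landmark_set(obj[LANDMARK_NAMES], mesh = mesh, surface_tol = surface_tol)
}

#' Write landmarks to a JSON file
#'
#' Coordinates are written at full double precision so that a read/write
#' round trip is bit-identical.
#'
#' @param lm a [landmark_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  # 17 significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(lapply(unclass(lm), as.numeric), path, digits = I(17))
  invisible(path)
}
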