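#' Control parameters for trochlea measurement
#'
#' @param snap_tol endpoint/landmark snapping tolerance onto section curves
#'   (mm).
#' @param surface_tol landmark-to-surface tolerance (mm).
#' @param patch_margin inflation of the corner quadrilateral when separating
#'   the trochlear patch (mm).
#' @param cyl_max_iter,cyl_tol cylinder-fit iteration cap and convergence
#'   tolerance.
#' @return A list of class `"trochlea_control"`.
#' @export
trochlea_control <- function(snap_tol = 0.5, surface_tol = 2, patch_margin = 0,
                             cyl_max_iter = 200, cyl_tol = 1e-12) {
  stopifnot(snap_tol > 0, surface_tol > 0, cyl_max_iter >= 1, cyl_tol > 0)
  structure(list(snap_tol = snap_tol, surface_tol = surface_tol,
                 patch_margin = patch_margin, cyl_max_iter = cyl_max_iter,
                 cyl_tol = cyl_tol), class = "trochlea_control")
}

#' Measure the six regional radii and the cylinder-fit radius of a talus
#'
#' The full measurement chain: build the anatomical frame from the seven
#' landmarks and standardize the specimen; place the six coronal station
#' planes; find the station top points; build the four nearly sagittal
#' region sections (AM, PM, AL, PL) and measure each radius by a three-point
#' circumcircle (the two bounding tops and their arc-length midpoint); cut
#' the mid-sagittal profile for the mid-anterior and mid-posterior radii;
#' separate the trochlear patch and fit a least-squares cylinder.
#'
#' @param mesh a [surface_mesh()] (mm), or a path to an STL file.
#' @param landmarks a [landmark_set()], or a path to a landmark JSON file.
#' @param side `"auto"`, `"right"` or `"left"` (see [build_frame()]).
#' @param control a [trochlea_control()].
#' @return Object of class `"trochlea_measurement"`: `radii` (named vector
#'   am/al/pm/pl/ma/mp, mm), `cylinder` (a [fit_cylinder()] result), `frame`,
#'   `tops` (the six station top points), `specimen_id`, `side`, and
#'   `patch_size` (vertex count of the separated patch).
#' @export
measure_trochlea <- function(mesh, landmarks, side = "auto",
                             control = trochlea_control()) {
  if (is.character(mesh)) mesh <- read_stl(mesh)
  if (is.character(landmarks))
    landmarks <- read_landmarks(landmarks, mesh = mesh,
                                surface_tol = control$surface_tol)
  else validate_landmarks(landmarks, mesh = mesh, surface_tol = control$surface_tol)
  frame <- build_frame(mesh, landmarks, side = side)
  m <- apply_frame(frame, mesh)
  lm <- apply_frame(frame, landmarks)
  stations <- station_planes(lm)
  tops <- list()
  for (nm in c("am", "mid_medial", "pm")) {
    cu <- pick_station_curve(m, stations[[nm]], "medial")
    tops[[nm]] <- top_point(cu, "medial")
  }
  for (nm in c("al", "mid_lateral", "pl")) {
    cu <- pick_station_curve(m, stations[[nm]], "lateral")
    tops[[nm]] <- top_point(cu, "lateral")
  }
  pairs <- list(am = c("am", "mid_medial"), pm = c("pm", "mid_medial"),
                al = c("al", "mid_lateral"), pl = c("pl", "mid_lateral"))
  radii <- c(am = NA_real_, al = NA_real_, pm = NA_real_, pl = NA_real_)
  for (nm in names(pairs)) {
    tA <- tops[[pairs[[nm]][1]]]
    tB <- tops[[pairs[[nm]][2]]]
    pl_sec <- region_section_plane(tA, tB, m)
    radii[nm] <- as.numeric(region_radius(m, pl_sec, tA, tB,
                                          max_snap = control$snap_tol))
  }
  radii <- c(radii, midsagittal_radii(m, max_snap = control$snap_tol))
  patch <- extract_trochlear_patch(m, lm, margin = control$patch_margin)
  cyl <- fit_cylinder(m$vertices[patch, , drop = FALSE],
                      init_axis = c(1, 0, 0),
                      max_iter = control$cyl_max_iter, tol = control$cyl_tol)
  structure(list(radii = radii[c("am", "al", "pm", "pl", "ma", "mp")],
                 cylinder = cyl, frame = frame, tops = tops,
                 specimen_id = mesh$specimen_id, side = frame$side,
                 patch_size = length(patch), patch_area = attr(patch, "area")),
            class = "trochlea_measurement")
}

# largest curve of a station cut that has points on the requested half
pick_station_curve <- function(mesh, plane, half) {
  curves <- mesh_plane_intersection(mesh, plane)
  if (length(curves) == 0)
    stop("station plane does not intersect the mesh", call. = FALSE)
  for (cu in curves) {
    has <- if (half == "medial") any(cu$points[, 1] < 0) else any(cu$points[, 1] > 0)
    if (has) return(cu)
  }
  stop(sprintf("station cut has no points on the %s half", half), call. = FALSE)
}

#' @export
print.trochlea_measurement <- function(x, ...) {
  cat(sprintf("trochlea_measurement '%s' (%s side)\n", x$specimen_id, x$side))
  r <- x$radii
  cat(sprintf("  radii (mm): AM %.2f  AL %.2f  PM %.2f  PL %.2f  MA %.2f  MP %.2f\n",
              r["am"], r["al"], r["pm"], r["pl"], r["ma"], r["mp"]))
  cat(sprintf("  cylinder fit: radius %.2f mm (rms %.4f mm, %d patch vertices)\n",
              x$cylinder$radius, x$cylinder$rms, x$patch_size))
  invisible(x)
}

#' @export
summary.trochlea_measurement <- function(object, ...) {
  out <- data.frame(
    region = c("AM", "AL", "PM", "PL", "MA", "MP", "cylinder"),
    radius_mm = round(c(object$radii, object$cylinder$radius), 4))
  attr(out, "specimen_id") <- object$specimen_id
  out
}

#' @export
coef.trochlea_measurement <- function(object, ...) {
  c(object$radii, cyl = object$cylinder$radius)
}

#' Measure a whole cohort from a manifest
#'
#' Runs [measure_trochlea()] on every manifest row. A specimen whose
#' measurement fails (a geometry error, a corrupt file) is logged and
#' skipped; other specimens are unaffected.
#'
#' @param manifest a [read_manifest()] data frame, or a manifest CSV path.
#' @param control a [trochlea_control()].
#' @param verbose print one line per specimen.
#' @return A data frame of records (one row per successful specimen, columns
#'   as [write_records()]), with attribute `log` — a data frame of
#'   per-specimen status and messages — and attribute `n_failed`.
#' @export
run_batch <- function(manifest, control = trochlea_control(), verbose = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (nrow(manifest) == 0) stop("empty manifest", call. = FALSE)
  recs <- vector("list", nrow(manifest))
  log <- data.frame(specimen_id = manifest$specimen_id, side = manifest$side,
                    status = "ok", message = "", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      mm <- measure_trochlea(row$mesh_path, row$landmark_path,
                             side = row$side, control = control)
      data.frame(specimen_id = row$specimen_id, sex = row$sex, age = row$age,
                 side = row$side,
                 r_am = mm$radii[["am"]], r_al = mm$radii[["al"]],
                 r_pm = mm$radii[["pm"]], r_pl = mm$radii[["pl"]],
                 r_ma = mm$radii[["ma"]], r_mp = mm$radii[["mp"]],
                 r_cyl = mm$cylinder$radius, cyl_rms = mm$cylinder$rms,
                 stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      log$status[i] <- "failed"
      log$message[i] <- conditionMessage(res)
      if (verbose) message(sprintf("  %s [%s]: FAILED (%s)", row$specimen_id,
                                   row$side, conditionMessage(res)))
    } else {
      recs[[i]] <- res
      if (verbose) message(sprintf("  %s [%s]: ok", row$specimen_id, row$side))
    }
  }
  out <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(out)) out <- data.frame()
  nf <- sum(log$status == "failed")
  if (verbose) message(sprintf("%d succeeded / %d failed", nrow(out), nf))
  attr(out, "log") <- log
  attr(out, "n_failed") <- nf
  out
}
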