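#' Read a surface mesh from an STL file
#'
#' Reads ASCII or binary STL (auto-detected). STL stores independent
#' triangles, so duplicate vertices within `merge_tol` are merged after
#' reading so that faces share indices; the result is validated.
#'
#' @param path path to an `.stl` file.
#' @param specimen_id identifier stored on the mesh; defaults to the file
#'   name without extension.
#' @param merge_tol vertex merge tolerance in mm.
#' @return A [surface_mesh()].
#' @export
read_stl <- function(path, specimen_id = NULL, merge_tol = 1e-6) {
  if (!file.exists(path)) stop(sprintf("STL file not found: %s", path), call. = FALSE)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 15) stop(sprintf("not a valid STL file (too short): %s", path), call. = FALSE)
  if (is.null(specimen_id)) specimen_id <- sub("\\.[sS][tT][lL]$", "", basename(path))
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = min(sz, 512))
  is_ascii <- identical(rawToChar(head[1:5]), "solid") &&
    !any(head == as.raw(0)) && grepl("facet", rawToChar(head), fixed = TRUE)
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path, sz)
  nf <- nrow(tri) / 3
  if (nf < 1) stop(sprintf("empty STL file: %s", path), call. = FALSE)
  faces <- matrix(seq_len(nrow(tri)), ncol = 3, byrow = TRUE)
  mesh <- surface_mesh(tri, faces, specimen_id, validate = FALSE)
  merge_vertices(mesh, tol = merge_tol)
}

read_stl_binary <- function(path, sz) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", n = 80))
  nf <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (is.na(nf) || nf < 1 || sz < 84 + 50 * nf)
    stop(sprintf("truncated or corrupt binary STL: %s", path), call. = FALSE)
  raw <- readBin(con, "raw", n = 50 * nf)
  # each record: 12 float32 (normal + 3 vertices) + uint16 attribute
  m <- matrix(raw, nrow = 50)
  fl <- readBin(as.vector(m[1:48, ]), "numeric", n = 12L * nf, size = 4, endian = "little")
  fl <- matrix(fl, ncol = 12, byrow = TRUE)
  # columns 4:12 are the three vertices; interleave to v1,v2,v3 per facet
  out <- matrix(0, 3 * nf, 3)
  out[seq(1, 3 * nf, by = 3), ] <- fl[, 4:6, drop = FALSE]
  out[seq(2, 3 * nf, by = 3), ] <- fl[, 7:9, drop = FALSE]
  out[seq(3, 3 * nf, by = 3), ] <- fl[, 10:12, drop = FALSE]
  out
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) < 3 || length(vl) %% 3 != 0)
    stop(sprintf("corrupt ASCII STL (vertex count %d): %s", length(vl), path), call. = FALSE)
  nums <- t(vapply(strsplit(trimws(vl), "\\s+"),
                   function(x) as.numeric(x[2:4]), numeric(3)))
  if (any(!is.finite(nums))) stop(sprintf("non-numeric vertex in ASCII STL: %s", path), call. = FALSE)
  nums
}

#' Write a surface mesh to an STL file
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @param binary write binary STL (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  V <- mesh$vertices; F <- mesh$faces
  n <- face_normals(mesh)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", paste("trochlea surface_mesh", mesh$specimen_id)))
    writeBin(hdr[1:80], con)
    writeBin(as.integer(nrow(F)), con, size = 4, endian = "little")
    rec <- cbind(n, V[F[, 1], ], V[F[, 2], ], V[F[, 3], ])
    flo <- writeBin(as.numeric(t(rec)), raw(), size = 4, endian = "little")
    flo <- matrix(flo, nrow = 48)
    att <- matrix(as.raw(0), nrow = 2, ncol = nrow(F))
    writeBin(as.vector(rbind(flo, att)), con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("solid %s", mesh$specimen_id), con)
    for (i in seq_len(nrow(F))) {
      writeLines(c(
        sprintf("  facet normal %.9e %.9e %.9e", n[i, 1], n[i, 2], n[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9e %.9e %.9e",
                V[F[i, ], 1], V[F[i, ], 2], V[F[i, ], 3]),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines(sprintf("endsolid %s", mesh$specimen_id), con)
  }
  invisible(path)
}
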