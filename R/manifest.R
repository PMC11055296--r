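#' Read a cohort manifest
#'
#' A manifest is a UTF-8 CSV with header row and columns `specimen_id`,
#' `sex` (male/female), `age` (years), `side` (left/right), `mesh_path`,
#' `landmark_path`. Paths are interpreted relative to the manifest's
#' directory unless absolute. An optional `subject_id` column marks
#' bilateral specimens sharing a subject.
#'
#' @param path manifest CSV path.
#' @param check_files require the referenced files to exist (default `TRUE`).
#' @return A data frame of class `"cohort_manifest"`.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("specimen_id", "sex", "age", "side", "mesh_path", "landmark_path")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0)
    stop(sprintf("manifest is missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  if (nrow(df) == 0) stop("manifest has no rows", call. = FALSE)
  if (!all(df$sex %in% c("male", "female")))
    stop("manifest: sex must be 'male' or 'female'", call. = FALSE)
  if (!all(df$side %in% c("left", "right")))
    stop("manifest: side must be 'left' or 'right'", call. = FALSE)
  if (any(!is.finite(df$age)) || any(df$age <= 0))
    stop("manifest: age must be positive", call. = FALSE)
  key <- paste(df$specimen_id, df$side)
  if (anyDuplicated(key))
    stop("manifest: duplicate (specimen_id, side)", call. = FALSE)
  base <- dirname(normalizePath(path))
  abspath <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  df$mesh_path <- abspath(df$mesh_path)
  df$landmark_path <- abspath(df$landmark_path)
  if (check_files) {
    gone <- !file.exists(df$mesh_path) | !file.exists(df$landmark_path)
    if (any(gone))
      stop(sprintf("manifest references missing file(s) for specimen(s): %s",
                   paste(df$specimen_id[gone], collapse = ", ")), call. = FALSE)
  }
  class(df) <- c("cohort_manifest", "data.frame")
  df
}

#' Write per-specimen measurement records
#'
#' One CSV row per record with columns `specimen_id, sex, age, side, r_am,
#' r_al, r_pm, r_pl, r_ma, r_mp, r_cyl, cyl_rms`; all radii in mm formatted
#' with 4 decimal places.
#'
#' @param records a data frame with the columns above (e.g. from
#'   [run_batch()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  cols <- c("specimen_id", "sex", "age", "side",
            "r_am", "r_al", "r_pm", "r_pl", "r_ma", "r_mp", "r_cyl", "cyl_rms")
  missing <- setdiff(cols, names(records))
  if (length(missing) > 0)
    stop(sprintf("records are missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  out <- records[cols]
  num <- c("r_am", "r_al", "r_pm", "r_pl", "r_ma", "r_mp", "r_cyl", "cyl_rms")
  for (cn in num) out[[cn]] <- sprintf("%.4f", records[[cn]])
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("cannot write records to %s", path), call. = FALSE)
  invisible(path)
}

#' Read measurement records written by [write_records()]
#'
#' @param path records CSV path.
#' @return Data frame with numeric radius columns.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop(sprintf("records file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  num <- intersect(c("age", "r_am", "r_al", "r_pm", "r_pl", "r_ma", "r_mp",
                     "r_cyl", "cyl_rms"), names(df))
  for (cn in num) df[[cn]] <- as.numeric(df[[cn]])
  df
}
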