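#' Effect profiles for synthetic cohorts
#'
#' A profile fixes the distribution of true regional radii in a generated
#' cohort: per-region means and SDs (mm), a multiplicative male/female scale
#' on the regional radii, sex-specific mean and SD of the cylinder-fit
#' radius, and a linear age slope (mm per year, applied around the mean age).
#'
#' * `"reference"` uses published-cohort-scale region means and SDs, a
#'   sex difference on the fitted radius, and no age effect.
#' * `"ordered"` uses strictly ordered region means (PM > PL > MP > AL >
#'   MA > AM) with adjacent gaps of 5 mm and moderate SDs, sized so that
#'   every adjacent LSD comparison is detectable with margin at a cohort of
#'   ~91 tali, accounting for the variance inflation from bilateral
#'   (within-subject correlated) specimens.
#' * `"null"` removes all sex, side and age effects (all regions share one
#'   mean), for calibration studies.
#'
#' @param name profile name.
#' @return A list with entries `region_mean`, `region_sd` (named am, al, pm,
#'   pl, ma, mp), `sex_scale`, `cyl_mean`, `cyl_sd` (male/female), and
#'   `age_slope`.
#' @export
effect_profile <- function(name = c("reference", "ordered", "null")) {
  name <- match.arg(name)
  switch(name,
    "reference" = list(
      region_mean = c(am = 15.97, al = 22.06, pm = 34.17, pl = 27.95,
                      ma = 16.97, mp = 22.44),
      region_sd = c(am = 3.08, al = 3.94, pm = 16.22, pl = 12.08,
                    ma = 3.09, mp = 5.05),
      sex_scale = c(male = 1.06, female = 1),
      cyl_mean = c(male = 21.90, female = 19.57),
      cyl_sd = c(male = 1.97, female = 1.26),
      age_slope = 0),
    "ordered" = list(
      region_mean = c(am = 16, al = 26, pm = 41, pl = 36, ma = 21, mp = 31),
      region_sd = c(am = 3.1, al = 3.9, pm = 6, pl = 5.5, ma = 3.1, mp = 4.5),
      sex_scale = c(male = 1, female = 1),
      cyl_mean = c(male = 20.5, female = 20.5),
      cyl_sd = c(male = 1.95, female = 1.95),
      age_slope = 0),
    "null" = list(
      region_mean = c(am = 22, al = 22, pm = 22, pl = 22, ma = 22, mp = 22),
      region_sd = c(am = 3, al = 3, pm = 3, pl = 3, ma = 3, mp = 3),
      sex_scale = c(male = 1, female = 1),
      cyl_mean = c(male = 20.5, female = 20.5),
      cyl_sd = c(male = 1.95, female = 1.95),
      age_slope = 0))
}

#' Generate a synthetic cohort
#'
#' Draws a cohort of subjects (with demographics mirroring a CT morphometry
#' study: bilateral subjects share a subject-level effect, unilateral
#' subjects get one side) and produces either:
#'
#' * `level = "records"` — a per-specimen records data frame of true
#'   regional radii drawn from the effect profile (regions modelled
#'   independently, so any configured ordering of region means can be
#'   realized), with a small measurement noise; or
#' * `level = "mesh"` — actual trochlea meshes and landmark files written to
#'   `dir` plus a manifest, with per-specimen crest radii drawn around the
#'   profile's AM/AL/PM/PL means (mid-sagittal radii are then the
#'   mediolateral blends of the crest radii, a constraint of the geometry).
#'
#' @param n_male,n_female subject counts.
#' @param bilateral_fraction fraction of subjects contributing both sides.
#' @param effect an [effect_profile()] name or list.
#' @param seed RNG seed; the cohort is a deterministic function of the seed.
#' @param level `"records"` or `"mesh"`.
#' @param dir output directory for `level = "mesh"` (default a tempdir).
#' @param grid_nx,grid_ny mesh sampling for `level = "mesh"`.
#' @param measurement_sd additive noise on recorded radii (records level).
#' @return For `"records"`: a data frame with columns `specimen_id`,
#'   `subject_id`, `sex`, `age`, `side`, the six `r_*` radii, `r_cyl`,
#'   `cyl_rms`, with attribute `truth` (the per-specimen noise-free radii).
#'   For `"mesh"`: a [read_manifest()]-compatible data frame (also written
#'   to `dir/manifest.csv`) with attribute `truth`.
#' @export
make_synthetic_cohort <- function(n_male = 28, n_female = 33,
                                  bilateral_fraction = 30 / 61,
                                  effect = "reference", seed = 1L,
                                  level = c("records", "mesh"), dir = NULL,
                                  grid_nx = 80, grid_ny = 80,
                                  measurement_sd = 0.15) {
  level <- match.arg(level)
  if (is.character(effect)) effect <- effect_profile(effect)
  stopifnot(n_male >= 0, n_female >= 0, n_male + n_female > 0)
  # mesh-level cohorts keep the crest-radius spread moderate: the two-crest
  # geometric model needs each crest to remain locally maximal, which very
  # asymmetric draws (plausible as *measured* values, not as crest radii)
  # would violate
  if (level == "mesh") effect$region_sd <- pmin(effect$region_sd, 2)
  with_seed(seed, {
    nsub <- n_male + n_female
    sex <- sample(rep(c("male", "female"), c(n_male, n_female)))
    age <- pmin(pmax(round(stats::rnorm(nsub, 38, 13)), 14), 69)
    nbil <- round(bilateral_fraction * nsub)
    bilateral <- seq_len(nsub) %in% sample(nsub, nbil)
    uni_side <- sample(c("left", "right"), nsub, replace = TRUE,
                       prob = c(0.55, 0.45))
    rows <- list(); truths <- list(); meshes <- list()
    regions <- c("am", "al", "pm", "pl", "ma", "mp")
    subj_frac <- 0.6   # share of between-specimen SD at the subject level
    for (i in seq_len(nsub)) {
      sc <- effect$sex_scale[[sex[i]]]
      mu <- effect$region_mean * sc +
        effect$age_slope * (age[i] - 38)
      sd_s <- effect$region_sd * subj_frac
      sd_r <- effect$region_sd * sqrt(1 - subj_frac^2)
      subj_eff <- stats::rnorm(length(regions), 0, sd_s)
      cyl_mu <- effect$cyl_mean[[sex[i]]] + effect$age_slope * (age[i] - 38)
      cyl_subj <- stats::rnorm(1, 0, effect$cyl_sd[[sex[i]]] * subj_frac)
      sides <- if (bilateral[i]) c("left", "right") else uni_side[i]
      for (sd_ in sides) {
        r <- mu + subj_eff + stats::rnorm(length(regions), 0, sd_r)
        names(r) <- regions
        r <- pmax(r, 2)  # radii are physical lengths
        rcyl <- max(cyl_mu + cyl_subj +
                      stats::rnorm(1, 0, effect$cyl_sd[[sex[i]]] *
                                     sqrt(1 - subj_frac^2)), 2)
        truths[[length(truths) + 1]] <- data.frame(
          specimen_id = sprintf("S%03d_%s", i, substr(sd_, 1, 1)),
          subject_id = sprintf("S%03d", i), sex = sex[i], age = age[i],
          side = sd_, t(r), r_cyl = rcyl, stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, truths)
    names(truth)[match(regions, names(truth))] <- paste0("r_", regions)
    if (level == "records") {
      rec <- truth
      rc <- paste0("r_", c(regions, "cyl"))
      for (cn in rc)
        rec[[cn]] <- rec[[cn]] + stats::rnorm(nrow(rec), 0, measurement_sd)
      rec$cyl_rms <- abs(stats::rnorm(nrow(rec), 0.1, 0.02))
      attr(rec, "truth") <- truth
      rec
    } else {
      make_mesh_cohort(truth, dir, grid_nx, grid_ny)
    }
  })
}

# write meshes + landmarks + manifest for a truth table (crest radii from
# the am/al/pm/pl columns; feasibility enforced by truncation)
make_mesh_cohort <- function(truth, dir, grid_nx, grid_ny) {
  if (is.null(dir)) dir <- tempfile("cohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- trochlea_spec(grid_nx = grid_nx, grid_ny = grid_ny)
  smax <- base$ap_extent / 2 + base$anterior_halfwidth_extra / 2 +
    base$anterior_halfwidth_extra * base$skirt_width /
    (2 * base$crest_halfwidth)
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    rr <- pmin(pmax(c(tr$r_am, tr$r_pm, tr$r_al, tr$r_pl), smax + 0.5), 45)
    # keep the truth table consistent with the buildable geometry
    truth[i, c("r_am", "r_pm", "r_al", "r_pl")] <- rr
    truth[i, "r_ma"] <- (rr[1] + rr[3]) / 2
    truth[i, "r_mp"] <- (rr[2] + rr[4]) / 2
    spec <- trochlea_spec(r_med_ant = rr[1], r_med_post = rr[2],
                          r_lat_ant = rr[3], r_lat_post = rr[4],
                          grid_nx = grid_nx, grid_ny = grid_ny)
    gen <- generate_trochlea(spec, side = tr$side, specimen_id = tr$specimen_id)
    mp <- file.path(dir, paste0(tr$specimen_id, ".stl"))
    lp <- file.path(dir, paste0(tr$specimen_id, ".json"))
    write_stl(gen$mesh, mp)
    write_landmarks(gen$landmarks, lp)
    rows[[i]] <- data.frame(specimen_id = tr$subject_id, sex = tr$sex,
                            age = tr$age, side = tr$side, mesh_path = mp,
                            landmark_path = lp, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  class(manifest) <- c("cohort_manifest", "data.frame")
  attr(manifest, "truth") <- truth
  attr(manifest, "dir") <- dir
  manifest
}
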