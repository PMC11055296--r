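#' Published reference cohort summaries
#'
#' Loads the bundled (n, mean, SD) summaries of a published CT morphometry
#' cohort of 91 tali: the six regional radii of curvature and the
#' cylinder-fit radius by sex and side. Two group sizes (male/female talus
#' counts) were not published and are reconstructed from the reported t
#' statistic; they are flagged in the bundled file.
#'
#' @param path alternative JSON file in the same schema.
#' @return A list: `regions` (list of [group_summary()], in AM, AL, PL, PM,
#'   MP, MA order), `by_sex`, `by_side`, `pooled` ([group_summary()]),
#'   `range`, `published_tests` (named numeric), `region_ordering`.
#' @export
reference_cohort <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "reference_summaries.json",
                        package = "trochlea", mustWork = TRUE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  to_gs <- function(df) lapply(seq_len(nrow(df)), function(i)
    group_summary(n = df$n[i], mean = df$mean[i], sd = df$sd[i],
                  label = df$label[i]))
  list(regions = to_gs(obj$regions),
       by_sex = to_gs(obj$fitted_radius$by_sex),
       by_side = to_gs(obj$fitted_radius$by_side),
       pooled = group_summary(n = obj$fitted_radius$pooled$n,
                              mean = obj$fitted_radius$pooled$mean,
                              sd = obj$fitted_radius$pooled$sd,
                              label = "pooled fitted radius"),
       range = as.numeric(obj$fitted_radius$range),
       published_tests = unlist(obj$published_tests),
       region_ordering = unlist(obj$region_ordering))
}

#' Recompute published test statistics from the bundled summaries
#'
#' Recomputes, purely from the published (n, mean, SD) triplets: the one-way
#' ANOVA F across the six regional radii, the pooled t for the fitted radius
#' between sexes and between sides, and the count-weighted pooled mean of
#' the sex-specific fitted radii, and compares each with the published
#' value.
#'
#' @param ref a [reference_cohort()] list (loaded automatically if omitted).
#' @return Data frame with columns `quantity`, `observed`, `published`,
#'   `rel_diff`.
#' @export
check_reference_stats <- function(ref = reference_cohort()) {
  f <- unname(anova_summary(ref$regions)$statistic)
  t_sex <- unname(pooled_t_summary(ref$by_sex[[1]], ref$by_sex[[2]])$statistic)
  t_side <- unname(pooled_t_summary(ref$by_side[[1]], ref$by_side[[2]])$statistic)
  pooled <- pool_summaries(ref$by_sex)
  obs <- c(f, t_sex, t_side, pooled$mean, pooled$sd)
  pub <- c(ref$published_tests[["anova_f_six_regions"]],
           ref$published_tests[["t_fitted_radius_sex"]],
           ref$published_tests[["t_fitted_radius_side"]],
           ref$pooled$mean, ref$pooled$sd)
  data.frame(
    quantity = c("anova_f_six_regions", "t_fitted_radius_sex",
                 "t_fitted_radius_side", "pooled_mean_fitted_radius",
                 "pooled_sd_fitted_radius"),
    observed = obs, published = pub, rel_diff = abs(obs - pub) / abs(pub),
    stringsAsFactors = FALSE)
}
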