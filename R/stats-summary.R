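#' Group summary triplet
#'
#' The (n, mean, SD) triplet that published cohort tables report and on
#' which the summary-statistics layer operates directly.
#'
#' @param n group size (>= 2 for use in tests).
#' @param mean group mean (mm).
#' @param sd group standard deviation (>= 0).
#' @param label group label.
#' @param x optionally, a raw value vector from which n/mean/sd are computed.
#' @return Object of class `"group_summary"`.
#' @export
group_summary <- function(n = NULL, mean = NULL, sd = NULL, label = "",
                          x = NULL) {
  if (!is.null(x)) {
    n <- length(x); mean <- base::mean(x); sd <- stats::sd(x)
  }
  if (!is.finite(n) || n < 1) stop("group_summary: n must be >= 1", call. = FALSE)
  if (!is.finite(sd) || sd < 0) stop("group_summary: sd must be >= 0", call. = FALSE)
  structure(list(n = as.integer(n), mean = as.numeric(mean),
                 sd = as.numeric(sd), label = as.character(label)),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%s: n = %d, %.4f +/- %.4f\n",
              if (nzchar(x$label)) x$label else "group", x$n, x$mean, x$sd))
  invisible(x)
}

as_summary_list <- function(groups) {
  if (inherits(groups, "group_summary")) return(list(groups))
  stopifnot(all(vapply(groups, inherits, logical(1), "group_summary")))
  groups
}

# htest-shaped result so base print methods apply
make_htest <- function(statistic, df, p, method, data.name, estimate = NULL) {
  rval <- list(statistic = statistic, parameter = df, p.value = p,
               method = method, data.name = data.name)
  if (!is.null(estimate)) rval$estimate <- estimate
  class(rval) <- "htest"
  rval
}

#' Pooled-variance two-sample t test from summaries
#'
#' Student's t test (pooled variance, not Welch) computed directly from two
#' (n, mean, SD) triplets:
#' \deqn{t = (m_1 - m_2) / (s_p \sqrt{1/n_1 + 1/n_2}),\quad
#'       s_p^2 = \frac{(n_1-1)s_1^2 + (n_2-1)s_2^2}{n_1+n_2-2}}
#' with \eqn{n_1 + n_2 - 2} degrees of freedom and a two-sided p value.
#'
#' @param g1,g2 [group_summary()] objects (n >= 2 each).
#' @return An `"htest"`-classed result; with zero pooled variance the
#'   statistic is 0 (equal means) or signed `Inf` (unequal means, flagged in
#'   the method string).
#' @export
pooled_t_summary <- function(g1, g2) {
  if (g1$n < 2 || g2$n < 2) stop("pooled t needs n >= 2 in both groups", call. = FALSE)
  df <- g1$n + g2$n - 2
  sp2 <- ((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / df
  delta <- g1$mean - g2$mean
  method <- "Two-sample pooled-variance t test (from summaries)"
  if (sp2 <= 0) {
    t <- if (abs(delta) < .Machine$double.eps) 0 else sign(delta) * Inf
    if (is.infinite(t)) method <- paste(method, "[degenerate: zero pooled variance]")
  } else {
    t <- delta / sqrt(sp2 * (1 / g1$n + 1 / g2$n))
  }
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df)
  make_htest(c(t = t), c(df = df), p, method,
             sprintf("%s vs %s", g1$label, g2$label),
             estimate = c(`mean difference` = delta))
}

#' Paired t test
#'
#' @param x,y matched value vectors (equal length >= 2).
#' @return An `"htest"` result (t, df = n - 1, two-sided p). Zero-variance
#'   differences with a nonzero mean give a signed infinite statistic.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("paired t: unequal lengths", call. = FALSE)
  n <- length(x)
  if (n < 2) stop("paired t needs n >= 2 pairs", call. = FALSE)
  d <- x - y
  sdd <- stats::sd(d)
  method <- "Paired t test"
  if (sdd <= 0) {
    t <- if (abs(mean(d)) < .Machine$double.eps) 0 else sign(mean(d)) * Inf
    if (is.infinite(t)) method <- paste(method, "[degenerate: zero-variance differences]")
  } else {
    t <- mean(d) / (sdd / sqrt(n))
  }
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), n - 1)
  make_htest(c(t = t), c(df = n - 1), p, method, "paired differences",
             estimate = c(`mean difference` = mean(d)))
}

#' One-way ANOVA from summaries
#'
#' Between- and within-group sums of squares computed from (n, mean, SD)
#' triplets: \eqn{SSB = \sum n_i (m_i - \bar m)^2},
#' \eqn{SSW = \sum (n_i - 1) s_i^2}, \eqn{F = (SSB/(k-1)) / (SSW/(N-k))}.
#'
#' @param groups list of [group_summary()] objects (>= 2 groups).
#' @return An `"htest"` result with the F statistic, both degrees of
#'   freedom, and the mean square within as `estimate`.
#' @export
anova_summary <- function(groups) {
  groups <- as_summary_list(groups)
  k <- length(groups)
  if (k < 2) stop("ANOVA needs at least 2 groups", call. = FALSE)
  n <- vapply(groups, `[[`, numeric(1), "n")
  m <- vapply(groups, `[[`, numeric(1), "mean")
  s <- vapply(groups, `[[`, numeric(1), "sd")
  N <- sum(n)
  gm <- sum(n * m) / N
  ssb <- sum(n * (m - gm)^2)
  ssw <- sum((n - 1) * s^2)
  df1 <- k - 1; df2 <- N - k
  method <- "One-way ANOVA (from summaries)"
  if (ssw <= 0) {
    F <- if (ssb < .Machine$double.eps) 0 else Inf
    if (is.infinite(F)) method <- paste(method, "[degenerate: zero within-group variance]")
  } else {
    F <- (ssb / df1) / (ssw / df2)
  }
  p <- if (is.infinite(F)) 0 else stats::pf(F, df1, df2, lower.tail = FALSE)
  make_htest(c(F = F), c(df1 = df1, df2 = df2), p, method,
             paste(vapply(groups, `[[`, character(1), "label"), collapse = ", "),
             estimate = c(MSW = if (df2 > 0) ssw / df2 else NA_real_))
}

#' LSD (least significant difference) pairwise comparisons from summaries
#'
#' Fisher's LSD: for each pair, \eqn{t = (m_i - m_j) /
#' \sqrt{MSW (1/n_i + 1/n_j)}} on \eqn{N - k} degrees of freedom, where MSW
#' is the ANOVA mean square within. LSD applies no multiplicity correction
#' by definition; an optional Bonferroni adjustment is available.
#'
#' @param groups list of [group_summary()] objects.
#' @param adjust `"none"` (LSD, default) or `"bonferroni"`.
#' @return Data frame with one row per pair: labels, mean difference, t, df,
#'   and two-sided p.
#' @export
lsd_pairwise <- function(groups, adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  groups <- as_summary_list(groups)
  an <- anova_summary(groups)
  msw <- unname(an$estimate["MSW"])
  df <- unname(an$parameter["df2"])
  k <- length(groups)
  rows <- list()
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    gi <- groups[[i]]; gj <- groups[[j]]
    delta <- gi$mean - gj$mean
    se <- sqrt(msw * (1 / gi$n + 1 / gj$n))
    t <- if (se > 0) delta / se else if (abs(delta) < .Machine$double.eps) 0 else
      sign(delta) * Inf
    p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df)
    rows[[length(rows) + 1]] <- data.frame(
      group1 = gi$label, group2 = gj$label, diff = delta,
      t = t, df = df, p = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (adjust == "bonferroni") out$p <- pmin(1, out$p * nrow(out))
  out
}

#' Pearson correlation test
#'
#' Sample correlation with a two-sided p value via
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}}; a thin wrapper with explicit guards
#' around [stats::cor.test()].
#'
#' @param x,y value vectors (length >= 3, nonzero variances).
#' @return An `"htest"` result from [stats::cor.test()].
#' @export
correlation_test <- function(x, y) {
  if (length(x) != length(y)) stop("correlation: unequal lengths", call. = FALSE)
  if (length(x) < 3) stop("correlation needs n >= 3", call. = FALSE)
  if (stats::sd(x) <= 0 || stats::sd(y) <= 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  stats::cor.test(x, y, alternative = "two.sided", method = "pearson")
}

#' Count-weighted pooling of group summaries
#'
#' Pools (n, mean, SD) triplets into one: pooled n is the total count,
#' pooled mean the count-weighted mean, and the pooled SD follows from the
#' total sum of squares (within-group plus between-group):
#' \deqn{s^2 = \frac{\sum (n_i - 1) s_i^2 + \sum n_i (m_i - \bar m)^2}{N - 1}}
#'
#' @param groups list of [group_summary()] objects (a single group is
#'   returned unchanged).
#' @param label label for the pooled summary.
#' @return A [group_summary()].
#' @export
pool_summaries <- function(groups, label = "pooled") {
  groups <- as_summary_list(groups)
  if (length(groups) == 1) return(groups[[1]])
  n <- vapply(groups, `[[`, numeric(1), "n")
  m <- vapply(groups, `[[`, numeric(1), "mean")
  s <- vapply(groups, `[[`, numeric(1), "sd")
  N <- sum(n)
  gm <- sum(n * m) / N
  ss <- sum((n - 1) * s^2) + sum(n * (m - gm)^2)
  group_summary(n = N, mean = gm, sd = sqrt(ss / (N - 1)), label = label)
}

#' Cohort statistics report from per-specimen records
#'
#' Computes, for each measured area (the six regional radii and the
#' cylinder-fit radius): per-group (n, mean, SD) summaries under the
#' requested grouping; pooled t tests between the two groups; paired t
#' tests between left and right tali of bilateral subjects (matched by
#' `subject_id` if present, else `specimen_id`); and the Pearson correlation
#' of age with the cylinder-fit radius, overall and stratified by sex.
#'
#' @param records a records data frame ([run_batch()] output or
#'   [read_records()]), optionally with a `subject_id` column.
#' @param grouping `"sex"`, `"side"` or `"age_split"`.
#' @param age_cut split age in years for `"age_split"`; `"median"` (default)
#'   uses the cohort median.
#' @return Object of class `"cohort_report"`: `summaries` (data frame),
#'   `t_tests` (list of `"htest"` per area), `paired` (list per area),
#'   `correlations`, `grouping`, `age_cut`, `warnings`.
#' @export
cohort_report <- function(records, grouping = c("sex", "side", "age_split"),
                          age_cut = "median") {
  grouping <- match.arg(grouping)
  areas <- intersect(c("r_am", "r_al", "r_pm", "r_pl", "r_ma", "r_mp", "r_cyl"),
                     names(records))
  warns <- character(0)
  if (grouping == "age_split") {
    if (identical(age_cut, "median")) age_cut <- stats::median(records$age)
    gvar <- ifelse(records$age <= age_cut,
                   sprintf("age<=%g", age_cut), sprintf("age>%g", age_cut))
  } else {
    gvar <- records[[grouping]]
    age_cut <- NA_real_
  }
  levels <- unique(gvar)
  summaries <- list(); t_tests <- list()
  for (area in areas) {
    gs <- lapply(levels, function(lv) {
      v <- records[[area]][gvar == lv]
      if (length(v) < 2) return(NULL)  # sd undefined below n = 2
      group_summary(x = v, label = sprintf("%s %s", area, lv))
    })
    gs <- gs[!vapply(gs, is.null, logical(1))]
    for (g in gs)
      summaries[[length(summaries) + 1]] <-
        data.frame(area = area, group = g$label, n = g$n, mean = g$mean,
                   sd = g$sd, stringsAsFactors = FALSE)
    if (length(gs) == 2 && all(vapply(gs, `[[`, numeric(1), "n") >= 2)) {
      t_tests[[area]] <- pooled_t_summary(gs[[1]], gs[[2]])
    } else if (length(gs) >= 2) {
      warns <- c(warns, sprintf("%s: a group has n < 2, comparison skipped", area))
    }
  }
  # paired left/right within subject
  paired <- list()
  idcol <- if ("subject_id" %in% names(records)) "subject_id" else "specimen_id"
  if (all(c("side") %in% names(records))) {
    wide <- merge(records[records$side == "left", c(idcol, areas)],
                  records[records$side == "right", c(idcol, areas)],
                  by = idcol, suffixes = c("_L", "_R"))
    if (nrow(wide) >= 2) {
      for (area in areas)
        paired[[area]] <- paired_t_test(wide[[paste0(area, "_L")]],
                                        wide[[paste0(area, "_R")]])
    } else if (nrow(wide) > 0) {
      warns <- c(warns, "fewer than 2 bilateral subjects: paired tests skipped")
    }
  }
  correlations <- list()
  if ("r_cyl" %in% areas && "age" %in% names(records) && nrow(records) >= 3 &&
      stats::sd(records$age) > 0) {
    correlations$overall <- correlation_test(records$age, records$r_cyl)
    if ("sex" %in% names(records)) {
      for (sx in unique(records$sex)) {
        sub <- records[records$sex == sx, ]
        if (nrow(sub) >= 3 && stats::sd(sub$age) > 0)
          correlations[[sx]] <- correlation_test(sub$age, sub$r_cyl)
      }
    }
  }
  structure(list(summaries = do.call(rbind, summaries), t_tests = t_tests,
                 paired = paired, correlations = correlations,
                 grouping = grouping, age_cut = age_cut, warnings = warns),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("cohort_report (grouping: %s%s)\n", x$grouping,
              if (is.finite(x$age_cut)) sprintf(", age cut %g y", x$age_cut) else ""))
  s <- x$summaries
  if (!is.null(s)) {
    s$mean <- round(s$mean, 2); s$sd <- round(s$sd, 2)
    print(s, row.names = FALSE)
  }
  for (area in names(x$t_tests)) {
    ht <- x$t_tests[[area]]
    cat(sprintf("  %s: t = %.3f, df = %d, p %s\n", area, ht$statistic,
                ht$parameter, format_p(ht$p.value)))
  }
  if (length(x$paired) > 0) {
    cat("paired left vs right:\n")
    for (area in names(x$paired)) {
      ht <- x$paired[[area]]
      cat(sprintf("  %s: t = %.3f, df = %d, p %s\n", area, ht$statistic,
                  ht$parameter, format_p(ht$p.value)))
    }
  }
  for (nm in names(x$correlations)) {
    ht <- x$correlations[[nm]]
    cat(sprintf("age vs fitted radius (%s): r = %.3f, p %s\n", nm,
                ht$estimate, format_p(ht$p.value)))
  }
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}

# report-style p formatting: 3 decimals, "< 0.001" below
format_p <- function(p) if (p < 0.001) "< 0.001" else sprintf("= %.3f", p)
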