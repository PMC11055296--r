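test_that("summary-based pooled t agrees with raw-data t.test to 1e-9", {
  set.seed(21)
  for (i in 1:5) {
    x <- rnorm(17, 20, 2); y <- rnorm(23, 19, 2.5)
    ours <- pooled_t_summary(group_summary(x = x, label = "x"),
                            group_summary(x = y, label = "y"))
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(unname(ours$statistic), unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-9)
    expect_equal(unname(ours$parameter), unname(ref$parameter))
  }
  ident <- group_summary(n = 10, mean = 5, sd = 1)
  same <- pooled_t_summary(ident, ident)
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)
  # zero pooled variance with unequal means: infinite-t flag
  degen <- pooled_t_summary(group_summary(n = 5, mean = 1, sd = 0),
                            group_summary(n = 5, mean = 2, sd = 0))
  expect_true(is.infinite(unname(degen$statistic)))
  expect_match(degen$method, "degenerate")
})

test_that("paired t matches the hand-computable case and t.test", {
  d <- c(1, 2, 3)
  ours <- paired_t_test(d + 10, rep(10, 3))
  expect_equal(unname(ours$statistic), 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(unname(ours$parameter), 2)
  set.seed(22)
  x <- rnorm(15); y <- x + rnorm(15, 0.3)
  ref <- t.test(x, y, paired = TRUE)
  ours2 <- paired_t_test(x, y)
  expect_equal(unname(ours2$statistic), unname(ref$statistic), tolerance = 1e-9)
  expect_equal(ours2$p.value, ref$p.value, tolerance = 1e-9)
  expect_equal(unname(paired_t_test(x, x)$statistic), 0)
})

test_that("summary ANOVA equals classical raw-data ANOVA and F = t^2 for k = 2", {
  set.seed(23)
  g <- rep(letters[1:4], times = c(12, 15, 9, 20))
  y <- rnorm(length(g), mean = as.integer(factor(g)))
  gs <- lapply(split(y, g), function(v) group_summary(x = v))
  ours <- anova_summary(gs)
  ref <- anova(aov(y ~ g))
  expect_equal(unname(ours$statistic), ref$`F value`[1], tolerance = 1e-9)
  expect_equal(ours$p.value, ref$`Pr(>F)`[1], tolerance = 1e-9)
  expect_equal(unname(ours$parameter), c(3, length(y) - 4))
  # two groups: F is the square of the pooled t
  two <- gs[1:2]
  expect_equal(unname(anova_summary(two)$statistic),
               unname(pooled_t_summary(two[[1]], two[[2]])$statistic)^2,
               tolerance = 1e-9)
  # identical groups: F = 0
  same <- list(group_summary(n = 10, mean = 3, sd = 1),
               group_summary(n = 10, mean = 3, sd = 1))
  expect_equal(unname(anova_summary(same)$statistic), 0)
})

test_that("LSD pairwise comparisons match pairwise.t.test with pooled SD", {
  set.seed(24)
  g <- rep(c("a", "b", "c"), times = c(10, 14, 12))
  y <- rnorm(length(g), mean = c(a = 0, b = 0.8, c = 2)[g])
  gs <- lapply(names(split(y, g)), function(nm)
    group_summary(x = split(y, g)[[nm]], label = nm))
  ours <- lsd_pairwise(gs)
  ref <- pairwise.t.test(y, g, p.adjust.method = "none", pool.sd = TRUE)
  expect_equal(ours$p[ours$group1 == "a" & ours$group2 == "b"],
               ref$p.value["b", "a"], tolerance = 1e-9)
  expect_equal(ours$p[ours$group1 == "a" & ours$group2 == "c"],
               ref$p.value["c", "a"], tolerance = 1e-9)
  expect_equal(ours$p[ours$group1 == "b" & ours$group2 == "c"],
               ref$p.value["c", "b"], tolerance = 1e-9)
  # identical pair -> p = 1; LSD p equals two-group pooled p only when k = 2
  same <- list(group_summary(n = 8, mean = 5, sd = 1, label = "g1"),
               group_summary(n = 8, mean = 5, sd = 1, label = "g2"))
  expect_equal(lsd_pairwise(same)$p, 1)
  gs2 <- gs[1:2]
  expect_equal(lsd_pairwise(gs2)$p,
               pooled_t_summary(gs2[[1]], gs2[[2]])$p.value, tolerance = 1e-9)
  bon <- lsd_pairwise(gs, adjust = "bonferroni")
  expect_true(all(bon$p >= ours$p))
})

test_that("correlation test matches cor.test and guards degenerate input", {
  x <- 1:10
  expect_equal(unname(correlation_test(x, x + 0)$estimate), 1)
  expect_equal(unname(correlation_test(x, -x)$estimate), -1)
  set.seed(25)
  a <- rnorm(30); b <- 0.5 * a + rnorm(30)
  ours <- correlation_test(a, b)
  ref <- cor.test(a, b)
  expect_equal(ours$p.value, ref$p.value)
  expect_error(correlation_test(x, rep(1, 10)), "zero variance")
  expect_error(correlation_test(1:2, 1:2), "n >= 3")
})

test_that("count-weighted pooling reproduces the total-sum-of-squares identity", {
  set.seed(26)
  x <- rnorm(37, 21.9, 2); y <- rnorm(54, 19.6, 1.3)
  pooled <- pool_summaries(list(group_summary(x = x), group_summary(x = y)))
  expect_equal(pooled$n, 91L)
  expect_equal(pooled$mean, mean(c(x, y)), tolerance = 1e-12)
  expect_equal(pooled$sd, sd(c(x, y)), tolerance = 1e-12)
  single <- group_summary(n = 9, mean = 2, sd = 0.5, label = "one")
  expect_identical(pool_summaries(list(single)), single)
})

test_that("type-I error of the tests is calibrated near the nominal 5%", {
  set.seed(27)
  n_rep <- 1000
  rej <- matrix(FALSE, n_rep, 3)
  for (r in seq_len(n_rep)) {
    x <- rnorm(20); y <- rnorm(25)
    rej[r, 1] <- pooled_t_summary(group_summary(x = x),
                                  group_summary(x = y))$p.value < 0.05
    a <- rnorm(15); b <- rnorm(15)
    rej[r, 2] <- paired_t_test(a, b)$p.value < 0.05
    u <- rnorm(91); v <- rnorm(91)
    rej[r, 3] <- correlation_test(u, v)$p.value < 0.05
  }
  rates <- colMeans(rej)
  expect_true(all(rates >= 0.03 & rates <= 0.07))
})

test_that("cohort_report assembles summaries, tests, pairs and correlations", {
  rec <- make_synthetic_cohort(n_male = 14, n_female = 16, seed = 5,
                               level = "records")
  rep_sex <- cohort_report(rec, grouping = "sex")
  expect_s3_class(rep_sex, "cohort_report")
  expect_true(all(c("r_am", "r_cyl") %in% names(rep_sex$t_tests)))
  expect_gt(length(rep_sex$paired), 0)      # bilateral subjects exist
  expect_true("overall" %in% names(rep_sex$correlations))
  # age split uses the cohort median by default
  rep_age <- cohort_report(rec, grouping = "age_split")
  expect_equal(rep_age$age_cut, median(rec$age))
  # sex effect built into the reference profile: male > female fitted radius
  ht <- rep_sex$t_tests$r_cyl
  male_first <- grepl("male", ht$data.name)
  expect_true(abs(unname(ht$statistic)) > 2)
  # a one-specimen cohort still yields a valid (if empty) report
  one <- rec[1, ]
  rep1 <- cohort_report(one, grouping = "sex")
  expect_s3_class(rep1, "cohort_report")
  expect_length(rep1$t_tests, 0)
})
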