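test_that("two-SD exclusion is a single pass with sample SD", {
  expect_length(exclude_outliers(rep(5, 6))$excluded, 0)
  # hand computation: mean 14.5, SD 30.15 -> only 100 exceeds 2 SD
  scr <- exclude_outliers(c(1:9, 100))
  expect_equal(scr$excluded, 100)
  expect_equal(scr$kept, as.numeric(1:9))
  # hand computation: mean 3.25, SD 4.5 -> |10 - 3.25| = 6.75 < 9, none out
  expect_length(exclude_outliers(c(1, 1, 1, 10))$excluded, 0)
  expect_error(exclude_outliers(c(1, 2)), "at least 3")
  # the rule is applied exactly once: kept values are returned untouched,
  # not re-screened (re-screening c(1:9) would use a different mean/SD)
  expect_identical(scr$kept, as.numeric(1:9))
})

test_that("one-way ANOVA matches a sums-of-squares oracle to 1e-6", {
  y <- c(18.2, 20.1, 17.6, 16.8, 18.8,
         24.1, 23.5, 22.9, 25.0, 24.4,
         31.2, 30.1, 32.5, 29.8, 31.0)
  d <- tibble::tibble(y = y, group = rep(c("a", "b", "c"), each = 5))
  fit <- run_anova(d, "y", "group")
  # independent oracle: explicit between/within sums of squares
  gm <- tapply(y, d$group, mean)
  ssb <- sum(5 * (gm - mean(y))^2)
  ssw <- sum((y - gm[d$group])^2)
  f_hand <- (ssb / 2) / (ssw / 12)
  expect_equal(fit$omnibus$statistic, f_hand, tolerance = 1e-6)
  expect_equal(fit$omnibus$df1, 2)
  expect_equal(fit$omnibus$df2, 12)
  expect_true(all(fit$posthoc$p_adj >= 0 & fit$posthoc$p_adj <= 1))
  expect_equal(nrow(fit$posthoc), 3)
})

test_that("identical group means give F = 0 and p = 1", {
  d <- tibble::tibble(y = rep(c(1, 2, 3), 2),
                      group = rep(c("a", "b"), each = 3))
  fit <- run_anova(d, "y", "group")
  expect_equal(fit$omnibus$statistic, 0, tolerance = 1e-12)
  expect_equal(fit$omnibus$p_value, 1, tolerance = 1e-12)
})

test_that("repeated-measures design puts the within factor in the subject stratum", {
  set.seed(4)
  d <- tidyr::expand_grid(animal = sprintf("A%d", 1:8),
                          epoch = c(0, 60, 120)) %>%
    dplyr::mutate(group = rep(rep(c("vehicle", "tki"), each = 3), 4),
                  y = -0.3 * epoch * (group == "tki") - 0.1 * epoch +
                    rnorm(dplyr::n(), sd = 2))
  fit <- run_anova(d, "y", "group", within = "epoch", subject = "animal",
                   posthoc = "bonferroni")
  expect_true(all(c("group", "epoch") %in% fit$omnibus$term))
  expect_true(all(fit$posthoc$method == "bonferroni"))
  # bonferroni comparisons reported at each epoch
  expect_equal(sort(unique(fit$posthoc$at)), c("0", "120", "60"))
  expect_error(run_anova(d, "y", "group", within = "epoch"), "subject")
})

test_that("pooled and sex-stratified designs both run on a cohort table", {
  m <- draw_cohort_models(4, base_seed = 2)
  pooled <- run_anova(m, "true_final_nmtf", "group")
  strat <- run_anova(m, "true_final_nmtf", c("group", "sex"))
  expect_equal(nrow(pooled$omnibus), 1)
  expect_equal(nrow(strat$omnibus), 3)  # group, sex, interaction
  expect_lt(pooled$omnibus$p_value, 0.05)
})

test_that("Shapiro-Wilk wrapper enforces n and discriminates distributions", {
  expect_error(shapiro_normality(c(1, 2)), "between 3 and 5000")
  p_norm <- vapply(1:30, function(i) {
    set.seed(1000 + i); shapiro_normality(rnorm(50))$p_value
  }, numeric(1))
  expect_gte(mean(p_norm > 0.05), 0.9)
  p_exp <- vapply(1:30, function(i) {
    set.seed(2000 + i); shapiro_normality(rexp(50))$p_value
  }, numeric(1))
  expect_gte(mean(p_exp < 0.05), 0.9)
})

test_that("power-based sample size follows the noncentral-t solution", {
  # d = 2 exactly (difference equal to 2 SDs)
  expect_equal(power_n_per_group(10, 5, 1), 6)
  # published design assumptions: mean 59.0, SD 8.5, 20% difference
  n_paper <- power_n_per_group(59.0, 8.5, 0.20)
  expect_equal(n_paper, 10)
  # independent oracle
  expect_equal(n_paper, ceiling(stats::power.t.test(
    delta = 0.2 * 59, sd = 8.5, power = 0.8)$n))
  # vanishing power floors at n = 2
  expect_equal(power_n_per_group(10, 5, 1, power = 1e-9), 2)
  expect_error(power_n_per_group(10, 5, 2), "\\(0, 1\\]")
})

test_that("a four-group cohort at published calibrations is well powered", {
  pvals <- vapply(1:50, function(r) {
    m <- draw_cohort_models(8, base_seed = 100 + r)
    run_anova(m, "true_final_nmtf", "group")$omnibus$p_value
  }, numeric(1))
  expect_gte(mean(pvals < 0.05), 0.95)
})

test_that("the cohort report ties normality, screening and ANOVA together", {
  m <- draw_cohort_models(8, base_seed = 42)
  rep <- stats_report(m, c("true_final_nmtf", "true_initial_nmtf"),
                      between = "group")
  td <- tidy(rep)
  expect_true(all(c("outcome", "statistic", "p_value", "shapiro_p",
                    "n_excluded") %in% names(td)))
  expect_equal(sort(unique(td$outcome)),
               c("true_final_nmtf", "true_initial_nmtf"))
  g <- glance(rep$outcomes$true_final_nmtf$anova)
  expect_true(g$significant)
  paths <- write_stats_report(rep, file.path(tempdir(), "tbl"))
  expect_true(all(file.exists(paths)))
})
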