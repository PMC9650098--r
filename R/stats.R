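#' Two-standard-deviation outlier exclusion
#'
#' Single-pass rule: the mean and sample SD are computed once on all values,
#' and a point is excluded iff its absolute deviation from the mean exceeds
#' twice that SD.  The rule is deliberately not iterated; re-applying it to
#' the kept values is a different (and stricter) procedure.
#'
#' @param values Numeric vector (n >= 3).
#' @return A list with `kept`, `excluded` (values) and `excluded_idx`.
#' @examples
#' exclude_outliers(c(1:9, 100))$excluded  # 100
#' @export
exclude_outliers <- function(values) {
  if (length(values) < 3) abort("Need at least 3 values for outlier screening.")
  mu <- mean(values)
  s <- sd(values)
  out <- if (s > 0) abs(values - mu) > 2 * s else rep(FALSE, length(values))
  list(kept = values[!out], excluded = values[out], excluded_idx = which(out))
}

#' Shapiro-Wilk normality check
#'
#' Thin wrapper over the standard test with the sample-size contract made
#' explicit (3 <= n <= 5000).
#'
#' @param values Numeric vector.
#' @return A one-row tibble with `statistic` (W) and `p_value`.
#' @export
shapiro_normality <- function(values) {
  if (length(values) < 3 || length(values) > 5000) {
    abort("Shapiro-Wilk requires between 3 and 5000 values.")
  }
  ht <- shapiro.test(values)
  tibble(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' One-/two-way ANOVA with Tukey or Bonferroni post-tests
#'
#' Fits a between-subjects ANOVA over one or two factors, or - when a
#' `within` factor and `subject` identifier are given - a repeated-measures
#' ANOVA with the subject stratum carrying the within-factor error (the
#' structure behind time-course comparisons where each animal contributes
#' every epoch).  Post-tests are Tukey HSD (between-subject designs) or
#' Bonferroni-adjusted pairwise t-tests; for repeated-measures designs the
#' Bonferroni pairwise comparisons of the between factor are run at each
#' level of the within factor, which is how time-resolved group differences
#' are usually reported.
#'
#' @param data Data frame with one row per observation.
#' @param outcome Name of the numeric outcome column.
#' @param between Character vector of one or two between-subject factor
#'   columns.
#' @param within Optional within-subject factor column (e.g. epoch time).
#' @param subject Subject identifier column; required with `within`.
#' @param posthoc `"tukey"` or `"bonferroni"`.
#' @param alpha Significance level recorded in the report.
#' @return An object of class `nmtf_anova` with `omnibus` and `posthoc`
#'   tibbles; see [tidy.nmtf_anova()] and [glance.nmtf_anova()].
#' @export
run_anova <- function(data, outcome, between, within = NULL, subject = NULL,
                      posthoc = c("tukey", "bonferroni"), alpha = 0.05) {
  posthoc <- match.arg(posthoc)
  if (length(between) < 1 || length(between) > 2) {
    abort("`between` must name one or two factor columns.")
  }
  cols <- c(outcome, between, within, subject)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(sprintf("`data` is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  df <- as.data.frame(data[cols])
  for (f in c(between, within, subject)) df[[f]] <- factor(df[[f]])
  for (f in c(between, within)) {
    if (nlevels(df[[f]]) < 2) abort(sprintf("Factor `%s` needs >= 2 levels.", f))
  }
  if (!is.null(within) && is.null(subject)) {
    abort("`subject` is required for a repeated-measures (within) design.")
  }

  if (is.null(within)) {
    fml <- stats::reformulate(paste(between, collapse = " * "), response = outcome)
    fit <- aov(fml, data = df)
    sm <- summary(fit)[[1]]
    terms <- trimws(rownames(sm))
    idx <- terms != "Residuals"
    omnibus <- tibble(
      term = terms[idx],
      df1 = sm$Df[idx],
      df2 = sm$Df[!idx],
      statistic = sm$`F value`[idx],
      p_value = sm$`Pr(>F)`[idx]
    )
  } else {
    rhs <- paste(c(paste(between, collapse = " * "), within), collapse = " + ")
    fml <- stats::as.formula(sprintf("%s ~ %s * %s + Error(%s/%s)",
                                     outcome, paste(between, collapse = " * "),
                                     within, subject, within))
    fit <- aov(fml, data = df)
    omnibus <- purrr::map(summary(fit), function(stratum) {
      sm <- stratum[[1]]
      terms <- trimws(rownames(sm))
      idx <- which(terms != "Residuals")
      if (!length(idx)) return(NULL)
      tibble(term = terms[idx], df1 = sm$Df[idx],
             df2 = sm$Df[terms == "Residuals"],
             statistic = sm$`F value`[idx], p_value = sm$`Pr(>F)`[idx])
    }) %>% bind_rows()
  }

  ph <- NULL
  main_factor <- between[1]
  if (nlevels(df[[main_factor]]) >= 2) {
    if (posthoc == "tukey" && is.null(within)) {
      fit1 <- aov(stats::reformulate(main_factor, response = outcome), data = df)
      tk <- TukeyHSD(fit1)[[main_factor]]
      ph <- tibble(contrast = rownames(tk), estimate = tk[, "diff"],
                   p_adj = tk[, "p adj"], method = "tukey")
    } else {
      strata <- if (is.null(within)) list(all = df) else split(df, df[[within]])
      ph <- purrr::imap(strata, function(d, lev) {
        pt <- stats::pairwise.t.test(d[[outcome]], d[[main_factor]],
                                     p.adjust.method = "bonferroni")
        m <- pt$p.value
        idx <- which(!is.na(m), arr.ind = TRUE)
        tibble(
          contrast = paste(rownames(m)[idx[, 1]], colnames(m)[idx[, 2]], sep = "-"),
          at = if (is.null(within)) NA_character_ else lev,
          estimate = NA_real_,
          p_adj = m[idx], method = "bonferroni")
      }) %>% bind_rows()
    }
  }

  structure(
    list(outcome = outcome, between = between, within = within,
         posthoc_method = posthoc, alpha = alpha,
         omnibus = omnibus, posthoc = ph),
    class = "nmtf_anova"
  )
}

#' @export
print.nmtf_anova <- function(x, ...) {
  cat(sprintf("<nmtf_anova> %s ~ %s%s\n", x$outcome,
              paste(x$between, collapse = " * "),
              if (!is.null(x$within)) sprintf(" (repeated over %s)", x$within) else ""))
  for (i in seq_len(nrow(x$omnibus))) {
    cat(sprintf("  %s: F(%d,%d) = %.2f, p = %.4g\n",
                x$omnibus$term[i], x$omnibus$df1[i], x$omnibus$df2[i],
                x$omnibus$statistic[i], x$omnibus$p_value[i]))
  }
  invisible(x)
}

#' Power-based sample size per group
#'
#' Smallest `n` per group such that a two-sided two-sample t-test at level
#' `alpha` detects a difference of `detectable_fraction * reference_mean`
#' with the requested power, given SD `reference_sd`.  Power is evaluated
#' with the noncentral-t distribution (noncentrality `d * sqrt(n/2)` at
#' `2n - 2` degrees of freedom).
#'
#' @param reference_mean,reference_sd Reference mean and SD of the outcome.
#' @param detectable_fraction Detectable difference as a fraction of the
#'   mean, in `(0, 1]`.
#' @param alpha Type-I error rate.
#' @param power Target power.
#' @return Integer sample size per group (minimum 2).
#' @examples
#' power_n_per_group(10, 5, 1)      # d = 2 -> 6 per group
#' power_n_per_group(59.0, 8.5, 0.20)
#' @export
power_n_per_group <- function(reference_mean, reference_sd,
                              detectable_fraction, alpha = 0.05,
                              power = 0.80) {
  stopifnot_scalar_pos(reference_mean, "reference_mean")
  stopifnot_scalar_pos(reference_sd, "reference_sd")
  if (detectable_fraction <= 0 || detectable_fraction > 1) {
    abort("`detectable_fraction` must lie in (0, 1].")
  }
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    abort("`alpha` and `power` must lie in (0, 1).")
  }
  d <- detectable_fraction * reference_mean / reference_sd
  n <- 2L
  repeat {
    df <- 2 * n - 2
    ncp <- d * sqrt(n / 2)
    tc <- qt(1 - alpha / 2, df)
    pw <- 1 - pt(tc, df, ncp) + pt(-tc, df, ncp)
    if (pw >= power || n >= 1e6) break
    n <- n + 1L
  }
  n
}

#' Statistical report over a cohort table
#'
#' The cohort-level statistical layer applied per outcome: Shapiro-Wilk
#' normality check, single-pass two-SD outlier exclusion, then the ANOVA of
#' the requested design with post-tests.  Sexes are pooled by default; pass
#' `between = c("group", "sex")` for a stratified design.
#'
#' @param data Long data frame with one row per observation.
#' @param outcomes Character vector of outcome columns to analyse.
#' @param between,within,subject,posthoc,alpha Passed to [run_anova()].
#' @param screen_outliers Apply the two-SD exclusion rule per outcome
#'   before the ANOVA.
#' @return An object of class `nmtf_stats_report`: per-outcome list with the
#'   normality check, excluded points and the fitted `nmtf_anova`.  Use
#'   [tidy()] for a Table-style long summary.
#' @export
stats_report <- function(data, outcomes, between = "group", within = NULL,
                         subject = NULL, posthoc = c("tukey", "bonferroni"),
                         alpha = 0.05, screen_outliers = TRUE) {
  posthoc <- match.arg(posthoc)
  per_outcome <- purrr::map(outcomes, function(oc) {
    if (!oc %in% names(data)) abort(sprintf("Outcome `%s` not in data.", oc))
    d <- data[stats::complete.cases(data[[oc]]), , drop = FALSE]
    sw <- shapiro_normality(d[[oc]])
    excluded <- numeric(0)
    if (screen_outliers) {
      scr <- exclude_outliers(d[[oc]])
      excluded <- scr$excluded
      if (length(scr$excluded_idx)) d <- d[-scr$excluded_idx, , drop = FALSE]
    }
    list(outcome = oc, shapiro = sw, excluded = excluded,
         anova = run_anova(d, oc, between, within, subject, posthoc, alpha))
  })
  names(per_outcome) <- outcomes
  structure(list(outcomes = per_outcome, alpha = alpha),
            class = "nmtf_stats_report")
}

#' @export
print.nmtf_stats_report <- function(x, ...) {
  cat(sprintf("<nmtf_stats_report> %d outcome(s), alpha = %g\n",
              length(x$outcomes), x$alpha))
  for (oc in x$outcomes) {
    cat(sprintf("- %s (Shapiro-Wilk p = %.3g, %d excluded)\n",
                oc$outcome, oc$shapiro$p_value, length(oc$excluded)))
    print(oc$anova)
  }
  invisible(x)
}

#' Write a statistical report as Table-style CSV files
#'
#' Writes `<prefix>_anova.csv` (outcome, term, F, df1, df2, p) and
#' `<prefix>_posthoc.csv` (pairwise comparisons with adjusted p-values).
#'
#' @param report An `nmtf_stats_report`.
#' @param prefix File path prefix (directories must exist).
#' @return Invisibly, the paths written.
#' @export
write_stats_report <- function(report, prefix) {
  stopifnot(inherits(report, "nmtf_stats_report"))
  omni <- purrr::map(report$outcomes, function(oc) {
    oc$anova$omnibus %>%
      mutate(outcome = oc$outcome,
             shapiro_p = oc$shapiro$p_value,
             n_excluded = length(oc$excluded), .before = 1)
  }) %>% bind_rows()
  ph <- purrr::map(report$outcomes, function(oc) {
    if (is.null(oc$anova$posthoc)) return(NULL)
    oc$anova$posthoc %>% mutate(outcome = oc$outcome, .before = 1)
  }) %>% bind_rows()
  paths <- c(paste0(prefix, "_anova.csv"), paste0(prefix, "_posthoc.csv"))
  readr::write_csv(omni, paths[1])
  readr::write_csv(ph, paths[2])
  invisible(paths)
}
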