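#' Tidy a per-recording analysis
#'
#' @param x An `nmtf_analysis`.
#' @param ... Unused.
#' @return A long tibble with one row per scalar statistic: `animal_id`,
#'   `group`, `sex`, `statistic`, `value`.
#' @export
tidy.nmtf_analysis <- function(x, ...) {
  tibble(
    animal_id = x$animal_id, group = x$group, sex = x$sex,
    statistic = c("specific_force", "initial_nmtf", "final_nmtf",
                  "final_intratrain_fatigue"),
    value = c(x$specific_force, x$initial_nmtf, x$final_nmtf,
              x$final_intratrain_fatigue)
  )
}

#' Tidy an ANOVA report
#'
#' @param x An `nmtf_anova`.
#' @param effects `"omnibus"` (per-factor F tests) or `"posthoc"`
#'   (pairwise comparisons).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.nmtf_anova <- function(x, effects = c("omnibus", "posthoc"), ...) {
  effects <- match.arg(effects)
  if (effects == "omnibus") {
    x$omnibus %>% mutate(outcome = x$outcome, .before = 1)
  } else {
    (x$posthoc %||% tibble()) %>% mutate(outcome = x$outcome, .before = 1)
  }
}

#' One-row summary of an ANOVA report
#'
#' @param x An `nmtf_anova`.
#' @param ... Unused.
#' @return A one-row tibble with the first between-factor F test and
#'   significance at the report's alpha.
#' @export
glance.nmtf_anova <- function(x, ...) {
  main <- x$omnibus[x$omnibus$term == x$between[1], ][1, ]
  tibble(
    outcome = x$outcome,
    statistic = main$statistic,
    df1 = main$df1, df2 = main$df2,
    p_value = main$p_value,
    significant = main$p_value < x$alpha,
    posthoc_method = x$posthoc_method
  )
}

#' Tidy a cohort statistical report
#'
#' @param x An `nmtf_stats_report`.
#' @param ... Unused.
#' @return A long tibble mirroring an omnibus ANOVA table: one row per
#'   outcome and factor with F, degrees of freedom, p, the Shapiro-Wilk p
#'   and the number of excluded points.
#' @export
tidy.nmtf_stats_report <- function(x, ...) {
  purrr::map(x$outcomes, function(oc) {
    oc$anova$omnibus %>%
      mutate(outcome = oc$outcome, shapiro_p = oc$shapiro$p_value,
             n_excluded = length(oc$excluded), .before = 1)
  }) %>% bind_rows()
}
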