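#' Plot a force recording
#'
#' Force trace with superimposed-train epochs marked; a quick visual check
#' that the nerve-evoked plateaus decline faster than the muscle-evoked
#' ones when transmission fails.
#'
#' @param recording A `force_recording`.
#' @param window Optional time window `c(from, to)` in seconds.
#' @return A ggplot object.
#' @export
plot_recording <- function(recording, window = NULL) {
  df <- as_tibble(recording)
  if (!is.null(window)) {
    df <- df %>% filter(.data$time_s >= window[1], .data$time_s <= window[2])
  }
  sup <- df$time_s[df$muscle_stim > 0]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$force_N)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = "Force (N)",
                  title = sprintf("%s (%s)", recording$metadata$animal_id,
                                  recording$metadata$group)) +
    ggplot2::theme_minimal()
  if (length(sup)) {
    p <- p + ggplot2::geom_rug(
      data = tibble(time_s = sup, force_N = 0),
      sides = "b", colour = "red", alpha = 0.4, length = ggplot2::unit(0.03, "npc"))
  }
  p
}

#' @export
autoplot.nmtf_series <- function(object, ...) {
  df <- object %>%
    tidyr::pivot_longer(c("mf_norm", "nf_norm"), names_to = "channel",
                        values_to = "norm_force") %>%
    mutate(channel = dplyr::recode(.data$channel,
                                   mf_norm = "muscle-evoked",
                                   nf_norm = "nerve-evoked"))
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch_time, .data$norm_force,
                                   colour = .data$channel)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_line(data = object,
                       ggplot2::aes(.data$epoch_time, .data$nmtf / 100 + 1),
                       inherit.aes = FALSE, linetype = 2, colour = "grey40") +
    ggplot2::scale_y_continuous(
      "Normalised force",
      sec.axis = ggplot2::sec_axis(~ 100 * (. - 1), name = "NMTF (%)")) +
    ggplot2::labs(x = "Time (s)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-group cohort summaries
#'
#' Dot plot of a per-animal statistic with group means and 95% confidence
#' intervals, the standard presentation for cohort endpoints such as final
#' NMTF or specific force.
#'
#' @param summary Per-animal summary tibble (e.g.
#'   `analyze_trace_cohort()$summary`).
#' @param statistic Column to plot.
#' @return A ggplot object.
#' @export
plot_group_summary <- function(summary, statistic = "final_nmtf") {
  if (!statistic %in% names(summary)) {
    abort(sprintf("Column `%s` not found in summary.", statistic))
  }
  ggplot2::ggplot(summary,
                  ggplot2::aes(.data$group, .data[[statistic]])) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_cl_normal,
                          geom = "pointrange", colour = "red") +
    ggplot2::labs(x = NULL, y = statistic) +
    ggplot2::theme_minimal()
}

#' Plot an NMJ projection with its binary masks
#'
#' Side-by-side maximum-intensity projections of the endplate (BTX) and
#' terminal (SYN) channels, with the thresholded mask outlines available as
#' a quick QC of the morphometry inputs.
#'
#' @param projection An `nmj_projection` (see [project_stack()]).
#' @return A ggplot object.
#' @export
plot_nmj_projection <- function(projection) {
  stopifnot(inherits(projection, "nmj_projection"))
  to_df <- function(m, ch) {
    tibble(
      x = rep(seq_len(nrow(m)), ncol(m)),
      y = rep(seq_len(ncol(m)), each = nrow(m)),
      intensity = as.numeric(m),
      channel = ch
    )
  }
  df <- bind_rows(to_df(projection$post, "BTX (endplate)"),
                  to_df(projection$pre, "SYN (terminal)"))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::scale_fill_viridis_c(guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
}
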