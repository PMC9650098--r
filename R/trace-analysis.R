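#' Estimated muscle cross-sectional area of a diaphragm strip
#'
#' `CSA = strip weight (g) / (Lo (cm) x 1.056 g/cm^3)`, the standard wet-mass
#' estimate for a muscle strip of optimal length Lo and assumed density
#' 1.056 g/cm^3.
#'
#' @param strip_weight Strip weight, g.
#' @param optimal_length Optimal length Lo, cm.
#' @return Cross-sectional area, cm^2.
#' @examples
#' compute_muscle_csa(0.04224, 2.0)  # 0.02 cm^2
#' @export
compute_muscle_csa <- function(strip_weight, optimal_length) {
  stopifnot_scalar_pos(strip_weight, "strip_weight")
  stopifnot_scalar_pos(optimal_length, "optimal_length")
  strip_weight / (optimal_length * .muscle_density)
}

#' Specific force
#'
#' Force normalised to the estimated strip cross-sectional area, N/cm^2.
#'
#' @param peak_force Peak (plateau) force, N.
#' @param csa Cross-sectional area, cm^2 (see [compute_muscle_csa()]).
#' @return Specific force, N/cm^2.
#' @export
compute_specific_force <- function(peak_force, csa) {
  stopifnot_scalar_pos(csa, "csa")
  if (!is.numeric(peak_force) || peak_force < 0) {
    abort("`peak_force` must be a non-negative number.")
  }
  peak_force / csa
}

#' Initial neuromuscular transmission failure
#'
#' Percent difference between the first nerve-evoked and the first
#' muscle-evoked plateau force, `100 * (NF_init - MF_init) / MF_init`;
#' negative when the nerve-evoked force is lower (fibres already failing
#' transmission on the first train).
#'
#' @param nf_init First nerve-evoked plateau force, N.
#' @param mf_init First muscle-evoked plateau force, N.
#' @return Signed percent.
#' @export
compute_initial_nmtf <- function(nf_init, mf_init) {
  stopifnot_scalar_pos(mf_init, "mf_init")
  if (!is.numeric(nf_init) || nf_init < 0) {
    abort("`nf_init` must be a non-negative number.")
  }
  100 * (nf_init - mf_init) / mf_init
}

#' NMTF time course from per-epoch muscle and nerve forces
#'
#' Computes, at every assessed epoch, the neuromuscular transmission failure
#' statistic
#' \deqn{NMTF = -\left[\frac{MF/MF_{init} - NF/NF_{init}}{MF/MF_{init}}\right]
#'   \times 100}
#' which isolates the nerve-specific force loss from direct muscle fatigue:
#' muscle fibres that fail transmission are spared muscle-derived fatigue, so
#' only a differential decline of normalised nerve-evoked vs muscle-evoked
#' force counts as transmission failure.  The sign convention stores failure
#' as negative values (0 = no differential loss), matching how the statistic
#' is reported; the epoch-0 value is identically 0 because both normalised
#' forces are 1 there.
#'
#' @param data A data frame with one row per assessed epoch and columns
#'   `epoch_time` (s), `mf` (muscle-evoked plateau force) and `nf`
#'   (nerve-evoked plateau force), ordered by time.
#' @param mf_init,nf_init Initial forces; default to the first epoch's values.
#' @return A tibble of class `nmtf_series` with columns `epoch_time`, `mf`,
#'   `nf`, `mf_norm`, `nf_norm`, `nmtf`.
#' @examples
#' compute_nmtf_timecourse(
#'   tibble::tibble(epoch_time = c(0, 120), mf = c(1, 0.8), nf = c(1, 0.2)))
#' @export
compute_nmtf_timecourse <- function(data, mf_init = NULL, nf_init = NULL) {
  need <- c("epoch_time", "mf", "nf")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(sprintf("`data` is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(data) < 1) abort("`data` must contain at least one epoch.")
  mf_init <- mf_init %||% data$mf[1]
  nf_init <- nf_init %||% data$nf[1]
  stopifnot_scalar_pos(mf_init, "mf_init")
  stopifnot_scalar_pos(nf_init, "nf_init")
  if (any(data$mf < 0) || any(data$nf < 0)) {
    abort("Forces must be non-negative.")
  }
  out <- as_tibble(data[need]) %>%
    mutate(
      mf_norm = .data$mf / mf_init,
      nf_norm = .data$nf / nf_init,
      nmtf = -100 * (.data$mf_norm - .data$nf_norm) / .data$mf_norm
    )
  class(out) <- c("nmtf_series", class(out))
  out
}

#' Final NMTF of a time course
#'
#' @param series An `nmtf_series` (or any data frame with an `nmtf` column).
#' @return The NMTF value at the last assessed epoch, signed percent.
#' @export
final_nmtf <- function(series) {
  if (!"nmtf" %in% names(series) || nrow(series) < 1) {
    abort("`series` must contain an `nmtf` column with at least one epoch.")
  }
  series$nmtf[nrow(series)]
}

#' Intratrain fatigue of a single stimulus train
#'
#' Force droop within one train: `-100 * (max - min_after_peak) / max`, where
#' the minimum is taken between the time of the within-train maximum and the
#' end of the supplied window, so the rise phase and post-train relaxation do
#' not count as droop.  The trace is smoothed with a short moving average
#' before the extrema are read.
#'
#' @param force Force samples of the assessed window (for a superimposed
#'   train, the nerve-only portion before direct muscle stimulation begins).
#' @param sampling_rate Sampling rate, Hz.
#' @param smooth_ms Moving-average width, ms.
#' @return Signed percent in `[-100, 0]`.
#' @export
compute_intratrain_fatigue <- function(force, sampling_rate, smooth_ms = 5) {
  if (length(force) < 1) abort("Train window is empty.")
  stopifnot_scalar_pos(sampling_rate, "sampling_rate")
  k <- max(1L, as.integer(round(smooth_ms * sampling_rate / 1000)))
  sm <- smooth_trace(force, k)
  # the first/last half-window are not fully smoothed; keep the extrema
  # search inside the smoothed interior when the window allows it
  h <- k %/% 2
  idx <- if (length(sm) > 2 * (h + 1)) (h + 1):(length(sm) - h) else seq_along(sm)
  mx <- max(sm[idx])
  if (mx <= 0) abort("Maximum force within the train is zero.")
  i_max <- idx[which.max(sm[idx])]
  mn <- min(sm[i_max:idx[length(idx)]])
  -100 * (mx - mn) / mx
}

#' Detect stimulus trains in a force recording
#'
#' Groups nerve-stimulus marker pulses into trains and classifies each train
#' as nerve-only or superimposed (direct muscle stimulation present within
#' the train).  For superimposed trains the window is split at the first
#' muscle pulse, giving a nerve-only window and a muscle window within the
#' same train.  If marker channels are absent (or `use_markers = FALSE`),
#' onsets are recovered from the force trace itself by a two-pass threshold
#' (segments above `threshold_frac` of the global maximum, refined against
#' each train's local maximum); the fallback cannot classify superimposed
#' trains and is intended for marker-free archival traces.
#'
#' @param recording A `force_recording` (or compatible list with `time`,
#'   `force`, `nerve_stim`, `muscle_stim`, `sampling_rate`).
#' @param use_markers Use the stimulus marker channels (default) or the
#'   force-threshold fallback.
#' @param threshold_frac Fallback detection threshold as a fraction of the
#'   maximum force.
#' @return A tibble with one row per train: `train`, `onset`, `offset`,
#'   `superimposed`, `nerve_start`, `nerve_end`, `muscle_start`,
#'   `muscle_end` (s; muscle columns `NA` for nerve-only trains).
#' @export
detect_trains <- function(recording, use_markers = TRUE, threshold_frac = 0.05) {
  fs <- recording$sampling_rate
  have_markers <- use_markers && sum(recording$nerve_stim) > 0
  rising <- function(marker) {
    recording$time[which(diff(c(0L, as.integer(marker > 0))) == 1L)]
  }

  if (have_markers) {
    pulse_t <- rising(recording$nerve_stim)
    rate_guess <- 1 / min(diff(pulse_t))
    gap <- c(Inf, diff(pulse_t))
    grp <- cumsum(gap > 1.5 / rate_guess)
    onsets <- tapply(pulse_t, grp, min)
    last_pulse <- tapply(pulse_t, grp, max)
    offsets <- as.numeric(last_pulse) + 1 / rate_guess
    onsets <- as.numeric(onsets)
  } else {
    thr <- threshold_frac * max(recording$force)
    above <- recording$force > thr
    if (!any(above)) abort("No trains found in the recording.")
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    seg <- tibble(start = starts[r$values], end = ends[r$values])
    # merge runs separated by less than a third of a period-sized gap
    min_gap <- round(0.3 * fs)
    keep <- which(c(Inf, seg$start[-1] - seg$end[-nrow(seg)]) > min_gap)
    merged_start <- seg$start[keep]
    merged_end <- seg$end[c(keep[-1] - 1L, nrow(seg))]
    onsets <- offsets <- numeric(length(merged_start))
    for (i in seq_along(merged_start)) {
      # refine the onset against the early-train (nerve-rise) maximum, not
      # the whole-train maximum, so a large superimposed muscle plateau does
      # not inflate the local threshold and delay the crossing
      idx <- max(1L, merged_start[i] - round(0.03 * fs)):merged_end[i]
      early <- idx[idx <= merged_start[i] + round(0.12 * fs)]
      local_thr <- threshold_frac * max(recording$force[early])
      onsets[i] <- recording$time[idx[which(recording$force[idx] > local_thr)[1]]]
      offsets[i] <- recording$time[merged_end[i]]
    }
  }
  if (length(onsets) == 0) abort("No trains found in the recording.")

  if (length(onsets) > 2) {
    d <- diff(onsets)
    if (stats::sd(d) > 0.05 * median(d)) {
      warn("Train onsets are not on a regular grid; proceeding with detected onsets.")
    }
  }

  offsets <- pmin(offsets, c(onsets[-1], Inf))
  out <- tibble(
    train = seq_along(onsets),
    onset = onsets,
    offset = offsets,
    superimposed = FALSE,
    nerve_start = onsets,
    nerve_end = offsets,
    muscle_start = NA_real_,
    muscle_end = NA_real_
  )

  if (have_markers && sum(recording$muscle_stim) > 0) {
    mt <- recording$time[recording$muscle_stim > 0]
    for (i in seq_len(nrow(out))) {
      inside <- mt[mt >= out$onset[i] & mt < out$offset[i]]
      if (length(inside)) {
        out$superimposed[i] <- TRUE
        out$muscle_start[i] <- min(inside)
        out$muscle_end[i] <- min(out$offset[i], max(inside) + 1 / rate_guess)
        out$nerve_end[i] <- out$muscle_start[i]
      }
    }
  }
  out
}

#' Measure plateau forces and intratrain fatigue for detected trains
#'
#' Adds, per train, the smoothed peak force of the nerve-only window
#' (`nerve_peak`), of the muscle window for superimposed trains
#' (`muscle_peak`), the overall `peak_force` and `post_peak_min`, and for
#' superimposed trains the intratrain fatigue of the nerve-only window.
#'
#' @param recording A `force_recording`.
#' @param trains Output of [detect_trains()]; detected afresh by default.
#' @param smooth_ms Moving-average width used before peak extraction, ms.
#' @return The `trains` tibble with measurement columns appended.
#' @export
measure_trains <- function(recording, trains = detect_trains(recording),
                           smooth_ms = 5) {
  fs <- recording$sampling_rate
  k <- max(1L, as.integer(round(smooth_ms * fs / 1000)))
  sm <- smooth_trace(recording$force, k)
  t <- recording$time
  win <- function(a, b) which(t >= a & t < b)
  # keep peak searches half a smoother width away from window boundaries so
  # smoothed samples never mix in the adjacent stimulation segment
  h_t <- (k %/% 2) / fs

  res <- trains %>%
    mutate(nerve_peak = NA_real_, muscle_peak = NA_real_,
           peak_force = NA_real_, post_peak_min = NA_real_,
           intratrain_fatigue = NA_real_)
  for (i in seq_len(nrow(res))) {
    iw <- win(res$onset[i], res$offset[i])
    res$peak_force[i] <- max(sm[iw])
    imax <- iw[which.max(sm[iw])]
    res$post_peak_min[i] <- min(sm[imax:iw[length(iw)]])
    nw <- win(res$nerve_start[i], res$nerve_end[i])
    if (res$superimposed[i]) {
      nw_trim <- win(res$nerve_start[i], res$nerve_end[i] - h_t)
      if (length(nw_trim)) nw <- nw_trim
    }
    res$nerve_peak[i] <- max(sm[nw])
    if (res$superimposed[i]) {
      mw <- win(res$muscle_start[i] + h_t, res$muscle_end[i])
      if (!length(mw)) mw <- win(res$muscle_start[i], res$muscle_end[i])
      res$muscle_peak[i] <- max(sm[mw])
      res$intratrain_fatigue[i] <- compute_intratrain_fatigue(
        recording$force[win(res$nerve_start[i], res$nerve_end[i])], fs, smooth_ms)
    }
  }
  res
}

#' Analyze a force recording
#'
#' Full per-preparation analysis chain: detect trains, measure plateau
#' forces, and compute specific force (first muscle-evoked plateau over strip
#' CSA), initial NMTF, the NMTF time course over the superimposed epochs,
#' final NMTF, and the intratrain-fatigue series.
#'
#' @param recording A `force_recording`.
#' @param smooth_ms Moving-average width before peak extraction, ms.
#' @return An object of class `nmtf_analysis`: a list with scalar statistics
#'   (`csa`, `specific_force`, `initial_nmtf`, `final_nmtf`,
#'   `final_intratrain_fatigue`), the `nmtf` series tibble, the `intratrain`
#'   tibble, and the measured `trains` table.  Use [tidy()] for a long
#'   one-row-per-statistic tibble.
#' @export
analyze_recording <- function(recording, smooth_ms = 5) {
  proto <- recording$protocol
  n_expected <- ceiling(proto$total_duration / proto$train_period)
  t_last_expected <- (n_expected - 1) * proto$train_period
  if (max(recording$time) < t_last_expected) {
    abort(sprintf(
      "Recording is truncated: the final assessed epoch at %g s (train %d) is missing.",
      t_last_expected, n_expected))
  }

  trains <- measure_trains(recording, smooth_ms = smooth_ms)
  epochs <- trains %>% filter(.data$superimposed)
  if (nrow(epochs) < 2) {
    abort("Fewer than two superimposed epochs; cannot compute an NMTF time course.")
  }

  series <- compute_nmtf_timecourse(
    tibble(epoch_time = epochs$onset, mf = epochs$muscle_peak,
           nf = epochs$nerve_peak))
  csa <- compute_muscle_csa(recording$metadata$strip_weight,
                            recording$metadata$optimal_length)
  structure(
    list(
      animal_id = recording$metadata$animal_id,
      group = recording$metadata$group,
      sex = recording$metadata$sex,
      csa = csa,
      specific_force = compute_specific_force(epochs$muscle_peak[1], csa),
      initial_nmtf = compute_initial_nmtf(epochs$nerve_peak[1],
                                          epochs$muscle_peak[1]),
      final_nmtf = final_nmtf(series),
      final_intratrain_fatigue = epochs$intratrain_fatigue[nrow(epochs)],
      nmtf = series,
      intratrain = tibble(epoch_time = epochs$onset,
                          intratrain_fatigue = epochs$intratrain_fatigue),
      trains = trains
    ),
    class = "nmtf_analysis"
  )
}

#' @export
print.nmtf_analysis <- function(x, ...) {
  cat(sprintf(
    "<nmtf_analysis> %s (%s): specific force %.1f N/cm^2, initial NMTF %.1f%%, final NMTF %.1f%%, intratrain %.1f%%\n",
    x$animal_id, x$group, x$specific_force, x$initial_nmtf, x$final_nmtf,
    x$final_intratrain_fatigue))
  invisible(x)
}

#' Analyze a cohort of force recordings
#'
#' @param recordings A list of `force_recording` objects (e.g. from
#'   [simulate_cohort()]).
#' @param smooth_ms Moving-average width before peak extraction, ms.
#' @return A list of tibbles: `summary` (one row per animal with the scalar
#'   statistics), `timecourse` (per-animal per-epoch NMTF, long) and
#'   `intratrain` (per-animal per-epoch intratrain fatigue, long).
#' @export
analyze_trace_cohort <- function(recordings, smooth_ms = 5) {
  analyses <- purrr::map(recordings, analyze_recording, smooth_ms = smooth_ms)
  summary <- purrr::map(analyses, tidy) %>% bind_rows() %>%
    tidyr::pivot_wider(names_from = "statistic", values_from = "value")
  timecourse <- purrr::map(analyses, function(a) {
    tibble(animal_id = a$animal_id, group = a$group, sex = a$sex,
           epoch_time = a$nmtf$epoch_time, nmtf = a$nmtf$nmtf)
  }) %>% bind_rows()
  intratrain <- purrr::map(analyses, function(a) {
    tibble(animal_id = a$animal_id, group = a$group, sex = a$sex,
           epoch_time = a$intratrain$epoch_time,
           intratrain_fatigue = a$intratrain$intratrain_fatigue)
  }) %>% bind_rows()
  list(summary = summary, timecourse = timecourse, intratrain = intratrain)
}
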