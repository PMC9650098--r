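#' Simulate an isometric force recording under repetitive nerve stimulation
#'
#' Renders a force trace of the superimposed-stimulation NMTF protocol: the
#' phrenic nerve is stimulated in `train_duration`-long tetanic trains once
#' per `train_period`; every `superimpose_interval` seconds (and on the final
#' train) the muscle is additionally stimulated directly from
#' `superimpose_onset` to the end of the train, so that a nerve-only plateau
#' and a whole-muscle plateau can be read from the same train.  Plateau
#' amplitudes follow the closed forms of the [failure_model()]; the tetanic
#' envelope is a fused mono-exponential rise that reaches its plateau at
#' `5 * rise_tau` (individual 40 Hz pulses are not resolved, since all
#' statistics are computed from train plateaus), within-train droop is
#' applied to the nerve-driven component only, and relaxation after train
#' offset is exponential.
#'
#' @param protocol A [stim_protocol()].
#' @param prep A [prep_metadata()]; sets the absolute force scale through the
#'   strip cross-sectional area.
#' @param model A [failure_model()].
#' @param sampling_rate Transducer sampling rate, Hz.
#' @param seed Seed for the force-channel noise; `NULL` leaves the RNG state
#'   untouched.
#'
#' @return An object of class `force_recording`: a list with vectors `time`,
#'   `force`, `nerve_stim`, `muscle_stim`, scalars `sampling_rate`, and the
#'   `metadata`, `protocol` and `ground_truth` components.  `ground_truth`
#'   holds the analytic per-train muscle/nerve plateau forces (recorded
#'   before noise) plus the closed-form summary statistics of
#'   [trace_ground_truth_closed_form()].
#' @examples
#' rec <- simulate_recording(stim_protocol(total_duration = 30),
#'                           prep_metadata(),
#'                           group_calibrations()$vehicle, seed = 1)
#' @export
simulate_recording <- function(protocol = stim_protocol(),
                               prep = prep_metadata(),
                               model = failure_model(),
                               sampling_rate = 1000,
                               seed = NULL) {
  stopifnot(inherits(protocol, "stim_protocol"),
            inherits(prep, "prep_metadata"),
            inherits(model, "failure_model"))
  stopifnot_scalar_pos(sampling_rate, "sampling_rate")

  fs <- sampling_rate
  csa <- compute_muscle_csa(prep$strip_weight, prep$optimal_length)
  peak_force <- model$peak_specific_force * csa

  n_trains <- ceiling(protocol$total_duration / protocol$train_period)
  onsets <- (seq_len(n_trains) - 1) * protocol$train_period
  progress <- if (n_trains > 1) onsets / onsets[n_trains] else 0

  f_t <- model$f0 + (model$f_end - model$f0) * progress^model$gamma
  m_t <- 1 - (1 - model$m_end) * progress^model$fatigue_shape
  d_t <- model$d_end * progress
  amp_nerve <- peak_force * m_t * (1 - f_t)
  amp_muscle <- peak_force * m_t

  ratio <- onsets / protocol$superimpose_interval
  superimposed <- abs(ratio - round(ratio)) < 1e-9
  superimposed[n_trains] <- TRUE

  n <- round(protocol$total_duration * fs)
  time <- (seq_len(n) - 1) / fs
  force <- numeric(n)
  nerve_stim <- integer(n)
  muscle_stim <- integer(n)

  # clamped normalised mono-exponential: exactly 1 from 5*tau onwards
  rise <- function(t, tau) {
    ramp <- 5 * tau
    pmin(1, (1 - exp(-pmax(t, 0) / tau)) / (1 - exp(-ramp / tau)))
  }
  mark <- function(vec, t_pulse, width) {
    i0 <- round(t_pulse * fs) + 1L
    w <- max(1L, round(width * fs))
    for (i in i0) {
      j <- i:min(n, i + w - 1L)
      vec[j[j >= 1L & j <= n]] <- 1L
    }
    vec
  }

  n_pulses <- floor(protocol$train_duration * protocol$pulse_rate - 1e-9) + 1
  rise_ramp <- 5 * model$rise_tau

  for (k in seq_len(n_trains)) {
    on <- onsets[k]
    i0 <- round(on * fs) + 1L
    i1 <- min(n, round((on + protocol$train_period) * fs))
    t_rel <- time[i0:i1] - on

    w_nerve <- if (superimposed[k]) protocol$superimpose_onset else protocol$train_duration
    droop_start <- min(rise_ramp + model$plateau_hold, w_nerve)
    droop_floor <- max(droop_start, w_nerve - model$droop_floor_lead)
    g <- if (droop_floor > droop_start) {
      1 - d_t[k] * pmin(1, pmax(0, (t_rel - droop_start) / (droop_floor - droop_start)))
    } else {
      1 - d_t[k] * as.numeric(t_rel >= droop_start)
    }

    seg <- numeric(length(t_rel))
    in_nerve <- t_rel < w_nerve
    seg[in_nerve] <- amp_nerve[k] * rise(t_rel[in_nerve], model$rise_tau) * g[in_nerve]

    if (superimposed[k]) {
      in_muscle <- t_rel >= w_nerve & t_rel < protocol$train_duration
      level <- amp_nerve[k] * (1 - d_t[k])
      seg[in_muscle] <- level + (amp_muscle[k] - level) *
        rise(t_rel[in_muscle] - w_nerve, model$rise_tau)
      f_end_train <- level + (amp_muscle[k] - level) *
        rise(protocol$train_duration - w_nerve, model$rise_tau)
    } else {
      f_end_train <- amp_nerve[k] * (1 - d_t[k])
    }

    post <- t_rel >= protocol$train_duration
    seg[post] <- f_end_train *
      exp(-(t_rel[post] - protocol$train_duration) / model$relax_tau)

    force[i0:i1] <- seg

    pulse_times <- on + (seq_len(n_pulses) - 1) / protocol$pulse_rate
    nerve_stim <- mark(nerve_stim, pulse_times, protocol$nerve_pulse_width)
    if (superimposed[k]) {
      mt <- on + protocol$superimpose_onset +
        (seq_len(n_pulses) - 1) / protocol$pulse_rate
      mt <- mt[mt < on + protocol$train_duration]
      muscle_stim <- mark(muscle_stim, mt, protocol$muscle_pulse_width)
    }
  }

  ground_truth <- c(
    trace_ground_truth_closed_form(model),
    list(per_train = tibble(
      train = seq_len(n_trains),
      onset = onsets,
      progress = progress,
      superimposed = superimposed,
      mf_true = amp_muscle,
      nf_true = amp_nerve,
      droop_true = d_t
    ))
  )

  if (model$noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    force <- pmax(0, force + rnorm(n, sd = model$noise_sd * peak_force))
  }

  structure(
    list(time = time, force = force,
         nerve_stim = nerve_stim, muscle_stim = muscle_stim,
         sampling_rate = fs, metadata = prep, protocol = protocol,
         model = model, ground_truth = ground_truth),
    class = "force_recording"
  )
}

#' @export
print.force_recording <- function(x, ...) {
  cat(sprintf(
    "<force_recording> %s (%s): %.0f s at %g Hz, %d samples, %d nerve pulses\n",
    x$metadata$animal_id, x$metadata$group, max(x$time) + 1 / x$sampling_rate,
    x$sampling_rate, length(x$force), sum(x$nerve_stim > 0)))
  invisible(x)
}

#' @export
as_tibble.force_recording <- function(x, ...) {
  tibble(time_s = x$time, force_N = x$force,
         nerve_stim = x$nerve_stim, muscle_stim = x$muscle_stim)
}

#' Draw per-animal failure models for a simulated cohort
#'
#' Applies multiplicative Gaussian jitter to the group calibration parameters
#' (`f0`, `f_end`, `m_end`, `d_end`) to emulate between-animal dispersion,
#' clamps the draws to their physical ranges, and records each animal's
#' closed-form ground-truth statistics.  Useful on its own for power
#' simulations at the statistic level, without rendering waveforms.
#'
#' @param n_per_group Animals per group.
#' @param calibrations Named list of [failure_model()] objects, one per group
#'   (default [group_calibrations()]).
#' @param jitter_cv Named numeric vector of coefficients of variation for the
#'   jittered parameters.  Defaults approximate the dispersion of the
#'   published group means (95% CI about 3-8 percentage points on final NMTF
#'   and initial NMTF with n = 8).
#' @param base_seed Integer seed; all draws derive from it reproducibly.
#' @return A tibble with one row per animal: group, `animal_id`, `sex`, the
#'   jittered model parameters, and the closed-form `initial_nmtf`,
#'   `final_nmtf` and `final_intratrain_fatigue` truths.
#' @export
draw_cohort_models <- function(n_per_group = 8,
                               calibrations = group_calibrations(),
                               jitter_cv = c(f0 = 0.6, f_end = 0.05,
                                             m_end = 0.05, d_end = 0.4),
                               base_seed = 1) {
  if (n_per_group < 1) abort("`n_per_group` must be >= 1.")
  if (is.null(names(calibrations)) || any(!nzchar(names(calibrations)))) {
    abort("`calibrations` must be a named list of failure models, one per group.")
  }
  cv <- c(f0 = 0, f_end = 0, m_end = 0, d_end = 0)
  cv[names(jitter_cv)] <- jitter_cv

  set.seed(base_seed)
  rows <- purrr::imap(calibrations, function(cal, grp) {
    purrr::map(seq_len(n_per_group), function(i) {
      jit <- function(x, cvx, lo, hi) {
        if (cvx <= 0 || x == 0) return(max(lo, min(hi, x)))
        max(lo, min(hi, x * (1 + cvx * rnorm(1))))
      }
      f0 <- jit(cal$f0, cv[["f0"]], 0.005, 0.60)
      f_end <- jit(cal$f_end, cv[["f_end"]], f0, 0.98)
      m_end <- jit(cal$m_end, cv[["m_end"]], 0.30, 1.00)
      d_end <- jit(cal$d_end, cv[["d_end"]], 0.00, 0.60)
      m <- failure_model(
        f0 = f0, f_end = f_end, gamma = cal$gamma,
        m_end = m_end, fatigue_shape = cal$fatigue_shape, d_end = d_end,
        rise_tau = cal$rise_tau, relax_tau = cal$relax_tau,
        peak_specific_force = cal$peak_specific_force,
        noise_sd = cal$noise_sd,
        plateau_hold = cal$plateau_hold,
        droop_floor_lead = cal$droop_floor_lead)
      gt <- trace_ground_truth_closed_form(m)
      tibble(
        group = grp,
        animal_id = sprintf("%s_%02d", grp, i),
        sex = if (i %% 2 == 1) "female" else "male",
        f0 = f0, f_end = f_end, m_end = m_end, d_end = d_end,
        true_initial_nmtf = gt$initial_nmtf,
        true_final_nmtf = gt$final_nmtf,
        true_final_intratrain = gt$final_intratrain_fatigue,
        model = list(m)
      )
    }) %>% bind_rows()
  })
  bind_rows(rows)
}

#' Simulate a cohort of force recordings
#'
#' Draws jittered per-animal failure models with [draw_cohort_models()] and
#' renders one [simulate_recording()] per animal.  Per-animal noise seeds are
#' derived deterministically from `base_seed`, so two calls with the same
#' arguments are bit-identical.
#'
#' @inheritParams draw_cohort_models
#' @param protocol,sampling_rate Passed to [simulate_recording()].
#' @param strip_weight,optimal_length Preparation metadata shared across
#'   animals (g, cm).
#' @return A list with `recordings` (named list of `force_recording`) and
#'   `models` (the [draw_cohort_models()] tibble).
#' @export
simulate_cohort <- function(n_per_group = 8,
                            calibrations = group_calibrations(),
                            base_seed = 1,
                            jitter_cv = c(f0 = 0.6, f_end = 0.05,
                                          m_end = 0.05, d_end = 0.4),
                            protocol = stim_protocol(),
                            sampling_rate = 1000,
                            strip_weight = 0.04224,
                            optimal_length = 2.0) {
  models <- draw_cohort_models(n_per_group, calibrations, jitter_cv, base_seed)
  recordings <- purrr::map(seq_len(nrow(models)), function(i) {
    prep <- prep_metadata(strip_weight, optimal_length,
                          group = models$group[i],
                          animal_id = models$animal_id[i],
                          sex = models$sex[i])
    simulate_recording(protocol, prep, models$model[[i]],
                       sampling_rate = sampling_rate,
                       seed = (base_seed + 7919L * i) %% .Machine$integer.max)
  })
  names(recordings) <- models$animal_id
  list(recordings = recordings, models = models)
}
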