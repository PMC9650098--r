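#' Phenomenological transmission-failure model for the force generator
#'
#' Parameterises the two processes that shape diaphragm force during the
#' 120-s repetitive stimulation run: a nerve-specific transmission failure
#' fraction `f(s)` that removes force from nerve-evoked (but not directly
#' muscle-evoked) contractions, and a slower muscle-fatigue capacity `m(s)`
#' that scales both.  `s` is protocol progress, 0 at the first train and 1 at
#' the last.  Closed forms:
#'
#' \deqn{f(s) = f_0 + (f_{end} - f_0)\, s^{\gamma}}
#' \deqn{m(s) = 1 - (1 - m_{end})\, s^{\phi}}
#'
#' The nerve-evoked plateau force of the train at progress `s` is
#' `P m(s) (1 - f(s))` and the superimposed (direct muscle) plateau is
#' `P m(s)`, where `P` is the initial tetanic force.  A within-train droop of
#' the nerve-driven component ramps linearly from 0 to `d_end` across the
#' run.  The model is phenomenological: no quantal-release or vesicle-pool
#' mechanics are represented, only the force-level signatures the analyzers
#' measure.
#'
#' @param f0 Initial failure fraction in `[0, 1)`; the first nerve-evoked
#'   train produces `(1 - f0)` of the muscle-evoked force, so the initial
#'   NMTF is `-100 * f0` percent.
#' @param f_end Failure fraction at the final train, in `[0, 1)`.
#' @param gamma Ramp exponent (> 0) of the failure time course.
#' @param m_end Muscle capacity at the final train as a fraction of initial,
#'   in `(0, 1]`.
#' @param fatigue_shape Ramp exponent (> 0) of the muscle-fatigue decline.
#' @param d_end Within-train droop of the nerve-driven plateau at the final
#'   train, in `[0, 1)` (min/max within the assessed window is `1 - d_end`).
#' @param rise_tau Tetanic rise time constant, s.  The envelope is a
#'   normalised mono-exponential that reaches the plateau exactly at
#'   `5 * rise_tau` and holds it; individual 40 Hz pulses are fused.
#' @param relax_tau Exponential relaxation time constant after train offset, s.
#' @param peak_specific_force Initial tetanic specific force, N/cm^2; the
#'   absolute initial force is this value times the strip cross-sectional
#'   area from [compute_muscle_csa()].
#' @param noise_sd Additive Gaussian noise SD on the force channel as a
#'   fraction of the initial tetanic force.
#' @param plateau_hold Time the plateau is held flat before within-train
#'   droop begins, s.
#' @param droop_floor_lead Time before the end of the assessed window at
#'   which the droop reaches its floor `1 - d(s)` and settles, s.
#'
#' @return An object of class `failure_model`.
#' @seealso [calibrate_failure_model()], [group_calibrations()],
#'   [simulate_recording()]
#' @export
failure_model <- function(f0 = 0, f_end = 0, gamma = 1.5,
                          m_end = 1, fatigue_shape = 1.5,
                          d_end = 0,
                          rise_tau = 0.025, relax_tau = 0.030,
                          peak_specific_force = 22.3,
                          noise_sd = 0.005,
                          plateau_hold = 0.008,
                          droop_floor_lead = 0.008) {
  frac_in <- function(x, name, lo = 0, hi = 1, lo_open = FALSE, hi_open = TRUE) {
    ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
      (if (lo_open) x > lo else x >= lo) &&
      (if (hi_open) x < hi else x <= hi)
    if (!ok) abort(sprintf("`%s` must lie in %s%g, %g%s.", name,
                           if (lo_open) "(" else "[", lo, hi,
                           if (hi_open) ")" else "]"))
  }
  frac_in(f0, "f0"); frac_in(f_end, "f_end"); frac_in(d_end, "d_end")
  frac_in(m_end, "m_end", lo_open = TRUE, hi_open = FALSE)
  stopifnot_scalar_pos(gamma, "gamma")
  stopifnot_scalar_pos(fatigue_shape, "fatigue_shape")
  stopifnot_scalar_pos(rise_tau, "rise_tau")
  stopifnot_scalar_pos(relax_tau, "relax_tau")
  stopifnot_scalar_pos(peak_specific_force, "peak_specific_force")
  if (!is.numeric(noise_sd) || noise_sd < 0) abort("`noise_sd` must be >= 0.")
  structure(
    list(f0 = f0, f_end = f_end, gamma = gamma,
         m_end = m_end, fatigue_shape = fatigue_shape, d_end = d_end,
         rise_tau = rise_tau, relax_tau = relax_tau,
         peak_specific_force = peak_specific_force, noise_sd = noise_sd,
         plateau_hold = plateau_hold, droop_floor_lead = droop_floor_lead),
    class = "failure_model"
  )
}

#' @export
print.failure_model <- function(x, ...) {
  cat(sprintf(
    "<failure_model> f0=%.3f, f_end=%.3f (gamma %.2f), m_end=%.3f, droop_end=%.3f, noise %.2f%%\n",
    x$f0, x$f_end, x$gamma, x$m_end, x$d_end, 100 * x$noise_sd))
  invisible(x)
}

#' Calibrate a failure model to a target normalised nerve force
#'
#' Solves for the final failure fraction so that the normalised nerve-evoked
#' force at the end of the run, `NF/NF_init = m_end * (1 - f_end) / (1 - f0)`,
#' equals `nf_ratio_end`.  With muscle-evoked normalised force `MF/MF_init =
#' m_end`, the resulting final NMTF is
#' `-100 * (m_end - nf_ratio_end) / m_end`, so a printed group mean can be
#' dialled in directly.
#'
#' @param nf_ratio_end Target `NF/NF_init` at the final train, in `(0, 1]`.
#' @param m_end Muscle capacity at the final train (see [failure_model()]).
#' @param f0 Initial failure fraction.
#' @param ... Further arguments passed to [failure_model()].
#' @return A `failure_model`.
#' @examples
#' m <- calibrate_failure_model(0.2422, m_end = 0.700, f0 = 0.126)
#' trace_ground_truth_closed_form(m)$final_nmtf  # -65.4
#' @export
calibrate_failure_model <- function(nf_ratio_end, m_end = 0.700, f0 = 0.126,
                                    ...) {
  stopifnot_scalar_pos(nf_ratio_end, "nf_ratio_end")
  one_minus_fend <- nf_ratio_end * (1 - f0) / m_end
  if (one_minus_fend <= 0 || one_minus_fend > 1) {
    abort("Target nerve force ratio is unreachable for the given `m_end` and `f0`.")
  }
  failure_model(f0 = f0, f_end = 1 - one_minus_fend, m_end = m_end, ...)
}

#' Closed-form ground truth statistics of a failure model
#'
#' The analytic values of the statistics the trace analyzers estimate,
#' evaluated from the model's closed forms (no simulation, no noise).
#'
#' @param model A [failure_model()].
#' @return A list with `initial_nmtf`, `final_nmtf`,
#'   `final_intratrain_fatigue` (all signed percent, negative = failure /
#'   droop) and `specific_force` (N/cm^2).
#' @export
trace_ground_truth_closed_form <- function(model) {
  stopifnot(inherits(model, "failure_model"))
  nf_ratio <- model$m_end * (1 - model$f_end) / (1 - model$f0)
  list(
    initial_nmtf = -100 * model$f0,
    final_nmtf = -100 * (model$m_end - nf_ratio) / model$m_end,
    final_intratrain_fatigue = -100 * model$d_end,
    specific_force = model$peak_specific_force
  )
}

#' Per-group failure-model calibrations
#'
#' Default calibrations for the four treatment groups of the chemogenetic
#' TrkB-inhibition design, chosen so the closed-form group statistics equal
#' the published group means: initial NMTF (vehicle -12.6%, vehicle+1NMPP1
#' -20.5%, TKI -17.2%, TKI+BDNF -15.0%), final NMTF (-65.4, -86.4, -84.9,
#' -83.4%) and end-of-run intratrain fatigue (-1.9, -20.1, -22.1, -21.5%).
#' Muscle capacity at 120 s is 0.700 of initial in every group (direct muscle
#' fatigue is treatment-independent in this preparation).
#'
#' @param m_end Muscle capacity at the final train, shared across groups.
#' @param noise_sd Force-channel noise SD (fraction of initial force).
#' @return Named list of [failure_model()] objects, one per group.
#' @export
group_calibrations <- function(m_end = 0.700, noise_sd = 0.005) {
  spec <- list(
    vehicle        = list(f0 = 0.126, final_nmtf = -65.4, d_end = 0.019),
    vehicle_1nmpp1 = list(f0 = 0.205, final_nmtf = -86.4, d_end = 0.201),
    tki            = list(f0 = 0.172, final_nmtf = -84.9, d_end = 0.221),
    tki_bdnf       = list(f0 = 0.150, final_nmtf = -83.4, d_end = 0.215)
  )
  lapply(spec, function(g) {
    nf_ratio <- m_end * (1 + g$final_nmtf / 100)
    calibrate_failure_model(nf_ratio, m_end = m_end, f0 = g$f0,
                            d_end = g$d_end, noise_sd = noise_sd)
  })
}
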