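#' Stimulation protocol for the superimposed-stimulation NMTF assessment
#'
#' Describes the repetitive phrenic-nerve stimulation protocol used to induce
#' and quantify neuromuscular transmission failure (NMTF) in the ex vivo
#' phrenic nerve-diaphragm (Bulbring) preparation: 40 Hz trains of 330 ms
#' repeated each second (33% duty cycle) for 120 s, with direct muscle
#' stimulation superimposed on the second half of a train every 15 s.  The
#' final train of the run is always superimposed so that the end-of-protocol
#' muscle- and nerve-evoked forces are read from the same train.
#'
#' @param pulse_rate Stimulus pulse rate within a train, Hz.
#' @param train_duration Duration of each stimulus train, s.
#' @param train_period Interval between train onsets, s.
#' @param total_duration Total protocol duration, s.
#' @param superimpose_interval Interval between superimposed direct muscle
#'   stimulations, s.  Must be an integer multiple of `train_period`.
#' @param superimpose_onset Onset of the superimposed muscle stimulation
#'   within a train, s after train onset.  Must fall inside the train so a
#'   nerve-only plateau precedes it.
#' @param nerve_pulse_width,muscle_pulse_width Stimulus pulse widths, s.
#'
#' @return An object of class `stim_protocol` (a validated list).
#' @seealso [duty_cycle()], [simulate_recording()]
#' @examples
#' p <- stim_protocol()
#' duty_cycle(p)  # 33
#' @export
stim_protocol <- function(pulse_rate = 40,
                          train_duration = 0.330,
                          train_period = 1,
                          total_duration = 120,
                          superimpose_interval = 15,
                          superimpose_onset = 0.165,
                          nerve_pulse_width = 0.05e-3,
                          muscle_pulse_width = 0.5e-3) {
  for (nm in c("pulse_rate", "train_duration", "train_period",
               "total_duration", "superimpose_interval", "superimpose_onset",
               "nerve_pulse_width", "muscle_pulse_width")) {
    stopifnot_scalar_pos(get(nm), nm)
  }
  if (train_duration >= train_period) {
    abort("`train_duration` must be shorter than `train_period`.")
  }
  ratio <- superimpose_interval / train_period
  if (abs(ratio - round(ratio)) > 1e-9) {
    abort("`superimpose_interval` must be an integer multiple of `train_period`.")
  }
  if (superimpose_onset >= train_duration) {
    abort("`superimpose_onset` must fall within the train duration.")
  }
  structure(
    list(
      pulse_rate = pulse_rate,
      train_duration = train_duration,
      train_period = train_period,
      total_duration = total_duration,
      superimpose_interval = superimpose_interval,
      superimpose_onset = superimpose_onset,
      nerve_pulse_width = nerve_pulse_width,
      muscle_pulse_width = muscle_pulse_width
    ),
    class = "stim_protocol"
  )
}

#' Duty cycle of a stimulation protocol
#'
#' Percentage of each stimulation period occupied by the train
#' (`100 * train_duration / train_period`).
#'
#' @param protocol A [stim_protocol()].
#' @return Duty cycle in percent.
#' @export
duty_cycle <- function(protocol) {
  stopifnot(inherits(protocol, "stim_protocol"))
  100 * protocol$train_duration / protocol$train_period
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf(
    "<stim_protocol> %g Hz, %.0f-ms trains each %g s (%.0f%% duty) for %g s; muscle superimposed every %g s at +%.0f ms\n",
    x$pulse_rate, 1000 * x$train_duration, x$train_period, duty_cycle(x),
    x$total_duration, x$superimpose_interval, 1000 * x$superimpose_onset
  ))
  invisible(x)
}

#' Preparation metadata for a diaphragm strip
#'
#' Carries the physical quantities needed to normalise force to estimated
#' muscle cross-sectional area, plus experimental-design labels.
#'
#' @param strip_weight Muscle strip weight, g.
#' @param optimal_length Optimal muscle length (Lo) for isometric force, cm.
#' @param group Treatment group, one of `"vehicle"`, `"vehicle_1nmpp1"`,
#'   `"tki"`, `"tki_bdnf"` (vehicle, vehicle + acute 1NMPP1, chronic TrkB
#'   kinase inhibition, and TKI + acute BDNF).
#' @param animal_id Animal identifier.
#' @param sex `"female"` or `"male"`.
#' @return An object of class `prep_metadata`.
#' @export
prep_metadata <- function(strip_weight = 0.04224,
                          optimal_length = 2.0,
                          group = "vehicle",
                          animal_id = "A1",
                          sex = c("female", "male")) {
  stopifnot_scalar_pos(strip_weight, "strip_weight")
  stopifnot_scalar_pos(optimal_length, "optimal_length")
  group <- match.arg(group, .nmtf_groups)
  sex <- match.arg(sex)
  structure(
    list(
      strip_weight = strip_weight,
      optimal_length = optimal_length,
      muscle_density = .muscle_density,
      group = group,
      animal_id = as.character(animal_id),
      sex = sex
    ),
    class = "prep_metadata"
  )
}

#' @export
print.prep_metadata <- function(x, ...) {
  cat(sprintf("<prep_metadata> %s (%s, %s): %.5f g, Lo %.2f cm\n",
              x$animal_id, x$group, x$sex, x$strip_weight, x$optimal_length))
  invisible(x)
}
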