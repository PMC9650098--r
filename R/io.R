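#' Write / read a force recording as CSV + JSON sidecar
#'
#' The trace is stored as a four-column CSV (`time_s`, `force_N`,
#' `nerve_stim`, `muscle_stim`); preparation metadata, the stimulation
#' protocol and (when present) the generator ground truth go to a JSON
#' sidecar next to it.  Doubles are serialised at full precision, so
#' write-then-read is an identity up to floating-point round-trip.
#'
#' @param recording A `force_recording`.
#' @param path CSV path; the sidecar is written at the same path with a
#'   `.json` extension.
#' @return Invisibly, the two paths written.
#' @export
write_trace <- function(recording, path) {
  stopifnot(inherits(recording, "force_recording"))
  readr::write_csv(as_tibble(recording), path)
  gt <- recording$ground_truth
  sidecar <- list(
    sampling_rate_hz = recording$sampling_rate,
    strip_weight_g = recording$metadata$strip_weight,
    Lo_cm = recording$metadata$optimal_length,
    muscle_density_g_cm3 = recording$metadata$muscle_density,
    group = recording$metadata$group,
    animal_id = recording$metadata$animal_id,
    sex = recording$metadata$sex,
    protocol = unclass(recording$protocol),
    ground_truth = if (!is.null(gt)) {
      c(gt[setdiff(names(gt), "per_train")],
        list(per_train = as.data.frame(gt$per_train)))
    }
  )
  json_path <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(path, json_path))
}

#' @rdname write_trace
#' @param csv_path Path of the trace CSV.
#' @param sidecar_path Path of the JSON sidecar; defaults to the CSV path
#'   with a `.json` extension.
#' @return `read_trace()` returns a `force_recording`.
#' @export
read_trace <- function(csv_path, sidecar_path = sub("\\.csv$", ".json", csv_path)) {
  tr <- readr::read_csv(csv_path, show_col_types = FALSE)
  need <- c("time_s", "force_N", "nerve_stim", "muscle_stim")
  missing_cols <- setdiff(need, names(tr))
  if (length(missing_cols)) {
    abort(sprintf("Trace CSV is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  if (!file.exists(sidecar_path)) {
    abort(sprintf("Sidecar not found: %s", sidecar_path))
  }
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (nm in c("sampling_rate_hz", "strip_weight_g", "Lo_cm", "group",
               "animal_id")) {
    if (is.null(sc[[nm]])) abort(sprintf("Sidecar is missing field `%s`.", nm))
  }
  if (sc$Lo_cm <= 0 || sc$strip_weight_g <= 0) {
    abort("Sidecar strip weight and Lo must be positive.")
  }
  expected_n <- round(sc$protocol$total_duration * sc$sampling_rate_hz)
  if (abs(nrow(tr) - expected_n) > 1) {
    abort(sprintf(
      "Trace length (%d samples) does not match the sidecar protocol (%d expected).",
      nrow(tr), expected_n))
  }
  proto <- do.call(stim_protocol, sc$protocol[names(formals(stim_protocol))[
    names(formals(stim_protocol)) %in% names(sc$protocol)]])
  prep <- prep_metadata(sc$strip_weight_g, sc$Lo_cm, group = sc$group,
                        animal_id = sc$animal_id,
                        sex = sc$sex %||% "female")
  gt <- sc$ground_truth
  if (!is.null(gt) && !is.null(gt$per_train)) {
    gt$per_train <- as_tibble(gt$per_train)
  }
  structure(
    list(time = tr$time_s, force = tr$force_N,
         nerve_stim = as.integer(tr$nerve_stim),
         muscle_stim = as.integer(tr$muscle_stim),
         sampling_rate = sc$sampling_rate_hz,
         metadata = prep, protocol = proto, ground_truth = gt),
    class = "force_recording"
  )
}

#' Write / read a two-channel NMJ stack as multi-page TIFF + JSON sidecar
#'
#' Pages are channel-major (all z-slices of channel 1, then channel 2), as
#' declared in the sidecar.  Intensities are written as 16-bit integers, so
#' the round-trip is lossless for integer data in `[0, 65535]`.
#'
#' @param stack An `nmj_stack`.
#' @param path TIFF path; the sidecar is written alongside with a `.json`
#'   extension.
#' @return Invisibly, the two paths written.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "nmj_stack"))
  ns <- dim(stack$post)[3]
  pages <- c(
    lapply(seq_len(ns), function(s) stack$post[, , s] / 65535),
    lapply(seq_len(ns), function(s) stack$pre[, , s] / 65535)
  )
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  sidecar <- list(
    pixel_size_um = stack$pixel_size,
    z_step_um = stack$z_step,
    n_slices = ns,
    channels = stack$channels,
    page_order = "channel_major",
    fiber_diameter_um = stack$meta$fiber_diameter,
    seed = stack$meta$seed
  )
  json_path <- sub("\\.tiff?$", ".json", path)
  jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(path, json_path))
}

#' @rdname write_stack
#' @param tiff_path Path of the stack TIFF.
#' @param sidecar_path Path of the JSON sidecar; defaults to the TIFF path
#'   with a `.json` extension.
#' @return `read_stack()` returns an `nmj_stack`.
#' @export
read_stack <- function(tiff_path,
                       sidecar_path = sub("\\.tiff?$", ".json", tiff_path)) {
  if (!file.exists(sidecar_path)) {
    abort(sprintf("Sidecar not found: %s", sidecar_path))
  }
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(sc$pixel_size_um)) abort("Sidecar is missing `pixel_size_um`.")
  if (length(sc$channels) != 2) {
    abort(sprintf("Unsupported channel count: %d (two channels expected).",
                  length(sc$channels)))
  }
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  ns <- sc$n_slices
  if (length(pages) != 2 * ns) {
    abort(sprintf("Page count (%d) does not match sidecar (2 x %d slices).",
                  length(pages), ns))
  }
  d <- dim(pages[[1]])
  to_vol <- function(idx) {
    vol <- array(0, dim = c(d[1], d[2], ns))
    for (s in seq_len(ns)) vol[, , s] <- round(pages[[idx + s]] * 65535)
    vol
  }
  structure(
    list(post = to_vol(0), pre = to_vol(ns),
         pixel_size = sc$pixel_size_um, z_step = sc$z_step_um,
         channels = sc$channels,
         meta = list(fiber_diameter = sc$fiber_diameter_um, seed = sc$seed)),
    class = "nmj_stack"
  )
}

#' Run configuration for an end-to-end simulated study
#'
#' A fully serialisable description of one reproducible run: protocol
#' overrides, cohort sizes, per-group calibrations, NMJ cohort settings,
#' thresholding, and the master seed.  A run is reproducible from
#' `(config, seed)` alone.
#'
#' @param n_per_group Animals per treatment group for the force cohort.
#' @param groups Character vector of group names (subset of the four-group
#'   design) used to pick calibrations.
#' @param base_seed Master seed for the whole run.
#' @param protocol Named list of [stim_protocol()] overrides.
#' @param nmj_n_per_class,nmj_n_animals NMJ cohort sizes.
#' @param nmj_canvas,nmj_n_slices NMJ rendering size parameters.
#' @param threshold Threshold method for morphometry (`"otsu"` or
#'   `"fixed"`).
#' @param threshold_value Fixed threshold value if `threshold = "fixed"`.
#' @return A named list of class `nmtf_run_config`.
#' @export
run_config <- function(n_per_group = 8,
                       groups = .nmtf_groups,
                       base_seed = 1,
                       protocol = list(),
                       nmj_n_per_class = 5,
                       nmj_n_animals = 4,
                       nmj_canvas = 256,
                       nmj_n_slices = 8,
                       threshold = "otsu",
                       threshold_value = NULL) {
  groups <- match.arg(groups, .nmtf_groups, several.ok = TRUE)
  structure(
    list(n_per_group = n_per_group, groups = groups, base_seed = base_seed,
         protocol = protocol, nmj_n_per_class = nmj_n_per_class,
         nmj_n_animals = nmj_n_animals, nmj_canvas = nmj_canvas,
         nmj_n_slices = nmj_n_slices, threshold = threshold,
         threshold_value = threshold_value),
    class = "nmtf_run_config"
  )
}

#' Read a run configuration from YAML or JSON
#'
#' @param path Path to a `.yml`/`.yaml` or `.json` file whose keys are
#'   [run_config()] arguments.
#' @return A `nmtf_run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    abort(sprintf("Unknown config key(s): %s.", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, cfg)
}

#' Run the full simulate-analyze-report pipeline
#'
#' Simulates a force-recording cohort and an NMJ cohort under `config`,
#' analyses both, runs the statistical report, and writes all result tables
#' plus a provenance manifest into `out_dir`.  Rerunning with the same
#' config and seed reproduces the outputs exactly.  If the configured group
#' size is below the power-based requirement for the principal outcome, the
#' manifest (and a warning) flag the design as underpowered.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the result tables and the manifest.
#' @export
run_end_to_end <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "nmtf_run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  proto <- do.call(stim_protocol, config$protocol)
  cals <- group_calibrations()[config$groups]
  cohort <- simulate_cohort(config$n_per_group, cals,
                            base_seed = config$base_seed, protocol = proto)
  traces <- analyze_trace_cohort(cohort$recordings)
  readr::write_csv(traces$summary, file.path(out_dir, "trace_summary.csv"))
  readr::write_csv(traces$timecourse, file.path(out_dir, "trace_timecourse.csv"))
  readr::write_csv(traces$intratrain, file.path(out_dir, "trace_intratrain.csv"))

  nmj <- generate_nmj_cohort(config$nmj_n_per_class, config$nmj_n_animals,
                             seed = config$base_seed,
                             canvas = config$nmj_canvas,
                             n_slices = config$nmj_n_slices)
  nmj_res <- analyze_nmj_cohort(nmj, method = config$threshold,
                                value = config$threshold_value)
  readr::write_csv(nmj_res$per_nmj %>% select(-dplyr::any_of("stack")),
                   file.path(out_dir, "nmj_per_nmj.csv"))
  readr::write_csv(nmj_res$per_animal_class,
                   file.path(out_dir, "nmj_per_animal_class.csv"))
  readr::write_csv(nmj_res$per_animal, file.path(out_dir, "nmj_per_animal.csv"))

  outcomes <- c("final_nmtf", "initial_nmtf", "specific_force",
                "final_intratrain_fatigue")
  report <- if (length(config$groups) >= 2 &&
                config$n_per_group * length(config$groups) >= 4) {
    stats_report(traces$summary, outcomes, between = "group",
                 posthoc = "tukey")
  }
  if (!is.null(report)) write_stats_report(report, file.path(out_dir, "stats"))

  n_needed <- power_n_per_group(59.0, 8.5, 0.20)
  underpowered <- config$n_per_group < n_needed
  if (underpowered) {
    warn(sprintf(
      "Design is underpowered: %d per group configured, %d required for a 20%% difference.",
      config$n_per_group, n_needed))
  }

  files <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("nmtf")),
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    base_seed = config$base_seed,
    underpowered = underpowered,
    n_required_per_group = n_needed,
    outputs = as.list(setNames(unname(tools::md5sum(files)), basename(files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(traces = traces, nmj = nmj_res, report = report,
                 manifest = manifest))
}
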