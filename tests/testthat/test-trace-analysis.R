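test_that("muscle CSA follows the weight / (Lo x density) estimate", {
  expect_equal(compute_muscle_csa(0.04224, 2.0), 0.0200, tolerance = 1e-12)
  expect_equal(compute_muscle_csa(1.056, 1.0), 1.0, tolerance = 1e-12)
  expect_equal(compute_muscle_csa(0.0422, 2.0), 0.0422 / 2.112,
               tolerance = 1e-12)
  expect_error(compute_muscle_csa(0, 2), "positive")
  expect_error(compute_muscle_csa(0.04, -2), "positive")
})

test_that("specific force is force over CSA", {
  expect_equal(compute_specific_force(0.446, 0.0200), 22.3, tolerance = 1e-9)
  expect_equal(compute_specific_force(0, 0.5), 0)
  expect_equal(compute_specific_force(1, 1), 1)
  expect_error(compute_specific_force(1, 0), "positive")
})

test_that("NMTF formula isolates nerve-specific decline with a negative sign", {
  # equal normalised declines: no transmission failure at any epoch
  eq <- compute_nmtf_timecourse(
    tibble::tibble(epoch_time = c(0, 60, 120), mf = c(1, 0.8, 0.6),
                   nf = c(2, 1.6, 1.2)))
  expect_equal(eq$nmtf, c(0, 0, 0))
  # hand arithmetic: (0.8 - 0.2) / 0.8 x 100 = 75
  s <- compute_nmtf_timecourse(
    tibble::tibble(epoch_time = c(0, 120), mf = c(1, 0.8), nf = c(1, 0.2)))
  expect_equal(final_nmtf(s), -75.0)
  # hand arithmetic: (0.700 - 0.2422) / 0.700 x 100 = 65.4
  s2 <- compute_nmtf_timecourse(
    tibble::tibble(epoch_time = c(0, 120), mf = c(1, 0.700),
                   nf = c(1, 0.2422)))
  expect_equal(final_nmtf(s2), -65.4, tolerance = 1e-9)
  # epoch 0 is identically zero by construction
  expect_equal(s2$nmtf[1], 0)
})

test_that("NMTF time course enforces its contracts", {
  expect_error(compute_nmtf_timecourse(
    tibble::tibble(epoch_time = 0, mf = 0, nf = 1)), "positive")
  expect_error(compute_nmtf_timecourse(tibble::tibble(epoch_time = 0, mf = 1)),
               "missing column")
  expect_error(compute_nmtf_timecourse(
    tibble::tibble(epoch_time = c(0, 15), mf = c(1, -0.1), nf = c(1, 0.5))),
    "non-negative")
})

test_that("initial NMTF is the percent nerve/muscle force difference", {
  expect_equal(compute_initial_nmtf(1, 1), 0)
  expect_equal(compute_initial_nmtf(0.874, 1), -12.6, tolerance = 1e-9)
  expect_equal(compute_initial_nmtf(0, 1), -100)
  expect_error(compute_initial_nmtf(1, 0), "positive")
})

test_that("intratrain fatigue is the post-peak droop of the train plateau", {
  fs <- 1000
  flat <- c(seq(0, 1, length.out = 30), rep(1, 120))
  expect_equal(compute_intratrain_fatigue(flat, fs), 0, tolerance = 1e-9)
  droop <- function(floor_frac) {
    c(seq(0, 1, length.out = 30), rep(1, 30),
      seq(1, floor_frac, length.out = 80), rep(floor_frac, 25))
  }
  expect_equal(compute_intratrain_fatigue(droop(0.799), fs), -20.1,
               tolerance = 0.05)
  expect_equal(compute_intratrain_fatigue(droop(0.981), fs), -1.9,
               tolerance = 0.05)
  # relaxation after the window is excluded by construction of the window
  expect_error(compute_intratrain_fatigue(rep(0, 100), fs), "zero")
  expect_error(compute_intratrain_fatigue(numeric(0), fs), "empty")
})

test_that("train detection from force thresholds matches marker detection", {
  rec <- simulate_recording(short_protocol(), model = vehicle_model_quiet())
  tm <- detect_trains(rec)
  tf <- detect_trains(rec, use_markers = FALSE)
  expect_equal(nrow(tf), nrow(tm))
  expect_true(all(abs(tf$onset - tm$onset) <= 2 / rec$sampling_rate + 1e-9))
})

test_that("detection fails loudly on an empty recording", {
  flat <- list(time = seq(0, 1, by = 1e-3), force = rep(0, 1001),
               nerve_stim = integer(1001), muscle_stim = integer(1001),
               sampling_rate = 1000)
  expect_error(detect_trains(flat, use_markers = FALSE), "No trains")
})

test_that("analysis recovers every closed-form statistic on noise-free input", {
  model <- vehicle_model_quiet()
  rec <- simulate_recording(model = model)
  a <- analyze_recording(rec)
  gt <- rec$ground_truth
  expect_equal(a$final_nmtf, gt$final_nmtf, tolerance = 0.1)
  expect_equal(a$initial_nmtf, gt$initial_nmtf, tolerance = 0.1)
  expect_equal(a$final_intratrain_fatigue, gt$final_intratrain_fatigue,
               tolerance = 0.1)
  expect_equal(a$specific_force, gt$specific_force, tolerance = 0.1)
  # per-epoch NMTF stays within the sign convention
  expect_true(all(a$nmtf$nmtf <= 1e-6))
  expect_true(all(a$nmtf$nmtf >= -100))
})

test_that("cohort means stay within a point of truth under realistic noise", {
  model <- group_calibrations()$vehicle
  finals <- vapply(1:4, function(s) {
    analyze_recording(simulate_recording(model = model, seed = s))$final_nmtf
  }, numeric(1))
  expect_equal(mean(finals), -65.4, tolerance = 1)
})

test_that("a truncated recording errors naming the missing final epoch", {
  rec <- simulate_recording(model = vehicle_model_quiet())
  cut <- round(length(rec$force) * 0.25)
  for (f in c("time", "force", "nerve_stim", "muscle_stim")) {
    rec[[f]] <- rec[[f]][seq_len(cut)]
  }
  expect_error(analyze_recording(rec), "final assessed epoch")
})

test_that("tidy() and cohort analysis give long per-animal statistics", {
  co <- simulate_cohort(1, base_seed = 5, protocol = short_protocol())
  res <- analyze_trace_cohort(co$recordings)
  expect_equal(nrow(res$summary), 4)
  expect_true(all(c("specific_force", "initial_nmtf", "final_nmtf",
                    "final_intratrain_fatigue") %in% names(res$summary)))
  expect_equal(nrow(res$timecourse), 4 * 3)  # 3 superimposed epochs at 30 s
  a <- analyze_recording(co$recordings[[1]])
  td <- tidy(a)
  expect_equal(nrow(td), 4)
  expect_true(all(c("statistic", "value") %in% names(td)))
})
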