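test_that("no-failure model yields constant equal nerve and muscle forces", {
  model <- failure_model(f0 = 0, f_end = 0, m_end = 1, d_end = 0, noise_sd = 0)
  rec <- simulate_recording(short_protocol(), model = model)
  pt <- rec$ground_truth$per_train
  expect_equal(pt$mf_true, pt$nf_true)
  expect_lt(diff(range(pt$mf_true)), 1e-12)
  expect_equal(rec$ground_truth$final_nmtf, 0)
  a <- analyze_recording(rec)
  expect_equal(a$final_nmtf, 0, tolerance = 1e-6)
  expect_equal(a$initial_nmtf, 0, tolerance = 1e-6)
})

test_that("simulated trains follow the protocol grid", {
  rec <- simulate_recording(model = vehicle_model_quiet())
  trains <- detect_trains(rec)
  expect_equal(nrow(trains), 120)
  expect_equal(sum(trains$superimposed), 9)
  # superimposed epochs sit on the 15-s grid plus the final train
  expect_equal(trains$onset[trains$superimposed],
               c(seq(0, 105, by = 15), 119))
  short <- detect_trains(simulate_recording(short_protocol(),
                                            model = vehicle_model_quiet()))
  expect_equal(nrow(short), 30)
  expect_equal(sum(short$superimposed), 3)
})

test_that("marker channels respect pulse widths and the duty cycle", {
  rec <- simulate_recording(short_protocol(5), model = vehicle_model_quiet())
  # 40 Hz pulses within each 330-ms train: onsets every 25 ms
  pulse_idx <- which(diff(c(0L, rec$nerve_stim)) == 1L)
  first_train <- pulse_idx[pulse_idx <= rec$sampling_rate]
  expect_equal(diff(first_train), rep(25, length(first_train) - 1))
  expect_equal(duty_cycle(rec$protocol), 33)
})

test_that("generator rejects invalid inputs", {
  expect_error(simulate_recording(sampling_rate = 0), "positive")
  expect_error(simulate_recording(sampling_rate = -10), "positive")
})

test_that("noise is reproducible and seeds make runs bit-identical", {
  model <- group_calibrations()$vehicle
  r1 <- simulate_recording(short_protocol(), model = model, seed = 7)
  r2 <- simulate_recording(short_protocol(), model = model, seed = 7)
  expect_identical(r1$force, r2$force)
  r3 <- simulate_recording(short_protocol(), model = model, seed = 8)
  expect_false(identical(r1$force, r3$force))
})

test_that("ground-truth final NMTF is recorded before noise", {
  model <- group_calibrations()$tki
  rec <- simulate_recording(short_protocol(), model = model, seed = 1)
  expect_equal(rec$ground_truth$final_nmtf, -84.9, tolerance = 1e-9)
})

test_that("increasing the final failure fraction strictly worsens final NMTF", {
  finals <- vapply(c(0.2, 0.4, 0.6, 0.8), function(fe) {
    m <- failure_model(f0 = 0.1, f_end = fe, m_end = 0.8, noise_sd = 0)
    trace_ground_truth_closed_form(m)$final_nmtf
  }, numeric(1))
  expect_true(all(diff(finals) < 0))
  # and the recovered statistic follows suit on rendered traces
  rec_finals <- vapply(c(0.3, 0.6), function(fe) {
    m <- failure_model(f0 = 0.1, f_end = fe, m_end = 0.8, noise_sd = 0)
    analyze_recording(simulate_recording(short_protocol(), model = m))$final_nmtf
  }, numeric(1))
  expect_lt(rec_finals[2], rec_finals[1])
})

test_that("recovered NMTF is invariant to the muscle-fatigue level", {
  finals <- vapply(c(1.0, 0.85, 0.70), function(m_end) {
    m <- failure_model(f0 = 0.126, f_end = 0.6, m_end = m_end,
                       d_end = 0, noise_sd = 0)
    analyze_recording(simulate_recording(model = m))$final_nmtf
  }, numeric(1))
  expect_lt(diff(range(finals)), 0.5)
})

test_that("cohort simulation is sized, seeded and calibrated per group", {
  co <- simulate_cohort(2, base_seed = 11, protocol = short_protocol())
  expect_length(co$recordings, 8)  # 2 per group x 4 groups
  expect_equal(sort(unique(co$models$group)),
               sort(c("vehicle", "vehicle_1nmpp1", "tki", "tki_bdnf")))
  co2 <- simulate_cohort(2, base_seed = 11, protocol = short_protocol())
  expect_identical(co$recordings[[1]]$force, co2$recordings[[1]]$force)
  expect_error(draw_cohort_models(2, calibrations = list(failure_model())),
               "named list")
  expect_error(draw_cohort_models(0), ">= 1")
})

test_that("zero jitter and zero noise collapse a group to one truth value", {
  cal <- list(vehicle = vehicle_model_quiet())
  m <- draw_cohort_models(4, cal, jitter_cv = c(f0 = 0, f_end = 0,
                                                m_end = 0, d_end = 0),
                          base_seed = 3)
  expect_equal(length(unique(m$true_final_nmtf)), 1L)
  expect_equal(m$true_final_nmtf[1], -65.4, tolerance = 1e-9)
})
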