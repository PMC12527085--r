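test_that("activity scripts have the documented structure", {
  p <- sim_params(trial_duration_s = 180, n_sit_phases = 3)
  s <- make_script(p, seed = 4)
  expect_equal(s$state[1], "SIT")  # trial begins seated
  expect_equal(sum(s$state == "SIT"), 3)
  expect_equal(sum(s$state == "TRANSITION_UP"), 3)
  expect_equal(sum(s$state == "TRANSITION_DOWN"), 2)
  expect_equal(sum(s$duration_s), 180, tolerance = 1e-9)
  expect_true(all(s$duration_s > 0))
  # every SIT exits through a TRANSITION_UP; later SITs enter through a
  # TRANSITION_DOWN
  sit_idx <- which(s$state == "SIT")
  expect_true(all(s$state[sit_idx + 1] == "TRANSITION_UP"))
  expect_true(all(s$state[sit_idx[-1] - 1] == "TRANSITION_DOWN"))

  expect_equal(make_script(p, seed = 4), make_script(p, seed = 4))
  expect_false(isTRUE(all.equal(make_script(p, seed = 5), s)))

  over <- sim_params(trial_duration_s = 180, n_sit_phases = 10,
                     sit_duration_s = c(30, 30))
  expect_error(make_script(over, seed = 1), class = "sitseg_parameter_error")
})

test_that("a noise-free seated segment is static at 1 g", {
  p <- sim_params(noise_acc_sd_g = 0, noise_gyr_sd_deg_s = 0)
  script <- tibble::tibble(state = "SIT", duration_s = 60)
  sim <- synthesize(script, p, seed = 1)
  rec <- sim$recording
  mag_acc <- magnitude(rec$acc_x, rec$acc_y, rec$acc_z)
  mag_gyr <- magnitude(rec$gyr_x, rec$gyr_y, rec$gyr_z)
  expect_equal(mag_acc, rep(1, nrow(rec)), tolerance = 1e-9)
  expect_equal(mag_gyr, rep(0, nrow(rec)), tolerance = 1e-9)
})

test_that("transitions move the low-pass acceleration between plateaus", {
  p <- sim_params(noise_acc_sd_g = 0, noise_gyr_sd_deg_s = 0)
  script <- tibble::tibble(state = c("SIT", "TRANSITION_UP", "STAND"),
                           duration_s = c(30, 2, 30))
  sim <- synthesize(script, p, seed = 1)
  pr <- preprocess_recording(sim$recording)
  seated <- pr$acc_filt_x[pr$t > 10 & pr$t < 25]
  standing <- pr$acc_filt_x[pr$t > 40 & pr$t < 55]
  expect_equal(mean(seated), sin(p$tilt_sit_deg * pi / 180), tolerance = 1e-3)
  expect_equal(mean(standing), sin(p$tilt_stand_deg * pi / 180),
               tolerance = 1e-3)
  # the gyroscope pulses only during the transition
  expect_gt(max(abs(sim$recording$gyr_y[sim$recording$t >= 30 &
                                          sim$recording$t < 32])), 10)
  expect_lt(max(abs(sim$recording$gyr_y[sim$recording$t < 29])), 1e-9)
})

test_that("walking bouts carry a spectral peak at the gait frequency", {
  p <- sim_params(noise_acc_sd_g = 0.005, noise_gyr_sd_deg_s = 0.5,
                  gait_freq_hz = c(1.0, 1.0))
  script <- tibble::tibble(state = c("SIT", "TRANSITION_UP", "WALK"),
                           duration_s = c(10, 2, 60))
  sim <- synthesize(script, p, seed = 3)
  walk <- sim$recording$gyr_y[sim$recording$t >= 12]
  spec <- stats::spec.pgram(walk, taper = 0, plot = FALSE)
  f_peak <- spec$freq[which.max(spec$spec)] * 50
  expect_lt(abs(f_peak - 1.0), 50 / length(walk) + 1e-9)  # within one bin
})

test_that("ground-truth label measure equals the scripted activity exactly", {
  p <- sim_params(trial_duration_s = 240)
  s <- make_script(p, seed = 12)
  sim <- synthesize(s, p, seed = 12)
  lab <- sim$labels
  for (case in list(c("SIT", "SIT"), c("TRANSITION_UP", "TRANSITION"),
                    c("WALK", "WALKING"))) {
    scripted <- sum(s$duration_s[s$state %in%
                                   c(case[1], sub("_UP", "_DOWN", case[1]))])
    iv <- track_intervals(lab, case[2])
    expect_equal(sum(iv$end_s - iv$start_s), scripted, tolerance = 1e-9)
  }
  # transitions absorbed into SIT when requested
  sim2 <- synthesize(s, p, seed = 12, include_transitions_in_sit = TRUE)
  iv2 <- track_intervals(sim2$labels, "SIT")
  expect_equal(sum(iv2$end_s - iv2$start_s),
               sum(s$duration_s[s$state %in%
                                  c("SIT", "TRANSITION_UP", "TRANSITION_DOWN")]),
               tolerance = 1e-9)
})

test_that("cohorts are reproducible and subject-varied", {
  a <- generate_cohort(n_subjects = 3, trial_durations_s = c(180, 240),
                       master_seed = 5)
  b <- generate_cohort(n_subjects = 3, trial_durations_s = c(180, 240),
                       master_seed = 5)
  expect_equal(nrow(a), 6)
  expect_identical(a, b)
  # different subjects draw different gait parameters -> different signals
  expect_false(isTRUE(all.equal(a$recording[[1]]$gyr_y, a$recording[[3]]$gyr_y)))
  # quiet-state (non-walking) acceleration magnitude stays near 1 g
  rec <- a$recording[[1]]
  lab <- a$labels[[1]]
  sit <- track_intervals(lab, "SIT")
  in_sit <- rec$t >= sit$start_s[1] & rec$t < sit$end_s[1]
  expect_lt(abs(mean(magnitude(rec$acc_x, rec$acc_y, rec$acc_z)[in_sit]) - 1),
            0.01)
})

test_that("cohort disk round-trip preserves recordings and labels", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(n_subjects = 2, trial_durations_s = 180,
                         master_seed = 2)
  write_cohort(coh, dir, master_seed = 2)
  back <- read_cohort(dir)
  expect_equal(back$trial_id, coh$trial_id)
  expect_equal(back$recording[[1]]$acc_x, coh$recording[[1]]$acc_x,
               tolerance = 1e-9)
  expect_equal(as.data.frame(back$labels[[2]]), as.data.frame(coh$labels[[2]]),
               tolerance = 1e-9)
})
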