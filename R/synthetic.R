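#' Simulation parameters for the synthetic ankle-IMU generator
#'
#' Defaults emulate the free-living protocol the pipeline targets: trials
#' of 3/4/5 minutes beginning seated, with (at least) three sit phases
#' separated by walking bouts and brief standing, stand-to-sit and
#' sit-to-stand transitions of 1.5-3 s, gait at 0.8-1.2 Hz, and low
#' sensor noise. Tremor (4-6 Hz band) is available but off by default.
#' Two-element numeric parameters are ranges sampled per subject.
#'
#' @param fs sampling rate, Hz (default 50).
#' @param trial_duration_s trial length in seconds (180, 240 or 300).
#' @param n_sit_phases number of seated phases per trial (default 3).
#' @param sit_duration_s range of seated-phase durations, s.
#' @param transition_duration_s range of postural-transition durations, s.
#' @param stand_duration_s range of standing-bout durations, s.
#' @param min_walk_s minimum walking-bout duration, s.
#' @param gait_freq_hz range of per-subject gait (stride) frequency, Hz.
#' @param gait_gyr_amp_deg_s range of sagittal gyroscope amplitude during
#'   gait, deg/s.
#' @param gait_acc_amp_g acceleration oscillation amplitude during gait, g.
#' @param tilt_sit_deg shank tilt from vertical when seated (foot slid
#'   forward), degrees.
#' @param tilt_stand_deg shank tilt when standing, degrees.
#' @param tremor_amp_gyr_deg_s gyroscope tremor amplitude, deg/s (0 = off).
#' @param tremor_amp_acc_g acceleration tremor amplitude, g (0 = off).
#' @param tremor_freq_hz range of tremor frequency, Hz.
#' @param noise_acc_sd_g,noise_gyr_sd_deg_s white-noise SDs per sensor.
#' @return a `sim_params` list.
#' @export
sim_params <- function(fs = 50,
                       trial_duration_s = 180,
                       n_sit_phases = 3,
                       sit_duration_s = c(12, 25),
                       transition_duration_s = c(1.5, 3.0),
                       stand_duration_s = c(1.5, 4),
                       min_walk_s = 4,
                       gait_freq_hz = c(0.8, 1.2),
                       gait_gyr_amp_deg_s = c(80, 160),
                       gait_acc_amp_g = 0.15,
                       tilt_sit_deg = 40,
                       tilt_stand_deg = 0,
                       tremor_amp_gyr_deg_s = 0,
                       tremor_amp_acc_g = 0,
                       tremor_freq_hz = c(4, 6),
                       noise_acc_sd_g = 0.01,
                       noise_gyr_sd_deg_s = 0.5) {
  p <- as.list(environment())
  stopifnot(fs > 0, n_sit_phases >= 1,
            all(p$gait_freq_hz < fs / 2), all(p$tremor_freq_hz < fs / 2))
  structure(p, class = "sim_params")
}

rng_range <- function(r) if (length(r) == 2) runif(1, r[1], r[2]) else r

#' Build a randomized activity script for one trial
#'
#' The trial begins seated. Every seated phase is exited by a sit-to-stand
#' transition; every seated phase after the first is entered by a
#' stand-to-sit transition (the first needs none, the participant starting
#' in the chair). Between sit phases the script walks, with optional brief
#' standing before sitting down; walking durations absorb whatever time
#' the fixed trial length leaves over.
#'
#' @param params a [sim_params].
#' @param seed integer seed.
#' @return an `activity_script` tibble with columns `state`
#'   (`SIT`, `TRANSITION_UP`, `TRANSITION_DOWN`, `STAND`, `WALK`) and
#'   `duration_s`, summing exactly to the trial duration.
#' @export
make_script <- function(params = sim_params(), seed = 1) {
  with_local_seed(seed, {
    n <- params$n_sit_phases
    sits <- runif(n, params$sit_duration_s[1], params$sit_duration_s[2])
    t_up <- runif(n, params$transition_duration_s[1], params$transition_duration_s[2])
    t_dn <- runif(max(n - 1, 0), params$transition_duration_s[1],
                  params$transition_duration_s[2])
    stands <- runif(max(n - 1, 0), params$stand_duration_s[1],
                    params$stand_duration_s[2])
    fixed <- sum(sits) + sum(t_up) + sum(t_dn) + sum(stands)
    walk_total <- params$trial_duration_s - fixed
    if (walk_total < n * params$min_walk_s) {
      abort(paste0("Requested activities do not fit the trial: ",
                   signif(fixed, 5), " s of non-walking in a ",
                   params$trial_duration_s, " s trial leaves less than ",
                   n * params$min_walk_s, " s of walking."),
            class = "sitseg_parameter_error")
    }
    w <- runif(n, 1, 2)
    walks <- params$min_walk_s + (walk_total - n * params$min_walk_s) * w / sum(w)
    states <- character()
    durs <- double()
    add <- function(st, d) {
      states <<- c(states, st)
      durs <<- c(durs, d)
    }
    add("SIT", sits[1])
    add("TRANSITION_UP", t_up[1])
    add("WALK", walks[1])
    if (n > 1) {
      for (i in 2:n) {
        add("STAND", stands[i - 1])
        add("TRANSITION_DOWN", t_dn[i - 1])
        add("SIT", sits[i])
        add("TRANSITION_UP", t_up[i])
        add("WALK", walks[i])
      }
    }
    out <- tibble(state = states, duration_s = durs)
    stopifnot(abs(sum(out$duration_s) - params$trial_duration_s) < 1e-9)
    class(out) <- c("activity_script", class(out))
    out
  })
}

# smoothstep ramp and its time derivative on [0, 1]
smoothstep <- function(u) u * u * (3 - 2 * u)
smoothstep_deriv <- function(u) 6 * u * (1 - u)

#' Synthesize an ankle-IMU recording from an activity script
#'
#' The signal model is a tilting gravity vector plus activity-specific
#' oscillation: the accelerometer reads the projection of 1 g onto the
#' sensor axes under a shank tilt that ramps smoothly between its
#' standing and seated values during each transition; the gyroscope reads
#' the tilt rate (a pulse during each transition). Walking adds a
#' sinusoidal gait oscillation at the subject's gait frequency (dominant
#' on the sagittal gyroscope axis, with a weaker second harmonic on the
#' accelerometer); optional tremor adds a 4-6 Hz component; white noise
#' is added throughout. Sitting and standing are quiet apart from noise
#' and tremor.
#'
#' @param script an `activity_script` from [make_script()].
#' @param params a [sim_params].
#' @param seed integer seed.
#' @param subject_id,trial_id identifiers for the recording.
#' @param include_transitions_in_sit if `TRUE`, SIT ground-truth intervals
#'   absorb their flanking transitions (default `FALSE`: the Sit phase is
#'   the seated interval proper, transitions labeled separately).
#' @return list with elements `recording` ([imu_recording]) and `labels`
#'   ([label_track] with SIT, TRANSITION and WALKING intervals).
#' @export
synthesize <- function(script, params = sim_params(), seed = 1,
                       subject_id = "S01", trial_id = "T01",
                       include_transitions_in_sit = FALSE) {
  fs <- params$fs
  duration <- sum(script$duration_s)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  ends <- cumsum(script$duration_s)
  starts <- c(0, head(ends, -1))
  state_at <- script$state[findInterval(t, starts)]
  tilt_deg <- rep(params$tilt_stand_deg, n)
  tilt_rate <- rep(0, n)
  with_local_seed(seed, {
    gait_f <- rng_range(params$gait_freq_hz)
    gait_amp <- rng_range(params$gait_gyr_amp_deg_s)
    tremor_f <- rng_range(params$tremor_freq_hz)
    gait_phase <- runif(1, 0, 2 * pi)
    for (i in seq_len(nrow(script))) {
      sel <- t >= starts[i] & t < ends[i]
      st <- script$state[i]
      if (st == "SIT") {
        tilt_deg[sel] <- params$tilt_sit_deg
      } else if (st %in% c("TRANSITION_UP", "TRANSITION_DOWN")) {
        u <- (t[sel] - starts[i]) / script$duration_s[i]
        from <- if (st == "TRANSITION_UP") params$tilt_sit_deg else params$tilt_stand_deg
        to <- if (st == "TRANSITION_UP") params$tilt_stand_deg else params$tilt_sit_deg
        tilt_deg[sel] <- from + (to - from) * smoothstep(u)
        tilt_rate[sel] <- (to - from) * smoothstep_deriv(u) / script$duration_s[i]
      }
    }
    th <- tilt_deg * pi / 180
    acc_x <- sin(th)
    acc_y <- rep(0, n)
    acc_z <- cos(th)
    gyr_x <- rep(0, n)
    gyr_y <- tilt_rate  # deg/s: rotation in the sagittal (x-z) plane
    gyr_z <- rep(0, n)
    walking <- state_at == "WALK"
    if (any(walking)) {
      osc <- sin(2 * pi * gait_f * t + gait_phase)
      osc2 <- sin(4 * pi * gait_f * t + 2 * gait_phase)
      gyr_y[walking] <- gyr_y[walking] + gait_amp * osc[walking]
      gyr_x[walking] <- gyr_x[walking] + 0.3 * gait_amp * osc2[walking]
      acc_x[walking] <- acc_x[walking] + params$gait_acc_amp_g * osc[walking]
      acc_z[walking] <- acc_z[walking] + 0.5 * params$gait_acc_amp_g * osc2[walking]
    }
    if (params$tremor_amp_gyr_deg_s > 0 || params$tremor_amp_acc_g > 0) {
      trem <- sin(2 * pi * tremor_f * t)
      gyr_x <- gyr_x + params$tremor_amp_gyr_deg_s * trem
      acc_x <- acc_x + params$tremor_amp_acc_g * trem
    }
    acc_x <- acc_x + rnorm(n, sd = params$noise_acc_sd_g)
    acc_y <- acc_y + rnorm(n, sd = params$noise_acc_sd_g)
    acc_z <- acc_z + rnorm(n, sd = params$noise_acc_sd_g)
    gyr_x <- gyr_x + rnorm(n, sd = params$noise_gyr_sd_deg_s)
    gyr_y <- gyr_y + rnorm(n, sd = params$noise_gyr_sd_deg_s)
    gyr_z <- gyr_z + rnorm(n, sd = params$noise_gyr_sd_deg_s)
  })
  rec <- imu_recording(
    tibble(t = t, acc_x = acc_x, acc_y = acc_y, acc_z = acc_z,
           gyr_x = gyr_x, gyr_y = gyr_y, gyr_z = gyr_z),
    fs = fs, subject_id = subject_id, trial_id = trial_id)
  lab <- script_to_labels(script, include_transitions_in_sit)
  list(recording = rec, labels = lab)
}

# Ground-truth intervals exactly as scripted.
script_to_labels <- function(script, include_transitions_in_sit = FALSE) {
  ends <- cumsum(script$duration_s)
  starts <- c(0, head(ends, -1))
  rows <- tibble(start_s = starts, end_s = ends, state = script$state)
  sit <- rows[rows$state == "SIT", , drop = FALSE]
  if (include_transitions_in_sit) {
    tr <- rows[rows$state %in% c("TRANSITION_UP", "TRANSITION_DOWN"), , drop = FALSE]
    sit <- canonicalize_intervals(bind_rows(
      sit[, c("start_s", "end_s")], tr[, c("start_s", "end_s")]))
    sit$state <- "SIT"
  }
  lab <- bind_rows(
    mutate(sit[, c("start_s", "end_s")], label = "SIT"),
    mutate(rows[rows$state %in% c("TRANSITION_UP", "TRANSITION_DOWN"),
                c("start_s", "end_s")], label = "TRANSITION"),
    mutate(rows[rows$state == "WALK", c("start_s", "end_s")], label = "WALKING"))
  label_track(lab, duration_s = sum(script$duration_s))
}

#' Generate a synthetic cohort
#'
#' One recording per subject and trial length, with per-subject gait
#' frequency, gait amplitude, tremor frequency and activity timings drawn
#' from the configured ranges. Fully reproducible from `master_seed`.
#'
#' @param n_subjects number of subjects (default 20).
#' @param trial_durations_s trial lengths per subject, seconds (default
#'   180/240/300).
#' @param params a [sim_params]; its `trial_duration_s` is overridden per
#'   trial.
#' @param master_seed integer master seed.
#' @return an `imu_cohort` tibble with one row per trial: `subject_id`,
#'   `trial_id`, `duration_s` and list-columns `recording`, `labels`.
#' @export
generate_cohort <- function(n_subjects = 20, trial_durations_s = c(180, 240, 300),
                            params = sim_params(), master_seed = 1) {
  rows <- tidyr::expand_grid(subj = seq_len(n_subjects),
                             dur = trial_durations_s)
  out <- pmap(rows, function(subj, dur) {
    p <- params
    p$trial_duration_s <- dur
    sid <- sprintf("S%02d", subj)
    tid <- sprintf("%s_T%03ds", sid, dur)
    scr <- make_script(p, seed = derive_seed(master_seed, subj, dur, 1))
    sim <- synthesize(scr, p, seed = derive_seed(master_seed, subj, dur, 2),
                      subject_id = sid, trial_id = tid)
    tibble(subject_id = sid, trial_id = tid, duration_s = dur,
           recording = list(sim$recording), labels = list(sim$labels))
  })
  out <- bind_rows(out)
  class(out) <- c("imu_cohort", class(out))
  out
}

#' Write a cohort to disk in the package CSV dialects
#'
#' Writes one IMU CSV and one label CSV per trial plus a `manifest.csv`
#' listing files, durations and the master seed.
#'
#' @param cohort an `imu_cohort`.
#' @param dir output directory (created if needed).
#' @param master_seed seed recorded in the manifest.
#' @return the manifest tibble, invisibly.
#' @export
write_cohort <- function(cohort, dir, master_seed = NA_integer_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- pmap(cohort, function(subject_id, trial_id, duration_s,
                                    recording, labels) {
    imu_path <- file.path(dir, paste0(trial_id, "_imu.csv"))
    lab_path <- file.path(dir, paste0(trial_id, "_labels.csv"))
    write_imu(recording, imu_path)
    write_labels(labels, lab_path)
    tibble(subject_id = subject_id, trial_id = trial_id,
           duration_s = duration_s, imu_file = basename(imu_path),
           label_file = basename(lab_path), master_seed = master_seed)
  }) |> bind_rows()
  readr::write_csv(manifest, file.path(dir, "manifest.csv"), progress = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `manifest.csv`.
#' @return an `imu_cohort` tibble.
#' @export
read_cohort <- function(dir) {
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE, progress = FALSE)
  out <- pmap(manifest, function(subject_id, trial_id, duration_s,
                                 imu_file, label_file, ...) {
    rec <- read_imu(file.path(dir, imu_file), subject_id = subject_id,
                    trial_id = trial_id)
    lab <- read_labels(file.path(dir, label_file), duration_s = duration_s)
    tibble(subject_id = subject_id, trial_id = trial_id,
           duration_s = duration_s, recording = list(rec), labels = list(lab))
  }) |> bind_rows()
  class(out) <- c("imu_cohort", class(out))
  out
}
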