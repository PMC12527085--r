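# Shared in-code fixtures. Everything is generated at test time; nothing is
# read from disk except files the tests themselves write to tempdirs.

# A minimal 6-axis recording: quiet 1 g on z unless channels are overridden.
make_recording <- function(n = 500, fs = 50, subject_id = "S01",
                           trial_id = "T01", ...) {
  t <- (seq_len(n) - 1) / fs
  ch <- list(acc_x = rep(0, n), acc_y = rep(0, n), acc_z = rep(1, n),
             gyr_x = rep(0, n), gyr_y = rep(0, n), gyr_z = rep(0, n))
  over <- list(...)
  ch[names(over)] <- over
  imu_recording(tibble::tibble(t = t, !!!ch), fs = fs,
                subject_id = subject_id, trial_id = trial_id)
}

# A fake processed-signal table whose 16 channels can be set directly,
# bypassing the filters (for exercising the feature extractor in isolation).
make_processed <- function(n = 200, fs = 50, fill = 0, ...) {
  chans <- c("acc_raw_x", "acc_raw_y", "acc_raw_z", "acc_raw_mag",
             "gyr_raw_x", "gyr_raw_y", "gyr_raw_z", "gyr_raw_mag",
             "acc_filt_x", "acc_filt_y", "acc_filt_z", "acc_filt_mag",
             "gyr_filt_x", "gyr_filt_y", "gyr_filt_z", "gyr_filt_mag")
  out <- tibble::tibble(t = (seq_len(n) - 1) / fs)
  for (ch in chans) out[[ch]] <- rep(fill, n)
  over <- list(...)
  for (nm in names(over)) out[[nm]] <- over[[nm]]
  attr(out, "fs") <- fs
  attr(out, "subject_id") <- "S01"
  attr(out, "trial_id") <- "T01"
  class(out) <- c("processed_imu", class(out))
  out
}

# Random canonical interval set inside [0, duration)
random_intervals <- function(n, duration) {
  if (n == 0) return(tibble::tibble(start_s = double(), end_s = double()))
  a <- sort(runif(2 * n, 0, duration))
  tibble::tibble(start_s = a[seq(1, 2 * n, 2)], end_s = a[seq(2, 2 * n, 2)])
}

# Small feature table with labels for classifier plumbing tests: two
# Gaussian blobs in feature space.
make_blob_features <- function(n = 200, sep = 4, sd = 1, seed = 42) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x <- matrix(rnorm(n * 32, sd = sd), n, 32) + sep * y
  colnames(x) <- feature_columns()
  list(x = x, y = y)
}

# Tiny labeled trial set for cross-validation plumbing: `n_subjects`
# subjects, one trial each, `n_windows` windows of separable features.
make_tiny_trials <- function(n_subjects = 12, n_windows = 40, seed = 9) {
  set.seed(seed)
  purrr::map_dfr(seq_len(n_subjects), function(s) {
    sit <- rep(c(0L, 1L), length.out = n_windows)
    tra <- as.integer(dplyr::lag(sit, default = 0L) != sit)
    x <- matrix(rnorm(n_windows * 32, sd = 0.5), n_windows, 32) +
      2 * sit + outer(tra, c(rep(3, 16), rep(0, 16)))
    colnames(x) <- feature_columns()
    f <- tibble::as_tibble(x)
    f$subject_id <- sprintf("S%02d", s)
    f$trial_id <- sprintf("S%02d_T1", s)
    f$window_start_s <- (seq_len(n_windows) - 1) * 0.1
    f$transition_label <- tra
    f$sit_label <- sit
    tibble::tibble(subject_id = f$subject_id[1], trial_id = f$trial_id[1],
                   features = list(f))
  })
}

# Digital magnitude response of the two-pass (zero-phase) Butterworth
# low-pass, evaluated independently from the filter coefficients.
butter_two_pass_gain <- function(f_hz, fs, cutoff_hz, order = 2) {
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  z <- exp(-1i * 2 * pi * f_hz / fs)
  h <- sum(bf$b * z^(0:(length(bf$b) - 1))) /
    sum(bf$a * z^(0:(length(bf$a) - 1)))
  Mod(h)^2
}

# Amplitude of a sinusoid of known frequency in a signal (least squares).
fit_amplitude <- function(x, t, f_hz) {
  X <- cbind(sin(2 * pi * f_hz * t), cos(2 * pi * f_hz * t))
  cf <- qr.solve(X, x)
  sqrt(sum(cf^2))
}
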