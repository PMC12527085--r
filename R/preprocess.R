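#' Zero-lag Butterworth low-pass filter
#'
#' Applies a second-order Butterworth low-pass filter forward and backward
#' (zero phase lag; effective fourth-order magnitude response
#' `|H(f)|^2` of the one-way filter). Edges are handled by odd (point-)
#' reflection padding of length `3 * (order + 1)` samples, so short bouts
#' near the start and end of a trial are not distorted by start-up
#' transients.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param cutoff_hz -3 dB cutoff of the one-way filter, Hz; must lie in
#'   `(0, fs/2)`.
#' @param order filter order of the one-way pass (default 2).
#' @return filtered signal, same length as `x`.
#' @export
lowpass_zero_lag <- function(x, fs, cutoff_hz, order = 2) {
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    abort(paste0("cutoff_hz must lie strictly between 0 and the Nyquist rate fs/2 = ",
                 fs / 2, " Hz."), class = "sitseg_parameter_error")
  }
  pad <- 3L * (order + 1L)
  n <- length(x)
  if (n < 3L * pad) {
    abort(paste0("Signal too short for zero-lag filtering: need at least ",
                 3L * pad, " samples, got ", n, "."),
          class = "sitseg_length_error")
  }
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  b <- bf$b
  a <- bf$a
  zi <- lfilter_zi(b, a)
  # odd reflection about the end points absorbs local slope; steady-state
  # initial conditions absorb the IIR startup transient exactly
  left <- 2 * x[1] - x[(pad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - pad)]
  xp <- c(left, x, right)
  y <- lfilter(b, a, xp, zi * xp[1])
  y <- rev(y)
  y <- lfilter(b, a, y, zi * y[1])
  y <- rev(y)
  y[(pad + 1):(pad + n)]
}

# Steady-state initial filter state for a unit-amplitude step input
# (direct-form II transposed), so a constant signal produces a constant
# output from the first sample.
lfilter_zi <- function(b, a) {
  b <- b / a[1]
  a <- a / a[1]
  n <- length(a)
  comp <- rbind(-a[-1], cbind(diag(n - 2), numeric(n - 2)))
  IminusA <- diag(n - 1) - t(comp)
  B <- b[-1] - a[-1] * b[1]
  solve(IminusA, B)
}

# IIR filter with explicit initial state: superposition of the zero-state
# response and the zero-input (initial-state) response, each computed by a
# vectorized filter pass.
lfilter <- function(b, a, x, zi) {
  zs <- as.numeric(signal::filter(signal::Arma(b = b, a = a), x))
  imp <- c(1, numeric(length(x) - 1))
  ziresp <- as.numeric(signal::filter(signal::Arma(b = c(zi, 0), a = a), imp))
  zs + ziresp
}

#' Elementwise Euclidean magnitude of a tri-axial signal
#'
#' @param x,y,z equal-length numeric vectors.
#' @return `sqrt(x^2 + y^2 + z^2)`.
#' @export
magnitude <- function(x, y, z) {
  stopifnot(length(x) == length(y), length(y) == length(z))
  sqrt(x^2 + y^2 + z^2)
}

#' Derive the raw and filtered signal channels of the pipeline
#'
#' From a 6-axis recording, computes the 16 per-sample channels the
#' feature extractor consumes: the raw axes and their magnitudes, the
#' 0.5 Hz low-passed acceleration axes (the low-frequency, gravity-driven
#' component that shifts between postures) and their magnitude, and the
#' 4 Hz low-passed angular-velocity axes (voluntary movement, gait band)
#' and their magnitude. Raw magnitudes are taken from the unfiltered axes;
#' filtered magnitudes are the magnitude of the filtered axes — each axis
#' is filtered first, the magnitude computed second.
#'
#' @param rec an [imu_recording].
#' @param acc_cutoff_hz low-pass cutoff for the acceleration axes (default
#'   0.5 Hz).
#' @param gyr_cutoff_hz low-pass cutoff for the angular-velocity axes
#'   (default 4 Hz).
#' @return a `processed_imu` tibble with columns `t`,
#'   `acc_raw_{x,y,z,mag}`, `gyr_raw_{x,y,z,mag}`, `acc_filt_{x,y,z,mag}`,
#'   `gyr_filt_{x,y,z,mag}`; sampling rate and identifiers carried as
#'   attributes.
#' @export
preprocess_recording <- function(rec, acc_cutoff_hz = 0.5, gyr_cutoff_hz = 4) {
  fs <- imu_fs(rec)
  lp <- function(col, cutoff) lowpass_zero_lag(rec[[col]], fs, cutoff)
  out <- tibble(
    t = rec$t,
    acc_raw_x = rec$acc_x, acc_raw_y = rec$acc_y, acc_raw_z = rec$acc_z,
    acc_raw_mag = magnitude(rec$acc_x, rec$acc_y, rec$acc_z),
    gyr_raw_x = rec$gyr_x, gyr_raw_y = rec$gyr_y, gyr_raw_z = rec$gyr_z,
    gyr_raw_mag = magnitude(rec$gyr_x, rec$gyr_y, rec$gyr_z),
    acc_filt_x = lp("acc_x", acc_cutoff_hz),
    acc_filt_y = lp("acc_y", acc_cutoff_hz),
    acc_filt_z = lp("acc_z", acc_cutoff_hz))
  out$acc_filt_mag <- magnitude(out$acc_filt_x, out$acc_filt_y, out$acc_filt_z)
  out$gyr_filt_x <- lp("gyr_x", gyr_cutoff_hz)
  out$gyr_filt_y <- lp("gyr_y", gyr_cutoff_hz)
  out$gyr_filt_z <- lp("gyr_z", gyr_cutoff_hz)
  out$gyr_filt_mag <- magnitude(out$gyr_filt_x, out$gyr_filt_y, out$gyr_filt_z)
  attr(out, "fs") <- fs
  attr(out, "subject_id") <- attr(rec, "subject_id")
  attr(out, "trial_id") <- attr(rec, "trial_id")
  class(out) <- c("processed_imu", class(out))
  out
}

signal_channels <- function() {
  c("acc_raw_x", "acc_raw_y", "acc_raw_z", "acc_raw_mag",
    "gyr_raw_x", "gyr_raw_y", "gyr_raw_z", "gyr_raw_mag",
    "acc_filt_x", "acc_filt_y", "acc_filt_z", "acc_filt_mag",
    "gyr_filt_x", "gyr_filt_y", "gyr_filt_z", "gyr_filt_mag")
}
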