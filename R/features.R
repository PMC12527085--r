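#' Sliding-window specification
#'
#' Windows default to 1 s length with 90% overlap, the segmentation the
#' classifiers are trained on. At 50 Hz this gives 50-sample windows
#' advancing 5 samples (0.1 s) at a time, so consecutive windows share 45
#' samples.
#'
#' @param length_s window length in seconds (default 1).
#' @param overlap_fraction fraction of the window shared with its
#'   successor, in `[0, 1)` (default 0.9).
#' @return a `window_spec` object.
#' @export
window_spec <- function(length_s = 1.0, overlap_fraction = 0.9) {
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    abort("overlap_fraction must lie in [0, 1).", class = "sitseg_parameter_error")
  }
  structure(list(length_s = length_s, overlap_fraction = overlap_fraction),
            class = "window_spec")
}

# length_n / step_n for a spec at a sampling rate
window_geometry <- function(spec, fs) {
  length_n <- round(spec$length_s * fs)
  step_n <- round(length_n * (1 - spec$overlap_fraction))
  if (length_n < 2) {
    abort("Window length must cover at least 2 samples.",
          class = "sitseg_parameter_error")
  }
  if (step_n < 1) {
    abort("Window step must be at least 1 sample; decrease overlap_fraction.",
          class = "sitseg_parameter_error")
  }
  list(length_n = as.integer(length_n), step_n = as.integer(step_n))
}

#' Enumerate fully contained sliding windows
#'
#' Windows start at sample 0 and advance by the window step; only windows
#' lying fully inside the signal are kept (no partial windows), giving
#' `floor((n_samples - length_n)/step_n) + 1` windows.
#'
#' @param n_samples signal length in samples.
#' @param spec a [window_spec].
#' @param fs sampling rate, Hz.
#' @return tibble with 0-based half-open sample indices `start_n`,
#'   `end_n` and the window start time `start_s`. Zero rows (with a
#'   warning) if the signal is shorter than one window.
#' @export
window_indices <- function(n_samples, spec = window_spec(), fs) {
  g <- window_geometry(spec, fs)
  if (n_samples < g$length_n) {
    warn(paste0("Signal of ", n_samples, " samples is shorter than one window (",
                g$length_n, " samples); no windows produced."))
    return(tibble(start_n = integer(), end_n = integer(), start_s = double()))
  }
  starts <- seq.int(0L, n_samples - g$length_n, by = g$step_n)
  tibble(start_n = starts, end_n = starts + g$length_n, start_s = starts / fs)
}

#' Canonical feature column names
#'
#' The 32 features are the per-window mean and standard deviation of each
#' of the 16 signal channels, ordered raw-acceleration means, raw-
#' acceleration SDs, raw-gyroscope means, raw-gyroscope SDs, then the
#' filtered equivalents; within each block the axis order is x, y, z,
#' magnitude.
#'
#' @return character vector of 32 column names.
#' @export
feature_columns <- function() {
  blk <- function(sig, stat) paste0(sig, c("_x", "_y", "_z", "_mag"), "_", stat)
  c(blk("acc_raw", "mean"), blk("acc_raw", "sd"),
    blk("gyr_raw", "mean"), blk("gyr_raw", "sd"),
    blk("acc_filt", "mean"), blk("acc_filt", "sd"),
    blk("gyr_filt", "mean"), blk("gyr_filt", "sd"))
}

#' Extract per-window mean/SD features
#'
#' Slices the 16 processed channels into sliding windows and computes the
#' mean and sample standard deviation (n - 1 denominator) of each channel
#' per window: 16 features on the raw channels and 16 on the filtered
#' channels. A window's timestamp is its start time.
#'
#' @param processed a `processed_imu` tibble from
#'   [preprocess_recording()].
#' @param spec a [window_spec].
#' @return a tibble with `subject_id`, `trial_id`, `window_start_s` and
#'   the 32 [feature_columns()].
#' @export
compute_features <- function(processed, spec = window_spec()) {
  fs <- attr(processed, "fs")
  win <- window_indices(nrow(processed), spec, fs)
  g <- window_geometry(spec, fs)
  nwin <- nrow(win)
  out <- tibble(
    subject_id = rep(attr(processed, "subject_id") %||% NA_character_, nwin),
    trial_id = rep(attr(processed, "trial_id") %||% NA_character_, nwin),
    window_start_s = win$start_s)
  if (nwin == 0) {
    for (nm in feature_columns()) out[[nm]] <- double()
    return(out)
  }
  # index matrix: one column per window, one row per in-window sample
  idx <- outer(seq_len(g$length_n), win$start_n, `+`)
  for (ch in signal_channels()) {
    m <- matrix(processed[[ch]][idx], nrow = g$length_n)
    mu <- colMeans(m)
    dev <- m - rep(mu, each = g$length_n)
    sdv <- sqrt(colSums(dev * dev) / (g$length_n - 1))
    out[[paste0(ch, "_mean")]] <- mu
    out[[paste0(ch, "_sd")]] <- sdv
  }
  out[, c("subject_id", "trial_id", "window_start_s", feature_columns())]
}

#' Fit percentile normalization parameters
#'
#' Computes the per-feature 5th and 95th percentiles (linear-interpolation
#' quantiles) over the pooled rows of one or more feature matrices —
#' typically all subjects and all trial lengths together. The percentile
#' bounds deliberately exclude extreme values so outliers do not stretch
#' the normalized scale.
#'
#' @param features a feature tibble, or a list of them to pool.
#' @param probs lower/upper percentile probabilities (default `c(0.05,
#'   0.95)`).
#' @return a `norm_params` tibble with columns `feature`, `p5`, `p95`.
#' @export
fit_normalization <- function(features, probs = c(0.05, 0.95)) {
  if (is.data.frame(features)) features <- list(features)
  pooled <- bind_rows(lapply(features, function(f) f[, feature_columns()]))
  if (nrow(pooled) == 0) {
    abort("Cannot fit normalization on an empty feature matrix.",
          class = "sitseg_parameter_error")
  }
  qs <- vapply(pooled, function(v) quantile(v, probs = probs, names = FALSE, type = 7),
               numeric(2))
  out <- tibble(feature = colnames(qs), p5 = unname(qs[1, ]),
                p95 = unname(qs[2, ]))
  degen <- out$feature[out$p95 <= out$p5]
  if (length(degen) > 0) {
    abort(paste0("Degenerate feature(s) with P95 <= P5: ",
                 paste(degen, collapse = ", ")),
          class = "sitseg_degenerate_feature_error")
  }
  class(out) <- c("norm_params", class(out))
  out
}

#' Apply percentile normalization
#'
#' Maps each feature value v to `(2*v - (P5 + P95)) / (P95 - P5)`, an
#' affine map sending P5 to -1, P95 to +1 and their midpoint to 0. Values
#' beyond the percentiles map beyond `[-1, 1]`; no clipping is applied.
#'
#' @param features a feature tibble.
#' @param params a `norm_params` tibble from [fit_normalization()]
#'   covering every feature column.
#' @return the feature tibble with feature columns normalized.
#' @export
apply_normalization <- function(features, params) {
  missing <- setdiff(feature_columns(), params$feature)
  if (length(missing) > 0) {
    abort(paste0("Normalization parameters missing feature(s): ",
                 paste(missing, collapse = ", ")),
          class = "sitseg_parameter_error")
  }
  p <- setNames(split(params[, c("p5", "p95")], seq_len(nrow(params))), params$feature)
  for (nm in feature_columns()) {
    p5 <- p[[nm]]$p5
    p95 <- p[[nm]]$p95
    features[[nm]] <- (2 * features[[nm]] - (p5 + p95)) / (p95 - p5)
  }
  features
}

#' Read and write normalization parameters
#'
#' Serialized as a two-row CSV: one column per feature, first row the P5
#' values, second row the P95 values.
#'
#' @param params a `norm_params` tibble.
#' @param path file path.
#' @return `read_norm_params()` returns a `norm_params` tibble;
#'   `write_norm_params()` returns `path` invisibly.
#' @export
write_norm_params <- function(params, path) {
  wide <- as.data.frame(rbind(setNames(params$p5, params$feature),
                              setNames(params$p95, params$feature)))
  readr::write_csv(wide, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_norm_params
#' @export
read_norm_params <- function(path) {
  wide <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  out <- tibble(feature = names(wide),
                p5 = as.numeric(wide[1, ]), p95 = as.numeric(wide[2, ]))
  class(out) <- c("norm_params", class(out))
  out
}
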