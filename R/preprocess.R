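#' Band-pass filter specification
#'
#' Defaults follow the published processing chain: movement is isolated
#' in the 0.5-10 Hz band and residual background noise below 0.02 g is
#' gated to zero before the per-second activity is formed.
#'
#' @param low_hz high-pass edge, Hz.
#' @param high_hz low-pass edge, Hz.
#' @param noise_cutoff_g magnitude gate, g; values below it become 0.
#' @param order Butterworth order per band edge.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(low_hz = 0.5, high_hz = 10, noise_cutoff_g = 0.02,
                        order = 4) {
  assert_scalar_number(low_hz, "low_hz", 0, strict_lower = TRUE)
  assert_scalar_number(high_hz, "high_hz", low_hz, strict_lower = TRUE)
  assert_scalar_number(noise_cutoff_g, "noise_cutoff_g", 0)
  assert_scalar_number(order, "order", 1)
  structure(list(low_hz = low_hz, high_hz = high_hz,
                 noise_cutoff_g = noise_cutoff_g, order = as.integer(order)),
            class = "filter_spec")
}

# zero-phase filtering with odd-reflection padding; signal::filtfilt alone
# leaves large start/end transients because it does not extend the signal
filtfilt_padded <- function(bf, x) {
  n <- length(x)
  np <- min(n - 1L, 512L)
  if (np < 1L) return(x)
  left <- 2 * x[1L] - x[(np + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - np)]
  y <- signal::filtfilt(bf, c(left, x, right))
  y[(np + 1L):(np + n)]
}

#' Band-pass filter a recording
#'
#' Each axis is filtered with a zero-phase (forward-backward) Butterworth
#' band-pass after removal of its mean, so the DC gravity component is
#' rejected exactly and movement bursts are not shifted in time relative
#' to the PSG epoch grid.
#'
#' @param r an [accel_recording()], normally already at 30 Hz.
#' @param spec a [filter_spec()].
#' @return the filtered [accel_recording()].
#' @export
bandpass_accel <- function(r, spec = filter_spec()) {
  stopifnot(inherits(r, "accel_recording"), inherits(spec, "filter_spec"))
  fs <- r$sample_rate_hz
  if (spec$high_hz >= fs / 2)
    stop_param("high_hz (", spec$high_hz, ") must lie below the Nyquist ",
               "frequency ", fs / 2, " Hz")
  # require a few settling lengths of the slow (high-pass) edge
  min_n <- ceiling(3 * fs / spec$low_hz)
  if (nrow(r$data) < min_n)
    stop_input("recording too short to band-pass: need >= ", min_n,
               " samples at ", fs, " Hz, got ", nrow(r$data))
  bf <- signal::butter(spec$order,
                       c(spec$low_hz, spec$high_hz) / (fs / 2),
                       type = "pass")
  out <- apply(r$data, 2L, function(col) filtfilt_padded(bf, col - mean(col)))
  accel_recording(out, fs, r$start_time)
}

#' Per-sample Euclidean vector magnitude
#' @param r a (filtered) [accel_recording()].
#' @return numeric vector, `sqrt(x^2 + y^2 + z^2)` per sample, g.
#' @export
vector_magnitude <- function(r) {
  stopifnot(inherits(r, "accel_recording"))
  sqrt(rowSums(r$data^2))
}

#' Gate sub-threshold magnitudes to zero
#'
#' Values strictly below the cutoff are set to 0; values at or above it
#' pass unchanged.
#'
#' @param m non-negative per-sample magnitude vector, g.
#' @param cutoff_g gate level, g.
#' @return the gated vector.
#' @export
suppress_noise <- function(m, cutoff_g = 0.02) {
  assert_scalar_number(cutoff_g, "cutoff_g", 0)
  ifelse(m < cutoff_g, 0, m)
}

#' Per-second activity series
#'
#' Container for the per-second mean band-pass-filtered vector magnitude
#' (the activity value driving the sleep-index recursion), at 1 Hz.
#'
#' @param values non-negative numeric vector, one value per second, g.
#' @param start_time start of the first second, seconds.
#' @return an object of class `activity_series`.
#' @export
activity_series <- function(values, start_time = 0) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop_input("activity series is empty")
  if (any(!is.finite(values)))
    stop_input("non-finite activity at second ", which(!is.finite(values))[1L])
  if (any(values < 0))
    stop_input("negative activity at second ", which(values < 0)[1L])
  structure(list(values = values, start_time = as.numeric(start_time)),
            class = "activity_series")
}

#' @export
print.activity_series <- function(x, ...) {
  cat(sprintf("<activity_series> %d s, mean %.4f g, %.0f%% active seconds\n",
              length(x$values), mean(x$values), 100 * mean(x$values > 0)))
  invisible(x)
}

#' @export
duration.activity_series <- function(x) length(x$values)

#' Average a per-sample magnitude into whole seconds
#'
#' Each output value is the mean of the `rate_hz` samples of one second;
#' a trailing partial second is dropped.
#'
#' @param m per-sample magnitude vector.
#' @param rate_hz sampling rate of `m` (samples per second).
#' @param start_time start of the first second, seconds.
#' @return an [activity_series()].
#' @export
per_second_activity <- function(m, rate_hz, start_time = 0) {
  if (length(m) == 0L) stop_input("empty magnitude series")
  spp <- as.integer(round(rate_hz))
  n_sec <- length(m) %/% spp
  if (n_sec == 0L) stop_input("magnitude series shorter than one second")
  m <- m[seq_len(n_sec * spp)]
  activity_series(colMeans(matrix(m, nrow = spp)), start_time)
}

#' Raw recording to per-second activity
#'
#' The standard preprocessing chain: resample to 30 Hz, band-pass each
#' axis, take the vector magnitude, gate sub-cutoff noise, and average
#' into whole seconds. The first and last `edge_trim_s` seconds are
#' zeroed so band-pass edge transients cannot register as movement while
#' the series keeps its 1 Hz alignment with the recording start.
#'
#' @param r an [accel_recording()] at any rate.
#' @param spec a [filter_spec()].
#' @param target_rate_hz working rate for filtering (default 30 Hz).
#' @param edge_trim_s seconds zeroed at each end (default 2).
#' @return an [activity_series()] aligned to the recording start.
#' @export
compute_activity <- function(r, spec = filter_spec(), target_rate_hz = 30,
                             edge_trim_s = 2) {
  r30 <- resample_accel(r, target_rate_hz)
  filt <- bandpass_accel(r30, spec)
  m <- suppress_noise(vector_magnitude(filt), spec$noise_cutoff_g)
  a <- per_second_activity(m, target_rate_hz, r$start_time)
  k <- min(as.integer(edge_trim_s), length(a$values))
  if (k > 0L) {
    a$values[seq_len(k)] <- 0
    a$values[seq.int(length(a$values) - k + 1L, length(a$values))] <- 0
  }
  a
}

#' Write an activity series as CSV (`second,An_g`)
#' @param a an [activity_series()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_activity <- function(a, path) {
  stopifnot(inherits(a, "activity_series"))
  onset <- a$start_time + seq_along(a$values) - 1L
  writeLines(c("second,An_g", sprintf("%.1f,%.6f", onset, a$values)), path)
  invisible(path)
}
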