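#' Sleep-index algorithm parameters
#'
#' Defaults are the published operating point: time constant tau of
#' 18.5 min (1110 s) and gain k = 0.19, a wake threshold of 1 with the
#' index clamped at exp(1), removal of sleep/wake bouts shorter than
#' 10 s, a 2 min awakening back-shift, a 15 min minimum lying bout, and
#' 30 s scoring epochs.
#'
#' @param tau_s time constant of the index decay, seconds.
#' @param k_gain gain applied to the per-second activity, per g.
#' @param wake_threshold index value at or above which a second is wake.
#' @param s_max upper clamp of the index.
#' @param min_bout_s shortest sleep/wake bout retained, seconds.
#' @param wake_backshift_s each awakening is moved this far earlier, s.
#' @param min_lying_bout_s shortest lying bout scored, seconds.
#' @param epoch_s scoring epoch length, seconds.
#' @param lying_angle_deg thigh-to-gravity angle above which the posture
#'   counts as lying, degrees.
#' @param lying_smooth_s moving-average window for posture smoothing, s.
#' @return an object of class `algorithm_params`.
#' @examples
#' p <- algorithm_params()
#' p$tau_s / 60   # 18.5 min
#' @export
algorithm_params <- function(tau_s = 1110, k_gain = 0.19,
                             wake_threshold = 1, s_max = exp(1),
                             min_bout_s = 10, wake_backshift_s = 120,
                             min_lying_bout_s = 900, epoch_s = 30,
                             lying_angle_deg = 45, lying_smooth_s = 5) {
  assert_scalar_number(tau_s, "tau_s", 0, strict_lower = TRUE)
  assert_scalar_number(k_gain, "k_gain", 0, strict_lower = TRUE)
  assert_scalar_number(wake_threshold, "wake_threshold", 0,
                       strict_lower = TRUE)
  assert_scalar_number(s_max, "s_max", wake_threshold, strict_lower = TRUE)
  assert_scalar_number(min_bout_s, "min_bout_s", 0)
  assert_scalar_number(wake_backshift_s, "wake_backshift_s", 0)
  assert_scalar_number(min_lying_bout_s, "min_lying_bout_s", 0)
  assert_scalar_number(epoch_s, "epoch_s", 0, strict_lower = TRUE)
  assert_scalar_number(lying_angle_deg, "lying_angle_deg", 0, 90)
  assert_scalar_number(lying_smooth_s, "lying_smooth_s", 0)
  structure(list(tau_s = tau_s, k_gain = k_gain,
                 wake_threshold = wake_threshold, s_max = s_max,
                 min_bout_s = min_bout_s,
                 wake_backshift_s = wake_backshift_s,
                 min_lying_bout_s = min_lying_bout_s, epoch_s = epoch_s,
                 lying_angle_deg = lying_angle_deg,
                 lying_smooth_s = lying_smooth_s),
            class = "algorithm_params")
}

#' @export
print.algorithm_params <- function(x, ...) {
  cat(sprintf(paste0("<algorithm_params> tau %.1f min, k %.3g, ",
                     "threshold %g, clamp %.3f\n"),
              x$tau_s / 60, x$k_gain, x$wake_threshold, x$s_max))
  invisible(x)
}

#' Per-second sleep index
#'
#' The recursive state variable at the core of the method:
#' \deqn{S_n = \min(s_{max},\; e^{-1/\tau} S_{n-1} + k A_n)}
#' where \eqn{A_n} is the per-second activity in g. Movement pushes the
#' index up (to at most the clamp `s_max`); in quiescence it decays
#' exponentially with time constant `tau_s`, so after a full awakening
#' (index at the clamp, equal to e) sleep is declared only once tau
#' seconds have passed without further movement.
#'
#' @param a an [activity_series()].
#' @param params an [algorithm_params()].
#' @param s0 initial index value; defaults to the clamp (fully awake).
#' @return an object of class `sleep_index_series` with 1 Hz `values`.
#' @export
sleep_index <- function(a, params = algorithm_params(), s0 = NULL) {
  stopifnot(inherits(a, "activity_series"),
            inherits(params, "algorithm_params"))
  s0 <- s0 %||% params$s_max
  assert_scalar_number(s0, "s0", 0, params$s_max, strict_lower = TRUE)
  an <- a$values
  if (any(!is.finite(an)))
    stop_input("non-finite activity at second ", which(!is.finite(an))[1L])
  decay <- exp(-1 / params$tau_s)
  gain <- params$k_gain
  smax <- params$s_max
  s <- numeric(length(an))
  prev <- s0
  for (n in seq_along(an)) {
    prev <- decay * prev + gain * an[n]
    if (prev > smax) prev <- smax
    s[n] <- prev
  }
  structure(list(values = s, start_time = a$start_time, params = params),
            class = "sleep_index_series")
}

#' @export
print.sleep_index_series <- function(x, ...) {
  cat(sprintf("<sleep_index_series> %d s, range [%.3f, %.3f]\n",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Threshold the sleep index into sleep/wake seconds
#'
#' A second is wake when the index is at or above the threshold and
#' sleep when strictly below. The published rule leaves exact equality
#' open ("above 1 awake, below 1 asleep"); equality is resolved to wake,
#' the conservative choice for a sleep estimator.
#'
#' @param s a [sleep_index()] series.
#' @param params an [algorithm_params()].
#' @return a secondwise [state_series()].
#' @export
classify_states <- function(s, params = algorithm_params()) {
  stopifnot(inherits(s, "sleep_index_series"))
  state_series(ifelse(s$values >= params$wake_threshold, "wake", "sleep"),
               step_s = 1, start_time = s$start_time)
}

#' Write a secondwise index + classification checkpoint CSV
#' @param s a [sleep_index()] series.
#' @param params an [algorithm_params()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sleep_index <- function(s, params = algorithm_params(), path) {
  onset <- s$start_time + seq_along(s$values) - 1L
  lab <- ifelse(s$values >= params$wake_threshold, "wake", "sleep")
  writeLines(c("second,Sn,label",
               sprintf("%.1f,%.9f,%s", onset, s$values, lab)), path)
  invisible(path)
}
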