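#' Remove sleep/wake bouts shorter than the minimum duration
#'
#' Transient state flips are physiologically meaningless at 1 s
#' resolution, so maximal runs of either label shorter than
#' `min_bout_s` are absorbed into their surroundings: the shortest
#' offending run (earliest on ties) is relabelled to match its
#' neighbours and the scan repeats until every remaining run lasts at
#' least `min_bout_s`. Runs already at or above the minimum only ever
#' grow, so they are preserved in place.
#'
#' @param s a secondwise [state_series()].
#' @param params an [algorithm_params()] (uses `min_bout_s`).
#' @return the cleaned [state_series()].
#' @export
median_clean <- function(s, params = algorithm_params()) {
  stopifnot(inherits(s, "state_series"))
  min_len <- params$min_bout_s / s$step_s
  lab <- s$labels
  repeat {
    runs <- label_runs(lab)
    if (nrow(runs) <= 1L) break
    short <- which(runs$length < min_len)
    if (!length(short)) break
    i <- short[which.min(runs$length[short])]
    # neighbours of a run carry the opposite label (binary alphabet)
    flip <- if (i > 1L) runs$value[i - 1L] else runs$value[i + 1L]
    lab[runs$start[i]:runs$end[i]] <- flip
  }
  state_series(lab, s$step_s, s$start_time)
}

#' Move each awakening two minutes earlier
#'
#' The sleep index needs time to climb above the wake threshold once
#' movement resumes, so every detected awakening is considered to have
#' begun `wake_backshift_s` seconds before the index crossed the
#' threshold: at each sleep-to-wake transition the trailing
#' `wake_backshift_s` seconds of the preceding sleep bout are relabelled
#' wake (clipped at the bout start). A series that ends asleep has no
#' terminal awakening and is unchanged there.
#'
#' @param s a cleaned secondwise [state_series()].
#' @param params an [algorithm_params()] (uses `wake_backshift_s`).
#' @return the adjusted [state_series()].
#' @export
backshift_awakenings <- function(s, params = algorithm_params()) {
  stopifnot(inherits(s, "state_series"))
  shift <- as.integer(round(params$wake_backshift_s / s$step_s))
  runs <- label_runs(s$labels)
  lab <- s$labels
  for (i in seq_len(nrow(runs))) {
    if (runs$value[i] != "sleep" || i == nrow(runs)) next
    # sleep run followed by wake: pull the awakening onset back
    cut <- min(runs$length[i], shift)
    if (cut > 0L)
      lab[(runs$end[i] - cut + 1L):runs$end[i]] <- "wake"
  }
  state_series(lab, s$step_s, s$start_time)
}

#' Detect sustained lying bouts from raw posture
#'
#' A simple inclination detector standing in for a full posture
#' classifier: each axis is smoothed with a `lying_smooth_s` moving
#' average, and the angle between the longitudinal (x) axis and the
#' measured gravity vector is computed per sample. Samples with an angle
#' above `lying_angle_deg` count as recumbent; maximal recumbent runs
#' lasting at least `min_lying_bout_s` are returned as intervals on the
#' shared time base.
#'
#' @param r the raw (unfiltered) [accel_recording()], thigh-worn with
#'   the longitudinal axis mapped to x.
#' @param params an [algorithm_params()].
#' @return an [interval_set()] (possibly empty).
#' @export
detect_lying_bouts <- function(r, params = algorithm_params()) {
  stopifnot(inherits(r, "accel_recording"))
  fs <- r$sample_rate_hz
  k <- max(1L, as.integer(round(params$lying_smooth_s * fs)))
  sm <- apply(r$data, 2L, moving_average, k = k)
  vm <- sqrt(rowSums(sm^2))
  vm[vm < 1e-6] <- 1e-6
  angle <- acos(pmin(1, abs(sm[, 1L]) / vm)) * 180 / pi
  runs <- label_runs(ifelse(angle > params$lying_angle_deg, "ly", "up"))
  runs <- runs[runs$value == "ly" &
                 runs$length / fs >= params$min_lying_bout_s, , drop = FALSE]
  if (nrow(runs) == 0L) return(interval_set())
  interval_set(r$start_time + (runs$start - 1L) / fs,
               r$start_time + runs$end / fs)
}

#' Restrict sleep to lying bouts
#'
#' The index is only trusted while the wearer is recumbent: every second
#' whose onset falls outside all lying bouts is forced to wake; labels
#' inside bouts are untouched.
#'
#' @param s a secondwise [state_series()].
#' @param bouts an [interval_set()] of lying bouts on the shared base.
#' @return the restricted [state_series()].
#' @export
restrict_to_lying <- function(s, bouts) {
  stopifnot(inherits(s, "state_series"), inherits(bouts, "interval_set"))
  onset <- s$start_time + (seq_along(s$labels) - 1L) * s$step_s
  inside <- rep(FALSE, length(onset))
  for (i in seq_len(nrow(bouts)))
    inside <- inside | (onset >= bouts$start_s[i] & onset < bouts$end_s[i])
  lab <- s$labels
  lab[!inside] <- "wake"
  state_series(lab, s$step_s, s$start_time)
}

#' Down-sample a secondwise series into scoring epochs by majority vote
#'
#' Each `epoch_s` block takes the label held by the majority of its
#' seconds, matching the PSG scoring grid; an exact tie resolves to
#' wake. A trailing partial epoch is dropped.
#'
#' @param s a secondwise [state_series()].
#' @param params an [algorithm_params()] (uses `epoch_s`).
#' @return a [state_series()] with `step_s = epoch_s`.
#' @export
epoch_mode <- function(s, params = algorithm_params()) {
  stopifnot(inherits(s, "state_series"), s$step_s == 1)
  len <- as.integer(params$epoch_s)
  n_ep <- length(s$labels) %/% len
  if (n_ep == 0L) stop_input("series shorter than one epoch")
  m <- matrix(s$labels[seq_len(n_ep * len)] == "sleep", nrow = len)
  lab <- ifelse(colSums(m) > len / 2, "sleep", "wake")
  state_series(lab, len, s$start_time)
}

#' Full scoring pipeline: raw recording to 30-s sleep/wake epochs
#'
#' Composes the whole chain in the published order: resample to 30 Hz,
#' band-pass 0.5-10 Hz, vector magnitude, 0.02 g noise gate, per-second
#' activity, sleep-index recursion, threshold classification, short-bout
#' removal, 2 min awakening back-shift, restriction to lying bouts, and
#' majority-vote epoching.
#'
#' @param r a raw [accel_recording()].
#' @param params an [algorithm_params()].
#' @param spec a [filter_spec()].
#' @param bouts optional [interval_set()] of lying bouts; when `NULL`
#'   they are detected from the raw posture with [detect_lying_bouts()].
#' @param whole_recording_lying treat the full recording as one lying
#'   bout (e.g. laboratory nights with a known in-bed window).
#' @param keep_seconds also return the secondwise intermediates.
#' @return a [state_series()] of 30-s epochs; with `keep_seconds = TRUE`
#'   a list with elements `epochs`, `seconds`, `index`, `activity`,
#'   `bouts`.
#' @export
run_pipeline <- function(r, params = algorithm_params(),
                         spec = filter_spec(), bouts = NULL,
                         whole_recording_lying = FALSE,
                         keep_seconds = FALSE) {
  stopifnot(inherits(r, "accel_recording"))
  a <- compute_activity(r, spec)
  sx <- sleep_index(a, params)
  st <- classify_states(sx, params)
  st <- median_clean(st, params)
  st <- backshift_awakenings(st, params)
  if (whole_recording_lying) {
    bouts <- interval_set(r$start_time, r$start_time + duration(r))
  } else if (is.null(bouts)) {
    bouts <- detect_lying_bouts(r, params)
  }
  st <- restrict_to_lying(st, bouts)
  ep <- epoch_mode(st, params)
  if (keep_seconds)
    list(epochs = ep, seconds = st, index = sx, activity = a, bouts = bouts)
  else ep
}
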