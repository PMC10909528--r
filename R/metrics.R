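#' Derive per-night sleep variables from a sleep/wake series
#'
#' Computes the six standard summary variables for one night relative to
#' an analysis window (by default the whole series). With `t0` the
#' window start, sleep onset the first sleep label, and the last
#' awakening the onset of the final wake run that persists to the window
#' end (the window end itself if the night ends asleep):
#'
#' * sleep latency: window start to sleep onset (min);
#' * sleep interval: sleep onset to last awakening (min);
#' * total sleep time (TST): sleep between `t0` and the last awakening (min);
#' * WASO: wake between sleep onset and the last awakening (min);
#' * sleep efficiency: `100 * TST / (last awakening - t0)` (%);
#' * awakening index: wake bouts longer than `min_awakening_s` inside
#'   the sleep interval, per hour of sleep interval.
#'
#' The terminal wake run bounds the interval but is not itself counted
#' as WASO or as an awakening. By construction
#' `sleep_interval = TST + WASO` exactly.
#'
#' @param s a [state_series()] (secondwise or epochwise; epoch labels
#'   count as `step_s` seconds each).
#' @param window optional single-interval [interval_set()] on the shared
#'   time base; defaults to the full series extent.
#' @param min_awakening_s awakenings must exceed this duration to count.
#' @return an object of class `sleep_variables` (a one-row list); if the
#'   window holds no sleep, all variables are 0 and `no_sleep` is TRUE.
#' @export
derive_sleep_variables <- function(s, window = NULL, min_awakening_s = 10) {
  stopifnot(inherits(s, "state_series"))
  onset <- s$start_time + (seq_along(s$labels) - 1L) * s$step_s
  if (is.null(window)) {
    w0 <- s$start_time
    w1 <- s$start_time + duration(s)
  } else {
    stopifnot(inherits(window, "interval_set"), nrow(window) == 1L)
    w0 <- window$start_s[1L]
    w1 <- window$end_s[1L]
    if (w0 < s$start_time - 1e-9 || w1 > s$start_time + duration(s) + 1e-9)
      stop_input("analysis window extends beyond the series")
  }
  keep <- onset >= w0 - 1e-9 & onset < w1 - 1e-9
  lab <- s$labels[keep]
  t <- onset[keep]
  step <- s$step_s

  zero <- structure(list(sleep_interval_min = 0, total_sleep_time_min = 0,
                         sleep_latency_min = 0, waso_min = 0,
                         sleep_efficiency_pct = 0,
                         awakening_index_per_h = 0, no_sleep = TRUE),
                    class = "sleep_variables")
  if (!length(lab) || !any(lab == "sleep")) return(zero)

  t_on <- t[which(lab == "sleep")[1L]]
  runs <- label_runs(lab)
  last <- nrow(runs)
  t_last <- if (runs$value[last] == "wake") t[runs$start[last]] else
    t[length(t)] + step

  in_core <- t >= t_on & t < t_last
  tst_s <- sum(lab == "sleep" & t < t_last) * step
  waso_s <- sum(lab == "wake" & in_core) * step
  interval_s <- t_last - t_on
  latency_s <- t_on - w0

  core_runs <- runs[runs$value == "wake" &
                      t[runs$start] >= t_on &
                      t[runs$end] + step <= t_last + 1e-9, , drop = FALSE]
  n_awake <- sum(core_runs$length * step > min_awakening_s)

  structure(list(
    sleep_interval_min = interval_s / 60,
    total_sleep_time_min = tst_s / 60,
    sleep_latency_min = latency_s / 60,
    waso_min = waso_s / 60,
    sleep_efficiency_pct = 100 * tst_s / (t_last - w0),
    awakening_index_per_h = n_awake / (interval_s / 3600),
    no_sleep = FALSE), class = "sleep_variables")
}

#' @export
print.sleep_variables <- function(x, ...) {
  if (x$no_sleep) {
    cat("<sleep_variables> no sleep detected\n")
    return(invisible(x))
  }
  cat(sprintf(paste0("<sleep_variables> interval %.1f min, TST %.1f min, ",
                     "latency %.1f min,\n  WASO %.1f min, efficiency ",
                     "%.1f%%, awakening index %.2f /h\n"),
              x$sleep_interval_min, x$total_sleep_time_min,
              x$sleep_latency_min, x$waso_min, x$sleep_efficiency_pct,
              x$awakening_index_per_h))
  invisible(x)
}

#' @export
as.data.frame.sleep_variables <- function(x, ...) {
  data.frame(sleep_interval_min = x$sleep_interval_min,
             total_sleep_time_min = x$total_sleep_time_min,
             sleep_latency_min = x$sleep_latency_min,
             waso_min = x$waso_min,
             sleep_efficiency_pct = x$sleep_efficiency_pct,
             awakening_index_per_h = x$awakening_index_per_h,
             no_sleep = x$no_sleep)
}

#' Assemble per-night sleep variables for a cohort
#'
#' @param series_list named list of [state_series()], one per night.
#' @param windows optional list of single-interval [interval_set()]s
#'   parallel to `series_list`.
#' @param min_awakening_s passed to [derive_sleep_variables()].
#' @return a data frame with one row per night, an `id` column and the
#'   six variable columns.
#' @export
cohort_variables <- function(series_list, windows = NULL,
                             min_awakening_s = 10) {
  ids <- names(series_list) %||% as.character(seq_along(series_list))
  rows <- lapply(seq_along(series_list), function(i) {
    w <- if (is.null(windows)) NULL else windows[[i]]
    v <- derive_sleep_variables(series_list[[i]], window = w,
                                min_awakening_s = min_awakening_s)
    cbind(id = ids[i], as.data.frame(v))
  })
  do.call(rbind, rows)
}
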