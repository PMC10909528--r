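#' Configuration for synthetic night generation
#'
#' The generator emulates the structure a thigh-worn accelerometer sees
#' over a laboratory-style night: an alternating wake/sleep bout
#' sequence, a constant gravity component fixed by the lying posture,
#' sub-cutoff sensor noise, frequent band-limited movement bursts while
#' awake, and sparse brief twitches (position shifts) while asleep.
#'
#' Defaults describe a healthy adult on a typical recording night: an
#' 8 h recording starting about 10 min before sleep onset (the cohort
#' PSG mean latency), one to two consolidated behavioural awakenings of
#' a few minutes (exponential sleep bouts, mean 4 h; wake bouts mean
#' 5 min), vigorous leg movement most seconds while awake (6 bursts/min
#' at 0.4 g), occasional small twitches during sleep (0.5/min at
#' 0.05 g), 5 mg sensor noise well under the 0.02 g gate, and a 25 Hz
#' device with the thigh horizontal (gravity on z).
#'
#' @param seed integer fixing all randomness of the night.
#' @param night_length_min recording length, minutes.
#' @param mean_sleep_bout_min mean sleep bout duration, minutes.
#' @param mean_wake_bout_min mean intra-night wake bout duration, min.
#' @param initial_wake_min fixed wake period at lights-off, minutes.
#' @param wake_burst_rate_per_min movement bursts per minute awake.
#' @param wake_burst_amp_g burst amplitude while awake, g.
#' @param sleep_twitch_rate_per_min twitches per minute asleep.
#' @param sleep_twitch_amp_g twitch amplitude, g.
#' @param noise_sd_g Gaussian sensor noise SD per axis, g.
#' @param sample_rate_hz device sampling rate, Hz.
#' @param lying_orientation unit gravity direction in the device frame
#'   while lying (x is the longitudinal thigh axis).
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1, night_length_min = 480,
                              mean_sleep_bout_min = 240,
                              mean_wake_bout_min = 5,
                              initial_wake_min = 10,
                              wake_burst_rate_per_min = 6,
                              wake_burst_amp_g = 0.4,
                              sleep_twitch_rate_per_min = 0.5,
                              sleep_twitch_amp_g = 0.05,
                              noise_sd_g = 0.005,
                              sample_rate_hz = 25,
                              lying_orientation = c(0, 0, 1)) {
  assert_scalar_number(night_length_min, "night_length_min", 0,
                       strict_lower = TRUE)
  assert_scalar_number(mean_sleep_bout_min, "mean_sleep_bout_min", 0,
                       strict_lower = TRUE)
  assert_scalar_number(mean_wake_bout_min, "mean_wake_bout_min", 0)
  assert_scalar_number(initial_wake_min, "initial_wake_min", 0)
  assert_scalar_number(wake_burst_rate_per_min, "wake_burst_rate_per_min", 0)
  assert_scalar_number(wake_burst_amp_g, "wake_burst_amp_g", 0)
  assert_scalar_number(sleep_twitch_rate_per_min,
                       "sleep_twitch_rate_per_min", 0)
  assert_scalar_number(sleep_twitch_amp_g, "sleep_twitch_amp_g", 0)
  assert_scalar_number(noise_sd_g, "noise_sd_g", 0)
  assert_scalar_number(sample_rate_hz, "sample_rate_hz", 1, 200)
  lying_orientation <- lying_orientation / sqrt(sum(lying_orientation^2))
  structure(list(seed = as.integer(seed),
                 night_length_min = night_length_min,
                 mean_sleep_bout_min = mean_sleep_bout_min,
                 mean_wake_bout_min = mean_wake_bout_min,
                 initial_wake_min = initial_wake_min,
                 wake_burst_rate_per_min = wake_burst_rate_per_min,
                 wake_burst_amp_g = wake_burst_amp_g,
                 sleep_twitch_rate_per_min = sleep_twitch_rate_per_min,
                 sleep_twitch_amp_g = sleep_twitch_amp_g,
                 noise_sd_g = noise_sd_g,
                 sample_rate_hz = sample_rate_hz,
                 lying_orientation = lying_orientation),
            class = "simulation_config")
}

#' Simulate a ground-truth sleep/wake night
#'
#' Alternating wake and sleep bouts with exponentially distributed
#' durations (memoryless, the simplest plausible run-length law),
#' starting with a fixed `initial_wake_min` of wake and truncated to the
#' night length. Bout durations are rounded to whole seconds with a 1 s
#' floor; a zero mean wake bout degenerates to a single uninterrupted
#' sleep block.
#'
#' @param cfg a [simulation_config()].
#' @return a secondwise ground-truth [state_series()].
#' @export
simulate_hypnogram <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  n_s <- as.integer(round(cfg$night_length_min * 60))
  states <- "wake"
  durs <- as.integer(round(cfg$initial_wake_min * 60))
  total <- durs
  state <- "sleep"
  while (total < n_s) {
    mean_s <- if (state == "sleep") cfg$mean_sleep_bout_min * 60 else
      cfg$mean_wake_bout_min * 60
    dur <- if (mean_s <= 0) 0L else max(1L, round(stats::rexp(1, 1 / mean_s)))
    if (dur > 0L) {
      states <- c(states, state)
      durs <- c(durs, dur)
      total <- total + dur
    }
    state <- if (state == "sleep") "wake" else "sleep"
  }
  lab <- rep(states, durs)
  state_series(lab[seq_len(n_s)], step_s = 1, start_time = 0)
}

# add one tapered band-limited oscillation (a movement burst) in place
add_burst <- function(mat, fs, start_sample, dur_s, amp_g) {
  n <- nrow(mat)
  len <- max(2L, as.integer(round(dur_s * fs)))
  idx <- start_sample:min(n, start_sample + len - 1L)
  if (length(idx) < 2L) return(mat)
  tt <- seq_along(idx) / fs
  freq <- stats::runif(1, 2, 8)
  phase <- stats::runif(1, 0, 2 * pi)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = length(idx)))
  dir <- stats::rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  wave <- amp_g * taper * sin(2 * pi * freq * tt + phase)
  mat[idx, ] <- mat[idx, ] + outer(wave, dir)
  mat
}

#' Simulate the raw accelerometer signal of a night
#'
#' Builds the tri-axial signal consistent with a ground-truth series:
#' constant gravity along the lying orientation, Gaussian sensor noise,
#' and Poisson-timed movement bursts -- 2-8 Hz tapered oscillations of
#' 1-5 s (wake) or 1-3 s (sleep twitches) in a random direction -- whose
#' rate and amplitude depend on the concurrent state. Burst frequencies
#' sit inside the 0.5-10 Hz analysis band by construction.
#'
#' @param truth a secondwise [state_series()] (e.g. from
#'   [simulate_hypnogram()]).
#' @param cfg a [simulation_config()].
#' @return an [accel_recording()] at `cfg$sample_rate_hz`.
#' @export
simulate_accel <- function(truth, cfg) {
  stopifnot(inherits(truth, "state_series"), truth$step_s == 1,
            inherits(cfg, "simulation_config"))
  set.seed(cfg$seed + 500009L)
  fs <- cfg$sample_rate_hz
  n_sec <- length(truth$labels)
  n <- as.integer(round(n_sec * fs))
  mat <- matrix(stats::rnorm(n * 3L, sd = cfg$noise_sd_g), ncol = 3L)
  mat <- mat + matrix(cfg$lying_orientation, nrow = n, ncol = 3L,
                      byrow = TRUE)
  p_start <- ifelse(truth$labels == "wake",
                    cfg$wake_burst_rate_per_min / 60,
                    cfg$sleep_twitch_rate_per_min / 60)
  starts <- which(stats::runif(n_sec) < p_start)
  for (sec in starts) {
    wake <- truth$labels[sec] == "wake"
    dur <- if (wake) stats::runif(1, 1, 5) else stats::runif(1, 1, 3)
    amp <- (if (wake) cfg$wake_burst_amp_g else cfg$sleep_twitch_amp_g) *
      stats::runif(1, 0.5, 1.5)
    mat <- add_burst(mat, fs, as.integer((sec - 1L) * fs) + 1L, dur, amp)
  }
  accel_recording(mat, fs, truth$start_time)
}

#' Simulate one complete ground-truthed night
#'
#' @param cfg a [simulation_config()].
#' @return a list: `recording` (raw [accel_recording()]), `truth`
#'   (secondwise [state_series()]), `reference` (the truth mode-filtered
#'   to 30 s epochs), `hypnogram` (the epoch truth as a binary
#'   [hypnogram()]), `lying` (the whole night as an [interval_set()]).
#' @export
simulate_night <- function(cfg) {
  truth <- simulate_hypnogram(cfg)
  rec <- simulate_accel(truth, cfg)
  ref <- epoch_mode(truth, algorithm_params())
  list(recording = rec, truth = truth, reference = ref,
       hypnogram = hypnogram(ref$labels, ref$step_s, ref$start_time),
       lying = interval_set(0, duration(truth)))
}

#' Simulate a cohort of heterogeneous nights
#'
#' Each night derives its own RNG stream from `cfg$seed` and the night
#' index, and jitters the bout means, burst parameters and initial wake
#' period log-normally around the base configuration so nights differ
#' in sleep duration and fragmentation like participants do.
#'
#' @param n_nights number of nights.
#' @param cfg base [simulation_config()].
#' @param rel_sd log-normal spread (SD on the log scale) applied to the
#'   jittered parameters; 0 replicates the base configuration.
#' @return a named list of [simulate_night()] results
#'   (`night01`, `night02`, ...).
#' @export
simulate_cohort <- function(n_nights, cfg = simulation_config(),
                            rel_sd = 0.2) {
  stopifnot(n_nights >= 1)
  nights <- lapply(seq_len(n_nights), function(i) {
    seed_i <- (cfg$seed + 7919L * i) %% .Machine$integer.max
    set.seed(seed_i)
    jit <- function(x) x * stats::rlnorm(1, 0, rel_sd)
    cfg_i <- cfg
    cfg_i$seed <- seed_i
    cfg_i$mean_sleep_bout_min <- jit(cfg$mean_sleep_bout_min)
    cfg_i$mean_wake_bout_min <- jit(cfg$mean_wake_bout_min)
    cfg_i$initial_wake_min <- jit(cfg$initial_wake_min)
    cfg_i$wake_burst_rate_per_min <- jit(cfg$wake_burst_rate_per_min)
    cfg_i$wake_burst_amp_g <- jit(cfg$wake_burst_amp_g)
    cfg_i$sleep_twitch_rate_per_min <- jit(cfg$sleep_twitch_rate_per_min)
    simulate_night(cfg_i)
  })
  names(nights) <- sprintf("night%02d", seq_len(n_nights))
  nights
}
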