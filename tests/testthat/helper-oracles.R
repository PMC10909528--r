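# Independent oracles, deliberately coded apart from the package paths
# they check.

# closed-form solution of the clamp-free index recursion:
# S_n = exp(-n/tau) * s0 + k * sum_{i=1..n} exp(-(n-i)/tau) * A_i
closed_form_index <- function(an, tau, k, s0) {
  n <- length(an)
  vapply(seq_len(n), function(m) {
    exp(-m / tau) * s0 + k * sum(exp(-(m - seq_len(m)) / tau) * an[seq_len(m)])
  }, numeric(1))
}

# shortest maximal run length in a label vector
min_run_length <- function(labels) min(rle(as.character(labels))$lengths)

# brute-force majority vote over consecutive blocks
majority_epochs <- function(labels, len) {
  n_ep <- length(labels) %/% len
  vapply(seq_len(n_ep), function(i) {
    block <- labels[((i - 1) * len + 1):(i * len)]
    n_sleep <- sum(block == "sleep")
    if (n_sleep > len - n_sleep) "sleep" else "wake"
  }, character(1))
}

# textbook Bland-Altman statistics, written from the formulas
ba_oracle <- function(device, reference) {
  d <- device - reference
  n <- length(d)
  bias <- sum(d) / n
  sd_d <- sqrt(sum((d - bias)^2) / (n - 1))
  tq <- qt(0.975, n - 1)
  list(bias = bias, sd = sd_d,
       loa = c(bias - 1.96 * sd_d, bias + 1.96 * sd_d),
       ci_bias = c(bias - tq * sd_d / sqrt(n), bias + tq * sd_d / sqrt(n)),
       ci_loa_lower = bias - 1.96 * sd_d +
         c(-1, 1) * tq * sd_d * sqrt(3 / n),
       ci_loa_upper = bias + 1.96 * sd_d +
         c(-1, 1) * tq * sd_d * sqrt(3 / n))
}

# build a state series from run lengths in seconds: runs_ss(w = 10, s = 20, ...)
runs_ss <- function(..., step_s = 1, start_time = 0) {
  spec <- c(...)
  lab <- rep(ifelse(names(spec) == "s", "sleep", "wake"), spec)
  state_series(lab, step_s = step_s, start_time = start_time)
}

# a motionless lying recording: gravity on z plus optional noise
still_recording <- function(minutes, rate_hz = 25, noise_sd = 0,
                            gravity = c(0, 0, 1), seed = 42) {
  set.seed(seed)
  n <- round(minutes * 60 * rate_hz)
  mat <- matrix(rnorm(n * 3, sd = noise_sd), ncol = 3)
  mat <- mat + matrix(gravity, nrow = n, ncol = 3, byrow = TRUE)
  accel_recording(mat, rate_hz)
}
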