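# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("thighsleep_input_error", "error")))
}

stop_param <- function(...) {
  stop(errorCondition(paste0(...), class = c("thighsleep_param_error", "error")))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_param(name, " must be a single finite number")
  if (strict_lower && x <= lower)
    stop_param(name, " must be > ", lower, " (got ", x, ")")
  if (!strict_lower && x < lower)
    stop_param(name, " must be >= ", lower, " (got ", x, ")")
  if (x > upper)
    stop_param(name, " must be <= ", upper, " (got ", x, ")")
  invisible(x)
}

# centered moving average with edge replication; k in samples (odd forced)
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k == 1L || length(x) < 2L) return(x)
  half <- (k - 1L) %/% 2L
  xp <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  cs <- cumsum(xp)
  (cs[(k):(length(xp))] - c(0, cs[seq_len(length(xp) - k)])) / k
}

# run-length view of a label vector: data.frame(value, length, start) (1-based)
label_runs <- function(labels) {
  r <- rle(as.character(labels))
  ends <- cumsum(r$lengths)
  data.frame(value = r$values, length = r$lengths,
             start = ends - r$lengths + 1L, end = ends,
             stringsAsFactors = FALSE)
}
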