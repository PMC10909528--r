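#' Tri-axial accelerometer recording
#'
#' Container for a uniformly sampled tri-axial acceleration signal in units
#' of g. `start_time` is kept in seconds (an offset against an arbitrary
#' reference, typically 0 for the start of a study night) so that all
#' downstream series share one numeric time base.
#'
#' @param data numeric matrix or data frame with columns `x`, `y`, `z` (g).
#' @param sample_rate_hz sampling frequency in Hz (> 0).
#' @param start_time recording start, seconds on the shared time base.
#' @return An object of class `accel_recording`: a list with elements
#'   `data` (n x 3 matrix), `sample_rate_hz`, `start_time`.
#' @examples
#' rec <- accel_recording(cbind(x = 0, y = 0, z = rep(1, 100)), 25)
#' duration(rec)
#' @export
accel_recording <- function(data, sample_rate_hz, start_time = 0) {
  if (is.data.frame(data)) data <- as.matrix(data[, c("x", "y", "z")])
  if (!is.matrix(data) || ncol(data) != 3L)
    stop_input("accelerometer data must have three columns x, y, z")
  storage.mode(data) <- "double"
  colnames(data) <- c("x", "y", "z")
  bad <- which(!is.finite(data))
  if (length(bad))
    stop_input("non-finite acceleration value at row ",
               (bad[1L] - 1L) %% nrow(data) + 1L)
  if (max(abs(data)) > 16)
    stop_input("acceleration beyond +/-16 g; input is not in units of g")
  assert_scalar_number(sample_rate_hz, "sample_rate_hz", 0, strict_lower = TRUE)
  assert_scalar_number(start_time, "start_time")
  structure(list(data = data,
                 sample_rate_hz = as.numeric(sample_rate_hz),
                 start_time = as.numeric(start_time)),
            class = "accel_recording")
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf("<accel_recording> %d samples @ %g Hz (%.1f s), start %.3f s\n",
              nrow(x$data), x$sample_rate_hz, duration(x), x$start_time))
  invisible(x)
}

#' Duration of a recording or series, in seconds
#' @param x an `accel_recording`, `activity_series` or `state_series`.
#' @return duration in seconds.
#' @export
duration <- function(x) UseMethod("duration")

#' @export
duration.accel_recording <- function(x) nrow(x$data) / x$sample_rate_hz

#' Read an accelerometer recording from delimited text
#'
#' Accepts two CSV dialects: `time,x,y,z` where `time` is either an
#' ISO-8601 timestamp or a numeric seconds offset, or `x,y,z` with the
#' rate supplied by a `# rate_hz: <value>` header comment or the
#' `sample_rate_hint` argument. Timestamps must be monotonically
#' increasing and uniform to within 1% jitter of the median step.
#'
#' @param path CSV file path.
#' @param sample_rate_hint fallback sampling rate in Hz when the file has
#'   no time column and no `# rate_hz:` header.
#' @return an [accel_recording()].
#' @export
read_accel <- function(path, sample_rate_hint = NULL) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  header_rate <- NA_real_
  header_start <- NA_real_
  for (line in utils::head(readLines(path, n = 10L), 10L)) {
    if (!startsWith(line, "#")) next
    m <- regmatches(line, regexec("#\\s*rate_hz:\\s*([0-9.eE+-]+)", line))[[1]]
    if (length(m) == 2L) header_rate <- as.numeric(m[2])
    m <- regmatches(line, regexec("#\\s*start_s:\\s*([0-9.eE+-]+)", line))[[1]]
    if (length(m) == 2L) header_start <- as.numeric(m[2])
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("x", "y", "z") %in% names(df)))
    stop_input("accelerometer file must have columns x, y, z: ", path)

  if ("time" %in% names(df)) {
    tm <- df$time
    if (is.character(tm)) {
      parsed <- as.POSIXct(tm, tz = "UTC",
                           tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                          "%Y-%m-%d %H:%M:%OS"))
      if (anyNA(parsed)) stop_input("unparseable timestamp at row ",
                                    which(is.na(parsed))[1L])
      tm <- as.numeric(parsed)
    }
    dt <- diff(tm)
    bad <- which(dt <= 0)
    if (length(bad))
      stop_input("non-increasing timestamp at row ", bad[1L] + 1L)
    step <- stats::median(dt)
    if (max(abs(dt - step)) > 0.01 * step)
      stop_input("non-uniform sampling: timestamp jitter exceeds 1% of the ",
                 sprintf("median step (%.6g s)", step))
    rate <- 1 / step
    start <- tm[1L]
  } else {
    rate <- if (!is.na(header_rate)) header_rate else sample_rate_hint
    if (is.null(rate) || is.na(rate))
      stop_input("no time column, no '# rate_hz:' header and no ",
                 "sample_rate_hint; cannot establish the sampling rate")
    start <- if (!is.na(header_start)) header_start else 0
  }
  accel_recording(df[, c("x", "y", "z")], rate, start)
}

#' Write an accelerometer recording as delimited text
#'
#' Inverse of [read_accel()]; values are written with six decimal places,
#' the rate and start offset go into `#` header comments.
#'
#' @param r an [accel_recording()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_accel <- function(r, path) {
  stopifnot(inherits(r, "accel_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# rate_hz: %.10g", r$sample_rate_hz),
               sprintf("# start_s: %.6f", r$start_time),
               "x,y,z"), con)
  writeLines(sprintf("%.6f,%.6f,%.6f",
                     r$data[, 1], r$data[, 2], r$data[, 3]), con)
  invisible(path)
}

#' Resample a recording to a new uniform rate
#'
#' Linear interpolation onto the target grid. When downsampling, a
#' zero-phase Butterworth low-pass at 90% of the target Nyquist guards
#' against aliasing; upsampling needs no guard because no content exists
#' above the source Nyquist. The output spans the same duration as the
#' input to within one sample period.
#'
#' @param r an [accel_recording()].
#' @param target_rate_hz new rate, 1 to 200 Hz.
#' @return an [accel_recording()] at `target_rate_hz`.
#' @export
resample_accel <- function(r, target_rate_hz) {
  stopifnot(inherits(r, "accel_recording"))
  assert_scalar_number(target_rate_hz, "target_rate_hz", 1, 200)
  n <- nrow(r$data)
  if (n < 2L) stop_input("cannot resample a recording with < 2 samples")
  if (identical(as.numeric(target_rate_hz), r$sample_rate_hz)) return(r)

  src <- r$data
  if (target_rate_hz < r$sample_rate_hz) {
    guard_hz <- 0.9 * target_rate_hz / 2
    bf <- signal::butter(4, guard_hz / (r$sample_rate_hz / 2), type = "low")
    src <- apply(src, 2L, function(col) filtfilt_padded(bf, col))
  }
  t_src <- (seq_len(n) - 1L) / r$sample_rate_hz
  n_out <- max(2L, round(n * target_rate_hz / r$sample_rate_hz))
  t_out <- (seq_len(n_out) - 1L) / target_rate_hz
  out <- apply(src, 2L, function(col)
    stats::approx(t_src, col, xout = t_out, rule = 2)$y)
  accel_recording(out, target_rate_hz, r$start_time)
}

#' Shift the start time of a recording
#'
#' Replaces a physical device-synchronisation event with a numeric clock
#' offset: the samples are untouched, only the recording's position on
#' the shared time base moves.
#'
#' @param r an [accel_recording()].
#' @param offset_s seconds to add to the start time.
#' @return the shifted recording.
#' @export
apply_offset <- function(r, offset_s) {
  stopifnot(inherits(r, "accel_recording"))
  assert_scalar_number(offset_s, "offset_s")
  r$start_time <- r$start_time + offset_s
  r
}
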