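#' Scored hypnogram
#'
#' Ordered sleep-stage labels in fixed-length epochs. Accepted stages are
#' the AASM alphabet `W, N1, N2, N3, R` or the already-binary labels
#' `wake, sleep`. Legacy R&K stages (`S1`-`S4`, `MT`) are rejected unless
#' an explicit `stage_map` translates them, to avoid silent
#' misclassification.
#'
#' @param stages character vector of stage labels.
#' @param epoch_length_s scoring epoch length, seconds (default 30).
#' @param start_time start of the first epoch, seconds on the shared base.
#' @param stage_map optional named character vector mapping non-standard
#'   tokens onto the accepted alphabet, e.g. `c(S1 = "N1", S2 = "N2")`.
#' @return an object of class `hypnogram`.
#' @export
hypnogram <- function(stages, epoch_length_s = 30, start_time = 0,
                      stage_map = NULL) {
  if (length(stages) == 0L) stop_input("hypnogram has no epochs")
  assert_scalar_number(epoch_length_s, "epoch_length_s", 0, strict_lower = TRUE)
  stages <- as.character(stages)
  if (!is.null(stage_map)) {
    hit <- stages %in% names(stage_map)
    stages[hit] <- unname(stage_map[stages[hit]])
  }
  allowed <- c("W", "N1", "N2", "N3", "R", "wake", "sleep")
  unknown <- setdiff(unique(stages), allowed)
  if (length(unknown))
    stop_input("unknown stage token(s): ", paste(unknown, collapse = ", "),
               " (pass stage_map= to translate legacy staging)")
  structure(list(stages = stages,
                 epoch_length_s = as.numeric(epoch_length_s),
                 start_time = as.numeric(start_time)),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d epochs x %g s, start %.1f s\n",
              length(x$stages), x$epoch_length_s, x$start_time))
  invisible(x)
}

#' Read a hypnogram from delimited text
#'
#' Expects a CSV with a `stage` column; the epoch length is taken from a
#' `# epoch_s: <value>` header comment, defaulting to 30 s.
#'
#' @inheritParams hypnogram
#' @param path CSV file path.
#' @return a [hypnogram()].
#' @export
read_hypnogram <- function(path, stage_map = NULL) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  epoch_s <- 30
  start_s <- 0
  for (line in utils::head(readLines(path, n = 10L), 10L)) {
    if (!startsWith(line, "#")) next
    m <- regmatches(line, regexec("#\\s*epoch_s:\\s*([0-9.eE+-]+)", line))[[1]]
    if (length(m) == 2L) epoch_s <- as.numeric(m[2])
    m <- regmatches(line, regexec("#\\s*start_s:\\s*([0-9.eE+-]+)", line))[[1]]
    if (length(m) == 2L) start_s <- as.numeric(m[2])
  }
  df <- tryCatch(utils::read.csv(path, comment.char = "#",
                                 stringsAsFactors = FALSE),
                 error = function(e) stop_input("empty or unreadable ",
                                                "hypnogram file: ", path))
  if (!"stage" %in% names(df) || nrow(df) == 0L)
    stop_input("hypnogram file must have a non-empty 'stage' column: ", path)
  hypnogram(df$stage, epoch_s, start_s, stage_map = stage_map)
}

#' Write a hypnogram as delimited text
#' @param h a [hypnogram()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(h, path) {
  stopifnot(inherits(h, "hypnogram"))
  writeLines(c(sprintf("# epoch_s: %.10g", h$epoch_length_s),
               sprintf("# start_s: %.6f", h$start_time),
               "stage", h$stages), path)
  invisible(path)
}

#' Binary sleep/wake series
#'
#' The common currency of the pipeline: ordered `"sleep"`/`"wake"` labels
#' at a fixed step (1 s secondwise, or the scoring epoch length).
#'
#' @param labels character vector of `"sleep"`/`"wake"`.
#' @param step_s label spacing in seconds.
#' @param start_time start of the first label, seconds.
#' @return an object of class `state_series`.
#' @export
state_series <- function(labels, step_s = 1, start_time = 0) {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop_input("state series has no labels")
  bad <- setdiff(unique(labels), c("sleep", "wake"))
  if (length(bad)) stop_input("labels must be sleep/wake, got: ",
                              paste(bad, collapse = ", "))
  assert_scalar_number(step_s, "step_s", 0, strict_lower = TRUE)
  structure(list(labels = labels, step_s = as.numeric(step_s),
                 start_time = as.numeric(start_time)),
            class = "state_series")
}

#' @export
print.state_series <- function(x, ...) {
  cat(sprintf("<state_series> %d labels x %g s (%.1f min sleep)\n",
              length(x$labels), x$step_s,
              sum(x$labels == "sleep") * x$step_s / 60))
  invisible(x)
}

#' @export
duration.state_series <- function(x) length(x$labels) * x$step_s

#' Collapse a staged hypnogram to binary sleep/wake
#'
#' `W` maps to wake; `N1`, `N2`, `N3` and `R` all map to sleep. Inputs
#' already labelled `wake`/`sleep` pass through unchanged. The epoch time
#' base is preserved.
#'
#' @param h a [hypnogram()].
#' @return a [state_series()] at the hypnogram's epoch length.
#' @export
binarize_hypnogram <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  lab <- ifelse(h$stages %in% c("W", "wake"), "wake", "sleep")
  state_series(lab, h$epoch_length_s, h$start_time)
}

#' Write a state series as delimited text
#'
#' One row per label: `start_s,label`, where `start_s` is the label's
#' onset on the shared time base.
#'
#' @param s a [state_series()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_states <- function(s, path) {
  stopifnot(inherits(s, "state_series"))
  onset <- s$start_time + (seq_along(s$labels) - 1L) * s$step_s
  writeLines(c(sprintf("# step_s: %.10g", s$step_s), "start_s,label",
               sprintf("%.1f,%s", onset, s$labels)), path)
  invisible(path)
}

#' Read a state series written by [write_states()]
#' @param path CSV file path.
#' @return a [state_series()].
#' @export
read_states <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  step <- 1
  for (line in utils::head(readLines(path, n = 5L), 5L)) {
    m <- regmatches(line, regexec("#\\s*step_s:\\s*([0-9.eE+-]+)", line))[[1]]
    if (length(m) == 2L) step <- as.numeric(m[2])
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  state_series(df$label, step, df$start_s[1L])
}

#' Ordered set of half-open time intervals
#'
#' Carries lying bouts and analysis windows as `[start_s, end_s)` offsets
#' on the shared time base. Intervals must be sorted and non-overlapping.
#'
#' @param start_s,end_s numeric vectors of equal length.
#' @return an object of class `interval_set` (a data frame).
#' @export
interval_set <- function(start_s = numeric(), end_s = numeric()) {
  if (length(start_s) != length(end_s))
    stop_input("start_s and end_s must have equal length")
  if (any(end_s <= start_s)) stop_input("intervals must satisfy end > start")
  if (is.unsorted(start_s, strictly = TRUE) && length(start_s) > 1L)
    stop_input("intervals must be sorted by start")
  if (length(start_s) > 1L && any(start_s[-1L] < end_s[-length(end_s)]))
    stop_input("intervals must not overlap")
  structure(data.frame(start_s = as.numeric(start_s),
                       end_s = as.numeric(end_s)),
            class = c("interval_set", "data.frame"))
}

#' Read lying-bout / window intervals from CSV (`start_s,end_s`)
#' @param path CSV file path.
#' @return an [interval_set()].
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(interval_set())
  interval_set(df$start_s, df$end_s)
}

#' Write intervals as CSV (`start_s,end_s`)
#' @param iv an [interval_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(iv, path) {
  utils::write.csv(as.data.frame(unclass(iv))[c("start_s", "end_s")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
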