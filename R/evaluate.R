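#' Epoch-by-epoch confusion statistics against PSG
#'
#' Sleep is the positive class: TP = both say sleep, FP = device sleep
#' but reference wake, TN = both wake, FN = device wake but reference
#' sleep. Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), accuracy =
#' (TP+TN)/total. A zero denominator (e.g. an all-sleep reference night
#' has no wake epochs, so specificity does not exist) yields `NA` and
#' the statistic's name in `undefined`, never a silent NaN.
#'
#' @param pred device-derived epochwise [state_series()].
#' @param ref PSG-derived epochwise [state_series()] of equal length.
#' @return an object of class `confusion_stats`.
#' @export
epoch_confusion <- function(pred, ref) {
  stopifnot(inherits(pred, "state_series"), inherits(ref, "state_series"))
  if (length(pred$labels) != length(ref$labels))
    stop_input("epoch series lengths differ: device ", length(pred$labels),
               " vs reference ", length(ref$labels))
  p <- pred$labels == "sleep"
  r <- ref$labels == "sleep"
  tp <- sum(p & r); fp <- sum(p & !r); tn <- sum(!p & !r); fn <- sum(!p & r)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- safe(tp, tp + fn)
  spec <- safe(tn, tn + fp)
  acc <- safe(tp + tn, tp + tn + fp + fn)
  undef <- c("sensitivity", "specificity", "accuracy")[is.na(c(sens, spec, acc))]
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec, accuracy = acc,
                 undefined = undef),
            class = "confusion_stats")
}

#' @export
print.confusion_stats <- function(x, ...) {
  cat(sprintf(paste0("<confusion_stats> tp %d fp %d tn %d fn %d | ",
                     "sens %.3f spec %.3f acc %.3f\n"),
              x$tp, x$fp, x$tn, x$fn, x$sensitivity, x$specificity,
              x$accuracy))
  if (length(x$undefined))
    cat("  undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Cohort mean and SD of per-participant confusion statistics
#'
#' Averages per participant (not pooled over epochs). Undefined entries
#' are excluded from that statistic's mean/SD, with the exclusion count
#' reported.
#'
#' @param stats list of [epoch_confusion()] results.
#' @return a data frame with one row per statistic: `mean`, `sd`
#'   (sample), `n`, `n_excluded`.
#' @export
cohort_confusion <- function(stats) {
  if (!length(stats)) stop_input("no confusion statistics supplied")
  one <- function(field) {
    v <- vapply(stats, function(x) x[[field]], numeric(1))
    ok <- !is.na(v)
    data.frame(statistic = field, mean = mean(v[ok]),
               sd = if (sum(ok) > 1L) stats::sd(v[ok]) else NA_real_,
               n = sum(ok), n_excluded = sum(!ok))
  }
  do.call(rbind, lapply(c("sensitivity", "specificity", "accuracy"), one))
}

#' Bland-Altman agreement between device and reference measurements
#'
#' Differences are taken device minus reference, so a device that
#' underestimates shows a negative bias. Reports the bias with its
#' t-based 95% CI, the sample SD of the differences, the 95% limits of
#' agreement `bias +/- 1.96 SD`, their CIs via the classic
#' `SE = SD * sqrt(3/n)` approximation, the limits-of-agreement range
#' (LoAR, the distance between the two limits, a precision measure),
#' and the Pearson correlation with its Fisher-z CI.
#'
#' @param device numeric vector of device-derived values.
#' @param reference numeric vector of reference (PSG) values, paired.
#' @param conf confidence level (default 0.95).
#' @return an object of class `agreement_result`.
#' @export
bland_altman <- function(device, reference, conf = 0.95) {
  if (length(device) != length(reference))
    stop_input("device and reference must be paired (equal length)")
  ok <- is.finite(device) & is.finite(reference)
  device <- device[ok]; reference <- reference[ok]
  n <- length(device)
  if (n < 3L) stop_input("need at least 3 pairs, got ", n)
  d <- device - reference
  bias <- mean(d)
  sd_d <- stats::sd(d)
  z <- 1.96
  tcrit <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
  loa_l <- bias - z * sd_d
  loa_u <- bias + z * sd_d
  se_bias <- sd_d / sqrt(n)
  se_loa <- sd_d * sqrt(3 / n)
  if (sd_d > 0 && stats::sd(device) > 0 && stats::sd(reference) > 0) {
    ct <- stats::cor.test(device, reference, conf.level = conf)
    r <- unname(ct$estimate)
    ci_r <- as.numeric(ct$conf.int)
  } else {
    r <- NA_real_
    ci_r <- c(NA_real_, NA_real_)
  }
  structure(list(
    n = n, bias = bias, sd_diff = sd_d,
    loa_lower = loa_l, loa_upper = loa_u,
    loar = loa_u - loa_l,
    ci_bias = bias + c(-1, 1) * tcrit * se_bias,
    ci_loa_lower = loa_l + c(-1, 1) * tcrit * se_loa,
    ci_loa_upper = loa_u + c(-1, 1) * tcrit * se_loa,
    pearson_r = r, ci_r = ci_r),
    class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(paste0("<agreement_result> n %d | bias %.2f [%.2f, %.2f] | ",
                     "LoA [%.2f, %.2f] (LoAR %.2f) | r %.2f\n"),
              x$n, x$bias, x$ci_bias[1], x$ci_bias[2],
              x$loa_lower, x$loa_upper, x$loar, x$pearson_r))
  invisible(x)
}

#' Limits-of-agreement range from published limits
#'
#' The precision measure reported alongside the bias: the distance
#' between the upper and lower 95% limits of agreement. Useful to
#' recompute precision from tabulated limits.
#'
#' @param loa_lower,loa_upper the lower and upper limits.
#' @return `loa_upper - loa_lower`.
#' @export
loa_range <- function(loa_lower, loa_upper) loa_upper - loa_lower

#' Table of agreement statistics for the six sleep variables
#'
#' @param device,reference data frames from [cohort_variables()], paired
#'   by `id` (an error names unmatched ids).
#' @param conf confidence level.
#' @return a data frame, one row per variable, with the
#'   [bland_altman()] statistics spread into columns.
#' @export
agreement_table <- function(device, reference, conf = 0.95) {
  miss <- c(setdiff(device$id, reference$id), setdiff(reference$id, device$id))
  if (length(miss))
    stop_input("unmatched night ids: ", paste(unique(miss), collapse = ", "))
  reference <- reference[match(device$id, reference$id), ]
  vars <- c("sleep_interval_min", "total_sleep_time_min",
            "sleep_latency_min", "waso_min", "sleep_efficiency_pct",
            "awakening_index_per_h")
  rows <- lapply(vars, function(v) {
    ba <- bland_altman(device[[v]], reference[[v]], conf = conf)
    data.frame(variable = v, n = ba$n, bias = ba$bias,
               ci_bias_l = ba$ci_bias[1], ci_bias_u = ba$ci_bias[2],
               loa_lower = ba$loa_lower,
               ci_loa_lower_l = ba$ci_loa_lower[1],
               ci_loa_lower_u = ba$ci_loa_lower[2],
               loa_upper = ba$loa_upper,
               ci_loa_upper_l = ba$ci_loa_upper[1],
               ci_loa_upper_u = ba$ci_loa_upper[2],
               loar = ba$loar, pearson_r = ba$pearson_r,
               ci_r_l = ba$ci_r[1], ci_r_u = ba$ci_r[2])
  })
  do.call(rbind, rows)
}

#' Outlier sensitivity analysis on extreme sleepers
#'
#' Repeats the cohort agreement analysis after excluding nights whose
#' reference total sleep time lies more than 2 SD from the cohort mean
#' (very short or very long sleepers), to gauge how much they drive the
#' agreement statistics.
#'
#' @inheritParams agreement_table
#' @param sd_multiple exclusion threshold in SDs of reference TST.
#' @return a list: `excluded_ids`, `retained` ([agreement_table()] on
#'   the remainder), `full` (the all-nights table).
#' @export
outlier_sensitivity <- function(device, reference, sd_multiple = 2,
                                conf = 0.95) {
  if (nrow(device) < 5L) stop_input("need at least 5 nights, got ",
                                    nrow(device))
  full <- agreement_table(device, reference, conf = conf)
  reference <- reference[match(device$id, reference$id), ]
  tst <- reference$total_sleep_time_min
  out <- abs(tst - mean(tst)) > sd_multiple * stats::sd(tst)
  retained <- agreement_table(device[!out, , drop = FALSE],
                              reference[!out, , drop = FALSE], conf = conf)
  list(excluded_ids = as.character(device$id[out]), retained = retained,
       full = full)
}
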