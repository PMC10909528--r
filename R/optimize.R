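#' Grid search over the index time constant and gain
#'
#' Reproduces the calibration procedure: for every (tau, k) cell the
#' full pipeline is run on each recording, confusion statistics are
#' computed against its PSG reference, and the cell is scored by the sum
#' of the cohort sensitivity and specificity. Preprocessing (the
#' per-second activity and the lying bouts) does not depend on tau or k
#' and is computed once per recording.
#'
#' @param dataset list of nights, each a list with elements `recording`
#'   (an [accel_recording()]), `reference` (an epochwise
#'   [state_series()]) and optionally `lying` (an [interval_set()];
#'   detected from posture when absent).
#' @param tau_grid_s strictly increasing tau values, seconds.
#' @param k_grid strictly increasing gain values.
#' @param params baseline [algorithm_params()] supplying the non-searched
#'   constants.
#' @param spec a [filter_spec()].
#' @param pooled score cells on epoch counts pooled over all nights
#'   instead of the mean of per-night statistics.
#' @return an object of class `optimization_result`: `surface` (a data
#'   frame with one row per cell: `tau_s`, `k_gain`, `mean_sens`,
#'   `mean_spec`, `sum_sens_spec`, `n_valid`) and `best` (the argmax
#'   row; ties resolve to the smallest tau, then the smallest k).
#' @export
grid_search <- function(dataset, tau_grid_s, k_grid,
                        params = algorithm_params(), spec = filter_spec(),
                        pooled = FALSE) {
  if (!length(dataset)) stop_input("empty dataset")
  if (is.unsorted(tau_grid_s, strictly = TRUE) && length(tau_grid_s) > 1L)
    stop_param("tau_grid_s must be strictly increasing")
  if (is.unsorted(k_grid, strictly = TRUE) && length(k_grid) > 1L)
    stop_param("k_grid must be strictly increasing")

  prep <- lapply(dataset, function(night) {
    bouts <- night$lying
    if (is.null(bouts)) bouts <- detect_lying_bouts(night$recording, params)
    list(activity = compute_activity(night$recording, spec),
         bouts = bouts, reference = night$reference)
  })

  cells <- expand.grid(k_gain = k_grid, tau_s = tau_grid_s)[, 2:1]
  score_cell <- function(tau, k) {
    p <- params
    p$tau_s <- tau
    p$k_gain <- k
    stats <- lapply(prep, function(pr) {
      tryCatch({
        st <- classify_states(sleep_index(pr$activity, p), p)
        st <- backshift_awakenings(median_clean(st, p), p)
        st <- restrict_to_lying(st, pr$bouts)
        epoch_confusion(epoch_mode(st, p), pr$reference)
      }, error = function(e) NULL)
    })
    stats <- stats[!vapply(stats, is.null, logical(1))]
    if (!length(stats))
      return(c(mean_sens = NA_real_, mean_spec = NA_real_, n_valid = 0))
    if (pooled) {
      tp <- sum(vapply(stats, `[[`, 0, "tp"))
      fn <- sum(vapply(stats, `[[`, 0, "fn"))
      tn <- sum(vapply(stats, `[[`, 0, "tn"))
      fp <- sum(vapply(stats, `[[`, 0, "fp"))
      sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
      spc <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    } else {
      sens <- mean(vapply(stats, `[[`, 0, "sensitivity"), na.rm = TRUE)
      spc <- mean(vapply(stats, `[[`, 0, "specificity"), na.rm = TRUE)
    }
    c(mean_sens = sens, mean_spec = spc, n_valid = length(stats))
  }

  sc <- t(mapply(score_cell, cells$tau_s, cells$k_gain))
  surface <- data.frame(tau_s = cells$tau_s, k_gain = cells$k_gain,
                        mean_sens = sc[, "mean_sens"],
                        mean_spec = sc[, "mean_spec"],
                        sum_sens_spec = sc[, "mean_sens"] + sc[, "mean_spec"],
                        n_valid = sc[, "n_valid"])
  ord <- order(surface$tau_s, surface$k_gain)
  surface <- surface[ord, ]
  rownames(surface) <- NULL
  valid <- which(!is.na(surface$sum_sens_spec))
  if (!length(valid)) stop_input("every grid cell failed to evaluate")
  best_i <- valid[which.max(surface$sum_sens_spec[valid])]
  structure(list(surface = surface, best = surface[best_i, ],
                 n_tau = length(tau_grid_s), n_k = length(k_grid)),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf(paste0("<optimization_result> %d x %d grid | best tau %.1f ",
                     "min, k %.3g (sens %.3f + spec %.3f = %.3f)\n"),
              x$n_tau, x$n_k, x$best$tau_s / 60, x$best$k_gain,
              x$best$mean_sens, x$best$mean_spec, x$best$sum_sens_spec))
  invisible(x)
}

#' Write a grid-search surface as long-format CSV
#'
#' Columns `tau_min,k,sens,spec,sum`, suitable for rendering a
#' sensitivity/specificity heat map over the parameter plane.
#'
#' @param res an [grid_search()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_surface <- function(res, path) {
  stopifnot(inherits(res, "optimization_result"))
  df <- data.frame(tau_min = res$surface$tau_s / 60,
                   k = res$surface$k_gain,
                   sens = res$surface$mean_sens,
                   spec = res$surface$mean_spec,
                   sum = res$surface$sum_sens_spec)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
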