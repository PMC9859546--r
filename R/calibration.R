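#' Labeled material-handling tasks for threshold calibration
#'
#' Each task carries a vertebral fatigue-failure probability and an observed
#' low/high-risk label (from low-back-pain incidence). [calibrate()] chooses
#' the probability cutoff that classifies these labels best.
#'
#' @param id Character task identifiers.
#' @param failure_probability Fractions in \[0, 1\].
#' @param label `"low"` or `"high"` per task.
#' @return A tibble of class `mate_tasks` with those three columns.
#' @export
labeled_tasks <- function(id, failure_probability, label) {
  if (length(id) == 0L) {
    abort_input("Task list must be non-empty.", class = "mate_empty_tasks")
  }
  if (length(failure_probability) != length(id) ||
      length(label) != length(id)) {
    abort_input("`id`, `failure_probability` and `label` must have equal length.")
  }
  if (any(failure_probability < 0) || any(failure_probability > 1) ||
      anyNA(failure_probability)) {
    abort_input("`failure_probability` must lie in [0, 1].")
  }
  if (!all(label %in% c("low", "high"))) {
    abort_input('`label` must be "low" or "high".')
  }
  out <- tibble::tibble(id = as.character(id),
                        failure_probability = as.numeric(failure_probability),
                        label = as.character(label))
  structure(out, class = c("mate_tasks", class(out)))
}

#' @describeIn labeled_tasks Read tasks from a CSV with columns
#'   `id`, `failure_probability`, `label`.
#' @param path Path to the CSV file.
#' @export
read_labeled_tasks <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("File not found: %s", path))
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  need <- c("id", "failure_probability", "label")
  if (!all(need %in% names(df))) {
    abort_input("Task CSV needs columns id, failure_probability, label.")
  }
  labeled_tasks(df$id, df$failure_probability, df$label)
}

as_mate_tasks <- function(tasks) {
  if (inherits(tasks, "mate_tasks")) return(tasks)
  if (is.data.frame(tasks)) {
    return(labeled_tasks(tasks$id %||% seq_len(nrow(tasks)),
                         tasks$failure_probability, tasks$label))
  }
  abort_input("`tasks` must be a data frame of labeled tasks.")
}

#' Classification performance of a probability cutoff
#'
#' A task is predicted high risk when its failure probability strictly
#' exceeds the threshold (set `ties_high = TRUE` for the `>=` convention).
#' Returns the confusion matrix and the overall, high-risk (sensitivity) and
#' low-risk (specificity) classification accuracies. When only one label is
#' present, the accuracy for the absent class is `NA` and flagged.
#'
#' @param tasks A [labeled_tasks()] tibble (or plain data frame with the
#'   same columns).
#' @param threshold Probability cutoff, a fraction.
#' @param ties_high If `TRUE`, tasks exactly at the threshold are predicted
#'   high risk (`>=` rule); default `FALSE` (strict `>`).
#' @return A one-row tibble of class `mate_calibration`: `threshold`,
#'   `overall_accuracy`, `high_risk_accuracy`, `low_risk_accuracy`, `tp`,
#'   `fn`, `fp`, `tn`, `single_class`.
#' @examples
#' tasks <- labeled_tasks(c("a", "b"), c(0.05, 0.20), c("low", "high"))
#' evaluate_threshold(tasks, 0.10)
#' @export
evaluate_threshold <- function(tasks, threshold, ties_high = FALSE) {
  tasks <- as_mate_tasks(tasks)
  threshold <- check_number(threshold, "threshold", lower = 0, upper = 1)
  pred_high <- if (ties_high) {
    tasks$failure_probability >= threshold
  } else {
    tasks$failure_probability > threshold
  }
  is_high <- tasks$label == "high"
  tp <- sum(pred_high & is_high)
  fn <- sum(!pred_high & is_high)
  fp <- sum(pred_high & !is_high)
  tn <- sum(!pred_high & !is_high)
  n_high <- tp + fn
  n_low <- fp + tn
  single <- n_high == 0L || n_low == 0L
  out <- tibble::tibble(
    threshold = threshold,
    overall_accuracy = (tp + tn) / nrow(tasks),
    high_risk_accuracy = if (n_high > 0L) tp / n_high else NA_real_,
    low_risk_accuracy = if (n_low > 0L) tn / n_low else NA_real_,
    tp = tp, fn = fn, fp = fp, tn = tn,
    single_class = single
  )
  structure(out, class = c("mate_calibration", class(out)))
}

calibration_grid <- function(p) {
  # candidate cutoffs at midpoints between adjacent distinct probabilities;
  # with a strict ">" rule the accuracy profile is constant between
  # observations, so this grid is exact
  u <- sort(unique(p))
  sort(unique(c(0, (u[-length(u)] + u[-1L]) / 2, u[length(u)], 1)))
}

#' Calibrate the failure-probability risk cutoff
#'
#' Sweeps candidate thresholds at the midpoints between adjacent distinct
#' failure probabilities (plus 0 and 1) and returns the one maximizing
#' overall classification accuracy. Because the decision rule is a strict
#' `>`, accuracy is piecewise constant between observations and the midpoint
#' grid evaluates every achievable confusion matrix exactly. Ties are broken
#' in favour of higher high-risk accuracy (protective: fewer missed
#' high-risk tasks), then the lowest threshold.
#'
#' @inheritParams evaluate_threshold
#' @return A one-row `mate_calibration` tibble (see [evaluate_threshold()])
#'   with attribute `sweep`: the full threshold-sweep tibble.
#' @examples
#' tasks <- labeled_tasks(letters[1:4], c(.02, .05, .2, .4),
#'                        c("low", "low", "high", "high"))
#' calibrate(tasks)$threshold  # strictly between 0.05 and 0.2
#' @export
calibrate <- function(tasks, ties_high = FALSE) {
  tasks <- as_mate_tasks(tasks)
  grid <- calibration_grid(tasks$failure_probability)
  sweep <- purrr::map_dfr(grid, function(th) {
    evaluate_threshold(tasks, th, ties_high = ties_high)
  })
  best <- sweep |>
    dplyr::arrange(dplyr::desc(.data$overall_accuracy),
                   dplyr::desc(dplyr::coalesce(.data$high_risk_accuracy, -1)),
                   .data$threshold) |>
    dplyr::slice(1L)
  best <- structure(best, class = c("mate_calibration", class(tibble::tibble())))
  attr(best, "sweep") <- sweep
  best
}

#' @export
print.mate_calibration <- function(x, ...) {
  cat(sprintf(
    "<calibration> threshold %.4g | overall %.1f%% | high-risk %.1f%% | low-risk %.1f%%\n",
    x$threshold, 100 * x$overall_accuracy,
    100 * x$high_risk_accuracy, 100 * x$low_risk_accuracy))
  invisible(x)
}
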