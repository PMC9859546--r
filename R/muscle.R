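#' Duty cycle of a task schedule
#'
#' The duty cycle (DC) is the fraction of total working time spent executing
#' the loaded movement: one cycle's duration times its repetition rate,
#' relative to the minute. A 6 s task performed five times per minute
#' occupies 30 s of every minute, a duty cycle of 50%.
#'
#' @param schedule A [task_schedule()].
#' @return The duty cycle as a fraction in \[0, 1\].
#' @export
duty_cycle <- function(schedule) {
  stopifnot(inherits(schedule, "mate_schedule"))
  schedule$cycle_duration * schedule$repetitions_per_minute / 60
}

#' Maximal acceptable effort at a given duty cycle
#'
#' The maximal acceptable effort (MAE) is the activation fraction a muscle
#' can sustain at a given duty cycle without excessive fatigue:
#' \deqn{MAE = 1 - (DC - 1/28800)^{0.24}}
#' The offset 1/28800 corresponds to a single maximal effort in an 8 h shift
#' (28800 s), where the full effort (MAE = 1) is acceptable. MAE decreases
#' strictly as the duty cycle grows; at DC = 0.30 it is 25.1%.
#'
#' @param dc Duty cycle, a fraction; must be at least 1/28800 (a fractional
#'   power of a negative base is undefined).
#' @return MAE as a fraction in \[0, 1\].
#' @examples
#' mae(0.5)   # 0.1533
#' mae(duty_cycle(task_schedule(6, 3, 120)))  # 0.251
#' @export
mae <- function(dc) {
  if (!is.numeric(dc) || any(!is.finite(dc))) {
    abort_input("`dc` must be finite numeric.")
  }
  if (any(dc < 1 / 28800)) {
    abort_input(sprintf(
      "Duty cycle %g is below 1/28800; the effort equation is undefined there.",
      min(dc)), class = "mate_domain_error")
  }
  if (any(dc > 1)) {
    abort_input("Duty cycle cannot exceed 1.", class = "mate_domain_error")
  }
  1 - (dc - 1 / 28800)^0.24
}

#' Muscle-group risk from peak activations
#'
#' A functional muscle group is considered at risk when at least half of its
#' agonists (the ceiling for odd group sizes) have a peak activation that
#' strictly exceeds the maximal acceptable effort: the remaining compensatory
#' reserve is then substantially limited. Peaks are the raw per-channel
#' maxima over time (see [trace_peaks()]; an optional smoothing window is
#' available there for noisy field data).
#'
#' @param trace An activation [mate_trace()].
#' @param catalog A [muscle_catalog()].
#' @param mae_threshold The maximal acceptable effort, a fraction (see
#'   [mae()]).
#' @param window Passed to [trace_peaks()]; default 1 (no smoothing).
#' @return A tibble with one row per group: `group`, `n_channels`,
#'   `n_exceeding`, `n_required` (the at-risk quorum, `ceiling(n/2)`),
#'   `at_risk`, and a `peaks` list-column of named per-channel peak
#'   activations.
#' @examples
#' tr <- mate_trace(data.frame(time = 0:2 / 10, a = c(0, .4, .1),
#'                             b = c(0, .1, .05)), kind = "activation")
#' cat <- muscle_catalog(list(flexors = c("a", "b")))
#' group_risk(tr, cat, mae_threshold = 0.251)
#' @export
group_risk <- function(trace, catalog, mae_threshold, window = 1L) {
  stopifnot(inherits(trace, "mate_trace"), inherits(catalog, "mate_catalog"))
  if (trace_kind(trace) != "activation") {
    abort_input("`trace` must hold activations, not forces.")
  }
  mae_threshold <- check_number(mae_threshold, "mae_threshold",
                                lower = 0, upper = 1)
  missing <- setdiff(unique(catalog$channel), trace_channels(trace))
  if (length(missing) > 0L) {
    abort_input(paste0("Catalog channels absent from the trace: ",
                       paste(missing, collapse = ", ")),
                class = "mate_lookup_error")
  }
  peaks <- trace_peaks(trace, window = window)
  catalog |>
    dplyr::left_join(peaks, by = "channel") |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_channels = dplyr::n(),
      n_exceeding = sum(.data$peak > mae_threshold),
      n_required = ceiling(dplyr::n() / 2),
      at_risk = .data$n_exceeding >= .data$n_required,
      peaks = list(stats::setNames(.data$peak, .data$channel)),
      .groups = "drop"
    ) |>
    dplyr::mutate(mae = mae_threshold, .after = "group")
}
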