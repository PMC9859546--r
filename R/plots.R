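#' Plot a trace
#'
#' Channels over time, faceting-free line plot coloured by channel.
#'
#' @param object A [mate_trace()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mate_trace
#' @export
autoplot.mate_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"time",
                              names_to = "channel", values_to = "value")
  ylab <- if (trace_kind(object) == "activation") {
    "activation (fraction)"
  } else {
    "force (N)"
  }
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value,
                                     colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = ylab,
                  title = attr(object, "trace_name")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a calibration threshold sweep
#'
#' Overall, high-risk and low-risk classification accuracy as a step
#' function of the candidate threshold, with the selected cutoff marked.
#'
#' @param object A [calibrate()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mate_calibration
#' @export
autoplot.mate_calibration <- function(object, ...) {
  sweep <- attr(object, "sweep")
  if (is.null(sweep)) {
    abort_input("No sweep attached; plot the result of calibrate().")
  }
  long <- sweep |>
    dplyr::select("threshold", "overall_accuracy", "high_risk_accuracy",
                  "low_risk_accuracy") |>
    tidyr::pivot_longer(-"threshold", names_to = "accuracy",
                        values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$threshold, .data$value,
                                     colour = .data$accuracy)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "failure-probability threshold",
                  y = "classification accuracy") +
    ggplot2::theme_minimal()
}

#' Maximal loading cycles before high risk, across ages
#'
#' The largest acceptable number of loading cycles as a function of peak L5
#' compressive force, drawn for several subject ages — the curve family that
#' shows how the same task becomes unacceptable sooner for older workers.
#'
#' @param forces Vector of peak L5 forces, N.
#' @param ages Vector of subject ages, years.
#' @param sex,bmi Passed to [subject_profile()].
#' @param model A [ucs_model()].
#' @param table A [fatigue_table()].
#' @param risk_threshold Failure-probability cutoff (default 0.10).
#' @return A ggplot; the underlying tibble is in the plot's `data`.
#' @export
plot_max_cycles <- function(forces = seq(2000, 8000, by = 250),
                            ages = c(25, 40, 55, 70), sex = "female",
                            bmi = 25, model = default_ucs_model(),
                            table = default_fatigue_table(),
                            risk_threshold = 0.10) {
  grid <- tidyr::expand_grid(force = forces, age = ages) |>
    dplyr::mutate(max_cycles = purrr::map2_dbl(
      .data$force, .data$age, function(f, a) {
        max_cycles_before_risk(f, subject_profile(a, sex = sex, bmi = bmi),
                               model = model, table = table,
                               risk_threshold = risk_threshold)
      }))
  ggplot2::ggplot(grid, ggplot2::aes(.data$force, pmax(.data$max_cycles, 1),
                                     colour = factor(.data$age))) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "peak L5 compressive force (N)",
                  y = "maximal cycles before high risk",
                  colour = "age (yr)") +
    ggplot2::theme_minimal()
}
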