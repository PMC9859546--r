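#' Describe a repetitive occupational task
#'
#' The schedule is the source of the task's duty cycle (fraction of working
#' time spent executing the loaded movement) and of the loading cycle count
#' over the shift. A minute cannot contain more work than itself, so
#' `cycle_duration * repetitions_per_minute` must not exceed 60 s.
#'
#' @param cycle_duration Duration of one task cycle, seconds (> 0).
#' @param repetitions_per_minute Task repetitions per minute (>= 0).
#' @param total_duration Total duration of the work bout, minutes (> 0).
#' @param handled_mass Handled mass, kg (>= 0).
#' @return A one-row tibble of class `mate_schedule`.
#' @examples
#' sched <- task_schedule(6, 3, 120, handled_mass = 10)
#' duty_cycle(sched)
#' cycle_count(sched)
#' @export
task_schedule <- function(cycle_duration, repetitions_per_minute,
                          total_duration, handled_mass = 0) {
  cycle_duration <- check_number(cycle_duration, "cycle_duration",
                                 lower = 0, strict_lower = TRUE)
  repetitions_per_minute <- check_number(repetitions_per_minute,
                                         "repetitions_per_minute", lower = 0)
  total_duration <- check_number(total_duration, "total_duration",
                                 lower = 0, strict_lower = TRUE)
  handled_mass <- check_number(handled_mass, "handled_mass", lower = 0)
  if (cycle_duration * repetitions_per_minute > 60 + 1e-9) {
    abort_input(sprintf(
      "cycle_duration (%g s) x repetitions_per_minute (%g/min) = %g s of work per 60 s minute.",
      cycle_duration, repetitions_per_minute,
      cycle_duration * repetitions_per_minute),
      class = "mate_schedule_error")
  }
  structure(
    tibble::tibble(cycle_duration = cycle_duration,
                   repetitions_per_minute = repetitions_per_minute,
                   total_duration = total_duration,
                   handled_mass = handled_mass),
    class = c("mate_schedule", class(tibble::tibble())))
}

#' Describe the assessed worker
#'
#' Age, sex and BMI feed the vertebral ultimate-compressive-strength model.
#' BMI may be given directly or computed from mass and height; when all three
#' are given they must agree to within 0.05 kg/m².
#'
#' @param age Age in years, within \[15, 100\].
#' @param sex `"female"` (default, the protective choice: lower vertebral
#'   strength) or `"male"`.
#' @param bmi Body-mass index, kg/m², within \[12, 60\]; optional if `mass`
#'   and `height` are given.
#' @param mass Body mass, kg (optional).
#' @param height Standing height, m (optional).
#' @return A one-row tibble of class `mate_subject` with columns `age`,
#'   `sex`, `bmi`.
#' @examples
#' subject_profile(age = 21, sex = "male", mass = 71.4, height = 1.75)
#' @export
subject_profile <- function(age, sex = "female", bmi = NULL,
                            mass = NULL, height = NULL) {
  age <- check_number(age, "age", lower = 15, upper = 100)
  if (!is.character(sex) || !sex %in% c("female", "male")) {
    abort_input('`sex` must be "female" or "male".', class = "mate_range_error")
  }
  derived <- NULL
  if (!is.null(mass) && !is.null(height)) {
    mass <- check_number(mass, "mass", lower = 0, strict_lower = TRUE)
    height <- check_number(height, "height", lower = 0, strict_lower = TRUE)
    derived <- mass / height^2
  }
  if (is.null(bmi)) {
    if (is.null(derived)) {
      abort_input("Provide either `bmi` or both `mass` and `height`.",
                  class = "mate_missing_key")
    }
    bmi <- derived
  } else if (!is.null(derived) && abs(bmi - derived) >= 0.05) {
    abort_input(sprintf(
      "`bmi` (%.2f) disagrees with mass/height (%.2f kg/m^2).", bmi, derived))
  }
  bmi <- check_number(bmi, "bmi", lower = 12, upper = 60)
  structure(
    tibble::tibble(age = age, sex = sex, bmi = bmi),
    class = c("mate_subject", class(tibble::tibble())))
}

#' Map agonist channels to functional muscle groups
#'
#' A functional group is a set of agonists sharing a primary action (e.g.
#' shoulder flexors); the group-level risk rule counts how many of its
#' agonists' peak activations exceed the maximal acceptable effort.
#'
#' @param groups Named list: group name to a character vector of channel
#'   names, or to a list of `{channel, side}` entries (`side` one of
#'   `"left"`, `"right"`, `"central"`; defaults to `"central"`).
#' @return A tibble of class `mate_catalog` with columns `group`, `channel`,
#'   `side`.
#' @examples
#' muscle_catalog(list(shoulder_flexors = c("delt_ant_r", "delt_ant_l")))
#' @export
muscle_catalog <- function(groups) {
  if (!is.list(groups) || is.null(names(groups)) || any(!nzchar(names(groups)))) {
    abort_input("`groups` must be a named list of channel vectors.")
  }
  rows <- purrr::imap_dfr(groups, function(entries, group) {
    if (length(entries) == 0L) {
      abort_input(sprintf("Muscle group `%s` is empty.", group))
    }
    if (is.character(entries)) {
      tibble::tibble(group = group, channel = entries, side = "central")
    } else {
      purrr::map_dfr(entries, function(e) {
        if (is.character(e)) {
          return(tibble::tibble(group = group, channel = e, side = "central"))
        }
        if (is.null(e$channel)) {
          abort_input(sprintf("Entry in group `%s` lacks a `channel`.", group))
        }
        side <- e$side %||% "central"
        if (!side %in% c("left", "right", "central")) {
          abort_input(sprintf("Invalid side `%s` in group `%s`.", side, group))
        }
        tibble::tibble(group = group, channel = e$channel, side = side)
      })
    }
  })
  dup <- rows |>
    dplyr::count(.data$group, .data$channel) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort_input(sprintf("Duplicate channel `%s` in group `%s`.",
                        dup$channel[1L], dup$group[1L]))
  }
  structure(rows, class = c("mate_catalog", class(rows)))
}
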