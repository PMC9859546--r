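#' Full-body risk assessment for one recorded condition
#'
#' Runs every risk layer on one trial: duty cycle and maximal acceptable
#' effort from the schedule, the agonist-group rule on the activation trace,
#' the cartilage endurance-limit test on each hip force channel, and the
#' vertebral fatigue-failure probability with its calibrated low/high
#' cutoff on the L5 channel. Classic scales (NIOSH lifting index, RULA,
#' REBA) are appended when their inputs are supplied. A region whose
#' channels are absent is reported as not assessed (`NA`) rather than
#' failing the whole report.
#'
#' @param activations Activation [mate_trace()], or `NULL`.
#' @param forces Force [mate_trace()], or `NULL`.
#' @param schedule A [task_schedule()].
#' @param subject A [subject_profile()].
#' @param catalog A [muscle_catalog()], or `NULL` to skip the muscle layer.
#' @param hip_channels Character vector of hip force-channel names; default
#'   picks channels matching `"hip"` case-insensitively. Each channel is
#'   assessed independently (left and right hips get their own verdicts).
#' @param spine_channel L5 compressive-force channel name; default picks the
#'   first channel matching `"L5"` case-insensitively.
#' @param hip_thr A [hip_threshold()].
#' @param ucs A [ucs_model()].
#' @param table A [fatigue_table()].
#' @param risk_threshold Spine failure-probability cutoff (default 0.10).
#' @param niosh A [niosh_inputs()] row, or `NULL`.
#' @param posture A [posture_inputs()] list, or `NULL`.
#' @param name Condition name carried into the report.
#' @return A list of class `mate_report`: `name`, `duty_cycle`, `mae`,
#'   `schedule`, `subject`, `muscle` (group-verdict tibble or `NULL`),
#'   `hip` (per-channel tibble or `NULL`), `spine` (one-row tibble or
#'   `NULL`), `classic` (one-row tibble or `NULL`), and `thresholds`
#'   echoing every threshold and coefficient used.
#' @examples
#' sched <- task_schedule(6, 3, 120, 10)
#' subj <- subject_profile(21, "male", mass = 71.4, height = 1.75)
#' act <- generate_trace(data.frame(name = c("delt_r", "delt_l"),
#'                                  peak_value = 0.4, peak_time = 1),
#'                       kind = "activation", seed = 2)
#' frc <- generate_trace(data.frame(name = c("hip_r", "L5_S1"),
#'                                  peak_value = c(4000, 4749),
#'                                  peak_time = 1),
#'                       kind = "force", seed = 3)
#' cat <- muscle_catalog(list(shoulder_flexors = c("delt_r", "delt_l")))
#' assess(act, frc, sched, subj, catalog = cat)
#' @export
assess <- function(activations = NULL, forces = NULL, schedule, subject,
                   catalog = NULL, hip_channels = NULL, spine_channel = NULL,
                   hip_thr = hip_threshold(), ucs = default_ucs_model(),
                   table = default_fatigue_table(), risk_threshold = 0.10,
                   niosh = NULL, posture = NULL, name = "condition") {
  stopifnot(inherits(schedule, "mate_schedule"),
            inherits(subject, "mate_subject"))
  dc <- duty_cycle(schedule)
  mae_value <- mae(dc)

  muscle <- NULL
  if (!is.null(activations) && !is.null(catalog)) {
    muscle <- group_risk(activations, catalog, mae_value)
  }

  hip <- NULL
  spine <- NULL
  if (!is.null(forces)) {
    chans <- trace_channels(forces)
    if (is.null(hip_channels)) {
      hip_channels <- grep("hip", chans, ignore.case = TRUE, value = TRUE)
    } else {
      missing <- setdiff(hip_channels, chans)
      if (length(missing) > 0L) {
        abort_input(paste0("Hip channels absent from the force trace: ",
                           paste(missing, collapse = ", ")),
                    class = "mate_lookup_error")
      }
    }
    if (length(hip_channels) > 0L) {
      hip <- purrr::map_dfr(hip_channels, function(ch) {
        stress <- peak_hip_stress(forces, ch, hip_thr)
        tibble::tibble(channel = ch, peak_force = max(forces[[ch]]),
                       peak_stress = stress,
                       at_risk = hip_at_risk(stress, hip_thr))
      })
    }
    if (is.null(spine_channel)) {
      hit <- grep("l5", chans, ignore.case = TRUE, value = TRUE)
      spine_channel <- if (length(hit) > 0L) hit[1L] else NULL
    } else if (!spine_channel %in% chans) {
      abort_input(sprintf("Spine channel `%s` absent from the force trace.",
                          spine_channel), class = "mate_lookup_error")
    }
    if (!is.null(spine_channel)) {
      spine <- assess_spine(forces, spine_channel, schedule, subject,
                            model = ucs, table = table,
                            risk_threshold = risk_threshold)
    }
  }

  classic <- NULL
  if (!is.null(niosh) || !is.null(posture)) {
    li <- if (!is.null(niosh)) lifting_index(niosh) else NULL
    classic <- tibble::tibble(
      niosh_li = if (!is.null(li)) li$li else NA_real_,
      niosh_rwl = if (!is.null(li)) li$rwl else NA_real_,
      rwl_defined = if (!is.null(li)) li$rwl_defined else NA,
      rula = if (!is.null(posture)) rula(posture)$rula else NA_integer_,
      reba = if (!is.null(posture)) reba(posture)$reba else NA_integer_
    )
  }

  structure(list(
    name = name, duty_cycle = dc, mae = mae_value,
    schedule = schedule, subject = subject,
    muscle = muscle, hip = hip, spine = spine, classic = classic,
    thresholds = list(
      hip = unclass(hip_thr), ucs_model = unclass(ucs),
      spine_risk_threshold = risk_threshold,
      fatigue_table_dim = dim(table$probability)
    )
  ), class = "mate_report")
}

#' @export
print.mate_report <- function(x, ...) {
  cat(sprintf("== Risk report: %s ==\n", x$name))
  cat(sprintf("Duty cycle %.1f%% -> maximal acceptable effort %.1f%%\n",
              100 * x$duty_cycle, 100 * x$mae))
  if (!is.null(x$muscle)) {
    risky <- x$muscle$group[x$muscle$at_risk]
    cat(sprintf("Muscle groups at risk: %s\n",
                if (length(risky)) paste(risky, collapse = ", ") else "none"))
  } else cat("Muscle layer: not assessed (NA)\n")
  if (!is.null(x$hip)) {
    for (i in seq_len(nrow(x$hip))) {
      cat(sprintf("Hip %s: peak stress %.2f MPa -> %s\n", x$hip$channel[i],
                  x$hip$peak_stress[i],
                  if (x$hip$at_risk[i]) "AT RISK" else "below endurance limit"))
    }
  } else cat("Hip layer: not assessed (NA)\n")
  if (!is.null(x$spine)) {
    cat(sprintf(
      "Spine: peak L5 %.0f N = %.1f%% of UCS (%.0f N), %d cycles -> P(failure) %.1f%% [%s]\n",
      x$spine$peak_force, x$spine$relative_load, x$spine$ucs,
      x$spine$n_cycles, 100 * x$spine$failure_probability,
      if (x$spine$high_risk) "HIGH RISK" else "low risk"))
  } else cat("Spine layer: not assessed (NA)\n")
  if (!is.null(x$classic)) {
    cat(sprintf("Classic scales: NIOSH LI %s, RULA %s, REBA %s\n",
                format(x$classic$niosh_li), format(x$classic$rula),
                format(x$classic$reba)))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a risk report into one row per assessed region
#'
#' @param x A `mate_report`.
#' @param ... Unused.
#' @return A tibble with columns `region`, `metric`, `value`, `at_risk`.
#' @method tidy mate_report
#' @export
tidy.mate_report <- function(x, ...) {
  rows <- list(
    tibble::tibble(region = "task", metric = "duty_cycle",
                   value = x$duty_cycle, at_risk = NA),
    tibble::tibble(region = "task", metric = "mae", value = x$mae,
                   at_risk = NA)
  )
  if (!is.null(x$muscle)) {
    rows <- c(rows, list(tibble::tibble(
      region = paste0("muscle/", x$muscle$group), metric = "n_exceeding",
      value = as.numeric(x$muscle$n_exceeding), at_risk = x$muscle$at_risk)))
  }
  if (!is.null(x$hip)) {
    rows <- c(rows, list(tibble::tibble(
      region = paste0("hip/", x$hip$channel), metric = "peak_stress",
      value = x$hip$peak_stress, at_risk = x$hip$at_risk)))
  }
  if (!is.null(x$spine)) {
    rows <- c(rows, list(tibble::tibble(
      region = "spine", metric = "failure_probability",
      value = x$spine$failure_probability, at_risk = x$spine$high_risk)))
  }
  if (!is.null(x$classic)) {
    rows <- c(rows, list(tibble::tibble(
      region = "classic",
      metric = c("niosh_li", "rula", "reba"),
      value = c(x$classic$niosh_li, as.numeric(x$classic$rula),
                as.numeric(x$classic$reba)),
      at_risk = NA)))
  }
  dplyr::bind_rows(rows)
}

#' One-row summary of a risk report
#'
#' @param x A `mate_report`.
#' @param ... Unused.
#' @return A one-row tibble: `duty_cycle`, `mae`, `n_muscle_groups_at_risk`,
#'   `hip_at_risk`, `spine_failure_probability`, `spine_high_risk`.
#' @method glance mate_report
#' @export
glance.mate_report <- function(x, ...) {
  tibble::tibble(
    name = x$name,
    duty_cycle = x$duty_cycle,
    mae = x$mae,
    n_muscle_groups_at_risk =
      if (!is.null(x$muscle)) sum(x$muscle$at_risk) else NA_integer_,
    hip_at_risk = if (!is.null(x$hip)) any(x$hip$at_risk) else NA,
    spine_failure_probability =
      if (!is.null(x$spine)) x$spine$failure_probability else NA_real_,
    spine_high_risk = if (!is.null(x$spine)) x$spine$high_risk else NA
  )
}

#' Compare two risk reports region by region
#'
#' Differences are `b - a` for every shared numeric metric, with
#' classification changes flagged. Both reports must have assessed the same
#' regions.
#'
#' @param a,b `mate_report` objects for the two conditions.
#' @return A tibble of class `mate_delta` with columns `region`, `metric`,
#'   `value_a`, `value_b`, `delta`, `at_risk_a`, `at_risk_b`, `changed`.
#' @export
compare_reports <- function(a, b) {
  stopifnot(inherits(a, "mate_report"), inherits(b, "mate_report"))
  ta <- tidy(a)
  tb <- tidy(b)
  ka <- paste(ta$region, ta$metric)
  kb <- paste(tb$region, tb$metric)
  if (!setequal(ka, kb)) {
    abort_input(paste0(
      "Reports assess different regions; cannot compare. Only in one: ",
      paste(union(setdiff(ka, kb), setdiff(kb, ka)), collapse = ", ")))
  }
  out <- dplyr::inner_join(ta, tb, by = c("region", "metric"),
                           suffix = c("_a", "_b")) |>
    dplyr::mutate(
      delta = .data$value_b - .data$value_a,
      changed = !is.na(.data$at_risk_a) & !is.na(.data$at_risk_b) &
        .data$at_risk_a != .data$at_risk_b
    ) |>
    dplyr::select("region", "metric", "value_a", "value_b", "delta",
                  "at_risk_a", "at_risk_b", "changed")
  structure(out, class = c("mate_delta", class(out)))
}

#' Write a risk report to machine-readable JSON
#'
#' @param x A `mate_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  stopifnot(inherits(x, "mate_report"))
  obj <- list(
    name = x$name, duty_cycle = x$duty_cycle, mae = x$mae,
    schedule = as.list(tibble::as_tibble(x$schedule)),
    subject = as.list(tibble::as_tibble(x$subject)),
    muscle = if (!is.null(x$muscle)) {
      dplyr::select(x$muscle, -"peaks")
    },
    hip = x$hip, spine = x$spine, classic = x$classic,
    thresholds = x$thresholds
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
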