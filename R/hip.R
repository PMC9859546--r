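#' Hip-cartilage endurance threshold
#'
#' Articular cartilage of the hip shows an endurance limit: a stress below
#' which repetitive loading never produces material failure, regardless of
#' the number of cycles. The canonical stored value is the endurance force
#' of 9434 N over an average femoral head area of 1610 mm², from which the
#' endurance stress (5.86 MPa, about 30% of cartilage ultimate stress) is
#' derived — the printed stress is the rounded quotient of those two.
#'
#' @param femoral_head_area Average femoral head contact area, mm².
#' @param endurance_force Endurance limit expressed as a force, N.
#' @return A list of class `mate_hip_threshold` with `femoral_head_area`,
#'   `endurance_force` and the derived `endurance_stress` (MPa, 4 s.f.).
#' @export
hip_threshold <- function(femoral_head_area = 1610, endurance_force = 9434) {
  femoral_head_area <- check_number(femoral_head_area, "femoral_head_area",
                                    lower = 0, strict_lower = TRUE)
  endurance_force <- check_number(endurance_force, "endurance_force",
                                  lower = 0, strict_lower = TRUE)
  structure(list(
    femoral_head_area = femoral_head_area,
    endurance_force = endurance_force,
    endurance_stress = signif(endurance_force / femoral_head_area, 4)
  ), class = "mate_hip_threshold")
}

#' Peak hip contact stress from a force trace
#'
#' The peak hip contact force over the trial, divided by the average femoral
#' head area (N / mm² = MPa).
#'
#' @param trace A force [mate_trace()].
#' @param channel Name of the hip contact-force channel.
#' @param threshold A [hip_threshold()].
#' @return Peak stress in MPa.
#' @examples
#' tr <- mate_trace(data.frame(time = 0:2, hip_r = c(0, 9434, 100)),
#'                  kind = "force")
#' peak_hip_stress(tr, "hip_r")  # 5.86 MPa
#' @export
peak_hip_stress <- function(trace, channel, threshold = hip_threshold()) {
  stopifnot(inherits(trace, "mate_trace"),
            inherits(threshold, "mate_hip_threshold"))
  if (!channel %in% trace_channels(trace)) {
    abort_input(sprintf("Channel `%s` not found in the trace.", channel),
                class = "mate_lookup_error")
  }
  max(trace[[channel]]) / threshold$femoral_head_area
}

#' Is the hip at risk at a given peak stress?
#'
#' Stresses at or below the endurance limit never produce cartilage failure,
#' independent of the task's repetition; only a peak stress strictly above
#' the limit flags the hip as at risk.
#'
#' @param stress Peak hip stress, MPa (>= 0).
#' @param threshold A [hip_threshold()].
#' @return Logical.
#' @export
hip_at_risk <- function(stress, threshold = hip_threshold()) {
  stopifnot(inherits(threshold, "mate_hip_threshold"))
  if (any(stress < 0)) abort_input("`stress` must be non-negative.")
  stress > threshold$endurance_stress
}
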