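#' Generate a synthetic activation or force trace
#'
#' Each channel is a baseline plus a Gaussian bump of controllable height,
#' timing and width, plus seeded white noise. The risk layers consume only
#' per-channel peaks and the task schedule, so exact peak control matters
#' more than kinematic realism. Activations are clipped to \[0, 1.2\].
#'
#' @param channels A data frame with one row per channel: `name`, optional
#'   `baseline` (default 0), `peak_value`, `peak_time` (s), `peak_width`
#'   (s, Gaussian sigma, default 5% of duration).
#' @param kind `"activation"` or `"force"`.
#' @param duration Trial duration, s.
#' @param sample_rate Sampling rate, Hz (> 0).
#' @param noise_sd White-noise standard deviation in the channel's units
#'   (activation fraction or N).
#' @param seed Integer seed; the same seed reproduces the trace exactly.
#' @param name Trial name.
#' @return A [mate_trace()].
#' @examples
#' generate_trace(data.frame(name = "hip_r", peak_value = 500, peak_time = 1),
#'                kind = "force", duration = 2, seed = 1)
#' @export
generate_trace <- function(channels, kind = c("activation", "force"),
                           duration = 2, sample_rate = 100, noise_sd = 0,
                           seed = 1L, name = "synthetic") {
  kind <- match.arg(kind)
  duration <- check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  sample_rate <- check_number(sample_rate, "sample_rate",
                              lower = 0, strict_lower = TRUE)
  noise_sd <- check_number(noise_sd, "noise_sd", lower = 0)
  channels <- tibble::as_tibble(channels)
  if (nrow(channels) == 0L || !"name" %in% names(channels)) {
    abort_input("`channels` needs at least one row with a `name` column.")
  }
  if (!"peak_value" %in% names(channels)) {
    abort_input("`channels` needs a `peak_value` column.")
  }
  if (!"peak_time" %in% names(channels)) channels$peak_time <- duration / 2
  if (!"baseline" %in% names(channels)) channels$baseline <- 0
  if (!"peak_width" %in% names(channels)) channels$peak_width <- duration * 0.05
  if (any(channels$peak_time < 0) || any(channels$peak_time > duration)) {
    abort_input("`peak_time` must lie within the trial duration.")
  }
  if (kind == "activation" && any(channels$peak_value > 1.2)) {
    abort_input("Activation peaks must not exceed 1.2.")
  }
  time <- seq(0, duration, by = 1 / sample_rate)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  out <- tibble::tibble(time = time)
  for (i in seq_len(nrow(channels))) {
    ch <- channels[i, ]
    v <- ch$baseline +
      ch$peak_value * exp(-0.5 * ((time - ch$peak_time) / ch$peak_width)^2)
    if (noise_sd > 0) v <- v + stats::rnorm(length(time), 0, noise_sd)
    if (kind == "activation") v <- pmin(pmax(v, 0), 1.2)
    out[[ch$name]] <- v
  }
  suppressWarnings(mate_trace(out, kind = kind, name = name))
}

#' Generate a labeled calibration task set
#'
#' Emulates a labeled material-handling dataset: failure probabilities drawn
#' uniformly on (0, 1), true label high when the probability strictly
#' exceeds the planted boundary, then each label flipped independently with
#' the given noise probability. With `n = 2` one task is forced to each side
#' of the boundary so both labels occur.
#'
#' @param n Number of tasks (>= 2).
#' @param boundary Planted probability boundary, in (0, 1).
#' @param noise Label-flip probability, in \[0, 0.5).
#' @param seed Integer seed.
#' @return A [labeled_tasks()] tibble with an extra `true_label` column.
#' @export
generate_calibration_set <- function(n = 148, boundary = 0.10, noise = 0.30,
                                     seed = 1L) {
  if (!is.numeric(n) || n < 2) abort_input("`n` must be at least 2.")
  boundary <- check_number(boundary, "boundary", lower = 0, upper = 1,
                           strict_lower = TRUE, strict_upper = TRUE)
  noise <- check_number(noise, "noise", lower = 0, upper = 0.5,
                        strict_upper = TRUE)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  p <- stats::runif(n)
  if (n == 2) p <- c(stats::runif(1, 0, boundary), stats::runif(1, boundary, 1))
  true_label <- ifelse(p > boundary, "high", "low")
  flip <- stats::runif(n) < noise
  label <- ifelse(flip, ifelse(true_label == "high", "low", "high"), true_label)
  out <- labeled_tasks(sprintf("task_%03d", seq_len(n)), p, label)
  out$true_label <- true_label
  out
}
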