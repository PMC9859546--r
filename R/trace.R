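#' Build a time-series trace of activations or forces
#'
#' A trace holds uniformly or non-uniformly sampled named channels for one
#' trial: either dimensionless muscle activations in \[0, 1\] (model optimizers
#' may overshoot slightly; values above 1 up to 1.5 are kept with a warning,
#' values above 1.5 are rejected as a sign of a wrong channel mapping) or
#' joint contact forces in newtons.
#'
#' @param data A data frame whose first/`time` column is time in seconds
#'   (strictly increasing) and whose remaining numeric columns are channels.
#' @param kind `"activation"` or `"force"`; fixes units and validation.
#' @param name Optional trial name, kept as an attribute.
#'
#' @return A tibble of class `mate_trace` with a `time` column plus one column
#'   per channel; attributes `kind` and `trace_name`.
#' @examples
#' tr <- mate_trace(data.frame(time = c(0, 0.01, 0.02),
#'                             F_L5 = c(100, 200, 150)), kind = "force")
#' trace_peaks(tr)
#' @export
mate_trace <- function(data, kind = c("activation", "force"), name = "trace") {
  kind <- match.arg(kind)
  data <- tibble::as_tibble(data)
  if (!"time" %in% names(data)) {
    if (ncol(data) < 2L) {
      abort_input("A trace needs a `time` column and at least one channel.")
    }
    names(data)[1L] <- "time"
  }
  data <- dplyr::relocate(data, "time")
  chans <- setdiff(names(data), "time")
  if (length(chans) == 0L) abort_input("A trace needs at least one channel.")
  if (!is.numeric(data$time) || anyNA(data$time)) {
    abort_input("`time` must be numeric with no missing values.")
  }
  if (nrow(data) < 1L) abort_input("A trace needs at least one sample.")
  if (nrow(data) > 1L && any(diff(data$time) <= 0)) {
    abort_input("`time` must be strictly increasing.",
                class = "mate_time_error")
  }
  for (ch in chans) {
    v <- data[[ch]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      abort_input(sprintf("Channel `%s` must be finite numeric.", ch))
    }
    if (kind == "activation") {
      if (any(v < 0) || any(v > 1.5)) {
        abort_input(sprintf(
          "Channel `%s` has activations outside [0, 1.5]; check the channel mapping.",
          ch))
      }
      if (any(v > 1)) {
        warning(sprintf("Channel `%s` has activations above 1 (max %.3f); ",
                        ch, max(v)),
                "keeping them (optimizer overshoot).", call. = FALSE)
      }
    }
  }
  structure(data,
            class = c("mate_trace", class(data)),
            kind = kind, trace_name = name)
}

#' @export
print.mate_trace <- function(x, ...) {
  cat(sprintf("<mate_trace '%s'> kind: %s, %d channels, %d samples, %.3f s\n",
              attr(x, "trace_name"), attr(x, "kind"),
              ncol(x) - 1L, nrow(x), diff(range(x$time))))
  NextMethod()
}

trace_kind <- function(trace) attr(trace, "kind") %||% "force"

trace_channels <- function(trace) setdiff(names(trace), "time")

#' Peak value of every channel in a trace
#'
#' The raw maximum over time per channel; no smoothing is applied by default.
#' An optional centred moving-average window is available for noisy field
#' recordings.
#'
#' @param trace A [mate_trace()].
#' @param window Odd moving-average window length in samples; 1 (default)
#'   means no smoothing.
#' @return A tibble with columns `channel` and `peak`.
#' @export
trace_peaks <- function(trace, window = 1L) {
  stopifnot(inherits(trace, "mate_trace"))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    abort_input("`window` must be a positive odd integer.")
  }
  smooth <- function(v) {
    if (window == 1L || length(v) < window) return(v)
    as.numeric(stats::filter(v, rep(1 / window, window), sides = 2))
  }
  purrr::map_dfr(trace_channels(trace), function(ch) {
    v <- smooth(trace[[ch]])
    tibble::tibble(channel = ch, peak = max(v, na.rm = TRUE))
  })
}
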