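#' Vertebral ultimate-compressive-strength model
#'
#' Lumbar vertebral ultimate compressive strength (UCS) is modelled as a
#' linear function of age and sex — material strength declines with age and
#' is higher in males — scaled by a relative endplate-area factor that grows
#' linearly with BMI (heavier trunks associate with larger endplates):
#' \deqn{UCS = (c_0 + c_{sex}[male] - c_{age} \cdot age/10) \times (b_0 + b_1 BMI)}
#' with the area factor clipped to \[0.5, 1.5\] and the result converted from
#' kN to N. The package ships a synthetic default
#' (`inst/extdata/ucs_model_synthetic.yaml`) whose coefficients sit in the
#' range of published lumbar strength regressions; supply your own
#' coefficients for subject-specific work.
#'
#' @param c0 Baseline strength, kN.
#' @param c_age Strength decline per decade of age, kN (>= 0).
#' @param c_sex Additive strength for male subjects, kN.
#' @param b0,b1 Intercept and BMI slope of the relative endplate-area factor.
#' @return A list of class `mate_ucs_model`.
#' @seealso [ultimate_compressive_strength()], [read_ucs_model()]
#' @export
ucs_model <- function(c0, c_age, c_sex = 0, b0 = 1, b1 = 0) {
  c0 <- check_number(c0, "c0", lower = 0, strict_lower = TRUE)
  c_age <- check_number(c_age, "c_age", lower = 0)
  c_sex <- check_number(c_sex, "c_sex")
  b0 <- check_number(b0, "b0")
  b1 <- check_number(b1, "b1")
  # strictly positive over the full subject domain (ages up to 100, either sex,
  # area factor at its 0.5 floor)
  if ((c0 - c_age * 10) * 0.5 <= 0) {
    abort_config(sprintf(
      "UCS model predicts non-positive strength at age 100 (c0=%g, c_age=%g).",
      c0, c_age), class = "mate_model_domain_error")
  }
  structure(list(c0 = c0, c_age = c_age, c_sex = c_sex, b0 = b0, b1 = b1),
            class = "mate_ucs_model")
}

#' @describeIn ucs_model Read a UCS model from a YAML file with keys
#'   `c0`, `c_age`, `c_sex`, `b0`, `b1`.
#' @param path Path to a YAML coefficients file.
#' @export
read_ucs_model <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("File not found: %s", path))
  y <- yaml::read_yaml(path)
  for (k in c("c0", "c_age")) {
    if (is.null(y[[k]])) {
      abort_config(sprintf("UCS model file is missing `%s`.", k))
    }
  }
  ucs_model(c0 = y$c0, c_age = y$c_age, c_sex = y$c_sex %||% 0,
            b0 = y$b0 %||% 1, b1 = y$b1 %||% 0)
}

#' @describeIn ucs_model The synthetic default model shipped with the package.
#' @export
default_ucs_model <- function() {
  read_ucs_model(system.file("extdata", "ucs_model_synthetic.yaml",
                             package = "mate", mustWork = TRUE))
}

#' Ultimate compressive strength of a subject's vertebra
#'
#' Evaluates a [ucs_model()] for one subject and returns the strength in
#' newtons. Strength is non-increasing in age and, with a positive BMI
#' slope, increasing in BMI through the endplate-area factor.
#'
#' @param subject A [subject_profile()].
#' @param model A [ucs_model()]; defaults to the shipped synthetic model.
#' @return UCS in N (single positive number).
#' @examples
#' ultimate_compressive_strength(
#'   subject_profile(age = 40, bmi = 25),
#'   ucs_model(c0 = 10, c_age = 0.5))  # 8000 N
#' @export
ultimate_compressive_strength <- function(subject, model = default_ucs_model()) {
  stopifnot(inherits(subject, "mate_subject"), inherits(model, "mate_ucs_model"))
  strength_kn <- model$c0 + model$c_sex * (subject$sex == "male") -
    model$c_age * subject$age / 10
  area_factor <- min(max(model$b0 + model$b1 * subject$bmi, 0.5), 1.5)
  ucs <- strength_kn * area_factor * 1000
  if (ucs <= 0) {
    abort_config(sprintf("UCS model yields non-positive strength (%g N).", ucs),
                 class = "mate_model_domain_error")
  }
  ucs
}

#' Number of loading cycles over the work bout
#'
#' Repetitions per minute times total duration in minutes, rounded to the
#' nearest integer. Cumulative damage across different tasks in a shift is
#' deliberately not summed; assess each task on its own schedule.
#'
#' @param schedule A [task_schedule()].
#' @return Integer cycle count.
#' @examples
#' cycle_count(task_schedule(6, 3, 120))    # 360
#' cycle_count(task_schedule(6, 0.2, 120))  # 24
#' @export
cycle_count <- function(schedule) {
  stopifnot(inherits(schedule, "mate_schedule"))
  as.integer(round(schedule$repetitions_per_minute * schedule$total_duration))
}

#' S-N fatigue-failure probability table
#'
#' The probability that a vertebra fails by fatigue, as a surface over
#' relative load (% of ultimate compressive strength) and number of loading
#' cycles — the S-N curve of the biomaterial with its scatter expressed as a
#' probability. Probabilities must be non-decreasing along both axes: more
#' load or more cycles never lowers failure probability.
#'
#' @param load_levels Ascending vector of relative loads, % of UCS.
#' @param cycle_levels Ascending vector of cycle counts (>= 1).
#' @param probability Matrix of failure probabilities in \[0, 1\], one row
#'   per load level, one column per cycle level.
#' @return A list of class `mate_fatigue_table`.
#' @seealso [failure_probability()], [read_fatigue_table()]
#' @export
fatigue_table <- function(load_levels, cycle_levels, probability) {
  if (length(load_levels) == 0L || length(cycle_levels) == 0L) {
    abort_config("Fatigue table must have at least one load and cycle level.")
  }
  probability <- as.matrix(probability)
  if (any(diff(load_levels) <= 0) || any(diff(cycle_levels) <= 0)) {
    abort_config("Load and cycle levels must be strictly ascending.")
  }
  if (any(cycle_levels < 1)) {
    abort_config("Cycle levels must be >= 1 (interpolation is in log10 cycles).")
  }
  if (!identical(dim(probability),
                 c(length(load_levels), length(cycle_levels)))) {
    abort_config(sprintf(
      "Probability matrix must be %d x %d (load x cycle levels).",
      length(load_levels), length(cycle_levels)))
  }
  if (any(probability < 0) || any(probability > 1)) {
    abort_config("Failure probabilities must lie in [0, 1].")
  }
  if (nrow(probability) > 1L && any(apply(probability, 2L, diff) < 0)) {
    abort_config("Failure probability must be non-decreasing in load.")
  }
  if (ncol(probability) > 1L && any(apply(probability, 1L, diff) < 0)) {
    abort_config("Failure probability must be non-decreasing in cycles.")
  }
  structure(list(load_levels = as.numeric(load_levels),
                 cycle_levels = as.numeric(cycle_levels),
                 probability = probability),
            class = "mate_fatigue_table")
}

#' @describeIn fatigue_table Read a table from a long-format CSV with columns
#'   `load`, `cycles`, `probability` (lines starting with `#` are comments).
#' @param path Path to the CSV file.
#' @export
read_fatigue_table <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("File not found: %s", path))
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  need <- c("load", "cycles", "probability")
  if (!all(need %in% names(df))) {
    abort_config("Fatigue-table CSV needs columns load, cycles, probability.")
  }
  wide <- df |>
    dplyr::arrange(.data$load, .data$cycles) |>
    tidyr::pivot_wider(names_from = "cycles", values_from = "probability")
  loads <- wide$load
  cycles <- as.numeric(setdiff(names(wide), "load"))
  mat <- as.matrix(wide[setdiff(names(wide), "load")])
  if (anyNA(mat)) abort_config("Fatigue-table CSV grid is incomplete.")
  dimnames(mat) <- NULL
  fatigue_table(loads, cycles, mat)
}

#' @describeIn fatigue_table The synthetic default table shipped with the
#'   package (probit in relative load, log-linear in cycles, endurance region
#'   below 30% UCS).
#' @export
default_fatigue_table <- function() {
  read_fatigue_table(system.file("extdata", "fatigue_table_synthetic.csv",
                                 package = "mate", mustWork = TRUE))
}

#' Fatigue-failure probability at a relative load and cycle count
#'
#' Bilinear interpolation over the fatigue table: linear in relative load and
#' in log10 cycles (S-N behaviour is log-linear in cycles). Loads below the
#' table's lowest level are in the endurance region and return 0; loads above
#' the highest level clamp to the top row; cycle counts clamp to the table's
#' cycle range; zero cycles means no loading and returns 0. Grid nodes are
#' reproduced exactly.
#'
#' @param relative_load Relative load, % of UCS (>= 0); vectorised.
#' @param n_cycles Cycle count (>= 0); vectorised (recycled against
#'   `relative_load`).
#' @param table A [fatigue_table()]; defaults to the shipped synthetic table.
#' @return Failure probability, a fraction (vector).
#' @export
failure_probability <- function(relative_load, n_cycles,
                                table = default_fatigue_table()) {
  stopifnot(inherits(table, "mate_fatigue_table"))
  if (any(relative_load < 0) || any(n_cycles < 0)) {
    abort_input("`relative_load` and `n_cycles` must be non-negative.")
  }
  n <- max(length(relative_load), length(n_cycles))
  relative_load <- rep_len(relative_load, n)
  n_cycles <- rep_len(n_cycles, n)

  loads <- table$load_levels
  lcyc <- log10(table$cycle_levels)
  frac_idx <- function(x, grid) {
    # fractional index into an ascending grid, clamped to its ends
    x <- pmin(pmax(x, grid[1L]), grid[length(grid)])
    if (length(grid) == 1L) return(rep(1, length(x)))
    i <- findInterval(x, grid, rightmost.closed = TRUE)
    i <- pmin(i, length(grid) - 1L)
    i + (x - grid[i]) / (grid[i + 1L] - grid[i])
  }
  fi <- frac_idx(relative_load, loads)
  fj <- frac_idx(log10(pmax(n_cycles, 1)), lcyc)
  i0 <- pmin(floor(fi), length(loads) - 1L); i0 <- pmax(i0, 1L)
  j0 <- pmin(floor(fj), length(lcyc) - 1L); j0 <- pmax(j0, 1L)
  if (length(loads) == 1L) { i0 <- rep(1L, n); fi <- rep(1, n) }
  if (length(lcyc) == 1L) { j0 <- rep(1L, n); fj <- rep(1, n) }
  wi <- fi - i0
  wj <- fj - j0
  i1 <- pmin(i0 + 1L, length(loads))
  j1 <- pmin(j0 + 1L, length(lcyc))
  P <- table$probability
  p <- (1 - wi) * (1 - wj) * P[cbind(i0, j0)] +
    wi * (1 - wj) * P[cbind(i1, j0)] +
    (1 - wi) * wj * P[cbind(i0, j1)] +
    wi * wj * P[cbind(i1, j1)]
  p[relative_load < loads[1L]] <- 0  # endurance region
  p[n_cycles == 0] <- 0
  pmin(pmax(p, 0), 1)
}

#' Classify a failure probability as low or high risk
#'
#' High risk when the failure probability strictly exceeds the calibrated
#' risk threshold (default 10%, the cutoff that best separates low- from
#' high-risk material-handling tasks by low-back-pain incidence).
#'
#' @param p Failure probability, in \[0, 1\]; vectorised.
#' @param risk_threshold Cutoff, a fraction (default 0.10).
#' @return Logical: `TRUE` for high risk.
#' @export
classify_spine <- function(p, risk_threshold = 0.10) {
  if (any(p < 0) || any(p > 1)) abort_input("`p` must lie in [0, 1].")
  risk_threshold <- check_number(risk_threshold, "risk_threshold",
                                 lower = 0, upper = 1)
  p > risk_threshold
}

#' Maximal cycle count before the spine becomes high risk
#'
#' The largest number of loading cycles for which the vertebral failure
#' probability stays at or below the risk threshold, at the relative load
#' implied by a peak L5 force and the subject's vertebral strength. Found by
#' bisection on the integer cycle axis over the table's cycle range; returns
#' the table maximum when the threshold is never exceeded, and 0 when even
#' the minimum tabulated cycle count exceeds it.
#'
#' @param peak_force Peak L5 compressive force, N (> 0).
#' @param subject A [subject_profile()].
#' @param model A [ucs_model()].
#' @param table A [fatigue_table()].
#' @param risk_threshold Failure-probability cutoff (default 0.10).
#' @return Integer cycle count.
#' @export
max_cycles_before_risk <- function(peak_force, subject,
                                   model = default_ucs_model(),
                                   table = default_fatigue_table(),
                                   risk_threshold = 0.10) {
  peak_force <- check_number(peak_force, "peak_force",
                             lower = 0, strict_lower = TRUE)
  ucs <- ultimate_compressive_strength(subject, model)
  load <- 100 * peak_force / ucs
  n_max <- as.integer(max(table$cycle_levels))
  n_min <- as.integer(ceiling(min(table$cycle_levels)))
  p_at <- function(n) failure_probability(load, n, table)
  if (p_at(n_max) <= risk_threshold) return(n_max)
  if (p_at(n_min) > risk_threshold) return(0L)
  lo <- n_min  # p(lo) <= threshold
  hi <- n_max  # p(hi) > threshold
  while (hi - lo > 1L) {
    mid <- lo + (hi - lo) %/% 2L
    if (p_at(mid) <= risk_threshold) lo <- mid else hi <- mid
  }
  lo
}

#' Full spine assessment for one trial
#'
#' Combines the subject's vertebral strength, the trial's peak L5 compressive
#' force and the task's cycle count into a fatigue-failure probability and a
#' low/high-risk verdict. The L5 channel must hold compressive-force
#' magnitudes; negative samples trigger a warning and are used in absolute
#' value.
#'
#' @param trace A force [mate_trace()].
#' @param channel Name of the L5 compressive-force channel.
#' @param schedule A [task_schedule()].
#' @param subject A [subject_profile()].
#' @param model A [ucs_model()].
#' @param table A [fatigue_table()].
#' @param risk_threshold Failure-probability cutoff (default 0.10).
#' @return A one-row tibble: `ucs`, `peak_force`, `relative_load` (% of UCS),
#'   `n_cycles`, `failure_probability`, `risk_threshold`, `high_risk`.
#' @export
assess_spine <- function(trace, channel, schedule, subject,
                         model = default_ucs_model(),
                         table = default_fatigue_table(),
                         risk_threshold = 0.10) {
  stopifnot(inherits(trace, "mate_trace"))
  if (!channel %in% trace_channels(trace)) {
    abort_input(sprintf("Channel `%s` not found in the trace.", channel),
                class = "mate_lookup_error")
  }
  v <- trace[[channel]]
  if (any(v < 0)) {
    warning(sprintf(
      "Channel `%s` has negative samples; using magnitudes (compression sign convention).",
      channel), call. = FALSE)
    v <- abs(v)
  }
  ucs <- ultimate_compressive_strength(subject, model)
  peak <- max(v)
  load <- 100 * peak / ucs
  n <- cycle_count(schedule)
  p <- failure_probability(load, n, table)
  tibble::tibble(
    ucs = ucs, peak_force = peak, relative_load = load, n_cycles = n,
    failure_probability = p, risk_threshold = risk_threshold,
    high_risk = classify_spine(p, risk_threshold)
  )
}
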