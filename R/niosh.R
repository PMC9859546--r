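# Revised NIOSH lifting equation (1991 revision, Applications Manual
# conventions). RWL = LC * HM * VM * DM * AM * FM * CM with LC = 23 kg; the
# frequency (FM) and coupling (CM) multipliers are band lookups, not
# interpolated, exactly as published.

# FM table: rows are the tabulated lifting frequencies (lifts/min), columns
# are duration class x vertical band. Transcribed from the revised lifting
# equation's frequency-multiplier table.
NIOSH_FM_FREQ <- c(0.2, 0.5, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15)
NIOSH_FM <- matrix(c(
  # <=1h V<75, <=1h V>=75, <=2h V<75, <=2h V>=75, <=8h V<75, <=8h V>=75
  1.00, 1.00, 0.95, 0.95, 0.85, 0.85,  # 0.2
  0.97, 0.97, 0.92, 0.92, 0.81, 0.81,  # 0.5
  0.94, 0.94, 0.88, 0.88, 0.75, 0.75,  # 1
  0.91, 0.91, 0.84, 0.84, 0.65, 0.65,  # 2
  0.88, 0.88, 0.79, 0.79, 0.55, 0.55,  # 3
  0.84, 0.84, 0.72, 0.72, 0.45, 0.45,  # 4
  0.80, 0.80, 0.60, 0.60, 0.35, 0.35,  # 5
  0.75, 0.75, 0.50, 0.50, 0.27, 0.27,  # 6
  0.70, 0.70, 0.42, 0.42, 0.22, 0.22,  # 7
  0.60, 0.60, 0.35, 0.35, 0.18, 0.18,  # 8
  0.52, 0.52, 0.30, 0.30, 0.00, 0.15,  # 9
  0.45, 0.45, 0.26, 0.26, 0.00, 0.13,  # 10
  0.41, 0.41, 0.00, 0.23, 0.00, 0.00,  # 11
  0.37, 0.37, 0.00, 0.21, 0.00, 0.00,  # 12
  0.00, 0.34, 0.00, 0.00, 0.00, 0.00,  # 13
  0.00, 0.31, 0.00, 0.00, 0.00, 0.00,  # 14
  0.00, 0.28, 0.00, 0.00, 0.00, 0.00   # 15
), nrow = 17, byrow = TRUE,
  dimnames = list(NULL, c("1h_lo", "1h_hi", "2h_lo", "2h_hi", "8h_lo", "8h_hi")))

# CM table: coupling quality x vertical band.
NIOSH_CM <- matrix(c(
  1.00, 1.00,  # good
  0.95, 1.00,  # fair
  0.90, 0.90   # poor
), nrow = 3, byrow = TRUE,
  dimnames = list(c("good", "fair", "poor"), c("lo", "hi")))

niosh_fm <- function(frequency, duration_class, vertical) {
  if (frequency < 0) abort_input("`frequency` must be non-negative.")
  if (frequency > 15) return(0)
  f <- max(frequency, 0.2)  # below 0.2/min the table's lowest band applies
  row <- which(NIOSH_FM_FREQ >= f - 1e-9)[1L]  # next tabulated band up
  band <- paste0(switch(duration_class, "1h" = "1h", "2h" = "2h", "8h" = "8h"),
                 if (vertical < 75) "_lo" else "_hi")
  unname(NIOSH_FM[row, band])
}

niosh_cm <- function(coupling, vertical) {
  unname(NIOSH_CM[coupling, if (vertical < 75) "lo" else "hi"])
}

#' Inputs to the revised NIOSH lifting equation
#'
#' @param load_mass Handled mass, kg.
#' @param horizontal Horizontal hand location H, cm (values below 25 are
#'   clamped to 25; above 63 the lift is beyond reach and HM = 0).
#' @param vertical Vertical hand location V at origin, cm, within \[0, 175\];
#'   outside that range the load is beyond vertical reach and VM = 0.
#' @param travel Vertical travel distance D, cm (below 25 clamped to 25;
#'   above 175 yields DM = 0).
#' @param asymmetry Asymmetry angle A, degrees (above 135 yields AM = 0).
#' @param frequency Lifting frequency, lifts/min.
#' @param duration_class Work duration class: `"1h"`, `"2h"` or `"8h"`.
#' @param coupling Hand-to-object coupling: `"good"`, `"fair"` or `"poor"`.
#' @return A one-row tibble of class `mate_niosh_inputs`.
#' @export
niosh_inputs <- function(load_mass, horizontal = 25, vertical = 75,
                         travel = 25, asymmetry = 0, frequency = 0.2,
                         duration_class = c("8h", "2h", "1h"),
                         coupling = c("good", "fair", "poor")) {
  duration_class <- match.arg(duration_class)
  coupling <- match.arg(coupling)
  load_mass <- check_number(load_mass, "load_mass", lower = 0)
  horizontal <- check_number(horizontal, "horizontal", lower = 0)
  vertical <- check_number(vertical, "vertical", lower = 0)
  travel <- check_number(travel, "travel", lower = 0)
  asymmetry <- check_number(asymmetry, "asymmetry", lower = 0)
  frequency <- check_number(frequency, "frequency", lower = 0)
  out <- tibble::tibble(load_mass = load_mass, horizontal = horizontal,
                        vertical = vertical, travel = travel,
                        asymmetry = asymmetry, frequency = frequency,
                        duration_class = duration_class, coupling = coupling)
  structure(out, class = c("mate_niosh_inputs", class(out)))
}

#' Recommended weight limit (revised NIOSH lifting equation)
#'
#' \deqn{RWL = 23 \cdot \frac{25}{H} \cdot (1 - 0.003|V-75|) \cdot
#'   (0.82 + \frac{4.5}{D}) \cdot (1 - 0.0032 A) \cdot FM \cdot CM}
#' with every multiplier clamped to \[0, 1\] and set to 0 outside the
#' equation's validity range (H > 63 cm, V outside \[0, 175\] cm,
#' D > 175 cm, A > 135 degrees, frequency > 15/min).
#'
#' @param inputs A [niosh_inputs()] row.
#' @return A one-row tibble: the six multipliers `hm`, `vm`, `dm`, `am`,
#'   `fm`, `cm`, the `rwl` in kg, and `rwl_defined` (`FALSE` when any
#'   multiplier is 0 so no weight is recommended).
#' @examples
#' niosh_rwl(niosh_inputs(23))  # ideal lift: RWL 23 kg
#' @export
niosh_rwl <- function(inputs) {
  stopifnot(inherits(inputs, "mate_niosh_inputs"))
  clamp01 <- function(x) min(max(x, 0), 1)
  hm <- if (inputs$horizontal > 63) 0 else clamp01(25 / max(inputs$horizontal, 25))
  vm <- if (inputs$vertical > 175) 0 else clamp01(1 - 0.003 * abs(inputs$vertical - 75))
  dm <- if (inputs$travel > 175) 0 else clamp01(0.82 + 4.5 / max(inputs$travel, 25))
  am <- if (inputs$asymmetry > 135) 0 else clamp01(1 - 0.0032 * inputs$asymmetry)
  fm <- niosh_fm(inputs$frequency, inputs$duration_class, inputs$vertical)
  cm <- niosh_cm(inputs$coupling, inputs$vertical)
  rwl <- 23 * hm * vm * dm * am * fm * cm
  tibble::tibble(hm = hm, vm = vm, dm = dm, am = am, fm = fm, cm = cm,
                 rwl = rwl, rwl_defined = rwl > 0)
}

#' NIOSH lifting index
#'
#' LI = handled mass / recommended weight limit. When the RWL is 0 (a
#' multiplier outside its validity range, e.g. overhead work above vertical
#' reach) no weight is recommended and the LI is reported as `Inf` with
#' `rwl_defined = FALSE` — it is not forced to 0, which would masquerade as
#' "no risk".
#'
#' @param inputs A [niosh_inputs()] row.
#' @return A one-row tibble: `rwl`, `li`, `rwl_defined`.
#' @examples
#' lifting_index(niosh_inputs(23))  # LI = 1
#' @export
lifting_index <- function(inputs) {
  r <- niosh_rwl(inputs)
  li <- if (r$rwl_defined) inputs$load_mass / r$rwl else Inf
  tibble::tibble(rwl = r$rwl, li = li, rwl_defined = r$rwl_defined)
}
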