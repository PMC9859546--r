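# Rapid Upper Limb Assessment (RULA). Exact lookups through the published
# worksheet's Table A (arm/wrist), Table B (neck/trunk/legs) and Table C
# (grand score), with the worksheet's muscle-use and force/load adjustment
# points. Tables are transcribed literally from the RULA worksheet; no
# procedural regeneration, so each cell is auditable against the sheet.

# Table A: upper arm (1-6) x lower arm (1-3) rows; wrist (1-4) x wrist twist
# (1-2) columns.
RULA_TABLE_A <- array(
  c(
    # [upper, lower, wrist*twist] flattened row-wise per (upper, lower)
    1, 2, 2, 2, 2, 3, 3, 3,
    2, 2, 2, 2, 3, 3, 3, 3,
    2, 3, 3, 3, 3, 3, 4, 4,
    2, 3, 3, 3, 3, 4, 4, 4,
    3, 3, 3, 3, 3, 4, 4, 4,
    3, 4, 4, 4, 4, 4, 5, 5,
    3, 3, 4, 4, 4, 4, 5, 5,
    3, 4, 4, 4, 4, 4, 5, 5,
    4, 4, 4, 4, 4, 5, 5, 5,
    4, 4, 4, 4, 4, 5, 5, 5,
    4, 4, 4, 4, 4, 5, 5, 5,
    4, 4, 4, 5, 5, 5, 6, 6,
    5, 5, 5, 5, 5, 6, 6, 7,
    5, 6, 6, 6, 6, 7, 7, 7,
    6, 6, 6, 7, 7, 7, 7, 8,
    7, 7, 7, 7, 7, 8, 8, 9,
    8, 8, 8, 8, 8, 9, 9, 9,
    9, 9, 9, 9, 9, 9, 9, 9
  ),
  dim = c(8, 3, 6),  # [wrist*twist, lower, upper]
  dimnames = NULL
)

# Table B: neck (1-6) rows; trunk (1-6) x legs (1-2) columns.
RULA_TABLE_B <- matrix(c(
  1, 3, 2, 3, 3, 4, 5, 5, 6, 6, 7, 7,
  2, 3, 2, 3, 4, 5, 5, 5, 6, 7, 7, 7,
  3, 3, 3, 4, 4, 5, 5, 6, 6, 7, 7, 7,
  5, 5, 5, 6, 6, 7, 7, 7, 7, 7, 8, 8,
  7, 7, 7, 7, 7, 8, 8, 8, 8, 8, 8, 8,
  8, 8, 8, 8, 8, 8, 8, 9, 9, 9, 9, 9
), nrow = 6, byrow = TRUE)

# Table C: score A (1-8, >=8 clamped) x score B (1-7, >=7 clamped).
RULA_TABLE_C <- matrix(c(
  1, 2, 3, 3, 4, 5, 5,
  2, 2, 3, 4, 4, 5, 5,
  3, 3, 3, 4, 4, 5, 6,
  3, 3, 3, 4, 5, 6, 6,
  4, 4, 4, 5, 6, 7, 7,
  4, 4, 5, 6, 6, 7, 7,
  5, 5, 6, 6, 7, 7, 7,
  5, 5, 6, 7, 7, 7, 7
), nrow = 8, byrow = TRUE)

check_score <- function(x, name, max) {
  if (is.null(x) || !is.numeric(x) || length(x) != 1L || is.na(x) ||
      x != round(x) || x < 1 || x > max) {
    abort_input(sprintf("`%s` must be an integer worksheet score in 1..%d.",
                        name, max), class = "mate_range_error")
  }
  as.integer(x)
}

check_points <- function(x, name, max) {
  if (is.null(x) || !is.numeric(x) || length(x) != 1L || is.na(x) ||
      x != round(x) || x < 0 || x > max) {
    abort_input(sprintf("`%s` must be adjustment points in 0..%d.", name, max),
                class = "mate_range_error")
  }
  as.integer(x)
}

#' Posture descriptors for the RULA and REBA worksheets
#'
#' Each descriptor is the category score read off the corresponding
#' worksheet diagram (not a raw joint angle). RULA uses `upper_arm` (1-6),
#' `lower_arm` (1-3), `wrist` (1-4), `wrist_twist` (1-2), `neck` (1-6),
#' `trunk` (1-6), `legs` (1-2), plus `muscle_use` (0-1) and `force` (0-3)
#' adjustment points applied to both the arm/wrist and neck/trunk/legs
#' scores. REBA uses `trunk` (1-5), `neck` (1-3), `legs` (1-4),
#' `upper_arm` (1-6), `lower_arm` (1-2), `wrist` (1-3), plus `load` (0-3),
#' `coupling` (0-3) and `activity` (0-3) points. Scores outside a
#' worksheet's range raise a validation error from the scorer using them.
#'
#' @param upper_arm,lower_arm,wrist,wrist_twist,neck,trunk,legs Worksheet
#'   posture categories (integers; defaults are the neutral posture, all 1).
#' @param muscle_use,force,load,coupling,activity Adjustment points
#'   (integers, default 0).
#' @return A list of class `mate_posture`.
#' @export
posture_inputs <- function(upper_arm = 1, lower_arm = 1, wrist = 1,
                           wrist_twist = 1, neck = 1, trunk = 1, legs = 1,
                           muscle_use = 0, force = 0, load = 0,
                           coupling = 0, activity = 0) {
  structure(list(upper_arm = upper_arm, lower_arm = lower_arm, wrist = wrist,
                 wrist_twist = wrist_twist, neck = neck, trunk = trunk,
                 legs = legs, muscle_use = muscle_use, force = force,
                 load = load, coupling = coupling, activity = activity),
            class = "mate_posture")
}

#' RULA grand score
#'
#' Deterministic lookup through the RULA worksheet: Table A combines upper
#' arm, lower arm, wrist and wrist twist; Table B combines neck, trunk and
#' legs; muscle-use and force points are added to each; Table C combines the
#' two into the grand score (1-7).
#'
#' @param posture A [posture_inputs()] list.
#' @return A one-row tibble: `score_a` (posture A + points), `score_b`
#'   (posture B + points), `rula` (grand score, 1-7).
#' @examples
#' rula(posture_inputs())$rula  # neutral posture: 1
#' @export
rula <- function(posture) {
  stopifnot(inherits(posture, "mate_posture"))
  ua <- check_score(posture$upper_arm, "upper_arm", 6)
  la <- check_score(posture$lower_arm, "lower_arm", 3)
  wr <- check_score(posture$wrist, "wrist", 4)
  wt <- check_score(posture$wrist_twist, "wrist_twist", 2)
  nk <- check_score(posture$neck, "neck", 6)
  tr <- check_score(posture$trunk, "trunk", 6)
  lg <- check_score(posture$legs, "legs", 2)
  mu <- check_points(posture$muscle_use, "muscle_use", 1)
  fo <- check_points(posture$force, "force", 3)
  a_post <- RULA_TABLE_A[(wr - 1L) * 2L + wt, la, ua]
  b_post <- RULA_TABLE_B[nk, (tr - 1L) * 2L + lg]
  score_a <- a_post + mu + fo
  score_b <- b_post + mu + fo
  grand <- RULA_TABLE_C[min(score_a, 8L), min(score_b, 7L)]
  tibble::tibble(score_a = score_a, score_b = score_b, rula = grand)
}
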