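# Rapid Entire Body Assessment (REBA). Exact lookups through the published
# worksheet's Table A (trunk/neck/legs + load), Table B (upper arm/lower
# arm/wrist + coupling) and Table C, plus the activity points. Tables are
# transcribed literally from the REBA worksheet.

# Table A: neck (1-3) x trunk (1-5) x legs (1-4).
REBA_TABLE_A <- array(
  c(
    # neck 1, trunk 1..5, legs 1..4 each
    1, 2, 3, 4,  2, 3, 4, 5,  2, 4, 5, 6,  3, 5, 6, 7,  4, 6, 7, 8,
    # neck 2
    1, 2, 3, 4,  3, 4, 5, 6,  4, 5, 6, 7,  5, 6, 7, 8,  6, 7, 8, 9,
    # neck 3
    3, 3, 5, 6,  4, 5, 6, 7,  5, 6, 7, 8,  6, 7, 8, 9,  7, 8, 9, 9
  ),
  dim = c(4, 5, 3)  # [legs, trunk, neck]
)

# Table B: wrist (1-3) x upper arm (1-6) x lower arm (1-2).
REBA_TABLE_B <- array(
  c(
    # lower arm 1, upper arm 1..6, wrist 1..3 each
    1, 2, 2,  1, 2, 3,  3, 4, 5,  4, 5, 5,  6, 7, 8,  7, 8, 8,
    # lower arm 2
    1, 2, 3,  2, 3, 4,  4, 5, 5,  5, 6, 7,  7, 8, 8,  8, 9, 9
  ),
  dim = c(3, 6, 2)  # [wrist, upper, lower]
)

# Table C: score A (1-12) x score B (1-12).
REBA_TABLE_C <- matrix(c(
  1, 1, 1, 2, 3, 3, 4, 5, 6, 7, 7, 7,
  1, 2, 2, 3, 4, 4, 5, 6, 6, 7, 7, 8,
  2, 3, 3, 3, 4, 5, 6, 7, 7, 8, 8, 8,
  3, 4, 4, 4, 5, 6, 7, 8, 8, 9, 9, 9,
  4, 4, 4, 5, 6, 7, 8, 8, 9, 9, 9, 9,
  6, 6, 6, 7, 8, 8, 9, 9, 10, 10, 10, 10,
  7, 7, 7, 8, 9, 9, 9, 10, 10, 11, 11, 11,
  8, 8, 8, 9, 10, 10, 10, 10, 10, 11, 11, 11,
  9, 9, 9, 10, 10, 10, 11, 11, 11, 12, 12, 12,
  10, 10, 10, 11, 11, 11, 11, 12, 12, 12, 12, 12,
  11, 11, 11, 11, 12, 12, 12, 12, 12, 12, 12, 12,
  12, 12, 12, 12, 12, 12, 12, 12, 12, 12, 12, 12
), nrow = 12, byrow = TRUE)

#' REBA score
#'
#' Deterministic lookup through the REBA worksheet: Table A combines trunk,
#' neck and legs and adds the load/force points; Table B combines upper arm,
#' lower arm and wrist and adds the coupling points; Table C combines the
#' two, and the activity points are added to give the final score (1-15).
#'
#' @param posture A [posture_inputs()] list. REBA uses `trunk` (1-5),
#'   `neck` (1-3), `legs` (1-4), `upper_arm` (1-6), `lower_arm` (1-2),
#'   `wrist` (1-3), `load` (0-3), `coupling` (0-3), `activity` (0-3).
#' @return A one-row tibble: `score_a`, `score_b`, `score_c`, `reba`.
#' @examples
#' reba(posture_inputs())$reba  # neutral posture: 1
#' @export
reba <- function(posture) {
  stopifnot(inherits(posture, "mate_posture"))
  tr <- check_score(posture$trunk, "trunk", 5)
  nk <- check_score(posture$neck, "neck", 3)
  lg <- check_score(posture$legs, "legs", 4)
  ua <- check_score(posture$upper_arm, "upper_arm", 6)
  la <- check_score(posture$lower_arm, "lower_arm", 2)
  wr <- check_score(posture$wrist, "wrist", 3)
  ld <- check_points(posture$load, "load", 3)
  cp <- check_points(posture$coupling, "coupling", 3)
  ac <- check_points(posture$activity, "activity", 3)
  score_a <- REBA_TABLE_A[lg, tr, nk] + ld
  score_b <- REBA_TABLE_B[wr, ua, la] + cp
  score_c <- REBA_TABLE_C[min(score_a, 12L), min(score_b, 12L)]
  tibble::tibble(score_a = score_a, score_b = score_b, score_c = score_c,
                 reba = score_c + ac)
}
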