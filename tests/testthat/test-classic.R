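test_that("recommended weight limit reproduces the published multipliers", {
  ideal <- niosh_inputs(23, horizontal = 25, vertical = 75, travel = 25,
                        asymmetry = 0, frequency = 0.2,
                        duration_class = "1h", coupling = "good")
  r <- niosh_rwl(ideal)
  expect_equal(unlist(r[c("hm", "vm", "dm", "am", "fm", "cm")]),
               c(hm = 1, vm = 1, dm = 1, am = 1, fm = 1, cm = 1))
  expect_equal(r$rwl, 23)
  expect_equal(lifting_index(ideal)$li, 1.0)

  # single-multiplier departures from ideal
  expect_equal(niosh_rwl(niosh_inputs(10, horizontal = 50,
                                      duration_class = "1h"))$rwl, 11.5)
  expect_equal(niosh_rwl(niosh_inputs(10, vertical = 175,
                                      duration_class = "1h"))$vm, 0.7)
  expect_equal(niosh_rwl(niosh_inputs(10, travel = 70,
                                      duration_class = "1h"))$dm,
               0.82 + 4.5 / 70)
  expect_equal(niosh_rwl(niosh_inputs(10, asymmetry = 90,
                                      duration_class = "1h"))$am,
               1 - 0.0032 * 90)
})

test_that("frequency and coupling multipliers follow the band tables", {
  expect_equal(niosh_rwl(niosh_inputs(10, frequency = 3,
                                      duration_class = "8h"))$fm, 0.55)
  expect_equal(niosh_rwl(niosh_inputs(10, vertical = 50, frequency = 9,
                                      duration_class = "8h"))$fm, 0)   # V<75
  expect_equal(niosh_rwl(niosh_inputs(10, vertical = 100, frequency = 9,
                                      duration_class = "8h"))$fm, 0.15)
  expect_equal(niosh_rwl(niosh_inputs(10, frequency = 16))$fm, 0)
  expect_equal(niosh_rwl(niosh_inputs(10, vertical = 50,
                                      coupling = "fair"))$cm, 0.95)
  expect_equal(niosh_rwl(niosh_inputs(10, vertical = 100,
                                      coupling = "fair"))$cm, 1.0)
  expect_equal(niosh_rwl(niosh_inputs(10, coupling = "poor"))$cm, 0.90)
})

test_that("an undefined RWL is flagged instead of reporting zero risk", {
  overhead <- niosh_inputs(5, vertical = 200)  # above vertical reach
  r <- lifting_index(overhead)
  expect_false(r$rwl_defined)
  expect_equal(r$rwl, 0)
  expect_true(is.infinite(r$li))
})

test_that("RWL never increases as any single input worsens", {
  base <- list(load_mass = 10, horizontal = 30, vertical = 60, travel = 40,
               asymmetry = 20, frequency = 2, duration_class = "2h",
               coupling = "fair")
  rwl_of <- function(args) niosh_rwl(do.call(niosh_inputs, args))$rwl
  worsen <- list(horizontal = 45, vertical = 30, travel = 90,
                 asymmetry = 60, frequency = 6)
  for (field in names(worsen)) {
    worse <- base
    worse[[field]] <- worsen[[field]]
    expect_lte(rwl_of(worse), rwl_of(base))
  }
})

test_that("worksheet scorers return the neutral-posture floor", {
  expect_equal(rula(posture_inputs())$rula, 1)
  expect_equal(reba(posture_inputs())$reba, 1)
})

test_that("worksheet scorers reach their table maxima at worst-case inputs", {
  worst_rula <- posture_inputs(upper_arm = 6, lower_arm = 3, wrist = 4,
                               wrist_twist = 2, neck = 6, trunk = 6,
                               legs = 2, muscle_use = 1, force = 3)
  expect_equal(rula(worst_rula)$rula, 7)
  worst_reba <- posture_inputs(trunk = 5, neck = 3, legs = 4, upper_arm = 6,
                               lower_arm = 2, wrist = 3, load = 3,
                               coupling = 3, activity = 3)
  expect_equal(reba(worst_reba)$reba, 15)
})

test_that("worksheet chains match hand-traced mid-range cases", {
  # RULA: upper arm 3, lower arm 2, wrist 2, twist 1 -> Table A = 4;
  # neck 2, trunk 2, legs 1 -> Table B = 2; +1 muscle use each -> C(5, 3) = 4
  p <- posture_inputs(upper_arm = 3, lower_arm = 2, wrist = 2,
                      wrist_twist = 1, neck = 2, trunk = 2, legs = 1,
                      muscle_use = 1)
  r <- rula(p)
  expect_equal(r$score_a, 5)
  expect_equal(r$score_b, 3)
  expect_equal(r$rula, 4)
  # REBA: trunk 3, neck 2, legs 2 -> Table A = 5, +1 load = 6;
  # upper arm 4, lower arm 2, wrist 2 -> Table B = 6, +1 coupling = 7;
  # C(6, 7) = 9, +1 activity = 10
  q <- posture_inputs(trunk = 3, neck = 2, legs = 2, upper_arm = 4,
                      lower_arm = 2, wrist = 2, load = 1, coupling = 1,
                      activity = 1)
  b <- reba(q)
  expect_equal(b$score_a, 6)
  expect_equal(b$score_b, 7)
  expect_equal(b$reba, 10)
})

test_that("descriptors outside the worksheet ranges are rejected", {
  expect_error(rula(posture_inputs(upper_arm = 7)), class = "mate_range_error")
  expect_error(rula(posture_inputs(wrist = 5)), class = "mate_range_error")
  expect_error(reba(posture_inputs(trunk = 6)), class = "mate_range_error")
  expect_error(reba(posture_inputs(load = 4)), class = "mate_range_error")
})
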