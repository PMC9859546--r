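test_that("vertebral strength evaluates the linear model with area scaling", {
  m <- fixture_ucs_model()  # c0 10 kN, 0.5 kN/decade, area factor 1
  expect_equal(ultimate_compressive_strength(subject_profile(40, bmi = 25), m),
               8000)
  u60 <- ultimate_compressive_strength(subject_profile(60, bmi = 25), m)
  u20 <- ultimate_compressive_strength(subject_profile(20, bmi = 25), m)
  expect_lt(u60, u20)

  mb <- ucs_model(c0 = 10, c_age = 0.5, b0 = 0.8, b1 = 0.008)
  r <- ultimate_compressive_strength(subject_profile(40, bmi = 30), mb) /
    ultimate_compressive_strength(subject_profile(40, bmi = 20), mb)
  expect_equal(r, (0.8 + 30 * 0.008) / (0.8 + 20 * 0.008))

  expect_error(ucs_model(c0 = 4, c_age = 0.5),
               class = "mate_model_domain_error")
})

test_that("cycle count is repetitions times duration", {
  expect_equal(cycle_count(task_schedule(6, 3, 120)), 360L)
  expect_equal(cycle_count(task_schedule(6, 0.2, 120)), 24L)
  expect_equal(cycle_count(task_schedule(6, 0, 120)), 0L)
})

test_that("failure probability interpolates bilinearly in load and log-cycles", {
  tb <- toy_fatigue_table()
  expect_equal(failure_probability(50, 1000, tb), 0.6)  # exact node
  expect_equal(failure_probability(30, 10, tb), 0)      # exact node
  # hand bilinear midpoint: load halfway 30-50, cycles halfway in log10
  expect_equal(failure_probability(40, 100, tb), 0.225)
  # endurance region and clamping
  expect_equal(failure_probability(10, 1e6, tb), 0)
  expect_equal(failure_probability(80, 1000, tb), 0.6)   # above top row
  expect_equal(failure_probability(50, 1e9, tb), 0.6)    # beyond cycle range
  expect_equal(failure_probability(50, 0, tb), 0)        # no loading
})

test_that("interpolated surface inherits double monotonicity", {
  set.seed(21)
  for (rep in 1:10) {
    tb <- random_monotone_table()
    loads <- seq(min(tb$load_levels), max(tb$load_levels), length.out = 25)
    cycles <- 10^seq(log10(min(tb$cycle_levels)),
                     log10(max(tb$cycle_levels)), length.out = 25)
    for (n in cycles[c(3, 12, 22)]) {
      p <- failure_probability(loads, n, tb)
      expect_true(all(diff(p) >= -1e-12))
    }
    for (l in loads[c(3, 12, 22)]) {
      p <- failure_probability(l, cycles, tb)
      expect_true(all(diff(p) >= -1e-12))
    }
  }
})

test_that("older subjects never get a lower failure probability", {
  set.seed(5)
  for (rep in 1:10) {
    tb <- random_monotone_table()
    m <- ucs_model(c0 = runif(1, 8, 12), c_age = runif(1, 0.1, 0.6),
                   c_sex = runif(1, 0, 1.5), b0 = 1, b1 = 0)
    force <- runif(1, 1000, 6000)
    n <- round(runif(1, 10, 5000))
    ages <- sort(runif(2, 20, 90))
    p <- vapply(ages, function(a) {
      subj <- subject_profile(a, bmi = 25)
      failure_probability(
        100 * force / ultimate_compressive_strength(subj, m), n, tb)
    }, numeric(1))
    expect_gte(p[2], p[1])
  }
})

test_that("risk classification is strict at the threshold", {
  expect_true(classify_spine(0.25))
  expect_false(classify_spine(0.10))
  expect_false(classify_spine(0))
})

test_that("maximal cycles before risk agrees with an exhaustive scan", {
  subj <- subject_profile(40, bmi = 25)
  m <- fixture_ucs_model()
  # oracle: scan every integer cycle count in the table range
  scan_oracle <- function(force, tb, thr) {
    load <- 100 * force / ultimate_compressive_strength(subj, m)
    grid <- seq(ceiling(min(tb$cycle_levels)), max(tb$cycle_levels))
    ok <- failure_probability(load, grid, tb) <= thr
    if (all(ok)) max(tb$cycle_levels)
    else if (!ok[1]) 0L
    else grid[max(which(ok))]
  }
  tb <- toy_fatigue_table()
  for (force in c(1000, 3200, 4000, 4800, 8000)) {
    expect_equal(
      max_cycles_before_risk(force, subj, m, tb, risk_threshold = 0.10),
      scan_oracle(force, tb, 0.10),
      info = sprintf("force %g", force))
  }
  # below the endurance region: never at risk
  expect_equal(max_cycles_before_risk(100, subj, m, tb, 0.10),
               max(tb$cycle_levels))
})

test_that("spine assessment composes strength, peak force and cycle count", {
  sched <- task_schedule(6, 3, 120)
  subj <- subject_profile(40, bmi = 25)
  tr <- mate_trace(data.frame(time = 0:2, L5 = c(100, 4000, 200)), "force")
  a <- assess_spine(tr, "L5", sched, subj, model = fixture_ucs_model(),
                    table = toy_fatigue_table())
  expect_equal(a$ucs, 8000)
  expect_equal(a$relative_load, 50)
  expect_equal(a$n_cycles, 360L)
  expect_equal(a$failure_probability,
               failure_probability(50, 360, toy_fatigue_table()))
  expect_identical(a$high_risk, a$failure_probability > 0.10)

  neg <- mate_trace(data.frame(time = 0:1, L5 = c(-4000, 100)), "force")
  expect_warning(
    aneg <- assess_spine(neg, "L5", sched, subj, model = fixture_ucs_model(),
                         table = toy_fatigue_table()),
    "magnitude")
  expect_equal(aneg$peak_force, 4000)
})

test_that("shipped synthetic fatigue table loads and validates", {
  tb <- default_fatigue_table()
  expect_s3_class(tb, "mate_fatigue_table")
  expect_true(all(tb$probability >= 0 & tb$probability <= 1))
  # spot-check against the generating probit rule documented in the file
  expect_equal(tb$probability[which(tb$load_levels == 60),
                              which(tb$cycle_levels == 1000)],
               round(pnorm((60 - (95 - 12 * 3)) / 12), 4))
})
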