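make_condition <- function(repetitions = 3, l5_peak = 4749, hip_peak = 4000,
                           act_peaks = c(delt_ant_r = 0.4, delt_ant_l = 0.35)) {
  list(
    schedule = task_schedule(6, repetitions, 120, handled_mass = 10),
    subject = subject_profile(21, "male", mass = 71.4, height = 1.75),
    activations = simple_activation_trace(act_peaks),
    forces = generate_trace(
      data.frame(name = c("hip_r", "L5_S1"),
                 peak_value = c(hip_peak, l5_peak), peak_time = 1),
      kind = "force", seed = 8),
    catalog = muscle_catalog(list(
      shoulder_flexors = c("delt_ant_r", "delt_ant_l")))
  )
}

run_assess <- function(cond, ...) {
  assess(cond$activations, cond$forces, cond$schedule, cond$subject,
         catalog = cond$catalog, ...)
}

test_that("the report equals the composition of the layer operations", {
  cond <- make_condition()
  rep <- run_assess(cond)
  dc <- duty_cycle(cond$schedule)
  expect_equal(rep$duty_cycle, dc)
  expect_equal(rep$mae, mae(dc))
  expect_equal(rep$muscle,
               group_risk(cond$activations, cond$catalog, mae(dc)))
  expect_equal(rep$hip$peak_stress,
               peak_hip_stress(cond$forces, "hip_r"))
  expect_equal(rep$spine,
               assess_spine(cond$forces, "L5_S1", cond$schedule,
                            cond$subject))
  g <- glance(rep)
  expect_equal(g$spine_failure_probability, rep$spine$failure_probability)
  expect_equal(g$n_muscle_groups_at_risk, sum(rep$muscle$at_risk))
})

test_that("a shoulder group peaking above the effort limit is listed at risk", {
  cond <- make_condition()  # MAE at DC 0.30 is 0.251; peaks 0.4/0.35 exceed
  rep <- run_assess(cond)
  expect_true("shoulder_flexors" %in% rep$muscle$group[rep$muscle$at_risk])
})

test_that("absent channels mark regions as not assessed instead of failing", {
  cond <- make_condition()
  forces_nohip <- generate_trace(
    data.frame(name = "L5_S1", peak_value = 4749, peak_time = 1),
    kind = "force", seed = 8)
  rep <- assess(cond$activations, forces_nohip, cond$schedule, cond$subject,
                catalog = cond$catalog)
  expect_null(rep$hip)
  expect_true(is.na(glance(rep)$hip_at_risk))
  expect_s3_class(rep$spine, "tbl_df")
  # explicitly named missing channels still error loudly
  expect_error(assess(forces = forces_nohip, schedule = cond$schedule,
                      subject = cond$subject, hip_channels = "hip_r"),
               class = "mate_lookup_error")
})

test_that("condition deltas are zero on identity and antisymmetric on swap", {
  a <- run_assess(make_condition())
  b <- run_assess(make_condition(repetitions = 0.2))
  d0 <- compare_reports(a, a)
  expect_true(all(d0$delta == 0))
  dab <- compare_reports(a, b)
  dba <- compare_reports(b, a)
  expect_equal(dab$delta, -dba$delta)
  spine_delta <- dab$delta[dab$region == "spine"]
  expect_lt(spine_delta, 0)  # fewer repetitions, lower failure probability
  expect_error(
    compare_reports(a, assess(schedule = make_condition()$schedule,
                              subject = make_condition()$subject)),
    "different regions")
})

test_that("tidy output is long, typed and covers every assessed region", {
  rep <- run_assess(make_condition(), niosh = niosh_inputs(10),
                    posture = posture_inputs())
  td <- tidy(rep)
  expect_true(all(c("task", "spine", "classic") %in%
                    sub("/.*", "", td$region)))
  expect_true(is.numeric(td$value))
  expect_equal(td$value[td$metric == "mae"], rep$mae)
})

test_that("report JSON and the CLI wrapper run end to end", {
  dir <- withr::local_tempdir()
  cond <- make_condition()
  act_path <- file.path(dir, "act.sto")
  frc_path <- file.path(dir, "frc.sto")
  write_motion_storage(cond$activations, act_path)
  write_motion_storage(cond$forces, frc_path)
  cfg <- box_transfer_config_file(dir)
  out <- file.path(dir, "out")
  status <- suppressMessages(mate_cli(c(
    "assess", "--activations", act_path, "--forces", frc_path,
    "--config", cfg, "--out", out)))
  expect_equal(status, 0L)
  expect_true(file.exists(file.path(out, "report.json")))
  parsed <- jsonlite::read_json(file.path(out, "report.json"))
  expect_equal(parsed$duty_cycle, 0.3, tolerance = 1e-9)
  # input errors exit 1, configuration errors exit 2
  expect_equal(suppressMessages(
    mate_cli(c("assess", "--config", file.path(dir, "nope.yaml")))), 1L)
  bad_table <- file.path(dir, "bad_table.csv")
  writeLines("load,cycles,probability\n30,10,2", bad_table)
  expect_equal(suppressMessages(mate_cli(c(
    "assess", "--forces", frc_path, "--config", cfg,
    "--fatigue-table", bad_table))), 2L)
})
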