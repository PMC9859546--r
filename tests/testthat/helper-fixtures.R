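# Fixtures built in code; nothing binary on disk.

toy_fatigue_table <- function() {
  # loads 30/50 %UCS, cycles 10/1000, probabilities chosen so the hand
  # bilinear value at (40, 100) is 0.225
  fatigue_table(load_levels = c(30, 50), cycle_levels = c(10, 1000),
                probability = matrix(c(0, 0.1, 0.2, 0.6), nrow = 2,
                                     byrow = TRUE))
}

fixture_ucs_model <- function() ucs_model(c0 = 10, c_age = 0.5)

random_monotone_table <- function(n_loads = 4, n_cycles = 5) {
  # cumulated positive increments along both axes give a doubly
  # non-decreasing probability surface
  inc <- matrix(runif(n_loads * n_cycles, 0, 0.1), n_loads, n_cycles)
  m <- t(apply(apply(inc, 2, cumsum), 1, cumsum))
  m <- m / max(m)
  fatigue_table(sort(runif(n_loads, 10, 100)),
                sort(10^runif(n_cycles, 0, 5)), m)
}

simple_activation_trace <- function(peaks, duration = 2) {
  generate_trace(
    data.frame(name = names(peaks), peak_value = unname(peaks),
               peak_time = duration / 2),
    kind = "activation", duration = duration, seed = 1
  )
}

box_transfer_config_file <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "config.yaml")
  writeLines(c(
    "task:",
    "  cycle_duration: 6",
    "  repetitions_per_minute: 3",
    "  total_duration: 120",
    "  handled_mass: 10",
    "subject:",
    "  age: 21",
    "  sex: male",
    "  mass: 71.4",
    "  height: 1.75",
    "channels:",
    "  hip: [hip_r]",
    "  spine: L5_S1",
    "muscle_groups:",
    "  shoulder_flexors: [delt_ant_r, delt_ant_l]"
  ), path)
  path
}
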