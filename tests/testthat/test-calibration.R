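test_that("threshold evaluation returns the confusion matrix and accuracies", {
  tasks <- labeled_tasks(c("a", "b"), c(0.05, 0.20), c("low", "high"))
  r <- evaluate_threshold(tasks, 0.10)
  expect_equal(r$overall_accuracy, 1.0)
  expect_equal(r$high_risk_accuracy, 1.0)
  expect_equal(r$low_risk_accuracy, 1.0)

  inv <- labeled_tasks(c("a", "b"), c(0.05, 0.20), c("high", "low"))
  expect_equal(evaluate_threshold(inv, 0.10)$overall_accuracy, 0.0)

  single <- labeled_tasks(c("a", "b"), c(0.05, 0.20), c("high", "high"))
  rs <- evaluate_threshold(single, 0.10)
  expect_true(rs$single_class)
  expect_true(is.na(rs$low_risk_accuracy))

  expect_error(labeled_tasks(character(), numeric(), character()),
               class = "mate_empty_tasks")
})

test_that("threshold sweep matches brute-force confusion-matrix enumeration", {
  # independent oracle: enumerate predictions directly at many thresholds
  tasks <- labeled_tasks(
    paste0("t", 1:6), c(0.02, 0.08, 0.08, 0.15, 0.30, 0.40),
    c("low", "low", "high", "high", "low", "high"))
  oracle <- function(th) {
    pred <- tasks$failure_probability > th
    truth <- tasks$label == "high"
    mean(pred == truth)
  }
  for (th in seq(0, 1, by = 0.01)) {
    expect_equal(evaluate_threshold(tasks, th)$overall_accuracy, oracle(th),
                 info = sprintf("threshold %g", th))
  }
  # best candidate on the midpoint grid is never beaten anywhere
  best <- calibrate(tasks)
  dense <- vapply(seq(0, 1, by = 0.001), oracle, numeric(1))
  expect_gte(best$overall_accuracy, max(dense))
})

test_that("calibration is exact on separable sets and honest on degenerate ones", {
  sep <- labeled_tasks(paste0("t", 1:6),
                       c(0.01, 0.03, 0.05, 0.2, 0.5, 0.9),
                       c(rep("low", 3), rep("high", 3)))
  best <- calibrate(sep)
  expect_equal(best$overall_accuracy, 1.0)
  expect_gt(best$threshold, 0.05)
  expect_lt(best$threshold, 0.2)

  same <- labeled_tasks(paste0("t", 1:5), rep(0.3, 5),
                        c("high", "high", "high", "low", "low"))
  expect_equal(calibrate(same)$overall_accuracy, 3 / 5)
})

test_that("calibration is invariant to task order and ties break protectively", {
  tasks <- generate_calibration_set(n = 60, seed = 4)
  shuffled <- tasks[sample(nrow(tasks)), ]
  a <- calibrate(tasks)
  b <- calibrate(shuffled)
  expect_equal(a$threshold, b$threshold)
  expect_equal(a$overall_accuracy, b$overall_accuracy)

  # two thresholds tie on overall accuracy; the more sensitive one wins
  tie <- labeled_tasks(paste0("t", 1:4), c(0.1, 0.2, 0.3, 0.4),
                       c("low", "high", "low", "high"))
  best <- calibrate(tie)
  sweep <- attr(best, "sweep")
  top <- sweep[sweep$overall_accuracy == max(sweep$overall_accuracy), ]
  expect_equal(best$high_risk_accuracy, max(top$high_risk_accuracy))
})

test_that("planted boundary with label noise is recovered within tolerance", {
  accs <- numeric(100)
  thresholds <- numeric(100)
  for (s in 1:100) {
    tasks <- generate_calibration_set(n = 148, boundary = 0.10,
                                      noise = 0.30, seed = s)
    best <- calibrate(tasks)
    accs[s] <- best$overall_accuracy
    thresholds[s] <- best$threshold
  }
  # expected accuracy = 1 - flip rate = 0.70 (empirical optimum sits a few
  # points above on finite samples)
  expect_gt(mean(accs), 0.62)
  expect_lt(mean(accs), 0.78)
  # the recovered cutoff concentrates near the planted boundary: the median
  # must fall inside the central band around 0.10 rather than at the extremes
  expect_gt(stats::median(thresholds), 0.0)
  expect_lt(stats::median(thresholds), 0.25)
})

test_that("labeled-task CSV loader round-trips through calibrate", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "tasks.csv")
  tasks <- generate_calibration_set(n = 30, seed = 9)
  readr::write_csv(tasks[c("id", "failure_probability", "label")], path)
  back <- read_labeled_tasks(path)
  expect_equal(calibrate(back)$threshold, calibrate(tasks)$threshold)
})
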