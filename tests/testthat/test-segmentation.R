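square_force <- function(n_cycles = 10, level = 6, cycle_s = 6, fs = 10) {
  t <- seq(0, n_cycles * cycle_s, by = 1 / fs)
  f <- ifelse(t %% cycle_s < cycle_s / 2 & t < n_cycles * cycle_s, level, 0)
  force_recording(cbind(f, 0, 0, 0), fs = fs, t = t)
}

test_that("a clean square profile yields one cycle per repetition", {
  fr <- square_force(10)
  cy <- detect_cycles(fr, "index")
  expect_equal(nrow(cy), 10)
  expect_equal(unique(cy$direction), 1)
  expect_equal(cy$duration, rep(3, 10), tolerance = 0.11)
})

test_that("force never exceeding the threshold yields no cycles", {
  fr <- square_force(5, level = 6)
  cy <- detect_cycles(fr, "index", f_max = 100)   # threshold 10 N > signal
  expect_equal(nrow(cy), 0)
})

test_that("noisy triangle cycles are recovered at the generator boundaries", {
  withr::local_seed(73)
  fs <- 10; cycle_s <- 8; reps <- 6; level <- 8
  t <- seq(0, reps * cycle_s, by = 1 / fs)
  tau <- t %% cycle_s
  f <- level * pmin(tau / (cycle_s / 2), 2 - tau / (cycle_s / 2))
  f[t >= reps * cycle_s] <- 0
  f <- pmax(f + rnorm(length(f), 0, 0.05), 0)
  fr <- force_recording(cbind(f, 0, 0, 0), fs = fs, t = t)
  cy <- detect_cycles(fr, "index", f_max = level)
  expect_equal(nrow(cy), reps)
  # boundaries within one frame of the programmed 10 % crossings
  up_cross <- (seq_len(reps) - 1) * cycle_s + 0.1 * cycle_s / 2
  expect_true(all(abs(cy$t_start - up_cross) <= 0.1 + 1e-9))
})

test_that("duration rule rejects the hand-computed outlier cycle", {
  durations <- c(rep(6, 9), 12)
  cy <- tibble::tibble(
    cycle = 1:10, finger = "index", direction = 1,
    t_start = cumsum(c(0, durations[-10])) , t_end = cumsum(durations),
    duration = durations, amplitude_mid = rep(5, 10),
    amplitude_peak = rep(5, 10)
  )
  class(cy) <- c("cycle_set", class(cy))
  rep_out <- reject_outliers(cy, "square")
  # population statistics: mean 6.6, sd 1.8, band 2.58 * 1.8 = 4.644
  expect_equal(attr(rep_out, "t_mean"), 6.6)
  expect_equal(attr(rep_out, "t_sd"), 1.8, tolerance = 1e-12)
  expect_identical(which(!rep_out$kept), 10L)
  expect_equal(rep_out$cause[10], "duration")
  # |12 - 6.6| = 5.4 exceeds 4.644; |6 - 6.6| = 0.6 does not
  expect_true(rep_out$duration_dev[10] > 2.58 * 1.8)
  expect_true(all(rep_out$duration_dev[1:9] < 2.58 * 1.8))
})

test_that("amplitude rule rejects one displaced plateau and nothing else", {
  amps <- seq(5, 6.8, by = 0.2)      # perfect linear trend over 10 cycles
  amps[4] <- amps[4] + 5             # one displaced plateau midpoint
  cy <- tibble::tibble(
    cycle = 1:10, finger = "index", direction = 1,
    t_start = (0:9) * 6, t_end = (0:9) * 6 + 3, duration = rep(3, 10),
    amplitude_mid = amps, amplitude_peak = amps
  )
  class(cy) <- c("cycle_set", class(cy))
  rep_out <- reject_outliers(cy, "square")
  # brute-force oracle for the residual rule
  fit <- stats::lm(amps ~ seq_along(amps))
  resid <- unname(stats::residuals(fit))
  mse <- mean(resid^2)
  expect_equal(rep_out$amplitude_residual, resid, tolerance = 1e-12)
  expect_identical(which(!rep_out$kept), which(abs(resid) > 1.96 * mse))
  expect_identical(which(!rep_out$kept), 4L)
  expect_equal(rep_out$cause[4], "amplitude")
})

test_that("identical cycles are never rejected and order is irrelevant", {
  cy <- tibble::tibble(
    cycle = 1:10, finger = "index", direction = 1,
    t_start = (0:9) * 6, t_end = (0:9) * 6 + 3, duration = rep(3, 10),
    amplitude_mid = rep(4, 10), amplitude_peak = rep(4, 10)
  )
  class(cy) <- c("cycle_set", class(cy))
  rep_out <- reject_outliers(cy, "triangle")
  expect_true(all(rep_out$kept))
  # fewer than 3 cycles: keep all, warn
  expect_warning(r2 <- reject_outliers(cy[1:2, ], "square"), "fewer than 3")
  expect_true(all(r2$kept))
})

test_that("phase masks partition time per finger", {
  labels <- label_intervals(c("IF", "IE"), c(2, 6), c(5, 8))
  tb <- seq(0, 10, by = 0.1)
  m <- build_phase_masks(labels, tb)
  expect_true(all(m$index[tb >= 2 & tb < 5]))
  expect_true(all(m$index[tb >= 6 & tb < 8]))
  expect_false(any(m$index[tb < 2 | (tb >= 5 & tb < 6) | tb >= 8]))
  expect_false(any(m$middle | m$ring | m$little))
  # rest-only labels leave every finger silent
  m0 <- build_phase_masks(label_intervals(character()), tb)
  expect_false(any(as.matrix(m0[fingers()])))
  # overlapping intervals for one finger are an error
  bad <- tibble::tibble(class = c("IF", "IF"), t_start = c(0, 1),
                        t_end = c(2, 3), level = 0.5,
                        task_id = NA_integer_, finger = "index")
  expect_error(build_phase_masks(bad, tb), "overlapping")
})

test_that("alternating square tasks have about 50 % active duty cycle", {
  profile <- make_offline_protocol(n_reps = 4)
  lab9 <- profile$labels[profile$labels$task_id == 9, ]
  blocks9 <- profile$blocks[profile$blocks$task_id == 9, ]
  m <- build_phase_masks(lab9, profile$targets$t)
  for (i in seq_len(nrow(blocks9))) {
    fg <- blocks9$finger[i]
    span <- profile$targets$t >= min(lab9$t_start[lab9$finger == fg]) &
      profile$targets$t < max(lab9$t_end[lab9$finger == fg]) +
        offline_task_table()$cycle_s[9] / 2
    duty <- mean(m[[fg]][span])
    expect_equal(duty, 0.5, tolerance = 0.1)
  }
})

test_that("the protocol split separates single- and mixed-direction tasks", {
  profile <- make_offline_protocol(n_reps = 1)
  sp <- build_split(profile$labels)
  expect_equal(sp$train, 1:8)
  expect_equal(sp$test, 9:12)
  # missing task 12 still splits, with a warning
  lab <- profile$labels[profile$labels$task_id != 12, ]
  expect_warning(sp2 <- build_split(lab), "missing task")
  expect_equal(sp2$test, 9:11)
  # unknown ids are an error
  lab$task_id[1] <- 13L
  expect_error(build_split(lab), "unknown task id")
  # train fraction by cycle duration is about two thirds
  tab <- offline_task_table()
  dur <- tab$cycle_s
  expect_equal(sum(dur[1:8]) / sum(dur), 2 / 3, tolerance = 1e-9)
})
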