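test_that("rest EMG is baseline Gaussian noise with the programmed sigma", {
  # 10 s of rest: per-channel RMS within 3 standard errors of baseline_sd
  profile <- fingerdecode:::rasterize_profile(
    tibble::tibble(class = "IF", t0 = 0, dur = 0.0001, shape = "square",
                   level = 0, task_id = NA_integer_, finger = "index",
                   params = list(list(cycle_s = 1))),
    total_s = 10
  )
  subject <- subject_params(sensor_sd = 0, spatial_jitter_sd = 0)
  sim <- simulate_session_features(profile, subject, seed = 101,
                                   channels = c(1, 50, 100))
  rms <- feature_matrix(sim$features)
  # RMS of n Gaussian samples: se ~ sd / sqrt(2 n); ~410 samples per
  # window, ~98 frames per channel
  se <- subject$baseline_sd / sqrt(2 * 410 * nrow(rms))
  expect_true(all(abs(colMeans(rms) - subject$baseline_sd) < 3 * se * 2))
  expect_lt(abs(mean(rms) - subject$baseline_sd), 0.05)
})

test_that("without enslaving only the task finger produces force", {
  profile <- make_training_protocol(classes = "MF", levels = 0.6)
  subject <- subject_params(enslaving = diag(4), sensor_sd = 0)
  sim <- simulate_session_features(profile, subject, seed = 5, channels = 1:2)
  f <- as.matrix(sim$force[fingers()])
  expect_true(any(f[, "middle"] != 0))
  expect_true(all(f[, c("index", "ring", "little")] == 0))
})

test_that("the active finger's force dominates the enslaved fingers", {
  profile <- make_training_protocol(classes = "RF", levels = 0.66)
  subject <- subject_params()
  sim <- simulate_session_features(profile, subject, seed = 7, channels = 1:2)
  f <- abs(as.matrix(sim$force[fingers()]))
  ratio <- max(f[, "ring"]) / max(f[, c("index", "middle", "little")])
  expect_gt(ratio, 3)
})

test_that("sessions are bitwise reproducible from the seed", {
  profile <- make_training_protocol(classes = "IF", levels = 0.9)
  subject <- subject_params(seed = 3)
  s1 <- simulate_session(profile, subject, seed = 11, channels = 1:6)
  s2 <- simulate_session(profile, subject, seed = 11, channels = 1:6)
  expect_identical(s1$emg$samples, s2$emg$samples)
  expect_identical(as.data.frame(s1$force), as.data.frame(s2$force))
  s3 <- simulate_session(profile, subject, seed = 12, channels = 1:6)
  expect_false(identical(s1$emg$samples, s3$emg$samples))
})

test_that("the features-only path matches the full-EMG path", {
  profile <- make_training_protocol(classes = c("IF", "LE"), levels = 0.6)
  subject <- subject_params(seed = 2)
  sess <- simulate_session(profile, subject, seed = 13, channels = 1:8)
  slow <- extract_rms_features(sess$emg)
  fast <- simulate_session_features(profile, subject, seed = 13,
                                    channels = 1:8)
  expect_identical(slow$t, fast$features$t)
  expect_equal(feature_matrix(slow), feature_matrix(fast$features),
               tolerance = 1e-10)
  expect_identical(as.matrix(sess$force[fingers()]),
                   as.matrix(fast$force[fingers()]))
})

test_that("active frames carry more subset RMS than rest frames", {
  profile <- make_training_protocol(classes = "IF", levels = 0.6)
  subject <- subject_params()
  sim <- simulate_session_features(profile, subject, seed = 17)
  idx <- fingerdecode:::align_to_frames(sim$features$t, profile$targets$t)
  truth <- reference_classes(profile)[idx, ]
  hotspot <- suggest_channel_subsets(sim$features, truth, k = 5)$IF
  sm <- rowMeans(feature_matrix(filter_channels(sim$features, hotspot)))
  expect_gt(min(tapply(sm, truth$class == "IF", mean)["TRUE"]),
            tapply(sm, truth$class == "IF", mean)["FALSE"] * 2)
})

test_that("stronger enslaving strictly increases non-target force", {
  profile <- make_training_protocol(classes = "IF", levels = 0.9)
  amp <- vapply(c(0, 0.05, 0.1, 0.2), function(eta) {
    subject <- subject_params(enslaving = enslaving_matrix(eta, eta / 3),
                              sensor_sd = 0)
    sim <- simulate_session_features(profile, subject, seed = 19,
                                     channels = 1:2)
    max(abs(sim$force$middle))
  }, numeric(1))
  expect_true(all(diff(amp) > 0))
})

test_that("MVC measurement recovers the programmed hotspot amplitude", {
  subject <- subject_params(spatial_jitter_sd = 0)
  mvc_profile <- make_mvc_protocol(classes = "IF")
  sim <- simulate_session_features(mvc_profile, subject, seed = 23)
  idx <- fingerdecode:::align_to_frames(sim$features$t, mvc_profile$targets$t)
  truth <- reference_classes(mvc_profile)[idx, ]
  hotspot <- suggest_channel_subsets(sim$features, truth, k = 5)$IF
  mvc <- measure_mvc(sim$features, list(IF = hotspot))
  # generator ground truth: baseline + gain * mean blob value over subset
  maps <- fingerdecode:::activation_maps(subject, grid_geometry(), hotspot)
  programmed <- subject$baseline_sd + subject$gain[["IF"]] * mean(maps["IF", ])
  expect_equal(unname(mvc), programmed, tolerance = 0.05 * programmed)
})
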