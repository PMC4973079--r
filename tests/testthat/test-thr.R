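make_hotspot_features <- function(n = 80, seed = 51) {
  # 1 x 6 strip: IF hottest on channels 1-2, RE on channels 5-6
  withr::with_seed(seed, {
    mk <- function(means) t(vapply(seq_len(n), function(i) {
      abs(rnorm(6, means, 1))
    }, numeric(6)))
    x <- rbind(mk(c(40, 35, 6, 6, 5, 5)),
               mk(c(5, 6, 6, 5, 42, 37)),
               mk(rep(5, 6)))
    truth <- rep(c("IF", "RE", "REST"), each = n)
    list(features = as_features(x), truth = truth)
  })
}

test_that("hotspot suggestion picks the class's top channels", {
  h <- make_hotspot_features()
  subs <- suggest_channel_subsets(h$features, h$truth, k = 2)
  expect_setequal(subs$IF, c(1L, 2L))
  expect_setequal(subs$RE, c(5L, 6L))
  # k = 1 with a single active channel returns that channel
  subs1 <- suggest_channel_subsets(h$features, h$truth, k = 1)
  expect_equal(subs1$IF, 1L)
})

test_that("channels shared between two classes are assigned to neither", {
  # both classes peak on channel 3
  withr::local_seed(53)
  n <- 60
  mk <- function(means) t(vapply(seq_len(n), function(i) {
    abs(rnorm(4, means, 0.5))
  }, numeric(4)))
  x <- rbind(mk(c(30, 8, 40, 5)), mk(c(5, 8, 42, 30)), mk(rep(5, 4)))
  truth <- rep(c("IF", "RE", "REST"), each = n)
  subs <- expect_warning(
    suggest_channel_subsets(as_features(x), truth, k = 2),
    "fewer than 2 non-conflicting"
  )
  expect_false(3L %in% subs$IF)
  expect_false(3L %in% subs$RE)
})

test_that("threshold calibration picks the separating plateau midpoint", {
  h <- make_hotspot_features()
  subs <- suggest_channel_subsets(h$features, h$truth, k = 2)
  mvc <- c(IF = 45, RE = 45)
  m <- calibrate_thresholds(subs, h$features, h$truth, mvc)
  tab <- m$table
  # perfectly separable: the threshold falls between the rest and active
  # subset-mean distributions and the detection is perfect
  x <- feature_matrix(h$features)
  if_means <- rowMeans(x[, subs$IF, drop = FALSE])
  rest_max <- max(if_means[h$truth != "IF"])
  act_min <- min(if_means[h$truth == "IF"])
  thr_if <- tab$threshold[tab$class == "IF"]
  expect_gt(thr_if, rest_max)
  expect_lt(thr_if, act_min)
  expect_equal(tab$balanced_accuracy, c(1, 1))
  expect_true(all(tab$controllable))
  # chosen threshold is at least as good as 1000 random candidates
  withr::local_seed(59)
  bacc <- function(thr) {
    det <- if_means > thr
    pos <- h$truth == "IF"
    (mean(det[pos]) + mean(!det[!pos])) / 2
  }
  rand <- runif(1000, min(if_means), max(if_means))
  expect_gte(bacc(thr_if), max(vapply(rand, bacc, numeric(1))))
})

test_that("degenerate calibration flags the class with a warning", {
  withr::local_seed(61)
  n <- 50
  x <- rbind(matrix(abs(rnorm(n * 2, 5, 1)), ncol = 2),     # "active" low
             matrix(abs(rnorm(n * 2, 9, 1)), ncol = 2))     # rest higher
  truth <- rep(c("IF", "REST"), each = n)
  expect_warning(
    m <- calibrate_thresholds(list(IF = 1:2), as_features(x), truth,
                              c(IF = 10)),
    "degenerate"
  )
  expect_false(m$table$controllable[1])
})

test_that("prediction follows crossing + highest-subset-mean competition", {
  tab <- tibble::tibble(
    class = c("IF", "RE"), channels = list(1:2, 3:4),
    threshold = c(10, 10), mvc = c(50, 50),
    balanced_accuracy = c(1, 1), recall = c(1, 1),
    controllable = c(TRUE, TRUE)
  )
  m <- structure(list(table = tab), class = "thr_decoder")
  nm <- sprintf("ch_%03d", 1:4)
  frame <- function(v) matrix(v, nrow = 1, dimnames = list(NULL, nm))
  # below both thresholds -> rest
  p <- predict_thr(m, frame(c(5, 5, 5, 5)))
  expect_equal(p$class, "REST")
  expect_equal(p$level, 0)
  # only one class crosses -> that class, scaled to % MVC
  p <- predict_thr(m, frame(c(30, 30, 5, 5)))
  expect_equal(p$class, "IF")
  expect_equal(p$level, 100 * 30 / 50)
  # both cross, higher subset mean wins
  p <- predict_thr(m, frame(c(20, 20, 40, 40)))
  expect_equal(p$class, "RE")
  expect_equal(p$ring, -80)          # extension trace is negative
  # monotonicity: raising the winning subset never lowers its level
  p2 <- predict_thr(m, frame(c(20, 20, 45, 45)))
  expect_gte(p2$level, p$level)
})

test_that("overlapped activation maps are flagged uncontrollable", {
  # hard subject: ring-extension map sits exactly on index flexion
  subject <- subject_params(preset = "hard")
  res <- run_thr_failure_experiment(subject, seed = 71,
                                    channels = select_regular_subset(
                                      grid_geometry(), 96)$channels)
  expect_true(length(res$flagged) >= 1)
  expect_true(any(res$flagged %in% c("IF", "RE")))
})
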