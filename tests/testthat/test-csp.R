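test_that("diagonal two-channel case matches the closed-form eigensolution", {
  xa <- diag_moment_features(4, 1)   # S_a = diag(4, 1)
  xb <- diag_moment_features(1, 4)   # S_b = diag(1, 4)
  f <- fit_csp_pair(xa, xb)
  # generalized eigenproblem S_a w = lambda (S_a + S_b) w: for diagonal
  # moments the eigenvalues are 4/5 and 1/5 with axis eigenvectors
  expect_equal(f$lambda, 0.8, tolerance = 1e-12)
  expect_equal(abs(f$w_a), c(1, 0), tolerance = 1e-10)
  expect_equal(abs(f$w_b), c(0, 1), tolerance = 1e-10)
  expect_equal(sum(f$w_a^2), 1, tolerance = 1e-12)
})

test_that("identical class statistics give lambda one half", {
  x <- diag_moment_features(2, 3)
  f <- fit_csp_pair(x, x)
  expect_equal(f$lambda, 0.5, tolerance = 1e-10)
})

test_that("fitted filter beats a large random direction search", {
  withr::local_seed(3)
  n <- 400; d <- 8
  a_mix <- matrix(rnorm(d * d), d); b_mix <- matrix(rnorm(d * d), d)
  xa <- matrix(rnorm(n * d), n) %*% a_mix
  xb <- matrix(rnorm(n * d), n) %*% b_mix
  f <- fit_csp_pair(xa, xb)
  ratio <- function(W) colMeans((xa %*% W)^2) / colMeans((xb %*% W)^2)
  fitted_ratio <- ratio(matrix(f$w_a))
  w_rand <- matrix(rnorm(1e5 * d), nrow = d)
  w_rand <- sweep(w_rand, 2, sqrt(colSums(w_rand^2)), `/`)
  rand_best <- max(ratio(w_rand))
  # brute-force search over 1e5 unit directions cannot beat the eigenvector
  expect_lte(rand_best, fitted_ratio * (1 + 1e-9))
})

test_that("the nine-class model has one filter per unordered pair", {
  withr::local_seed(5)
  fbc <- stats::setNames(lapply(movement_classes(), function(cl) {
    matrix(abs(rnorm(60 * 4, 10, 3)), ncol = 4)
  }), movement_classes())
  m <- fit_csp_pe(fbc)
  expect_length(m$filters, choose(9, 2))
  expect_equal(glance(m)$n_filters, 36)
  m2 <- fit_csp_pe(toy_features_by_class()[c("IF", "REST")])
  expect_length(m2$filters, 1)
  # a class with no frames is a named error
  fbc$MF <- fbc$MF[0, , drop = FALSE]
  expect_error(fit_csp_pe(fbc), "MF")
})

test_that("fused scores calibrate to one at the top training level", {
  withr::local_seed(9)
  # three-level training data: feature magnitude proportional to level
  base <- c(40, 8, 6, 5)
  lev <- rep(c(0.3, 0.6, 0.9), each = 150)
  xa <- t(vapply(lev, function(l) abs(rnorm(4, base * l, 1.5)), numeric(4)))
  rest <- matrix(abs(rnorm(150 * 4, 4, 1)), ncol = 4)
  m <- fit_csp_pe(list(IF = xa, REST = rest),
                  list(IF = lev, REST = rep(0, 150)))
  s <- csp_fused_scores(m, xa[lev == 0.9, ])
  expect_equal(mean(s[, "IF"]), 1, tolerance = 0.05)
  # the decoded level at the mean top-level vector is near 90 % MVC
  pred <- predict_csp_pe(m, colMeans(xa[lev == 0.9, ]))
  expect_equal(pred$class, "IF")
  expect_equal(pred$level, 90, tolerance = 10)
})

test_that("decoding is zero at rest input and honours the min fusion", {
  m <- fit_csp_pe(toy_features_by_class())
  pred0 <- predict_csp_pe(m, rep(0, 4))
  expect_equal(pred0$class, "REST")
  expect_equal(as.numeric(pred0[1, fingers()]), rep(0, 4))
  # fused score of every class is <= each of its pairwise responses
  withr::local_seed(13)
  x <- matrix(abs(rnorm(50 * 4, 15, 8)), ncol = 4)
  s <- csp_fused_scores(m, x)
  for (f in m$filters) {
    resp_a <- (x %*% f$w_a)^2 * f$norm_a * m$fused_scale[f$class_a]
    expect_true(all(s[, f$class_a] <= resp_a + 1e-9))
  }
  # min property: a zero pairwise response forces a zero fused score
  w <- m$filters[[1]]$w_a
  x_perp <- rep(1, 4) - sum(w) * w    # orthogonal to w_a of the first pair
  s_perp <- csp_fused_scores(m, x_perp)
  expect_equal(unname(s_perp[1, m$filters[[1]]$class_a]), 0, tolerance = 1e-12)
})

test_that("decisions are invariant to a common positive rescaling", {
  fbc <- toy_features_by_class()
  m1 <- fit_csp_pe(fbc)
  alpha <- 3.7
  m2 <- fit_csp_pe(lapply(fbc, function(x) alpha * x))
  withr::local_seed(17)
  x <- matrix(abs(rnorm(80 * 4, 20, 10)), ncol = 4)
  p1 <- predict_csp_pe(m1, x)
  p2 <- predict_csp_pe(m2, alpha * x)
  expect_equal(p1$class, p2$class)
  expect_equal(p1$level, p2$level, tolerance = 1e-6)
})

test_that("frame-wise decisions match generator labels on active phases", {
  # well-separated synthetic subject at 48 electrodes
  subject <- subject_params(seed = 2)
  data <- simulate_offline_dataset(subject, seed = 21, n_reps = 1,
                                   channels = select_regular_subset(
                                     grid_geometry(), 48)$channels)
  fits <- fit_offline_decoders(data, 48)
  te <- which(data$test_mask)
  x_te <- feature_matrix(filter_channels(data$features,
                                         fits$subset))[te, , drop = FALSE]
  pred <- predict_csp_pe(fits$csp, x_te)
  active <- data$truth$class[te] != "REST"
  agree <- mean(pred$class[active] == data$truth$class[te][active])
  expect_gte(agree, 0.9)
})
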