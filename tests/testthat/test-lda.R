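test_that("equal-variance one-dimensional boundary sits at the midpoint", {
  xa <- matrix(c(-1.5, -1, -0.5, -1), ncol = 1) ; xa <- xa - mean(xa) - 1
  xb <- -xa                                      # means exactly -1 and +1
  m <- fit_lda(list(IF = xa, MF = xb))
  d <- lda_discriminants(m, matrix(0))
  expect_equal(unname(d[1, 1]), unname(d[1, 2]), tolerance = 1e-12)
  expect_equal(predict_lda_class(m, matrix(-0.01)), "IF")
  expect_equal(predict_lda_class(m, matrix(0.01)), "MF")
})

test_that("decisions equal the closed-form Bayes rule on Gaussian data", {
  withr::local_seed(23)
  n <- 5000
  mu_a <- c(1, 0); mu_b <- c(-0.5, 1.5)
  mix <- matrix(c(1, 0.4, 0, 0.8), 2)
  xa <- matrix(rnorm(n * 2), ncol = 2) %*% mix + rep(mu_a, each = n)
  xb <- matrix(rnorm(n * 2), ncol = 2) %*% mix + rep(mu_b, each = n)
  m <- fit_lda(list(IF = xa, MF = xb))
  x_test <- rbind(xa[1:2500, ], xb[1:2500, ])
  ours <- predict_lda_class(m, x_test)
  # closed-form oracle: Gaussian log-densities with the fitted moments
  logdens <- function(x, mu, sigma_inv, logdet, prior) {
    xc <- sweep(x, 2, mu)
    -0.5 * rowSums((xc %*% sigma_inv) * xc) - 0.5 * logdet + log(prior)
  }
  si <- solve(m$pooled_cov)
  ld <- determinant(m$pooled_cov)$modulus[1]
  bayes <- ifelse(
    logdens(x_test, m$means["IF", ], si, ld, m$priors[["IF"]]) >=
      logdens(x_test, m$means["MF", ], si, ld, m$priors[["MF"]]),
    "IF", "MF"
  )
  expect_identical(ours, unname(bayes))
})

test_that("decisions agree with an independent LDA implementation", {
  skip_if_not_installed("MASS")
  fbc <- toy_features_by_class(n = 150)
  m <- fit_lda(fbc)
  x <- do.call(rbind, fbc)
  ref <- MASS::lda(x, grouping = rep(names(fbc), each = 150))
  ours <- predict_lda_class(m, x)
  theirs <- as.character(stats::predict(ref, x)$class)
  expect_gt(mean(ours == theirs), 0.995)
})

test_that("three collinear means give the middle class the centre region", {
  withr::local_seed(29)
  mk <- function(mu) matrix(rnorm(400, mu, 1), ncol = 2)
  m <- fit_lda(list(IF = mk(-4), MF = mk(0), RF = mk(4)))
  # brute-force posterior grid along the shared axis
  grid <- seq(-1.2, 1.2, length.out = 41)
  cls <- predict_lda_class(m, cbind(grid, grid))
  expect_true(all(cls == "MF"))
})

test_that("LDA is invariant to adding a constant feature offset", {
  fbc <- toy_features_by_class()
  m1 <- fit_lda(fbc)
  shift <- c(3, -1, 2, 0.5)
  m2 <- fit_lda(lapply(fbc, function(x) sweep(x, 2, -shift)))
  withr::local_seed(31)
  x <- matrix(abs(rnorm(100 * 4, 15, 6)), ncol = 4)
  expect_identical(predict_lda_class(m1, x),
                   predict_lda_class(m2, sweep(x, 2, -shift)))
  expect_equal(m2$pooled_cov, m1$pooled_cov, tolerance = 1e-10)
})

test_that("with equal priors and spherical covariance LDA is nearest mean", {
  withr::local_seed(37)
  centers <- rbind(c(0, 0), c(6, 0), c(0, 6))
  fbc <- list(IF = NULL, MF = NULL, RF = NULL)
  for (i in 1:3) fbc[[i]] <- matrix(rnorm(600, 0, 1), ncol = 2) +
      rep(centers[i, ], each = 300)
  m <- fit_lda(fbc)
  x <- matrix(runif(200, -2, 8), ncol = 2)
  nearest <- c("IF", "MF", "RF")[apply(x, 1, function(p) {
    which.min(colSums((t(m$means) - p)^2))
  })]
  expect_gt(mean(predict_lda_class(m, x) == nearest), 0.97)
})

test_that("force maps recover an exact linear relation and reject zeros", {
  withr::local_seed(41)
  x <- matrix(abs(rnorm(60 * 3, 10, 3)), ncol = 3)
  gain <- 0.8
  force <- matrix(0, 60, 4); force[, 1] <- gain * x[, 2]   # index from ch 2
  f <- as_features(x)
  fr <- force_recording(force, t = f$t - 0.1)
  truth <- tibble::tibble(t = f$t, class = rep("IF", 60), level = 0.5)
  fm <- fit_force_maps(f, fr, truth)
  beta <- fm$maps$IF
  expect_equal(unname(beta["ch_002"]), gain, tolerance = 1e-8)
  expect_equal(unname(beta[c("(Intercept)", "ch_001", "ch_003")]),
               rep(0, 3), tolerance = 1e-8)
  # noiseless fit has zero residual
  pred <- fingerdecode:::predict_force_map(fm, "IF", x)
  expect_equal(pred, gain * x[, 2], tolerance = 1e-8)
  # all-zero force gives an all-zero map
  fr0 <- force_recording(matrix(0, 60, 4), t = f$t - 0.1)
  fm0 <- fit_force_maps(f, fr0, truth)
  expect_equal(unname(fm0$maps$IF), rep(0, 4), tolerance = 1e-10)
})

test_that("offline prediction emits winner-only force, floored at zero", {
  fbc <- toy_features_by_class()
  m <- fit_lda(fbc)
  f <- as_features(rbind(colMeans(fbc$IF), colMeans(fbc$RE),
                         colMeans(fbc$REST)))
  force <- rbind(c(5, 0, 0, 0), c(0, 0, -4, 0), c(0, 0, 0, 0))
  fr <- force_recording(force, t = f$t - 0.1)
  truth <- tibble::tibble(t = f$t, class = c("IF", "RE", "REST"),
                          level = c(0.6, 0.6, 0))
  fm <- suppressWarnings(fit_force_maps(f, fr, truth))
  pred <- predict_lda_offline(m, fm, feature_matrix(f))
  expect_equal(pred$class, c("IF", "RE", "REST"))
  expect_equal(pred$index[1] > 0, TRUE)
  expect_equal(pred$ring[2] < 0, TRUE)     # extension is negative
  expect_equal(as.numeric(pred[3, fingers()]), rep(0, 4))
})

test_that("online prediction scales the class subset mean to % MVC", {
  fbc <- toy_features_by_class()
  m <- fit_lda(fbc)
  subsets <- list(IF = 1L, RE = 2L)
  mvc <- c(IF = 50, RE = 60)
  x_if <- colMeans(fbc$IF)
  x <- matrix(x_if, nrow = 1, dimnames = list(NULL, sprintf("ch_%03d", 1:4)))
  pred <- predict_lda_online(m, subsets, mvc, x)
  expect_equal(pred$class, "IF")
  expect_equal(pred$level, 100 * x_if[1] / 50, tolerance = 1e-9)
  # subset mean equal to MVC decodes as exactly 100 %
  x2 <- x; x2[1, 1] <- 50
  expect_equal(predict_lda_online(m, subsets, mvc, x2)$level, 100)
  # missing subset for the decided class is an error
  x_re <- matrix(colMeans(fbc$RE), nrow = 1,
                 dimnames = list(NULL, sprintf("ch_%03d", 1:4)))
  expect_error(predict_lda_online(m, list(IF = 1L), mvc, x_re),
               "missing channel subset or MVC")
})
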