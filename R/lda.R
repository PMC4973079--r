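#' Fit the pooled-covariance linear discriminant classifier
#'
#' Gaussian class-conditional model with per-class means and a single
#' covariance matrix pooled over all classes; with a shared covariance the
#' Bayes rule reduces to linear discriminant functions
#' `delta_c(x) = x' S^-1 mu_c - mu_c' S^-1 mu_c / 2 + log pi_c`.
#' Priors are the empirical class frequencies. When the pooled covariance
#' is ill-conditioned (condition number above `cond_max`) it is shrunk
#' towards a scaled identity with weight `gamma`, the same policy as the
#' CSP module.
#'
#' @param features_by_class named list (movement class -> frames x
#'   channels matrix), each class with at least 2 frames.
#' @param gamma,cond_max shrinkage regularization policy.
#' @return An object of class `lda_decoder` with fields `classes`, `means`
#'   (class x channel matrix), `pooled_cov`, `priors`, and the
#'   discriminant coefficients (`coef`, `const`).
#' @export
fit_lda <- function(features_by_class, gamma = 1e-3, cond_max = 1e10) {
  classes <- names(features_by_class)
  check_movement_class(classes)
  classes <- movement_classes()[movement_classes() %in% classes]
  xs <- lapply(features_by_class[classes], as.matrix)
  ns <- vapply(xs, nrow, integer(1))
  if (any(ns < 2)) {
    stop("each class needs at least 2 frames: ",
         paste(classes[ns < 2], collapse = ", "), call. = FALSE)
  }
  d <- ncol(xs[[1]])
  means <- do.call(rbind, lapply(xs, colMeans))
  pooled <- matrix(0, d, d)
  for (i in seq_along(xs)) {
    xc <- sweep(xs[[i]], 2, means[i, ])
    pooled <- pooled + crossprod(xc)
  }
  pooled <- pooled / (sum(ns) - length(ns))
  if (!all(is.finite(pooled))) stop("non-finite pooled covariance", call. = FALSE)
  if (kappa(pooled, exact = FALSE) > cond_max) {
    pooled <- (1 - gamma) * pooled +
      gamma * (sum(diag(pooled)) / d + 1e-12) * diag(d)
  }
  inv <- tryCatch(solve(pooled), error = function(e) NULL)
  if (is.null(inv)) {
    stop("singular pooled covariance after shrinkage", call. = FALSE)
  }
  priors <- ns / sum(ns)
  coef <- inv %*% t(means)                       # d x C
  const <- -0.5 * colSums(t(means) * coef) + log(priors)
  structure(
    list(classes = classes, means = means, pooled_cov = pooled,
         priors = priors, coef = coef, const = const,
         channel_ids = feature_channel_ids(features_by_class)),
    class = "lda_decoder"
  )
}

#' Linear discriminant scores and class decision
#'
#' @param model a fitted `lda_decoder`.
#' @param x feature vector or frames x channels matrix.
#' @return `lda_discriminants()`: frames x classes matrix of discriminant
#'   values; `predict_lda_class()`: character vector of decided classes
#'   (ties resolved in favour of rest, then canonical order).
#' @export
lda_discriminants <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != nrow(model$coef)) {
    stop("feature dimension does not match the fitted channel set",
         call. = FALSE)
  }
  d <- x %*% model$coef
  d <- sweep(d, 2, model$const, `+`)
  colnames(d) <- model$classes
  d
}

#' @rdname lda_discriminants
#' @export
predict_lda_class <- function(model, x) {
  decide_winner(lda_discriminants(model, x), model$classes)
}

#' Fit per-class force-regression maps
#'
#' The offline proportional back-end: for every non-rest class, ordinary
#' least squares from the class's active-phase RMS feature vectors to the
#' active finger's signed fingertip force (N). If a class has fewer active
#' frames than channels + 1 the system is under-determined and a small
#' ridge penalty is used instead, with a warning.
#'
#' @param features an `emg_features` tibble (10 Hz, synchronized with the
#'   forces).
#' @param force a [force_recording()] on the same time base.
#' @param truth a tibble with frame-wise `t` and true `class` (e.g. from
#'   [reference_classes()] aligned to the feature frames).
#' @param ridge ridge penalty used for under-determined classes.
#' @return An object of class `force_map`: per class, intercept + one
#'   coefficient per channel, mapping an RMS vector to newtons.
#' @export
fit_force_maps <- function(features, force, truth, ridge = 1e-3) {
  x <- feature_matrix(features)
  idx <- align_to_frames(features$t, force$t)
  fm <- as.matrix(force[fingers()])[idx, , drop = FALSE]
  cls_frames <- truth$class
  stopifnot(length(cls_frames) == nrow(x))
  maps <- list()
  for (cl in intersect(active_classes(), unique(cls_frames))) {
    sel <- which(cls_frames == cl)
    y <- fm[sel, class_finger(cl)]
    xa <- x[sel, , drop = FALSE]
    xd <- cbind(1, xa)
    if (length(sel) >= ncol(xd)) {
      fit <- stats::lm.fit(xd, y)
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
    } else {
      warning("force map for ", cl, " is under-determined (", length(sel),
              " frames, ", ncol(xa), " channels); using ridge regression",
              call. = FALSE)
      g <- crossprod(xd) + ridge * mean(colSums(xd^2)) * diag(ncol(xd))
      beta <- as.vector(solve(g, crossprod(xd, y)))
    }
    maps[[cl]] <- stats::setNames(as.vector(beta),
                                  c("(Intercept)", colnames(x)))
  }
  structure(list(maps = maps,
                 channel_ids = attr(features, "channel_ids")),
            class = "force_map")
}

predict_force_map <- function(force_map, class, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  beta <- force_map$maps[[class]]
  if (is.null(beta)) return(rep(0, nrow(x)))
  as.vector(cbind(1, as.matrix(x)) %*% beta)
}

#' Decode activation frames with LDA (offline force back-end)
#'
#' The class decision is the discriminant argmax; the proportional value is
#' the decided class's force-regression output in newtons, emitted only for
#' the decided class (winner-take-all) and floored at zero force in the
#' direction of the decision (a negative flexion-force prediction during a
#' flexion decision is clipped to 0, and symmetrically for extension).
#' Rest decisions yield all-zero output.
#'
#' @param model a fitted `lda_decoder`.
#' @param force_map a fitted [fit_force_maps()] on the same channel set.
#' @param x feature vector or frames x channels matrix.
#' @param t optional frame times.
#' @return A `finger_activation` tibble; `level` is in newtons here.
#' @export
predict_lda_offline <- function(model, force_map, x, t = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  cls <- predict_lda_class(model, x)
  level <- numeric(nrow(x))
  for (cl in setdiff(unique(cls), "REST")) {
    sel <- which(cls == cl)
    pred <- predict_force_map(force_map, cl, x[sel, , drop = FALSE])
    level[sel] <- pmax(class_sign(cl) * pred, 0)
  }
  activation_frames(cls, level, t)
}

#' Decode activation frames with LDA (online MVC-scaled back-end)
#'
#' The class decision is the discriminant argmax; the proportional value is
#' the mean RMS over the decided class's channel subset, scaled to percent
#' of that class's MVC.
#'
#' @param model a fitted `lda_decoder`.
#' @param subset_per_class named list, class -> channel ids (grid indices).
#' @param mvc named numeric vector, class -> MVC scale (microvolts RMS).
#' @param x named feature vector or frames x channels matrix with `ch_<id>`
#'   column names.
#' @param t optional frame times.
#' @return A `finger_activation` tibble; `level` in % MVC.
#' @export
predict_lda_online <- function(model, subset_per_class, mvc, x, t = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  x <- as.matrix(x)
  cls <- predict_lda_class(model, x)
  level <- numeric(nrow(x))
  for (cl in setdiff(unique(cls), "REST")) {
    if (is.null(subset_per_class[[cl]]) || is.na(mvc[cl])) {
      stop("missing channel subset or MVC for decided class ", cl,
           call. = FALSE)
    }
    cols <- match(sprintf("ch_%03d", subset_per_class[[cl]]), colnames(x))
    if (anyNA(cols)) {
      stop("subset channels for ", cl, " not present in features",
           call. = FALSE)
    }
    sel <- which(cls == cl)
    level[sel] <- 100 * rowMeans(x[sel, cols, drop = FALSE]) / mvc[cl]
  }
  activation_frames(cls, pmax(level, 0), t)
}

#' @export
print.lda_decoder <- function(x, ...) {
  cat(sprintf("<lda_decoder> %d classes, %d channels\n",
              length(x$classes), nrow(x$coef)))
  invisible(x)
}

#' @export
print.force_map <- function(x, ...) {
  cat(sprintf("<force_map> %d classes, %d channels\n",
              length(x$maps), length(x$channel_ids)))
  invisible(x)
}

# nearest-index alignment of feature frame times onto a 10 Hz stream; the
# feature frame ending at t is paired with the reference/force sample at
# the window centre t - 0.1 s.
align_to_frames <- function(t_frames, t_ref, offset = -0.1) {
  idx <- round((t_frames + offset - t_ref[1]) * 10) + 1
  pmin(pmax(idx, 1L), length(t_ref))
}
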