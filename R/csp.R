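#' Fit a common-spatial-patterns filter for one class pair
#'
#' Determines the spatial filter whose output has maximal variance for
#' class-a feature vectors and minimal variance for class-b vectors (and a
#' second filter with the roles reversed). With `S_a` and `S_b` the
#' second-moment matrices of the class RMS vectors, `w_a` solves the
#' generalized eigenproblem `S_a w = lambda (S_a + S_b) w` at the largest
#' eigenvalue and `w_b` at the smallest; both are unit-norm. The
#' eigenvalue lies in (0, 1): 0.5 means the classes are indistinguishable.
#'
#' Uncentered second moments are used rather than mean-removed covariances:
#' RMS features are non-negative and overall magnitude is the
#' discriminative quantity, which also lets the rest class contrast with
#' active classes through energy alone. When the composite matrix
#' `S_a + S_b` is ill-conditioned (condition number above `cond_max`) it is
#' shrunk towards a scaled identity, `S <- (1 - gamma) S + gamma tr(S)/d I`.
#'
#' @param features_a,features_b numeric matrices (frames x channels) of RMS
#'   feature vectors for the two classes.
#' @param top_a,top_b optional logical vectors marking the frames recorded
#'   at the top calibration level; the per-side normalisation constants
#'   `norm_a`, `norm_b` map the mean squared filter response over those
#'   frames to 1. Default: all frames.
#' @param gamma shrinkage weight used when regularization is triggered.
#' @param cond_max condition-number threshold that triggers shrinkage.
#' @return An object of class `csp_pair_filter` with fields `w_a`, `w_b`
#'   (unit-norm weight vectors), `lambda` (the top generalized eigenvalue),
#'   `norm_a`, `norm_b`.
#' @export
fit_csp_pair <- function(features_a, features_b, top_a = NULL, top_b = NULL,
                         gamma = 1e-3, cond_max = 1e10) {
  xa <- as.matrix(features_a)
  xb <- as.matrix(features_b)
  stopifnot(ncol(xa) == ncol(xb), nrow(xa) > 0, nrow(xb) > 0)
  d <- ncol(xa)
  s_a <- crossprod(xa) / nrow(xa)
  s_b <- crossprod(xb) / nrow(xb)
  m <- s_a + s_b
  if (!all(is.finite(m))) stop("non-finite class moments", call. = FALSE)
  if (kappa(m, exact = FALSE) > cond_max) {
    m <- (1 - gamma) * m + gamma * (sum(diag(m)) / d) * diag(d)
  }
  r <- tryCatch(chol(m), error = function(e) NULL)
  if (is.null(r)) {
    m <- (1 - gamma) * m + gamma * (sum(diag(m)) / d + 1e-12) * diag(d)
    r <- tryCatch(chol(m), error = function(e) NULL)
    if (is.null(r)) {
      stop("rank-deficient composite moment matrix after regularization",
           call. = FALSE)
    }
  }
  rinv <- backsolve(r, diag(d))
  a_w <- crossprod(rinv, s_a %*% rinv)
  eig <- eigen((a_w + t(a_w)) / 2, symmetric = TRUE)
  unitize <- function(v) v / sqrt(sum(v^2))
  w_a <- unitize(as.vector(rinv %*% eig$vectors[, 1]))
  w_b <- unitize(as.vector(rinv %*% eig$vectors[, d]))
  norm_for <- function(x, top, w) {
    if (is.null(top)) top <- rep(TRUE, nrow(x))
    resp <- mean((x[top, , drop = FALSE] %*% w)^2)
    if (resp <= 0) 1 else 1 / resp
  }
  structure(
    list(w_a = w_a, w_b = w_b, lambda = eig$values[1],
         norm_a = norm_for(xa, top_a, w_a), norm_b = norm_for(xb, top_b, w_b)),
    class = "csp_pair_filter"
  )
}

#' Fit the multi-class CSP proportional estimator (CSP-PE)
#'
#' Fits one CSP filter pair per unordered pair of movement classes (36
#' pairs for the full nine-class problem) in a one-vs-one configuration,
#' then calibrates the fused outputs: the squared, per-pair-normalised
#' filter responses of a class are fused by taking the minimum over all of
#' the class's pairwise competitions, and a per-class scale is set so that
#' the mean fused score over the frames at the class's top calibration
#' level equals 1. The decoded level is then proportional to the top
#' calibration level (`level_scale`): a fused score of 1 maps to that
#' level, in % MVC.
#'
#' @param features_by_class named list (movement class -> frames x
#'   channels matrix) of training RMS features. Must include `"REST"` and
#'   at least one other class.
#' @param level_by_frame named list (class -> numeric vector, one
#'   instantaneous target level per frame, as a fraction of MVC). Frames
#'   within 95 % of the class maximum count as top-level calibration
#'   frames. Defaults to level 1 for every frame.
#' @param gamma,cond_max regularization policy, see [fit_csp_pair()].
#' @return An object of class `csp_pe`: pairwise filters, per-class fused
#'   scale and `level_scale`, the channel ids, and rest-score statistics.
#' @export
fit_csp_pe <- function(features_by_class, level_by_frame = NULL,
                       gamma = 1e-3, cond_max = 1e10) {
  classes <- names(features_by_class)
  check_movement_class(classes)
  if (length(classes) < 2) stop("need at least two classes", call. = FALSE)
  empty <- classes[vapply(features_by_class,
                          function(x) NROW(x) == 0, logical(1))]
  if (length(empty) > 0) {
    stop("class with no training frames: ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  classes <- movement_classes()[movement_classes() %in% classes]
  xs <- lapply(features_by_class[classes], as.matrix)
  if (is.null(level_by_frame)) {
    level_by_frame <- lapply(xs, function(x) rep(1, nrow(x)))
  }
  top <- lapply(classes, function(cl) {
    lev <- level_by_frame[[cl]]
    if (is.null(lev) || cl == "REST") return(rep(TRUE, nrow(xs[[cl]])))
    lev >= 0.95 * max(lev)
  })
  names(top) <- classes
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  filters <- lapply(pairs, function(p) {
    f <- fit_csp_pair(xs[[p[1]]], xs[[p[2]]], top_a = top[[p[1]]],
                      top_b = top[[p[2]]], gamma = gamma, cond_max = cond_max)
    f$class_a <- p[1]
    f$class_b <- p[2]
    f
  })
  model <- structure(
    list(classes = classes, filters = filters,
         channel_ids = feature_channel_ids(features_by_class),
         fused_scale = stats::setNames(rep(1, length(classes)), classes),
         level_scale = stats::setNames(rep(0, length(classes)), classes)),
    class = "csp_pe"
  )
  for (cl in classes) {
    sc <- csp_fused_scores(model, xs[[cl]])[, cl]
    mtop <- mean(sc[top[[cl]]])
    model$fused_scale[cl] <- if (mtop > 0) 1 / mtop else 1
    model$level_scale[cl] <-
      if (cl == "REST") 0 else max(level_by_frame[[cl]])
  }
  rest_sc <- csp_fused_scores(model, xs[["REST"]] %||% xs[[classes[1]]])
  model$rest_statistics <- tibble::tibble(
    class = classes,
    mean = colMeans(rest_sc)[classes],
    var = apply(rest_sc, 2, stats::var)[classes]
  )
  # Rest decision bound: RMS features have a positive baseline, so every
  # filter responds on rest frames too; a class is only decodable when its
  # fused score clears its own rest-frame score distribution.
  model$rest_threshold <- stats::setNames(
    model$rest_statistics$mean + 3 * sqrt(model$rest_statistics$var),
    model$rest_statistics$class
  )
  model
}

feature_channel_ids <- function(features_by_class) {
  x <- features_by_class[[1]]
  cn <- colnames(x)
  if (is.null(cn)) return(seq_len(ncol(as.matrix(x))))
  as.integer(sub("ch_", "", cn))
}

#' Fused CSP-PE class scores
#'
#' For each input frame and class, the fused score is the minimum over the
#' class's pairwise competitions of the squared, normalised filter
#' response `(w' x)^2 * norm`. If a class loses even one competition its
#' fused score is small: the minimum penalises any lost contrast.
#' Calibration scales make the mean fused score of a class equal 1 at its
#' top training level.
#'
#' @param model a fitted `csp_pe`.
#' @param x numeric matrix (frames x channels) or a single feature vector.
#' @return Matrix frames x classes of fused scores (non-negative).
#' @export
csp_fused_scores <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != length(model$filters[[1]]$w_a)) {
    stop("feature dimension does not match the fitted channel set",
         call. = FALSE)
  }
  classes <- model$classes
  s <- matrix(Inf, nrow = nrow(x), ncol = length(classes),
              dimnames = list(NULL, classes))
  for (f in model$filters) {
    resp_a <- (x %*% f$w_a)^2 * f$norm_a
    resp_b <- (x %*% f$w_b)^2 * f$norm_b
    s[, f$class_a] <- pmin(s[, f$class_a], resp_a)
    s[, f$class_b] <- pmin(s[, f$class_b], resp_b)
  }
  sweep(s, 2, model$fused_scale[classes], `*`)
}

#' Decode activation frames with CSP-PE
#'
#' The winning movement is the active class with the largest fused score
#' (ties resolved by canonical class order); the frame is decoded as rest
#' when that score does not clear the winner's rest-frame score bound
#' (mean + 3 sd of the class's fused score over the rest training frames).
#' The decoded level is `100 * score * level_scale` in % MVC for the
#' winner's finger, zero for the others, and all-zero at rest. Levels are
#' floored at 0 and deliberately not clipped above 100 % MVC.
#'
#' @param model a fitted `csp_pe`.
#' @param x feature vector or frames x channels matrix.
#' @param t optional frame times for the output.
#' @return A `finger_activation` tibble: `t`, `class`, `level` (% MVC) and
#'   one signed % MVC trace column per finger.
#' @export
predict_csp_pe <- function(model, x, t = NULL) {
  s <- csp_fused_scores(model, x)
  winner <- decide_csp_winner(model, s)
  level <- numeric(nrow(s))
  act <- winner != "REST"
  if (any(act)) {
    level[act] <- 100 *
      s[cbind(which(act), match(winner[act], colnames(s)))] *
      model$level_scale[winner[act]]
  }
  activation_frames(winner, pmax(level, 0), t)
}

# active-class argmax, demoted to REST below the class's rest-score bound
decide_csp_winner <- function(model, s) {
  act <- intersect(model$classes, active_classes())
  if (length(act) == 0) return(rep("REST", nrow(s)))
  sa <- s[, act, drop = FALSE]
  win_i <- max.col(sa, ties.method = "first")
  winner <- act[win_i]
  best <- sa[cbind(seq_len(nrow(sa)), win_i)]
  thr <- model$rest_threshold %||%
    stats::setNames(rep(0, length(act)), act)
  winner[best <= thr[winner]] <- "REST"
  winner
}

# argmax with deterministic tie-breaking: rest first, then canonical order
decide_winner <- function(scores, classes) {
  apply(scores, 1, function(row) {
    best <- which(row == max(row))
    if (length(best) > 1 && "REST" %in% classes[best]) return("REST")
    classes[best[1]]
  })
}

# assemble the standard decoded-output tibble
activation_frames <- function(class, level, t = NULL) {
  n <- length(class)
  level <- ifelse(class == "REST", 0, level)
  tr <- matrix(0, nrow = n, ncol = 4, dimnames = list(NULL, fingers()))
  act <- class != "REST"
  if (any(act)) {
    tr[cbind(which(act), match(class_finger(class[act]), fingers()))] <-
      class_sign(class[act]) * level[act]
  }
  out <- tibble::tibble(class = class, level = level)
  if (!is.null(t)) out <- tibble::add_column(out, t = t, .before = 1)
  out <- dplyr::bind_cols(out, tibble::as_tibble(as.data.frame(tr)))
  class(out) <- c("finger_activation", class(out))
  out
}

#' @export
print.csp_pe <- function(x, ...) {
  cat(sprintf("<csp_pe> %d classes, %d pairwise filters, %d channels\n",
              length(x$classes), length(x$filters),
              length(x$channel_ids)))
  invisible(x)
}
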