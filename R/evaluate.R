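#' Simulate an offline experiment dataset
#'
#' Runs the twelve-task offline protocol through the session simulator and
#' returns everything the decoders and metrics need on the common 10 Hz
#' time base: RMS features, recorded forces, frame-wise ground truth and
#' the task blocks for the train/test split. EMG is only generated for the
#' requested channels (all 192 by default).
#'
#' @param subject a [subject_params()].
#' @param seed integer simulation seed.
#' @param n_reps cycles per task-finger block (protocol default 10; the
#'   scaled-down evaluation experiments use 2).
#' @param channels optional channel subset to simulate.
#' @param protocol_seed seed for the finger-order randomization.
#' @return A list: `features`, `force`, `labels`, `profile`, `truth`
#'   (frame-wise `class` and `level`), `force_at_frames` (matrix, N),
#'   `masks` (frame-wise per-finger active masks), `task_id` (per frame)
#'   and `train_mask`/`test_mask`.
#' @export
simulate_offline_dataset <- function(subject, seed = 1, n_reps = 2,
                                     channels = NULL, protocol_seed = seed) {
  profile <- make_offline_protocol(n_reps = n_reps, seed = protocol_seed)
  sim <- simulate_session_features(profile, subject, seed = seed,
                                   channels = channels)
  ref_idx <- align_to_frames(sim$features$t, profile$targets$t)
  truth <- reference_classes(profile)[ref_idx, ]
  masks <- build_phase_masks(profile$labels, profile$targets$t)[ref_idx, ]
  blocks <- profile$blocks
  blk_idx <- findInterval(truth$t, blocks$t_start + 1e-9)
  blk_idx <- pmin(pmax(blk_idx, 1L), nrow(blocks))
  task_id <- blocks$task_id[blk_idx]
  split <- build_split(profile$labels)
  list(
    features = sim$features, force = sim$force, labels = sim$labels,
    profile = profile, truth = truth,
    force_at_frames = as.matrix(sim$force[fingers()])[ref_idx, , drop = FALSE],
    masks = masks, task_id = task_id,
    train_mask = task_id %in% split$train,
    test_mask = task_id %in% split$test
  )
}

slice_features <- function(features, rows) {
  new_emg_features(features[rows, ],
                   window_ms = attr(features, "window_ms"),
                   overlap = attr(features, "overlap"),
                   channel_ids = attr(features, "channel_ids"))
}

features_by_class_of <- function(features, truth) {
  x <- feature_matrix(features)
  cls <- intersect(movement_classes(), unique(truth$class))
  stats::setNames(lapply(cls, function(cl) {
    x[truth$class == cl, , drop = FALSE]
  }), cls)
}

levels_by_class_of <- function(truth) {
  cls <- intersect(movement_classes(), unique(truth$class))
  stats::setNames(lapply(cls, function(cl) {
    truth$level[truth$class == cl]
  }), cls)
}

#' Calibrate a per-class force scale for CSP-PE offline decoding
#'
#' The fused CSP-PE score is quadratic in the underlying activation, so
#' its square root is the linear proportional quantity. For offline force
#' decoding, each class's signed force gain is fitted by
#' through-the-origin least squares of the recorded active-finger force on
#' the square root of the class's fused score over the training frames.
#'
#' @param model a fitted `csp_pe`.
#' @param features training `emg_features`.
#' @param force_at_frames frames x 4 matrix of recorded forces (N) aligned
#'   with the features.
#' @param truth frame-wise truth tibble (`class` column).
#' @return Named numeric vector class -> signed N per unit root-score.
#' @export
fit_csp_force_scale <- function(model, features, force_at_frames, truth) {
  s <- csp_fused_scores(model, feature_matrix(features))
  gains <- stats::setNames(rep(0, length(model$classes)), model$classes)
  for (cl in setdiff(model$classes, "REST")) {
    sel <- which(truth$class == cl)
    if (length(sel) == 0) next
    r <- sqrt(s[sel, cl])
    y <- force_at_frames[sel, class_finger(cl)]
    if (sum(r^2) > 0) gains[cl] <- sum(r * y) / sum(r^2)
  }
  gains
}

#' Decode forces with CSP-PE
#'
#' Winner-take-all class decision from the fused scores; the decoded force
#' is the winner's calibrated signed gain times the square root of its
#' fused score.
#'
#' @param model a fitted `csp_pe`.
#' @param force_scale gains from [fit_csp_force_scale()].
#' @param x feature matrix or vector.
#' @param t optional frame times.
#' @return A `finger_activation` tibble with `level` in newtons
#'   (magnitude) and signed per-finger trace columns.
#' @export
predict_csp_force <- function(model, force_scale, x, t = NULL) {
  s <- csp_fused_scores(model, x)
  winner <- decide_csp_winner(model, s)
  lv <- numeric(nrow(s))
  act <- winner != "REST"
  if (any(act)) {
    root <- sqrt(s[cbind(which(act), match(winner[act], colnames(s)))])
    signed <- force_scale[winner[act]] * root
    lv[act] <- pmax(class_sign(winner[act]) * signed, 0)
  }
  activation_frames(winner, lv, t)
}

#' Fit both machine-learning decoders on the training tasks
#'
#' @param data a dataset from [simulate_offline_dataset()].
#' @param n_channels electrode subset size (see [allowed_subset_sizes()]).
#' @return A list with the channel subset, the fitted `csp_pe` (+ force
#'   scale) and `lda_decoder` (+ force maps).
#' @export
fit_offline_decoders <- function(data, n_channels) {
  spec <- select_regular_subset(grid_geometry(), n_channels)
  feats <- filter_channels(data$features, spec)
  tr <- which(data$train_mask)
  feats_tr <- slice_features(feats, tr)
  truth_tr <- data$truth[tr, ]
  fbc <- features_by_class_of(feats_tr, truth_tr)
  csp <- fit_csp_pe(fbc, levels_by_class_of(truth_tr))
  csp_force <- fit_csp_force_scale(csp, feats_tr,
                                   data$force_at_frames[tr, , drop = FALSE],
                                   truth_tr)
  lda <- fit_lda(fbc)
  fmap <- fit_force_maps(feats_tr, data$force, truth_tr)
  list(subset = spec, features = feats, csp = csp, csp_force = csp_force,
       lda = lda, force_map = fmap)
}

#' Evaluate fitted decoders on the held-out test tasks
#'
#' Decodes the test-task frames (tasks 9-12), smooths the per-finger force
#' traces with [moving_average5()], and computes the outcome measures:
#' per-finger nMSE, PCORR and MAFA against the recorded forces, plus the
#' nine-class confusion matrix, classification accuracy and one-vs-all
#' sensitivity/specificity medians.
#'
#' @param fits from [fit_offline_decoders()].
#' @param data the dataset the decoders were fitted on.
#' @return A tibble in tidy form: `method`, `n_channels`, `metric`,
#'   `finger` (`NA` for global metrics), `value`; the confusion matrices
#'   are attached as attribute `confusions`.
#' @export
evaluate_offline_decoders <- function(fits, data) {
  te <- which(data$test_mask)
  x_te <- feature_matrix(slice_features(fits$features, te))
  truth_te <- data$truth[te, ]
  preds <- list(
    csp_pe = predict_csp_force(fits$csp, fits$csp_force, x_te,
                               t = truth_te$t),
    lda = predict_lda_offline(fits$lda, fits$force_map, x_te,
                              t = truth_te$t)
  )
  ref <- data$force_at_frames[te, , drop = FALSE]
  masks <- as.matrix(data$masks[te, fingers()])
  rows <- list()
  confusions <- list()
  for (method in names(preds)) {
    pred <- preds[[method]]
    cm <- confusion_matrix(truth_te$class, pred$class)
    confusions[[method]] <- cm
    ss <- sensitivity_specificity(cm, drop_absent = TRUE)
    for (fg in fingers()) {
      est <- moving_average5(pred[[fg]])
      act <- masks[, fg]
      sil <- !act
      scale_f <- max(ref[act, fg]) - min(ref[act, fg])
      rows[[length(rows) + 1]] <- tibble::tibble(
        method = method, n_channels = fits$subset$n_channels,
        metric = c("nmse", "pcorr", "mafa"), finger = fg,
        value = c(nmse(est, ref[, fg], act), pcorr(est, ref[, fg], act),
                  mafa(est, sil, scale_f))
      )
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      method = method, n_channels = fits$subset$n_channels,
      metric = c("ca", "median_sensitivity", "median_specificity"),
      finger = NA_character_,
      value = c(classification_accuracy(cm),
                attr(ss, "median_sensitivity"),
                attr(ss, "median_specificity"))
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "confusions") <- confusions
  out
}

#' Run the offline experiment over a synthetic cohort
#'
#' Simulates `n_subjects` synthetic subjects, each at several noise seeds,
#' runs the train/test offline evaluation at the requested electrode-subset
#' sizes, and returns the tidy metric rows for all runs. Only the union of
#' the required channel subsets is simulated.
#'
#' @param n_subjects number of synthetic subjects (blob centres, gains and
#'   baseline jittered per subject).
#' @param session_seeds integer vector of per-subject simulation seeds.
#' @param n_channels electrode subset sizes to evaluate.
#' @param n_reps cycles per task-finger block.
#' @param preset subject preset, see [subject_params()].
#' @param base_seed offsets all derived seeds, for end-to-end
#'   reproducibility.
#' @return Tidy tibble with columns `subject`, `seed`, `method`,
#'   `n_channels`, `metric`, `finger`, `value`.
#' @export
run_offline_cohort <- function(n_subjects = 5, session_seeds = 1:3,
                               n_channels = c(48, 8), n_reps = 2,
                               preset = "default", base_seed = 0) {
  union_channels <- sort(unique(unlist(lapply(
    n_channels, function(n) select_regular_subset(grid_geometry(), n)$channels
  ))))
  purrr::map_dfr(seq_len(n_subjects), function(i) {
    subject <- subject_params(preset = preset,
                              seed = base_seed * 1009 + i)
    purrr::map_dfr(session_seeds, function(s) {
      data <- simulate_offline_dataset(
        subject, seed = base_seed * 131071 + i * 1000 + s,
        n_reps = n_reps, channels = union_channels,
        protocol_seed = base_seed + i
      )
      purrr::map_dfr(n_channels, function(n) {
        fits <- fit_offline_decoders(data, n)
        res <- evaluate_offline_decoders(fits, data)
        tibble::add_column(res, subject = i, seed = s, .before = 1)
      })
    })
  })
}

#' Wrap a fitted decoder for the closed-loop tracking simulator
#'
#' Produces the one-argument decoder function consumed by
#' [simulate_tracking_subject()]: named RMS feature vector in, named
#' signed per-finger trace (% MVC) out.
#'
#' @param model a fitted `csp_pe`, `lda_decoder` or `thr_decoder`.
#' @param ... for the LDA online decoder, `subset_per_class` and `mvc`.
#' @return A function of one feature vector.
#' @export
as_tracking_decoder <- function(model, ...) {
  UseMethod("as_tracking_decoder")
}

trace_of <- function(pred) {
  stats::setNames(as.numeric(pred[1, fingers()]), fingers())
}

#' @export
as_tracking_decoder.csp_pe <- function(model, ...) {
  cols <- sprintf("ch_%03d", model$channel_ids)
  function(x) trace_of(predict_csp_pe(model, x[cols]))
}

#' @export
as_tracking_decoder.lda_decoder <- function(model, subset_per_class, mvc, ...) {
  cols <- sprintf("ch_%03d", model$channel_ids)
  function(x) {
    trace_of(predict_lda_online(model, subset_per_class, mvc,
                                matrix(x[cols], nrow = 1,
                                       dimnames = list(NULL, cols))))
  }
}

#' @export
as_tracking_decoder.thr_decoder <- function(model, ...) {
  function(x) {
    trace_of(predict_thr(model, matrix(x, nrow = 1,
                                       dimnames = list(NULL, names(x)))))
  }
}

#' Tracking outcome measures for a closed-loop run
#'
#' Smooths the decoded traces, then computes per-finger active-phase nMSE
#' and silent-phase MAFA against the reference (both in % MVC; the MAFA
#' scale is the MVC, i.e. 100 in percent units).
#'
#' @param track result of [simulate_tracking_subject()].
#' @return Tidy tibble `metric`, `finger`, `value`.
#' @export
evaluate_tracking <- function(track) {
  ref <- as.matrix(track$reference$targets[fingers()]) * 100
  masks <- as.matrix(
    build_phase_masks(track$reference$labels,
                      track$reference$targets$t)[fingers()]
  )
  purrr::map_dfr(fingers(), function(fg) {
    est <- moving_average5(track$decoded[[fg]])
    tibble::tibble(
      metric = c("nmse", "mafa"), finger = fg,
      value = c(nmse(est, ref[, fg], masks[, fg]),
                mafa(est, !masks[, fg], 100))
    )
  })
}

#' Thresholding failure-mode experiment
#'
#' Calibrates the thresholding decoder and fits CSP-PE on a simulated
#' training run, then tests both on a fresh run from the same subject.
#' With the `"hard"` subject preset (ring-extension map overlapped onto
#' index flexion) the thresholding calibration flags the overlapped
#' movement as uncontrollable, while CSP-PE still decodes it through the
#' residual spatial differences.
#'
#' @param subject a [subject_params()] (typically `preset = "hard"`).
#' @param seed integer seed.
#' @param channels optional channel subset (default: full grid).
#' @param n_runs number of calibration runs of the training protocol to
#'   concatenate. One run holds only three contractions per movement,
#'   too little to average over the slow spatial drift of real activation
#'   patterns, so the calibration repeats the run (the protocol allows
#'   repeating contractions as needed).
#' @return A list: `thr` (the calibrated `thr_decoder`), `flagged`
#'   (uncontrollable movements), `csp_sensitivity` (per-class test
#'   sensitivity tibble for CSP-PE) and `confusion`.
#' @export
run_thr_failure_experiment <- function(subject, seed = 1, channels = NULL,
                                       n_runs = 3) {
  train_profile <- make_training_protocol()
  truth_one <- reference_classes(train_profile)
  xs <- list()
  truths <- list()
  for (r in seq_len(n_runs)) {
    sim <- simulate_session_features(train_profile, subject,
                                     seed = seed + r - 1,
                                     channels = channels)
    idx <- align_to_frames(sim$features$t, train_profile$targets$t)
    xs[[r]] <- sim$features
    truths[[r]] <- truth_one[idx, ]
  }
  features <- concat_features(xs)
  truth <- dplyr::bind_rows(truths)
  subsets <- suppressWarnings(
    suggest_channel_subsets(features, truth)
  )
  mvc_profile <- make_mvc_protocol()
  mvc_sim <- simulate_session_features(mvc_profile, subject,
                                       seed = seed + 100, channels = channels)
  mvc <- vapply(stats::setNames(nm = active_classes()), function(cl) {
    chs <- subsets[[cl]]
    if (is.null(chs) || length(chs) == 0) return(NA_real_)
    measure_mvc(mvc_sim$features, stats::setNames(list(chs), cl))[[1]]
  }, numeric(1))
  thr <- suppressWarnings(
    calibrate_thresholds(subsets, features, truth, mvc)
  )
  flagged <- thr$table$class[!thr$table$controllable]
  csp <- fit_csp_pe(features_by_class_of(features, truth),
                    levels_by_class_of(truth))
  test <- simulate_session_features(train_profile, subject,
                                    seed = seed + 200, channels = channels)
  truth_te <- truth_one[
    align_to_frames(test$features$t, train_profile$targets$t), ]
  pred <- predict_csp_pe(csp, feature_matrix(test$features))
  cm <- confusion_matrix(truth_te$class, pred$class)
  sens <- sensitivity_specificity(cm, drop_absent = TRUE)
  list(thr = thr, flagged = flagged, csp_sensitivity = sens, confusion = cm)
}

# stack feature streams end to end, shifting times to stay increasing
concat_features <- function(features_list) {
  if (length(features_list) == 1) return(features_list[[1]])
  offset <- 0
  shifted <- lapply(features_list, function(f) {
    f$t <- f$t + offset
    offset <<- max(f$t) + 0.1
    f
  })
  out <- dplyr::bind_rows(shifted)
  new_emg_features(out,
                   window_ms = attr(features_list[[1]], "window_ms"),
                   overlap = attr(features_list[[1]], "overlap"),
                   channel_ids = attr(features_list[[1]], "channel_ids"))
}
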