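#' Suggest per-movement hotspot channel subsets
#'
#' Automated surrogate for the experimenter's visual hotspot selection:
#' for every movement class, the `k` channels with the highest mean RMS
#' during that class's active frames. Channels that rank in the top `k`
#' for more than one class sit in the intersection of activity maps and
#' are assigned to no class; a class left with fewer than `k`
#' non-conflicting channels keeps the remainder, with a warning. Manual
#' subsets can always be supplied instead wherever a `subset_per_class`
#' argument is accepted.
#'
#' @param features an `emg_features` tibble.
#' @param truth frame-wise true classes (character vector aligned with the
#'   feature frames, or a tibble with a `class` column).
#' @param k subset size per class (4-6 in practice; default 5).
#' @return Named list, class -> integer grid channel ids (possibly fewer
#'   than `k`).
#' @export
suggest_channel_subsets <- function(features, truth, k = 5) {
  if (is.data.frame(truth)) truth <- truth$class
  x <- feature_matrix(features)
  stopifnot(length(truth) == nrow(x))
  ids <- attr(features, "channel_ids")
  classes <- intersect(active_classes(), unique(truth))
  rank_for <- function(cl) order(colMeans(x[truth == cl, , drop = FALSE]),
                                 decreasing = TRUE)
  ranks <- lapply(stats::setNames(classes, classes), rank_for)
  topk <- lapply(ranks, function(r) ids[r[seq_len(min(k, length(ids)))]])
  conflicted <- unique(unlist(topk)[duplicated(unlist(topk))])
  out <- lapply(stats::setNames(classes, classes), function(cl) {
    setdiff(topk[[cl]], conflicted)
  })
  short <- names(out)[lengths(out) < k]
  if (length(short) > 0) {
    warning("fewer than ", k, " non-conflicting channels for: ",
            paste(short, collapse = ", "), call. = FALSE)
  }
  out
}

#' Calibrate thresholds for the direct thresholding decoder
#'
#' For each movement class, scans 50 candidate thresholds between the
#' class subset's mean RMS during rest frames and its maximum subset mean,
#' and keeps the threshold that maximizes the frame-wise balanced accuracy
#' of the class's one-vs-rest detection (`subset mean > threshold`); within
#' the accuracy-maximizing plateau the middle candidate is chosen. A class
#' whose rest-frame subset mean is not below its active-frame subset mean
#' is degenerate: its threshold is set to the midpoint and it is flagged.
#' Finally the full competition rule ([predict_thr()]) is replayed on the
#' calibration frames; a class whose own frames are recovered less than
#' `min_recall` of the time is flagged uncontrollable -- the decoder
#' cannot elicit that movement, as happens when two activation maps
#' overlap.
#'
#' @param subset_per_class named list, class -> channel ids, e.g. from
#'   [suggest_channel_subsets()].
#' @param features calibration `emg_features`.
#' @param truth frame-wise true classes (vector or tibble with `class`).
#' @param mvc named numeric vector, class -> MVC scale (microvolts RMS),
#'   used for the proportional output.
#' @param n_grid number of scanned thresholds.
#' @param min_recall competition-recall floor below which a class is
#'   flagged uncontrollable.
#' @return An object of class `thr_decoder`: a tibble with one row per
#'   class (`class`, `channels`, `threshold`, `mvc`, `balanced_accuracy`,
#'   `recall`, `controllable`).
#' @export
calibrate_thresholds <- function(subset_per_class, features, truth, mvc,
                                 n_grid = 50, min_recall = 0.75) {
  if (is.data.frame(truth)) truth <- truth$class
  x <- feature_matrix(features)
  stopifnot(length(truth) == nrow(x))
  classes <- names(subset_per_class)
  check_movement_class(classes)
  rows <- list()
  for (cl in classes) {
    chs <- subset_per_class[[cl]]
    if (length(chs) == 0) {
      rows[[cl]] <- tibble::tibble(
        class = cl, channels = list(integer()), threshold = NA_real_,
        mvc = unname(mvc[cl]), balanced_accuracy = NA_real_,
        controllable = FALSE
      )
      warning("no channels for class ", cl, "; flagged uncontrollable",
              call. = FALSE)
      next
    }
    sm <- rowMeans(feature_matrix(filter_channels(features, chs)))
    pos <- truth == cl
    rest_mean <- mean(sm[truth == "REST"])
    act_mean <- mean(sm[pos])
    degenerate <- !is.finite(rest_mean) || !is.finite(act_mean) ||
      rest_mean >= act_mean
    grid <- seq(min(rest_mean, act_mean), max(sm), length.out = n_grid)
    bacc <- vapply(grid, function(thr) {
      det <- sm > thr
      (mean(det[pos]) + mean(!det[!pos])) / 2
    }, numeric(1))
    best <- which(bacc == max(bacc))
    # middle of the (first contiguous) accuracy-maximizing plateau
    run_end <- which(diff(best) > 1)[1]
    if (!is.na(run_end)) best <- best[seq_len(run_end)]
    thr <- grid[best[ceiling(length(best) / 2)]]
    if (degenerate) {
      thr <- (rest_mean + act_mean) / 2
      warning("degenerate calibration for class ", cl,
              " (rest mean >= active mean)", call. = FALSE)
    }
    rows[[cl]] <- tibble::tibble(
      class = cl, channels = list(chs), threshold = thr,
      mvc = unname(mvc[cl]), balanced_accuracy = max(bacc),
      controllable = !degenerate
    )
  }
  model <- structure(list(table = dplyr::bind_rows(rows)),
                     class = "thr_decoder")
  # competition check: can each movement actually be elicited?
  pred <- predict_thr(model, x)$class
  recall <- vapply(classes, function(cl) {
    n_cl <- sum(truth == cl)
    if (n_cl == 0) return(NA_real_)
    mean(pred[truth == cl] == cl)
  }, numeric(1))
  model$table$recall <- unname(recall[model$table$class])
  weak <- !is.na(recall) & recall < min_recall
  if (any(weak)) {
    warning("movement(s) flagged uncontrollable (calibration recall < ",
            min_recall, "): ", paste(classes[weak], collapse = ", "),
            call. = FALSE)
  }
  model$table$controllable <- model$table$controllable & !weak
  model
}

#' Decode activation frames by direct thresholding
#'
#' A movement is a candidate when the mean RMS over its channel subset
#' crosses its calibrated threshold; among candidates the one with the
#' highest subset mean wins (ties broken by canonical class order). The
#' proportional value is the winner's subset mean scaled to % MVC. With no
#' candidate the frame is rest, all zeros. The rule is evaluated per frame
#' on instantaneous subset means, uses no training statistics beyond
#' subsets, thresholds and MVC, and is deterministic.
#'
#' @param model a `thr_decoder` from [calibrate_thresholds()].
#' @param x named feature vector or frames x channels matrix with
#'   `ch_<id>` column names.
#' @param t optional frame times.
#' @return A `finger_activation` tibble; `level` in % MVC.
#' @export
predict_thr <- function(model, x, t = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  x <- as.matrix(x)
  tab <- model$table[!is.na(model$table$threshold), ]
  tab <- tab[order(match(tab$class, movement_classes())), ]
  n <- nrow(x)
  if (nrow(tab) == 0) return(activation_frames(rep("REST", n), numeric(n), t))
  means <- vapply(seq_len(nrow(tab)), function(i) {
    cols <- match(sprintf("ch_%03d", tab$channels[[i]]), colnames(x))
    if (anyNA(cols)) {
      stop("subset channels for ", tab$class[i], " not present in features",
           call. = FALSE)
    }
    rowMeans(x[, cols, drop = FALSE])
  }, numeric(n))
  means <- matrix(means, nrow = n)
  crossed <- sweep(means, 2, tab$threshold, `>`)
  cls <- rep("REST", n)
  level <- numeric(n)
  any_c <- rowSums(crossed) > 0
  if (any(any_c)) {
    masked <- ifelse(crossed, means, -Inf)
    win <- apply(masked[any_c, , drop = FALSE], 1, which.max)
    cls[any_c] <- tab$class[win]
    level[any_c] <- 100 *
      means[cbind(which(any_c), win)] / tab$mvc[win]
  }
  activation_frames(cls, pmax(level, 0), t)
}

#' @export
print.thr_decoder <- function(x, ...) {
  cat(sprintf("<thr_decoder> %d movements, %d uncontrollable\n",
              nrow(x$table), sum(!x$table$controllable)))
  invisible(x)
}
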