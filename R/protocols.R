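#' The twelve-task offline protocol table
#'
#' Each offline task combines a movement type (flexion `F`, extension `E`,
#' or alternating `F-E`), a force-profile shape (square `S` with 50 % duty
#' cycle, or triangular `T`), a force level (33 or 66 % MVC) and a cycle
#' length (4, 6, 8 or 12 s). Tasks 1-8 (single-direction) form the
#' training set; tasks 9-12 (alternating flexion-extension) form the test
#' set.
#'
#' @return A tibble with columns `task_id`, `movement`, `profile`,
#'   `level_pct`, `cycle_s` and `split`.
#' @export
offline_task_table <- function() {
  tibble::tibble(
    task_id = 1:12,
    movement = c(rep("F", 4), rep("E", 4), rep("F-E", 4)),
    profile = rep(c("S", "S", "T", "T"), 3),
    level_pct = rep(c(33, 66, 66, 66), 3),
    cycle_s = rep(c(6, 12, 8, 4), 3),
    split = rep(c("train", "train", "test"), c(4, 4, 4))
  )
}

profile_shape_value <- function(shape, tau, level, p) {
  switch(shape,
    square = ifelse(tau >= 0 & tau < p$cycle_s / 2, level, 0),
    triangle = {
      half <- p$cycle_s / 2
      up <- level * tau / half
      down <- level * (2 - tau / half)
      ifelse(tau < 0 | tau >= p$cycle_s, 0, pmin(up, down))
    },
    trapezoid = {
      r <- p$rise; pl <- p$plateau; f <- p$fall
      v <- ifelse(tau < r, level * tau / r,
             ifelse(tau < r + pl, level,
               ifelse(tau < r + pl + f, level * (r + pl + f - tau) / f, 0)))
      ifelse(tau < 0, 0, v)
    },
    stop("unknown profile shape ", shape, call. = FALSE)
  )
}

# events: tibble(class, t0, dur, shape, level, task_id, finger, params list)
rasterize_profile <- function(events, total_s, blocks = NULL, fs = 10) {
  n <- floor(total_s * fs + 1e-9)
  t <- (seq_len(n) - 1) / fs
  targets <- matrix(0, nrow = n, ncol = 4,
                    dimnames = list(NULL, fingers()))
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    idx <- which(t >= ev$t0 - 1e-9 & t < ev$t0 + ev$dur - 1e-9)
    if (length(idx) == 0) next
    v <- profile_shape_value(ev$shape, t[idx] - ev$t0, ev$level,
                             ev$params[[1]])
    targets[idx, class_finger(ev$class)] <-
      targets[idx, class_finger(ev$class)] + class_sign(ev$class) * v
  }
  labels <- label_intervals(events$class, events$t0, events$t0 + events$dur,
                            level = events$level, task_id = events$task_id,
                            finger = events$finger)
  structure(
    list(
      targets = tibble::as_tibble(cbind(data.frame(t = t),
                                        as.data.frame(targets))),
      labels = labels,
      blocks = blocks,
      fs = fs
    ),
    class = "reference_profile"
  )
}

#' @export
print.reference_profile <- function(x, ...) {
  cat(sprintf("<reference_profile> %.1f s @ %g Hz, %d labelled activations\n",
              nrow(x$targets) / x$fs, x$fs, nrow(x$labels)))
  invisible(x)
}

#' Offline protocol generator
#'
#' Builds the reference profile of the twelve-task offline protocol (see
#' [offline_task_table()]): each task is performed by each finger, with the
#' stated cycle count per task-finger block and short rest periods between
#' blocks. For alternating (`F-E`) tasks, odd repetitions are flexion
#' cycles and even repetitions extension cycles. Targets are stored as a
#' signed fraction of MVC (flexion positive).
#'
#' @param n_reps repetitions (cycles) per task-finger block (protocol
#'   default 10).
#' @param task_fingers fingers performing each task (default all four).
#' @param seed optional integer; when given, the finger order within each
#'   task is randomized reproducibly, as in the protocol.
#' @param rest_s rest between task-finger blocks, seconds.
#' @param lead_in_s initial rest, seconds.
#' @return A `reference_profile`: a list with `targets` (tibble `t` +
#'   one signed column per finger, 10 Hz), `labels` (one row per cycle
#'   active span) and `blocks` (task-finger block intervals for the
#'   train/test split).
#' @export
make_offline_protocol <- function(n_reps = 10, task_fingers = fingers(),
                                  seed = NULL, rest_s = 3, lead_in_s = 2) {
  tab <- offline_task_table()
  events <- list()
  blocks <- list()
  t_cur <- 0
  for (i in seq_len(nrow(tab))) {
    task <- tab[i, ]
    fs_order <- task_fingers
    if (!is.null(seed)) {
      fs_order <- with_local_seed(seed * 131L + task$task_id,
                                  sample(task_fingers))
    }
    for (fg in fs_order) {
      block_start <- t_cur
      t_cur <- t_cur + if (length(blocks) == 0) lead_in_s else rest_s
      for (rep_i in seq_len(n_reps)) {
        dir <- switch(task$movement, F = "F", E = "E",
                      `F-E` = if (rep_i %% 2 == 1) "F" else "E")
        cls <- finger_class(fg, dir)
        shape <- if (task$profile == "S") "square" else "triangle"
        dur <- if (shape == "square") task$cycle_s / 2 else task$cycle_s
        events[[length(events) + 1]] <- tibble::tibble(
          class = cls, t0 = t_cur, dur = dur, shape = shape,
          level = task$level_pct / 100, task_id = task$task_id, finger = fg,
          params = list(list(cycle_s = task$cycle_s))
        )
        t_cur <- t_cur + task$cycle_s
      }
      blocks[[length(blocks) + 1]] <- tibble::tibble(
        task_id = task$task_id, finger = fg,
        t_start = block_start, t_end = t_cur
      )
    }
  }
  total <- t_cur + rest_s
  blk <- dplyr::bind_rows(blocks)
  blk$t_end <- c(blk$t_start[-1], total)
  rasterize_profile(dplyr::bind_rows(events), total_s = total, blocks = blk)
}

#' Training protocol generator (trapezoidal tracking)
#'
#' For every movement class, trapezoidal activation profiles with 2 s rise,
#' 3 s plateau and 2 s fall at plateaus of 30, 60 and 90 % MVC, separated
#' by 5 s rest intervals: each contraction lasts 7 s and the run comprises
#' 8 movements x 3 levels = 24 contractions.
#'
#' @param classes movement classes to include (default all eight non-rest
#'   classes).
#' @param levels plateau levels as fractions of MVC.
#' @param rise_s,plateau_s,fall_s trapezoid timing in seconds.
#' @param rest_s rest between contractions, seconds.
#' @param lead_in_s initial rest, seconds.
#' @return A `reference_profile` (targets in signed fraction of MVC).
#' @export
make_training_protocol <- function(classes = active_classes(),
                                   levels = c(0.30, 0.60, 0.90),
                                   rise_s = 2, plateau_s = 3, fall_s = 2,
                                   rest_s = 5, lead_in_s = 2) {
  check_movement_class(classes)
  events <- list()
  t_cur <- lead_in_s
  dur <- rise_s + plateau_s + fall_s
  for (cls in classes) {
    for (lev in levels) {
      events[[length(events) + 1]] <- tibble::tibble(
        class = cls, t0 = t_cur, dur = dur, shape = "trapezoid",
        level = lev, task_id = NA_integer_, finger = class_finger(cls),
        params = list(list(rise = rise_s, plateau = plateau_s, fall = fall_s))
      )
      t_cur <- t_cur + dur + rest_s
    }
  }
  rasterize_profile(dplyr::bind_rows(events), total_s = t_cur + 1)
}

#' Maximal-contraction protocol generator
#'
#' Short sustained maximal contractions (activation 1.0, i.e. 100 % MVC)
#' for each movement class, used by [measure_mvc()] to calibrate the MVC
#' scale of each movement.
#'
#' @inheritParams make_training_protocol
#' @param hold_s plateau duration at maximal activation, seconds.
#' @return A `reference_profile`.
#' @export
make_mvc_protocol <- function(classes = active_classes(), hold_s = 3,
                              rest_s = 3, lead_in_s = 2) {
  make_training_protocol(classes = classes, levels = 1.0, rise_s = 0.5,
                         plateau_s = hold_s, fall_s = 0.5, rest_s = rest_s,
                         lead_in_s = lead_in_s)
}

#' Online tracking reference generator
#'
#' The online test reference comprises 16 individual finger activations
#' (4 per finger: two flexion, two extension; for each direction one slow
#' and one fast cycle) in random order. Each activation ramps from 0 to
#' 80 % MVC in 4 s (slow) or 2 s (fast), holds the plateau for 3 s, and
#' ramps back down at the same speed.
#'
#' @param seed integer seed determining the activation order; the same seed
#'   gives an identical reference, different seeds permute the order only.
#' @param plateau_s plateau duration, seconds.
#' @param level plateau level as a fraction of MVC (default 0.8).
#' @param rest_s rest between activations, seconds.
#' @param lead_in_s initial rest, seconds.
#' @return A `reference_profile`.
#' @export
make_online_reference <- function(seed = 1, plateau_s = 3, level = 0.8,
                                  rest_s = 3, lead_in_s = 2) {
  combos <- tidyr::expand_grid(
    finger = fingers(), direction = c("F", "E"), ramp_s = c(4, 2)
  )
  combos <- with_local_seed(seed, combos[sample(nrow(combos)), ])
  events <- list()
  t_cur <- lead_in_s
  for (i in seq_len(nrow(combos))) {
    cb <- combos[i, ]
    dur <- 2 * cb$ramp_s + plateau_s
    events[[length(events) + 1]] <- tibble::tibble(
      class = finger_class(cb$finger, cb$direction), t0 = t_cur, dur = dur,
      shape = "trapezoid", level = level, task_id = NA_integer_,
      finger = cb$finger,
      params = list(list(rise = cb$ramp_s, plateau = plateau_s,
                         fall = cb$ramp_s))
    )
    t_cur <- t_cur + dur + rest_s
  }
  rasterize_profile(dplyr::bind_rows(events), total_s = t_cur + 1)
}

#' Ground-truth class and level per reference frame
#'
#' Derives the frame-wise true movement class from a reference profile: the
#' finger with the largest absolute target, provided it exceeds the
#' activation threshold (default 10 % MVC, matching the force-cycle
#' detection threshold); otherwise `REST`.
#'
#' @param profile a `reference_profile`.
#' @param threshold activation threshold (fraction of MVC) below which a
#'   frame counts as rest.
#' @return A tibble with `t`, `class` and `level` (absolute target of the
#'   active finger, fraction of MVC).
#' @export
reference_classes <- function(profile, threshold = 0.1) {
  tg <- as.matrix(profile$targets[fingers()])
  amax <- apply(abs(tg), 1, max)
  which_f <- apply(abs(tg), 1, which.max)
  sign_f <- sign(tg[cbind(seq_len(nrow(tg)), which_f)])
  cls <- ifelse(
    amax < threshold, "REST",
    finger_class(fingers()[which_f], ifelse(sign_f >= 0, "F", "E"))
  )
  tibble::tibble(t = profile$targets$t, class = cls,
                 level = ifelse(cls == "REST", 0, amax))
}

# Run code under a temporary RNG state seeded with `seed`.
with_local_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}
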