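#' Detect force cycles
#'
#' A contraction cycle starts when the magnitude of the finger's force
#' crosses 10 % of the maximum force exerted with that finger (by default
#' taken across the supplied recording; pass `f_max` to use the maximum
#' across all tasks) and ends when the force returns below that
#' subthreshold level. The cycle's plateau midpoint (force value at the
#' temporal centre of the suprathreshold segment) and vertex (peak) are
#' recorded for the outlier rules.
#'
#' @param force a [force_recording()].
#' @param finger finger name.
#' @param f_max maximum force for the finger across all tasks (N); default
#'   `max(abs(force))` of the supplied recording.
#' @param threshold_frac crossing threshold as a fraction of `f_max`.
#' @return A `cycle_set` tibble: one row per cycle with `cycle`, `finger`,
#'   `direction` (+1 flexion / -1 extension), `t_start`, `t_end`,
#'   `duration`, `amplitude_mid` and `amplitude_peak` (N, magnitudes).
#'   Zero rows when the force never exceeds the threshold.
#' @export
detect_cycles <- function(force, finger, f_max = NULL, threshold_frac = 0.1) {
  stopifnot(finger %in% fingers())
  f <- force[[finger]]
  t <- force$t
  if (is.null(f_max)) f_max <- max(abs(f))
  thr <- threshold_frac * f_max
  above <- abs(f) > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  rows <- lapply(keep, function(i) {
    lo <- starts[i]
    hi <- ends[i]
    seg <- f[lo:hi]
    mid <- seg[ceiling((length(seg) + 1) / 2)]
    peak <- seg[which.max(abs(seg))]
    tibble::tibble(
      finger = finger,
      direction = sign(peak),
      t_start = t[lo], t_end = t[hi] + (t[2] - t[1]),
      duration = t[hi] - t[lo] + (t[2] - t[1]),
      amplitude_mid = abs(mid), amplitude_peak = abs(peak)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(finger = character(), direction = double(),
                          t_start = double(), t_end = double(),
                          duration = double(), amplitude_mid = double(),
                          amplitude_peak = double())
  }
  out <- tibble::add_column(out, cycle = seq_len(nrow(out)), .before = 1)
  class(out) <- c("cycle_set", class(out))
  out
}

#' Reject atypical force cycles
#'
#' Two rules mark occasional atypical contractions as outliers:
#' \describe{
#'   \item{duration}{a cycle whose length deviates from the mean cycle
#'     length by more than 2.58 population standard deviations is
#'     rejected;}
#'   \item{amplitude}{a regression line is fitted over cycle index to the
#'     plateau midpoints (square profiles) or vertices (triangle
#'     profiles); cycles whose absolute residual exceeds 1.96 times the
#'     mean squared error of that fit are rejected.}
#' }
#' When every cycle is identical both dispersion statistics are zero and
#' nothing is rejected. With fewer than 3 cycles all cycles are kept, with
#' a warning. A cycle caught by both rules is reported under the duration
#' cause.
#'
#' @param cycles a `cycle_set` from [detect_cycles()].
#' @param profile_type `"square"` or `"triangle"`.
#' @return An `outlier_report` tibble: per cycle `kept`, `cause`
#'   (`"duration"`, `"amplitude"` or `NA`), `duration_dev` and
#'   `amplitude_residual`; attributes `t_mean`, `t_sd` and `mse` hold the
#'   statistics used.
#' @export
reject_outliers <- function(cycles, profile_type = c("square", "triangle")) {
  profile_type <- match.arg(profile_type)
  n <- nrow(cycles)
  if (n < 3) {
    warning("fewer than 3 cycles; keeping all", call. = FALSE)
    out <- tibble::tibble(cycle = cycles$cycle, kept = rep(TRUE, n),
                          cause = rep(NA_character_, n),
                          duration_dev = rep(NA_real_, n),
                          amplitude_residual = rep(NA_real_, n))
    class(out) <- c("outlier_report", class(out))
    return(out)
  }
  t_mean <- mean(cycles$duration)
  t_sd <- sqrt(mean((cycles$duration - t_mean)^2))   # population sd
  dur_dev <- abs(cycles$duration - t_mean)
  # numeric-noise floor: identical cycles must never be rejected
  tol_t <- 1e-9 * (1 + abs(t_mean))
  dur_out <- dur_dev > pmax(2.58 * t_sd, tol_t)
  amp <- if (profile_type == "square") cycles$amplitude_mid else
    cycles$amplitude_peak
  fit <- stats::lm(amp ~ seq_along(amp))
  resid <- as.vector(stats::residuals(fit))
  tol_a <- 1e-9 * (1 + mean(abs(amp)))
  resid[abs(resid) < tol_a] <- 0
  mse <- mean(resid^2)
  amp_out <- abs(resid) > pmax(1.96 * mse, tol_a)
  cause <- ifelse(dur_out, "duration",
                  ifelse(amp_out, "amplitude", NA_character_))
  out <- tibble::tibble(
    cycle = cycles$cycle,
    kept = !(dur_out | amp_out),
    cause = cause,
    duration_dev = dur_dev,
    amplitude_residual = resid
  )
  attr(out, "t_mean") <- t_mean
  attr(out, "t_sd") <- t_sd
  attr(out, "mse") <- mse
  class(out) <- c("outlier_report", class(out))
  out
}

#' Build per-finger active/silent phase masks
#'
#' A finger is active exactly where a non-rest label interval of that
#' finger covers the frame (`t_start <= t < t_end`); everywhere else it is
#' silent. Active and silent partition the evaluated span. Overlapping
#' intervals for the same finger are an error.
#'
#' @param labels a label tibble (see [label_intervals()]); rows with class
#'   `"REST"` are ignored.
#' @param time_base numeric vector of frame times (seconds), e.g. the 10 Hz
#'   reference grid.
#' @return A tibble with `t` and one logical column per finger (`TRUE` =
#'   active).
#' @export
build_phase_masks <- function(labels, time_base) {
  m <- matrix(FALSE, nrow = length(time_base), ncol = 4,
              dimnames = list(NULL, fingers()))
  lab <- labels[labels$class != "REST", , drop = FALSE]
  if (nrow(lab) > 0) {
    lab$mask_finger <- class_finger(lab$class)
    for (fg in unique(lab$mask_finger)) {
      sub <- lab[lab$mask_finger == fg, ]
      sub <- sub[order(sub$t_start), ]
      if (nrow(sub) > 1 &&
          any(sub$t_start[-1] < sub$t_end[-nrow(sub)] - 1e-9)) {
        stop("overlapping label intervals for finger ", fg, call. = FALSE)
      }
      for (i in seq_len(nrow(sub))) {
        m[time_base >= sub$t_start[i] - 1e-9 &
            time_base < sub$t_end[i] - 1e-9, fg] <- TRUE
      }
    }
  }
  tibble::as_tibble(cbind(data.frame(t = time_base), as.data.frame(m)))
}

#' Train/test split of the offline protocol
#'
#' Tasks with only flexion or only extension contractions (ids 1-8) form
#' the training set; tasks with both contraction types (ids 9-12) form the
#' test set. A session missing some test tasks still splits, with a
#' warning; a task id outside 1-12 is an error.
#'
#' @param labels a label tibble with a `task_id` column, or an
#'   [emg_session()].
#' @return A list with integer vectors `train` and `test`.
#' @export
build_split <- function(labels) {
  if (inherits(labels, "emg_session")) labels <- labels$labels
  ids <- sort(unique(labels$task_id[!is.na(labels$task_id)]))
  if (length(ids) == 0) stop("no task ids in labels", call. = FALSE)
  bad <- ids[!ids %in% 1:12]
  if (length(bad) > 0) {
    stop("unknown task id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(1:12, ids)
  if (length(missing) > 0) {
    warning("session is missing task(s) ", paste(missing, collapse = ", "),
            call. = FALSE)
  }
  list(train = ids[ids <= 8], test = ids[ids >= 9])
}
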