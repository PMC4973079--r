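# Window/sample index arithmetic. Sample i (1-based) carries time (i-1)/fs;
# the half-open time interval [t0, t1) maps to samples lo..hi. An epsilon
# guards against floating-point boundary error (fs * step is non-integer:
# 2048 Hz * 0.1 s = 204.8 samples).
sample_range <- function(fs, t0, t1) {
  lo <- ceiling(t0 * fs + 1 - 1e-9)
  hi <- ceiling(t1 * fs + 1 - 1e-9) - 1
  as.integer(c(max(lo, 1L), hi))
}

#' Windowed RMS feature extraction
#'
#' Computes the per-channel root mean square over sliding windows. With the
#' defaults (200 ms window, 50 % overlap) the output is a 10 Hz feature
#' stream: one vector every 100 ms. Frames are anchored to the nominal
#' step grid rather than integer sample strides -- frame k covers the
#' samples in `[k*step - window, k*step)` -- so the feature stream stays
#' exactly synchronized with the 10 Hz force recordings even though
#' 0.1 s x 2048 Hz is a non-integer number of samples. The last partial
#' window is dropped: the frame count is
#' `floor((T - window)/step) + 1` for a recording of duration `T`.
#'
#' @param emg an [emg_recording()].
#' @param window_ms window length in milliseconds (default 200).
#' @param overlap fractional overlap between consecutive windows in
#'   `[0, 1)` (default 0.5).
#' @return A tibble of class `emg_features` with column `t` (window end
#'   time, seconds) and one `ch_<id>` column per channel (microvolts RMS),
#'   carrying attributes `window_ms`, `overlap` and `channel_ids`.
#' @examples
#' emg <- emg_recording(matrix(rnorm(2048 * 4), ncol = 4),
#'                      geometry = grid_geometry(2, 2))
#' extract_rms_features(emg)
#' @export
extract_rms_features <- function(emg, window_ms = 200, overlap = 0.5) {
  stopifnot(inherits(emg, "emg_recording"), window_ms > 0,
            overlap >= 0, overlap < 1)
  win_s <- window_ms / 1000
  step_s <- win_s * (1 - overlap)
  if (step_s <= 0) stop("non-positive window step", call. = FALSE)
  n <- nrow(emg$samples)
  dur <- n / emg$fs
  if (dur < win_s) stop("window longer than recording", call. = FALSE)
  k_min <- ceiling(win_s / step_s - 1e-9)
  k_max <- floor(dur / step_s + 1e-9)
  ks <- seq.int(k_min, k_max)
  t_frames <- ks * step_s
  lo <- ceiling((t_frames - win_s) * emg$fs + 1 - 1e-9)
  hi <- ceiling(t_frames * emg$fs + 1 - 1e-9) - 1
  lo <- pmax(lo, 1L)
  counts <- hi - lo + 1
  nc <- ncol(emg$samples)
  out <- matrix(NA_real_, nrow = length(ks), ncol = nc)
  # channel-chunked cumulative sums of squares keep memory bounded
  chunk <- max(1L, min(nc, floor(4e7 / max(n, 1))))
  for (c0 in seq(1L, nc, by = chunk)) {
    cols <- c0:min(c0 + chunk - 1L, nc)
    cs <- apply(emg$samples[, cols, drop = FALSE]^2, 2, cumsum)
    cs <- rbind(0, cs)
    out[, cols] <- sqrt((cs[hi + 1L, , drop = FALSE] -
                           cs[lo, , drop = FALSE]) / counts)
  }
  colnames(out) <- sprintf("ch_%03d", emg$channel_ids)
  res <- tibble::as_tibble(as.data.frame(out))
  res <- tibble::add_column(res, t = emg$start_time + t_frames, .before = 1)
  new_emg_features(res, window_ms = window_ms, overlap = overlap,
                   channel_ids = emg$channel_ids)
}

new_emg_features <- function(tbl, window_ms, overlap, channel_ids) {
  attr(tbl, "window_ms") <- window_ms
  attr(tbl, "overlap") <- overlap
  attr(tbl, "channel_ids") <- as.integer(channel_ids)
  class(tbl) <- unique(c("emg_features", class(tbl)))
  tbl
}

#' Feature matrix and channel selection helpers
#'
#' `feature_matrix()` strips the time column and returns the frames x
#' channels numeric matrix. `filter_channels()` restricts a feature stream
#' to a channel subset (by grid channel id or a [select_regular_subset()]
#' result).
#'
#' @param features an `emg_features` tibble from [extract_rms_features()].
#' @return `feature_matrix()`: numeric matrix; `filter_channels()`: an
#'   `emg_features` tibble.
#' @export
feature_matrix <- function(features) {
  m <- as.matrix(features[setdiff(names(features), "t")])
  storage.mode(m) <- "double"
  m
}

#' @rdname feature_matrix
#' @param channels integer grid channel ids, or a `subset_spec`.
#' @export
filter_channels <- function(features, channels) {
  if (inherits(channels, "subset_spec")) channels <- channels$channels
  channels <- as.integer(channels)
  have <- attr(features, "channel_ids")
  if (!all(channels %in% have)) {
    stop("requested channels not present in the feature stream", call. = FALSE)
  }
  keep <- c("t", sprintf("ch_%03d", channels))
  new_emg_features(features[keep],
                   window_ms = attr(features, "window_ms"),
                   overlap = attr(features, "overlap"),
                   channel_ids = channels)
}

#' Measure MVC from maximal-contraction features
#'
#' The maximum voluntary contraction scale of a movement class is the
#' maximum over frames of the mean RMS across that class's channel subset,
#' computed on features recorded during maximal contractions.
#'
#' @param features an `emg_features` tibble.
#' @param subset_per_class named list, movement class -> integer channel
#'   ids (typically 4-6 hotspot channels per class).
#' @return Named numeric vector, class -> MVC scale (microvolts RMS).
#' @export
measure_mvc <- function(features, subset_per_class) {
  if (nrow(features) == 0) stop("no feature frames", call. = FALSE)
  check_movement_class(names(subset_per_class))
  vapply(subset_per_class, function(chs) {
    if (length(chs) == 0) stop("empty channel subset", call. = FALSE)
    sub <- feature_matrix(filter_channels(features, chs))
    max(rowMeans(sub))
  }, numeric(1))
}

#' Five-sample moving-average smoothing
#'
#' Output smoothing applied to decoded activation traces before computing
#' tracking metrics: each output sample is the mean of the current and the
#' next four samples of the input; tail windows are truncated to the
#' samples that remain.
#'
#' @param trace numeric vector (length >= 1).
#' @return Smoothed numeric vector of the same length.
#' @examples
#' moving_average5(c(1, 0, 0, 0, 0, 0))
#' @export
moving_average5 <- function(trace) {
  n <- length(trace)
  stopifnot(n >= 1)
  cs <- c(0, cumsum(trace))
  hi <- pmin(seq_len(n) + 4, n)
  (cs[hi + 1] - cs[seq_len(n)]) / (hi - seq_len(n) + 1)
}
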