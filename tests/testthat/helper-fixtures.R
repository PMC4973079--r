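# Shared small fixtures, built in code at test time.

# feature matrix whose second-moment matrix is exactly `m` (diagonal)
diag_moment_features <- function(d1, d2) {
  rbind(c(sqrt(2 * d1), 0), c(-sqrt(2 * d1), 0),
        c(0, sqrt(2 * d2)), c(0, -sqrt(2 * d2)))
}

# tiny two-channel recording with constant amplitude per channel
constant_emg <- function(amps, seconds = 1, fs = 2048) {
  n <- round(seconds * fs)
  emg_recording(matrix(rep(amps, each = n), nrow = n),
                fs = fs,
                geometry = grid_geometry(1, length(amps)))
}

# small synthetic training set: two well-separated classes + rest on a
# 2 x 2 grid, RMS-like non-negative features
toy_features_by_class <- function(n = 120, seed = 42) {
  withr::with_seed(seed, {
    list(
      IF = cbind(abs(rnorm(n, 40, 4)), abs(rnorm(n, 8, 2)),
                 abs(rnorm(n, 6, 2)), abs(rnorm(n, 5, 1))),
      RE = cbind(abs(rnorm(n, 7, 2)), abs(rnorm(n, 42, 4)),
                 abs(rnorm(n, 5, 1)), abs(rnorm(n, 6, 2))),
      REST = cbind(abs(rnorm(n, 5, 1)), abs(rnorm(n, 5, 1)),
                   abs(rnorm(n, 5, 1)), abs(rnorm(n, 5, 1)))
    )
  })
}

# wrap a plain matrix as an emg_features tibble
as_features <- function(x, channel_ids = seq_len(ncol(x)), t = NULL) {
  colnames(x) <- sprintf("ch_%03d", channel_ids)
  tbl <- tibble::as_tibble(as.data.frame(x))
  if (is.null(t)) t <- seq_len(nrow(x)) / 10
  tbl <- tibble::add_column(tbl, t = t, .before = 1)
  fingerdecode:::new_emg_features(tbl, window_ms = 200, overlap = 0.5,
                                  channel_ids = channel_ids)
}
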