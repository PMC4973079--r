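#' Multichannel EMG recording
#'
#' Container for raw monopolar EMG samples. Samples are stored as a
#' frames x channels matrix in microvolts; the sampling rate is nominally
#' 2048 Hz. `channel_ids` identifies which channels of the grid the columns
#' correspond to (by default, all of them in row-major order).
#'
#' @param samples numeric matrix, frames x channels, in microvolts.
#' @param fs sampling rate in Hz (> 0).
#' @param geometry a [grid_geometry()].
#' @param channel_ids integer vector mapping columns of `samples` to grid
#'   channel indices. Defaults to the full grid.
#' @param start_time recording start in seconds (time is seconds from
#'   session start throughout the package).
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(samples, fs = 2048, geometry = grid_geometry(),
                          channel_ids = NULL, start_time = 0) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (is.null(channel_ids)) channel_ids <- seq_len(n_channels(geometry))
  channel_ids <- as.integer(channel_ids)
  if (ncol(samples) != length(channel_ids)) {
    stop("channel-count mismatch: samples have ", ncol(samples),
         " columns but ", length(channel_ids), " channel ids", call. = FALSE)
  }
  if (any(channel_ids < 1 | channel_ids > n_channels(geometry))) {
    stop("channel ids outside the grid", call. = FALSE)
  }
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop("NaN or non-finite values in EMG payload", call. = FALSE)
  }
  stopifnot(length(fs) == 1, fs > 0)
  structure(
    list(samples = samples, fs = as.numeric(fs), geometry = geometry,
         channel_ids = channel_ids, start_time = as.numeric(start_time)),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d frames x %d channels @ %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, nrow(x$samples) / x$fs))
  invisible(x)
}

#' Per-finger isometric force recording
#'
#' Forces are stored as a tibble with a time column `t` (seconds) and one
#' signed column per finger (N; flexion positive, extension negative),
#' sampled nominally at 10 Hz. Values are clipped to the +/- 20 N sensor
#' range at acquisition/simulation time.
#'
#' @param forces matrix or data frame, frames x 4 fingers, in newtons.
#' @param fs sampling rate in Hz (default 10).
#' @param t optional time stamps; defaults to a regular grid at `fs`.
#' @return A tibble of class `force_recording` with attribute `fs`.
#' @export
force_recording <- function(forces, fs = 10, t = NULL) {
  forces <- as.data.frame(forces)
  stopifnot(ncol(forces) %in% c(4, 5))
  if (ncol(forces) == 5) {
    t <- forces[[1]]
    forces <- forces[-1]
  }
  names(forces) <- fingers()
  if (is.null(t)) t <- (seq_len(nrow(forces)) - 1) / fs
  out <- tibble::as_tibble(cbind(t = t, forces))
  if (anyNA(out)) stop("NaN values in force payload", call. = FALSE)
  if (max(abs(as.matrix(forces)), 0) > 20 + 1e-9) {
    stop("force exceeds the +/- 20 N sensor range; clip before storing",
         call. = FALSE)
  }
  attr(out, "fs") <- as.numeric(fs)
  class(out) <- c("force_recording", class(out))
  out
}

#' Label intervals
#'
#' @param class movement class codes (see [movement_classes()]).
#' @param t_start,t_end interval bounds in seconds (`t_start < t_end`).
#' @param level target level as a fraction of MVC (online) or a force
#'   context value; stored as given.
#' @param task_id,finger optional protocol annotations.
#' @return A tibble with one row per labelled interval.
#' @export
label_intervals <- function(class = character(), t_start = numeric(),
                            t_end = numeric(), level = NA_real_,
                            task_id = NA_integer_, finger = NA_character_) {
  check_movement_class(class)
  if (any(t_start >= t_end)) stop("label intervals need t_start < t_end", call. = FALSE)
  out <- tibble::tibble(
    class = class, t_start = as.numeric(t_start), t_end = as.numeric(t_end),
    level = as.numeric(level), task_id = as.integer(task_id),
    finger = as.character(finger)
  )
  check_label_overlap(out)
  out
}

check_label_overlap <- function(labels) {
  if (nrow(labels) < 2) return(invisible(labels))
  lab <- labels[order(labels$t_start), ]
  if (any(lab$t_start[-1] < lab$t_end[-nrow(lab)] - 1e-9)) {
    stop("label intervals overlap", call. = FALSE)
  }
  invisible(labels)
}

#' EMG + force session
#'
#' Bundles an EMG recording, an optional force recording, label intervals,
#' an optional per-class MVC map (activation scale in microvolts RMS) and
#' free-form metadata. Streams are aligned by their time stamps (seconds
#' from session start), not by sample index.
#'
#' @param emg an [emg_recording()].
#' @param force a [force_recording()] or `NULL`.
#' @param labels a label tibble as from [label_intervals()].
#' @param mvc named numeric vector, movement class -> MVC scale; values must
#'   be positive for non-rest classes.
#' @param metadata list of free-form metadata.
#' @return An object of class `emg_session`.
#' @export
emg_session <- function(emg, force = NULL, labels = label_intervals(character()),
                        mvc = NULL, metadata = list()) {
  stopifnot(inherits(emg, "emg_recording"))
  span <- emg$start_time + nrow(emg$samples) / emg$fs
  if (nrow(labels) > 0) {
    check_movement_class(labels$class)
    if (any(labels$t_end > span + 1e-6)) {
      stop("label intervals extend beyond the recording span", call. = FALSE)
    }
  }
  if (!is.null(mvc)) {
    check_movement_class(names(mvc))
    if (any(mvc[names(mvc) != "REST"] <= 0)) {
      stop("MVC values must be positive for non-rest classes", call. = FALSE)
    }
  }
  structure(
    list(emg = emg, force = force, labels = labels, mvc = mvc,
         metadata = metadata),
    class = "emg_session"
  )
}

#' @export
print.emg_session <- function(x, ...) {
  cat("<emg_session>\n")
  print(x$emg)
  cat(sprintf("  force: %s; labels: %d; mvc: %s\n",
              if (is.null(x$force)) "none" else paste0(nrow(x$force), " frames"),
              nrow(x$labels),
              if (is.null(x$mvc)) "none" else paste0(length(x$mvc), " classes")))
  invisible(x)
}

#' Write a session to disk
#'
#' A session directory holds `manifest.json` (rates, grid, units, MVC map,
#' metadata), `emg.f32` (little-endian 32-bit floats, row-major frames x
#' channels), `force.csv` (`t,index,middle,ring,little`) and `labels.csv`
#' (`class,t_start,t_end,level,task_id,finger`). The byte layout is
#' deterministic for a fixed input.
#'
#' @param session an [emg_session()].
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "emg_session"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create session directory ", path, call. = FALSE)
  emg <- session$emg
  manifest <- list(
    format = "fingerdecode-session",
    version = 1L,
    fs_emg = emg$fs,
    fs_force = if (is.null(session$force)) NULL else attr(session$force, "fs"),
    n_frames = nrow(emg$samples),
    start_time = emg$start_time,
    grid = list(rows = emg$geometry$n_rows, cols = emg$geometry$n_cols,
                pitch_mm = emg$geometry$pitch_mm),
    channel_ids = emg$channel_ids,
    units = list(emg = "uV", force = "N", time = "s"),
    mvc = as.list(session$mvc),
    metadata = session$metadata
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(file.path(path, "emg.f32"), "wb")
  on.exit(close(con), add = TRUE)
  # row-major frames x channels: write the transpose column-wise
  writeBin(as.vector(t(emg$samples)), con, size = 4, endian = "little")
  if (!is.null(session$force)) {
    readr::write_csv(fixed_decimals(tibble::as_tibble(as.data.frame(session$force))),
                     file.path(path, "force.csv"), progress = FALSE)
  }
  lab <- session$labels
  if (nrow(lab) == 0) {
    lab <- tibble::tibble(class = character(), t_start = double(),
                          t_end = double(), level = double(),
                          task_id = integer(), finger = character())
  }
  readr::write_csv(fixed_decimals(lab), file.path(path, "labels.csv"),
                   progress = FALSE)
  invisible(path)
}

# fixed 9-decimal formatting for CSV payloads: parsing and re-writing the
# file reproduces identical bytes, and 9 decimals is far below sensor
# resolution, so the representation is lossless in practice
fixed_decimals <- function(df, digits = 9) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) {
      v <- sprintf(paste0("%.", digits, "f"), df[[nm]])
      v[is.na(df[[nm]])] <- NA_character_
      df[[nm]] <- v
    }
  }
  df
}

#' Read a session from disk
#'
#' Counterpart of [write_session()]. Validates the payload against the
#' manifest: a channel-count mismatch between the declared grid/channel list
#' and the `emg.f32` payload, a missing file, or NaN values each raise a
#' distinct diagnostic.
#'
#' @param path session directory.
#' @return An [emg_session()].
#' @export
read_session <- function(path) {
  need <- file.path(path, c("manifest.json", "emg.f32", "labels.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0) {
    stop("missing session file(s): ", paste(basename(missing), collapse = ", "),
         call. = FALSE)
  }
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  geometry <- grid_geometry(manifest$grid$rows, manifest$grid$cols,
                            manifest$grid$pitch_mm)
  channel_ids <- as.integer(manifest$channel_ids)
  n_ch <- length(channel_ids)
  raw <- readBin(file.path(path, "emg.f32"), what = "numeric", size = 4,
                 n = file.size(file.path(path, "emg.f32")) / 4 + 8,
                 endian = "little")
  if (length(raw) != manifest$n_frames * n_ch) {
    stop("channel-count mismatch: manifest declares ", manifest$n_frames,
         " frames x ", n_ch, " channels but emg.f32 holds ", length(raw),
         " values", call. = FALSE)
  }
  if (anyNA(raw) || any(!is.finite(raw))) {
    stop("NaN or non-finite values in EMG payload", call. = FALSE)
  }
  samples <- matrix(raw, nrow = manifest$n_frames, ncol = n_ch, byrow = TRUE)
  emg <- emg_recording(samples, fs = manifest$fs_emg, geometry = geometry,
                       channel_ids = channel_ids,
                       start_time = manifest$start_time %||% 0)
  force <- NULL
  if (file.exists(file.path(path, "force.csv"))) {
    ftab <- readr::read_csv(file.path(path, "force.csv"), progress = FALSE,
                            show_col_types = FALSE)
    force <- force_recording(ftab, fs = manifest$fs_force %||% 10)
  }
  lab <- readr::read_csv(file.path(path, "labels.csv"), progress = FALSE,
                         show_col_types = FALSE,
                         col_types = readr::cols(
                           class = readr::col_character(),
                           t_start = readr::col_double(),
                           t_end = readr::col_double(),
                           level = readr::col_double(),
                           task_id = readr::col_integer(),
                           finger = readr::col_character()
                         ))
  mvc <- NULL
  if (length(manifest$mvc) > 0) mvc <- unlist(manifest$mvc)
  emg_session(emg, force = force, labels = tibble::as_tibble(lab), mvc = mvc,
              metadata = as.list(manifest$metadata))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
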