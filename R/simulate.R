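#' Synthetic subject parameters
#'
#' The simulator emulates a recording session as amplitude-modulated
#' Gaussian noise: every movement class has a focal activation map (a
#' unit-peak Gaussian blob on the electrode grid), the momentary standard
#' deviation of each EMG channel is the baseline noise level plus the
#' gain-weighted sum of the blob values times the class activations, and
#' fingertip forces are the force gain times the (enslaved) signed finger
#' activations plus sensor noise, clipped to the +/- 20 N sensor range.
#' Inter-finger enslaving couples the commanded activations through a
#' 4 x 4 matrix with unit diagonal and distance-decaying off-diagonals.
#'
#' Defaults place flexion-class blobs on one half of the 8 x 24 grid and
#' extension-class blobs on the other, with centres at least three
#' electrode pitches apart (a well-separated subject). The `"hard"` preset
#' places the ring-extension blob exactly on the index-flexion blob,
#' emulating a subject unable to produce a focal, distinct
#' ring-extension pattern: its EMG differs from index flexion only through
#' the enslaved secondary activations.
#'
#' @param preset `"default"` (well-separated maps) or `"hard"`
#'   (ring-extension map overlapped onto index flexion).
#' @param seed optional integer; when given, blob centres, gains and the
#'   baseline level are jittered reproducibly to emulate inter-subject
#'   variability.
#' @param sigma blob spatial standard deviation in electrode pitches.
#' @param gain EMG gain in microvolts RMS per unit activation (at 100 %
#'   MVC), recycled over classes.
#' @param baseline_sd baseline (rest) EMG noise standard deviation,
#'   microvolts.
#' @param enslaving 4 x 4 enslaving matrix (finger x finger); default 0.15
#'   for adjacent fingers, 0.05 for next-adjacent, 0 otherwise.
#' @param force_gain fingertip force in newtons per unit activation.
#' @param sensor_sd force sensor noise standard deviation, newtons.
#' @param spatial_jitter_sd standard deviation (electrode pitches) of the
#'   slow random drift of each blob centre, emulating the trial-to-trial
#'   spatial variability of real activation patterns (a subject never
#'   reproduces exactly the same map twice).
#' @param jitter_tau_s correlation time of the drift, seconds.
#' @return An object of class `subject_params`.
#' @export
subject_params <- function(preset = c("default", "hard"), seed = NULL,
                           sigma = 3, gain = 150, baseline_sd = 5,
                           enslaving = enslaving_matrix(),
                           force_gain = 12, sensor_sd = 0.05,
                           spatial_jitter_sd = 1.0, jitter_tau_s = 5) {
  preset <- match.arg(preset)
  cls <- active_classes()
  centers <- rbind(
    IF = c(2, 3), IE = c(2, 15), MF = c(6, 3), ME = c(6, 15),
    RF = c(2, 8), RE = c(2, 20), LF = c(6, 8), LE = c(6, 20)
  )[cls, ]
  gain <- stats::setNames(rep_len(gain, length(cls)), cls)
  if (!is.null(seed)) {
    jit <- with_local_seed(seed, list(
      dc = matrix(stats::runif(length(cls) * 2, -0.8, 0.8), ncol = 2),
      g = exp(stats::rnorm(length(cls), 0, 0.1)),
      b = stats::runif(1, 0.8, 1.2)
    ))
    centers <- centers + jit$dc
    gain <- gain * jit$g
    baseline_sd <- baseline_sd * jit$b
  }
  if (preset == "hard") centers["RE", ] <- centers["IF", ]
  stopifnot(all(gain > 0), baseline_sd > 0, force_gain > 0, sigma > 0,
            all(diag(enslaving) == 1), all(enslaving >= 0 & enslaving < 1.0001))
  structure(
    list(preset = preset, centers = centers, sigma = sigma, gain = gain,
         baseline_sd = baseline_sd, enslaving = enslaving,
         force_gain = force_gain, sensor_sd = sensor_sd,
         spatial_jitter_sd = spatial_jitter_sd,
         jitter_tau_s = jitter_tau_s, seed = seed),
    class = "subject_params"
  )
}

#' @rdname subject_params
#' @param adjacent,next_adjacent enslaving coefficients for fingers one and
#'   two positions apart.
#' @export
enslaving_matrix <- function(adjacent = 0.15, next_adjacent = 0.05) {
  d <- abs(outer(1:4, 1:4, `-`))
  m <- (d == 0) * 1 + (d == 1) * adjacent + (d == 2) * next_adjacent
  dimnames(m) <- list(fingers(), fingers())
  m
}

#' @export
print.subject_params <- function(x, ...) {
  cat(sprintf("<subject_params> preset '%s', sigma %.1f, baseline %.1f uV\n",
              x$preset, x$sigma, x$baseline_sd))
  invisible(x)
}

# class x channel activation-map matrix (unit-peak Gaussian blobs)
activation_maps <- function(subject, geometry, channel_ids) {
  pos <- channel_positions(geometry)[channel_ids, ]
  cls <- rownames(subject$centers)
  m <- matrix(0, nrow = length(cls), ncol = length(channel_ids),
              dimnames = list(cls, NULL))
  for (c in cls) {
    d2 <- (pos$row - subject$centers[c, 1])^2 +
      (pos$col - subject$centers[c, 2])^2
    m[c, ] <- exp(-d2 / (2 * subject$sigma^2))
  }
  m
}

# signed finger targets (4-vector) -> per-class non-negative activations,
# in canonical active-class order (IF, IE, MF, ME, ...)
class_activations <- function(targets, enslaving) {
  a <- as.vector(enslaving %*% targets)
  act <- c(pmax(a, 0), pmax(-a, 0))
  names(act) <- c(finger_class(fingers(), "F"), finger_class(fingers(), "E"))
  act[active_classes()]
}

# stateful per-cell EMG standard-deviation generator: applies the slow
# spatial drift of the blob centres, then sums gain-weighted blob values
# over the active classes. Draws exactly 2 * n_classes normals per cell.
emg_sd_stepper <- function(subject, geometry, channels, step_s) {
  pos <- channel_positions(geometry)[channels, ]
  cls <- rownames(subject$centers)
  drift <- matrix(0, length(cls), 2)
  rho <- exp(-step_s / subject$jitter_tau_s)
  innov <- subject$spatial_jitter_sd * sqrt(1 - rho^2)
  two_sig2 <- 2 * subject$sigma^2
  function(act) {
    drift <<- rho * drift +
      innov * matrix(stats::rnorm(2 * length(cls)), ncol = 2)
    sd_ch <- rep(subject$baseline_sd, nrow(pos))
    for (i in which(act > 1e-9)) {
      ctr <- subject$centers[i, ] + drift[i, ]
      d2 <- (pos$row - ctr[1])^2 + (pos$col - ctr[2])^2
      sd_ch <- sd_ch + subject$gain[cls[i]] * act[i] * exp(-d2 / two_sig2)
    }
    sd_ch
  }
}

# Shared simulation core. Draws, per 100 ms cell: the EMG noise matrix,
# then the 4 force-noise values -- in this exact order, so that the
# full-EMG and features-only paths are bitwise identical for a given seed.
simulate_cells <- function(profile, subject, seed, channels, fs_emg,
                           keep_samples, window_cells = 2) {
  geometry <- grid_geometry()
  if (is.null(channels)) channels <- seq_len(n_channels(geometry))
  if (inherits(channels, "subset_spec")) channels <- channels$channels
  tg <- as.matrix(profile$targets[fingers()])
  n_cells <- nrow(tg)
  nc <- length(channels)
  step <- 1 / profile$fs
  sd_step <- emg_sd_stepper(subject, geometry, channels, step)
  ranges <- t(vapply(seq_len(n_cells) - 1,
                     function(j) sample_range(fs_emg, j * step, (j + 1) * step),
                     integer(2)))
  counts <- ranges[, 2] - ranges[, 1] + 1
  ss <- matrix(0, nrow = n_cells, ncol = nc)
  force <- matrix(0, nrow = n_cells, ncol = 4)
  samples <- NULL
  if (keep_samples) samples <- matrix(0, nrow = sum(counts), ncol = nc)
  with_local_seed(seed, {
    for (j in seq_len(n_cells)) {
      act <- class_activations(tg[j, ], subject$enslaving)
      sd_ch <- sd_step(act)
      ns <- counts[j]
      cell <- matrix(stats::rnorm(ns * nc), nrow = ns, ncol = nc) *
        rep(sd_ch, each = ns)
      ss[j, ] <- colSums(cell^2)
      if (keep_samples) samples[ranges[j, 1]:ranges[j, 2], ] <- cell
      a_signed <- as.vector(subject$enslaving %*% tg[j, ])
      f <- subject$force_gain * a_signed + stats::rnorm(4) * subject$sensor_sd
      force[j, ] <- pmin(pmax(f, -20), 20)
    }
  })
  list(samples = samples, ss = ss, counts = counts, force = force,
       channels = channels, geometry = geometry, n_cells = n_cells)
}

#' Simulate an HD-sEMG + force session
#'
#' Generates a fully reproducible synthetic session from a reference
#' profile and subject parameters: raw EMG at `fs_emg`, 10 Hz fingertip
#' forces, and the profile's labels. See [subject_params()] for the
#' generative model.
#'
#' @param profile a `reference_profile` (targets as signed fraction of
#'   MVC).
#' @param subject a [subject_params()].
#' @param seed integer seed; identical `(profile, subject, seed)` triples
#'   give bitwise-identical sessions.
#' @param channels optional channel subset (grid ids or `subset_spec`) to
#'   simulate; channels are conditionally independent given the
#'   activations, so simulating a subset equals subsetting a full
#'   simulation.
#' @param fs_emg EMG sampling rate, Hz.
#' @return An [emg_session()].
#' @export
simulate_session <- function(profile, subject, seed = 1, channels = NULL,
                             fs_emg = 2048) {
  stopifnot(inherits(profile, "reference_profile"),
            inherits(subject, "subject_params"))
  cells <- simulate_cells(profile, subject, seed, channels, fs_emg,
                          keep_samples = TRUE)
  emg <- emg_recording(cells$samples, fs = fs_emg, geometry = cells$geometry,
                       channel_ids = cells$channels)
  force <- force_recording(cells$force, fs = profile$fs,
                           t = profile$targets$t)
  emg_session(emg, force = force, labels = profile$labels,
              metadata = list(seed = seed, preset = subject$preset))
}

#' Simulate a session and return its 10 Hz RMS features directly
#'
#' Equivalent to `extract_rms_features(simulate_session(...)$emg)` but
#' never materialises the raw EMG: per-window squared sums are accumulated
#' cell by cell. The random draws occur in the same order as in
#' [simulate_session()], so for a given seed the two paths produce the
#' same windows over the same noise and agree to floating-point rounding
#' (summation order differs). Only the default windowing (200 ms, 50 %
#' overlap) is supported.
#'
#' @inheritParams simulate_session
#' @return A list with `features` (an `emg_features` tibble), `force` (a
#'   [force_recording()]), `labels` and `profile`.
#' @export
simulate_session_features <- function(profile, subject, seed = 1,
                                      channels = NULL, fs_emg = 2048) {
  stopifnot(inherits(profile, "reference_profile"),
            inherits(subject, "subject_params"))
  cells <- simulate_cells(profile, subject, seed, channels, fs_emg,
                          keep_samples = FALSE)
  n_cells <- cells$n_cells
  ks <- seq.int(2, n_cells)
  rms <- sqrt((cells$ss[ks - 1, , drop = FALSE] +
                 cells$ss[ks, , drop = FALSE]) /
                (cells$counts[ks - 1] + cells$counts[ks]))
  colnames(rms) <- sprintf("ch_%03d", cells$channels)
  feats <- tibble::as_tibble(as.data.frame(rms))
  feats <- tibble::add_column(feats, t = ks * (1 / profile$fs), .before = 1)
  feats <- new_emg_features(feats, window_ms = 200, overlap = 0.5,
                            channel_ids = cells$channels)
  list(
    features = feats,
    force = force_recording(cells$force, fs = profile$fs,
                            t = profile$targets$t),
    labels = profile$labels,
    profile = profile
  )
}

#' Closed-loop tracking simulation with a surrogate subject
#'
#' Headless surrogate for an online tracking test: at every 100 ms step
#' the surrogate subject compares the latest decoded activation with the
#' reference target and adjusts its commanded finger activation by a
#' proportional correction `alpha * (target - decoded)` plus actuation
#' noise; the simulator then emits the next EMG cell and the decoder output
#' on the sliding 200 ms window is logged. The loop is deterministic for a
#' given seed.
#'
#' @param decoder either a fitted decoder (see [as_tracking_decoder()]) or
#'   a function. A one-argument function receives the named RMS feature
#'   vector; a two-argument function additionally receives the commanded
#'   signed trace in % MVC (useful as an oracle decoder). Both must return
#'   a named signed per-finger trace in % MVC.
#' @param reference a `reference_profile` (targets in fraction of MVC).
#' @param subject a [subject_params()].
#' @param seed integer seed.
#' @param channels optional channel subset to simulate.
#' @param alpha proportional correction gain of the surrogate subject.
#' @param act_noise actuation noise standard deviation (activation units).
#' @param fs_emg EMG sampling rate, Hz.
#' @return A list with `decoded` and `commanded` tibbles (`t` plus one
#'   signed % MVC column per finger) and the `reference` profile.
#' @export
simulate_tracking_subject <- function(decoder, reference, subject, seed = 1,
                                      channels = NULL, alpha = 0.5,
                                      act_noise = 0.01, fs_emg = 2048) {
  stopifnot(inherits(reference, "reference_profile"),
            inherits(subject, "subject_params"))
  if (!is.function(decoder)) decoder <- as_tracking_decoder(decoder)
  pass_command <- length(formals(decoder)) >= 2
  geometry <- grid_geometry()
  if (is.null(channels)) channels <- seq_len(n_channels(geometry))
  if (inherits(channels, "subset_spec")) channels <- channels$channels
  tg <- as.matrix(reference$targets[fingers()])
  n_cells <- nrow(tg)
  nc <- length(channels)
  step <- 1 / reference$fs
  sd_step <- emg_sd_stepper(subject, geometry, channels, step)
  u <- rep(0, 4)
  decoded_frac <- rep(0, 4)
  ss_prev <- NULL
  cnt_prev <- 0
  decoded <- matrix(0, nrow = n_cells, ncol = 4)
  commanded <- matrix(0, nrow = n_cells, ncol = 4)
  feat_names <- sprintf("ch_%03d", channels)
  with_local_seed(seed, {
    for (j in seq_len(n_cells)) {
      u <- u + alpha * (tg[j, ] - decoded_frac) +
        stats::rnorm(4) * act_noise
      u <- pmin(pmax(u, -1.2), 1.2)
      commanded[j, ] <- u
      act <- class_activations(u, subject$enslaving)
      sd_ch <- sd_step(act)
      rng <- sample_range(fs_emg, (j - 1) * step, j * step)
      ns <- rng[2] - rng[1] + 1
      cell <- matrix(stats::rnorm(ns * nc), nrow = ns, ncol = nc) *
        rep(sd_ch, each = ns)
      ss <- colSums(cell^2)
      if (!is.null(ss_prev)) {
        x <- sqrt((ss_prev + ss) / (cnt_prev + ns))
        names(x) <- feat_names
        trace <- if (pass_command) decoder(x, u * 100) else decoder(x)
        decoded[j, ] <- as.numeric(trace[fingers()])
        decoded_frac <- decoded[j, ] / 100
      }
      ss_prev <- ss
      cnt_prev <- ns
    }
  })
  mk <- function(m) {
    colnames(m) <- fingers()
    tibble::as_tibble(cbind(data.frame(t = reference$targets$t),
                            as.data.frame(m)))
  }
  list(decoded = mk(decoded), commanded = mk(commanded * 100),
       reference = reference)
}
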