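#' Construct a multichannel EMG recording
#'
#' @param data Numeric matrix, channels x samples (microvolts).
#' @param fs Sampling rate in Hz.
#' @param labels Unique channel labels (defaults to `ch1..chN`).
#' @param trigger Optional per-sample phase/direction code (length = samples).
#' @param t0 Start time in seconds (default 0).
#' @return An object of class `ff_recording`.
#' @export
emg_recording <- function(data, fs, labels = NULL, trigger = NULL, t0 = 0) {
  data <- as.matrix(data)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  if (length(labels) != nrow(data)) stop("one label per channel required")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  if (!is.null(trigger) && length(trigger) != ncol(data))
    stop("trigger length must equal the number of samples")
  rownames(data) <- labels
  structure(list(data = data, fs = fs, labels = labels,
                 trigger = trigger, t0 = t0),
            class = "ff_recording")
}

#' @export
print.ff_recording <- function(x, ...) {
  cat(sprintf("<ff_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

## ---- zero-phase filtering core ------------------------------------------

## Forward-backward Butterworth with odd-reflection padding at both ends.
## pad is chosen from the lowest band edge so filter transients decay inside
## the padded region rather than in the data.  Filtering is done about the
## series mean: with dc_gain = 1 (low-pass) the mean is restored afterwards,
## with dc_gain = 0 (band-/high-pass) it is removed exactly.  This makes
## constant inputs exact fixed points of the filters.
zero_phase <- function(x, filt, pad, dc_gain = 1) {
  n <- length(x)
  mu <- mean(x)
  x <- x - mu
  pad <- min(n - 1L, as.integer(pad))
  if (pad > 0L) {
    head_ref <- 2 * x[1] - x[seq(pad + 1L, 2L)]
    tail_ref <- 2 * x[n] - x[seq(n - 1L, n - pad)]
    xp <- c(head_ref, x, tail_ref)
  } else xp <- x
  y <- signal::filtfilt(filt, xp)
  if (pad > 0L) y <- y[(pad + 1L):(pad + n)]
  y + dc_gain * mu
}

apply_rows <- function(m, fun) {
  out <- t(apply(m, 1L, fun))
  dimnames(out) <- dimnames(m)
  out
}

#' Common average re-reference
#'
#' Subtracts the per-sample mean across all channels, removing any signal
#' common to the whole array (reference drift, line pickup shared by the
#' electrodes).
#'
#' @param rec An [emg_recording()].
#' @return The re-referenced recording; the channel mean of the output is 0
#'   at every sample.
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "ff_recording"))
  if (nrow(rec$data) < 2L) stop("average reference needs at least 2 channels")
  rec$data <- sweep(rec$data, 2L, colMeans(rec$data))
  rec
}

#' Band-pass filter a recording
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass applied per
#' channel.  Zero-phase filtering keeps the EMG aligned in time with the
#' kinematics, which the correlation-based channel selection relies on.
#'
#' @param rec An [emg_recording()].
#' @param lo,hi Band edges in Hz; `0 < lo < hi < fs/2`.
#' @return Filtered recording, same length.
#' @export
bandpass_filter <- function(rec, lo = 5, hi = 200) {
  stopifnot(inherits(rec, "ff_recording"))
  if (!(lo > 0 && lo < hi && hi < rec$fs / 2))
    stop("band edges must satisfy 0 < lo < hi < fs/2 (fs = ", rec$fs, ")")
  bf <- signal::butter(4, c(lo, hi) / (rec$fs / 2), type = "pass")
  pad <- ceiling(2 * rec$fs / lo)
  rec$data <- apply_rows(rec$data, function(x)
    zero_phase(x, bf, pad, dc_gain = 0))
  rec
}

#' Resample a recording
#'
#' Anti-aliased downsampling of every channel: a zero-phase 4th-order
#' Butterworth low-pass at 80% of the new Nyquist rate, then evaluation on
#' the new time grid.  The trigger channel is carried over by
#' nearest-sample lookup so phase codes stay exact.
#'
#' @param rec An [emg_recording()].
#' @param fs_new Target rate in Hz, at most the current rate.
#' @return Recording at `fs_new`; duration is preserved to within one sample.
#' @export
resample_signal <- function(rec, fs_new) {
  stopifnot(inherits(rec, "ff_recording"))
  if (fs_new > rec$fs) stop("upsampling is not supported (fs_new > fs)")
  if (fs_new == rec$fs) return(rec)
  n <- ncol(rec$data)
  m <- round(n * fs_new / rec$fs)
  cutoff <- 0.8 * fs_new / 2
  bf <- signal::butter(4, cutoff / (rec$fs / 2), type = "low")
  pad <- ceiling(2 * rec$fs / cutoff)
  t_old <- (seq_len(n) - 1L) / rec$fs
  t_new <- (seq_len(m) - 1L) / fs_new
  data_new <- t(apply(rec$data, 1L, function(x) {
    y <- zero_phase(x, bf, pad, dc_gain = 1)
    stats::approx(t_old, y, xout = t_new, rule = 2)$y
  }))
  rownames(data_new) <- rec$labels
  if (!is.null(rec$trigger)) {
    idx <- pmin(n, floor(t_new * rec$fs) + 1L)
    rec$trigger <- rec$trigger[idx]
  }
  rec$data <- data_new
  rec$fs <- fs_new
  rec
}

#' Rectified low-pass EMG envelope
#'
#' Full-wave rectification followed by a zero-phase 4th-order Butterworth
#' low-pass.  The envelope is the standard proxy for muscle contraction
#' level `u` fed into the decoding models; tiny negative filter undershoot
#' is clamped to zero so `u >= 0` always holds.
#'
#' @param x A signals-x-samples matrix, a numeric vector, or an
#'   [emg_recording()].
#' @param fs Sampling rate in Hz (taken from the recording if given one).
#' @param cutoff Low-pass cut-off in Hz, default 3.
#' @param source_kind `"raw_channel"` or `"independent_component"`;
#'   bookkeeping only.
#' @return An `ff_envelopes` object: list with `env` (signals x samples,
#'   non-negative), `fs`, `ids`, `source_kind`.
#' @export
emg_envelope <- function(x, fs = NULL, cutoff = 3,
                         source_kind = c("raw_channel", "independent_component")) {
  source_kind <- match.arg(source_kind)
  if (inherits(x, "ff_recording")) { fs <- x$fs; x <- x$data }
  if (is.null(fs)) stop("fs is required when x is a bare matrix")
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (!(cutoff > 0 && cutoff < fs / 2)) stop("cutoff must lie in (0, fs/2)")
  bf <- signal::butter(4, cutoff / (fs / 2), type = "low")
  pad <- ceiling(2 * fs / cutoff)
  env <- apply_rows(abs(x), function(v) zero_phase(v, bf, pad))
  env[env < 0] <- 0
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(env)))
  structure(list(env = env, fs = fs, ids = ids, source_kind = source_kind),
            class = "ff_envelopes")
}

#' Remove the resting offset estimated from the calibration segment
#'
#' Each experiment starts with a rest-only calibration segment recorded to
#' estimate offset and noise floor; subtracting its mean envelope gives
#' activation estimates that are ~0 at rest.
#'
#' @param envs An `ff_envelopes` object.
#' @param calibration_s Length of the calibration segment in seconds.
#' @return `ff_envelopes` with per-signal calibration mean subtracted and
#'   negatives clamped to zero.
#' @export
remove_offset <- function(envs, calibration_s) {
  stopifnot(inherits(envs, "ff_envelopes"), calibration_s > 0)
  k <- max(1L, min(ncol(envs$env), floor(calibration_s * envs$fs)))
  off <- rowMeans(envs$env[, seq_len(k), drop = FALSE])
  envs$env <- envs$env - off
  envs$env[envs$env < 0] <- 0
  envs
}
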