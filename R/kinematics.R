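#' Construct a phase schedule
#'
#' A schedule is the timed sequence of instructed phases (flexion / rest /
#' extension per finger) that drives an experiment.  Each phase carries the
#' trigger direction value: 2.094 rad for flexion, -0.523 rad for extension,
#' 0 at rest (see [trigger_value()]).
#'
#' @param phases data.frame with columns `start`, `end` (seconds), `kind`
#'   (`"flexion"`, `"rest"`, `"extension"`) and `finger` (a name from
#'   [finger_names()], or `NA` for rest).
#' @param calibration_s Length of the initial rest-only calibration segment
#'   contained in the schedule (seconds), stored as an attribute.
#' @return A data.frame of class `ff_schedule` with an added `t_dir` column.
#' @export
phase_schedule <- function(phases, calibration_s = 0) {
  req <- c("start", "end", "kind", "finger")
  if (!all(req %in% names(phases))) stop("phases needs columns: ",
                                         paste(req, collapse = ", "))
  phases <- phases[order(phases$start), , drop = FALSE]
  if (any(phases$end <= phases$start)) stop("non-positive phase durations")
  if (nrow(phases) > 1L &&
      any(abs(phases$start[-1L] - phases$end[-nrow(phases)]) > 1e-9))
    stop("phases must be contiguous and non-overlapping")
  if (!all(phases$kind %in% c("flexion", "rest", "extension")))
    stop("unknown phase kind")
  mv <- phases$kind != "rest"
  if (any(mv & !(phases$finger %in% .FINGERS)))
    stop("unknown finger label in movement phase")
  phases$t_dir <- trigger_value(phases$kind)
  rownames(phases) <- NULL
  structure(phases, class = c("ff_schedule", "data.frame"),
            calibration_s = calibration_s)
}

schedule_duration <- function(schedule) max(schedule$end)

## Per-sample trigger direction for one finger, on the grid t = t0 + i/fs.
t_dir_series <- function(schedule, finger, n, fs, t0 = 0) {
  t <- t0 + (seq_len(n) - 1L) / fs
  if (t[n] > schedule_duration(schedule) + 1e-9 || t[1] < min(schedule$start) - 1e-9)
    stop("schedule does not cover the requested time span")
  out <- numeric(n)
  for (i in seq_len(nrow(schedule))) {
    if (schedule$kind[i] == "rest" || !identical(schedule$finger[i], finger)) next
    sel <- t >= schedule$start[i] - 1e-9 & t < schedule$end[i] - 1e-9
    out[sel] <- schedule$t_dir[i]
  }
  out
}

## Integer per-sample phase code for the trigger channel:
## 0 rest, 10*finger_index + 1 flexion, + 2 extension.
trigger_code_series <- function(schedule, n, fs, t0 = 0) {
  t <- t0 + (seq_len(n) - 1L) / fs
  out <- integer(n)
  for (i in seq_len(nrow(schedule))) {
    k <- schedule$kind[i]
    if (k == "rest") next
    f <- match(schedule$finger[i], .FINGERS)
    sel <- t >= schedule$start[i] - 1e-9 & t < schedule$end[i] - 1e-9
    out[sel] <- 10L * f + if (k == "flexion") 1L else 2L
  }
  out
}

#' Construct a normalized-displacement (NRMSD) series
#'
#' @param values Fingers x samples matrix in `[0, 1]` with finger names as
#'   row names, or a vector for a single finger.
#' @param fs Sampling rate in Hz.
#' @param t0 Start time in seconds.
#' @return An object of class `ff_nrmsd`.
#' @export
nrmsd_series <- function(values, fs, t0 = 0) {
  if (is.vector(values)) values <- matrix(values, nrow = 1L,
                                          dimnames = list(.FINGERS[1L]))
  if (any(values < -1e-9) || any(values > 1 + 1e-9))
    stop("NRMSD values must lie in [0, 1]")
  values <- pmin(pmax(values, 0), 1)
  structure(list(values = values, fs = fs, t0 = t0), class = "ff_nrmsd")
}

#' Normalized root-mean-square displacement of finger joints
#'
#' For each finger, the RMS Euclidean displacement of its tracked 2-D joints
#' from a calibration (rest) pose, divided by the finger length and clipped
#' to `[0, 1]`.  This is the magnitude part of the ground-truth angle; the
#' protocol trigger supplies the sign/direction.
#'
#' @param positions Named list (one entry per finger) of `time x joints x 2`
#'   arrays of joint coordinates.
#' @param calibration_pose Named list of `joints x 2` reference matrices,
#'   typically the mean pose over the calibration segment.
#' @param finger_length Named numeric vector of finger lengths (same units
#'   as the coordinates), all positive.
#' @param fs Sampling rate of the position series in Hz.
#' @return An [nrmsd_series()] object.
#' @export
compute_nrmsd <- function(positions, calibration_pose, finger_length, fs) {
  fingers <- names(positions)
  if (is.null(fingers)) stop("positions must be a named list per finger")
  vals <- lapply(fingers, function(f) {
    pos <- positions[[f]]
    ref <- calibration_pose[[f]]
    L <- finger_length[[f]]
    if (is.null(ref)) stop("missing calibration pose for ", f)
    if (!is.numeric(L) || L <= 0) stop("finger_length must be > 0 for ", f)
    if (length(dim(pos)) != 3L || dim(pos)[3] != 2L)
      stop("positions[[", f, "]] must be a time x joints x 2 array")
    if (dim(pos)[2] != nrow(ref))
      stop("joint count mismatch between positions and calibration for ", f)
    d2 <- (pos[, , 1, drop = FALSE] - rep(ref[, 1], each = dim(pos)[1]))^2 +
          (pos[, , 2, drop = FALSE] - rep(ref[, 2], each = dim(pos)[1]))^2
    sqrt(rowMeans(matrix(d2, nrow = dim(pos)[1]))) / L
  })
  m <- do.call(rbind, vals)
  rownames(m) <- fingers
  nrmsd_series(pmin(m, 1), fs)
}

#' Construct a finger-angle trajectory
#'
#' @param angles Fingers x samples matrix of joint angles in radians with
#'   finger names as row names.
#' @param fs Sampling rate in Hz.
#' @param t0 Start time in seconds.
#' @return An object of class `ff_trajectory`.
#' @export
finger_trajectory <- function(angles, fs, t0 = 0) {
  if (is.vector(angles)) angles <- matrix(angles, nrow = 1L,
                                          dimnames = list(.FINGERS[1L]))
  if (any(!is.finite(angles))) stop("angles must be finite")
  if (any(abs(angles) > pi + 1e-9)) stop("|angle| must not exceed pi")
  structure(list(angles = angles, fs = fs, t0 = t0), class = "ff_trajectory")
}

#' Ground-truth finger angle from trigger and normalized displacement
#'
#' Implements the ground-truth construction `theta_f(t) = T_dir(t) *
#' NRMSD_f(t)`: the displacement magnitude from the finger tracker is signed
#' and scaled by the protocol trigger, giving 2.094 rad at full flexion and
#' -0.523 rad at full extension.
#'
#' @param nrmsd An [nrmsd_series()].
#' @param schedule An [phase_schedule()] covering the series' time span.
#' @return An [finger_trajectory()] at the same rate.
#' @export
finger_angle_from_trigger <- function(nrmsd, schedule) {
  stopifnot(inherits(nrmsd, "ff_nrmsd"), inherits(schedule, "ff_schedule"))
  n <- ncol(nrmsd$values)
  ang <- nrmsd$values
  for (f in rownames(nrmsd$values)) {
    td <- t_dir_series(schedule, f, n, nrmsd$fs, nrmsd$t0)
    ang[f, ] <- td * nrmsd$values[f, ]
  }
  finger_trajectory(ang, nrmsd$fs, nrmsd$t0)
}

#' Smooth a finger-angle trajectory
#'
#' Median filter (spike removal) followed by a zero-phase 4th-order
#' Butterworth low-pass, mirroring the smoothing applied to camera-based
#' pose estimates before they serve as decoding targets.
#'
#' @param traj An [finger_trajectory()].
#' @param lp_cutoff Low-pass cut-off in Hz, default 1.
#' @param median_window Median-filter window in seconds, default 0.5; must
#'   span at least 3 samples and no more than the series.
#' @return Smoothed trajectory, same length.
#' @export
smooth_trajectory <- function(traj, lp_cutoff = 1, median_window = 0.5) {
  stopifnot(inherits(traj, "ff_trajectory"))
  n <- ncol(traj$angles)
  k <- round(median_window * traj$fs)
  if (k %% 2 == 0) k <- k + 1L
  if (k < 3L) stop("median window must span at least 3 samples")
  if (k > n) stop("median window larger than the series")
  bf <- signal::butter(4, lp_cutoff / (traj$fs / 2), type = "low")
  pad <- ceiling(2 * traj$fs / lp_cutoff)
  sm <- apply_rows(traj$angles, function(x) {
    y <- stats::runmed(x, k, endrule = "median")
    zero_phase(y, bf, pad)
  })
  sm[abs(sm) > pi] <- sign(sm[abs(sm) > pi]) * pi
  traj$angles <- sm
  traj
}
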