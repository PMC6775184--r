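#' Configuration of the synthetic array-EMG experiment generator
#'
#' The generator emulates the acquisition and protocol used for array-EMG
#' finger decoding: a 96-electrode forearm array sampled at 2048 Hz, train
#' experiments of 6 motions (2 s flexion / 2 s rest / 2 s extension / 2 s
#' rest, i.e. 8 s per motion) on a single finger, 25 train experiments per
#' subject (5 per finger, Thumb to Pinky), and test experiments of 10
#' cycles sweeping all five fingers twice.  Per-finger flexor/extensor
#' activations drive joint angles through the equilibrium-point muscle
#' model; muscle sources are amplitude-modulated band-limited noise
#' carriers mixed onto the electrode grid with Gaussian spatial spread,
#' plus line interference, broadband sensor noise and low-frequency motion
#' artifacts.
#'
#' @param seed Master seed; everything downstream is reproducible from it.
#' @param n_subjects Number of simulated subjects (default 10).
#' @param fs_raw Acquisition rate in Hz (default 2048).
#' @param n_channels Electrode count, multiple of 8 (default 96).
#' @param phase_len Length of each instructed phase in seconds (default 2).
#' @param calibration_len Initial rest-only calibration segment (s, default 4).
#' @param motions_per_train_exp Motions per train experiment (default 6).
#' @param train_exps_per_finger Train experiments per finger (default 5).
#' @param test_exps Test experiments per subject (default 5).
#' @param cycles_per_test_exp Cycles per test experiment (default 10).
#' @param crosstalk Fraction in `[0, 1)` of an instructed activation leaking
#'   into adjacent fingers (finger interconnection; default 0.1).
#' @param snr_db Broadband source-to-sensor-noise power ratio in dB
#'   (default 10; `Inf` disables sensor noise).
#' @param line_freq Power-line frequency in Hz (default 50).
#' @param line_level Line-interference amplitude relative to the source RMS
#'   (default 0.1; 0 disables).
#' @param artifact_level Motion-artifact amplitude relative to the source
#'   RMS (default 0.5; 0 disables).
#' @param carrier_band EMG carrier band in Hz (default 20--250); capped at
#'   `0.45 * fs_raw` so the band always fits under Nyquist.
#' @param baseline Resting activation floor (default 0.02).
#' @param amp_jitter Per-burst peak-amplitude jitter fraction (default 0.1).
#' @param sigma_grid Gaussian spatial spread of each muscle source on the
#'   electrode grid, in grid units (default 1.5).
#' @return A validated list of class `ff_sim_config`.
#' @export
sim_config <- function(seed = 1L, n_subjects = 10L, fs_raw = 2048,
                       n_channels = 96L, phase_len = 2,
                       calibration_len = 4, motions_per_train_exp = 6L,
                       train_exps_per_finger = 5L, test_exps = 5L,
                       cycles_per_test_exp = 10L, crosstalk = 0.1,
                       snr_db = 10, line_freq = 50, line_level = 0.1,
                       artifact_level = 0.5, carrier_band = c(20, 250),
                       baseline = 0.02, amp_jitter = 0.1,
                       sigma_grid = 1.5) {
  cfg <- list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
              fs_raw = fs_raw, n_channels = as.integer(n_channels),
              phase_len = phase_len, calibration_len = calibration_len,
              motions_per_train_exp = as.integer(motions_per_train_exp),
              train_exps_per_finger = as.integer(train_exps_per_finger),
              test_exps = as.integer(test_exps),
              cycles_per_test_exp = as.integer(cycles_per_test_exp),
              crosstalk = crosstalk, snr_db = snr_db,
              line_freq = line_freq, line_level = line_level,
              artifact_level = artifact_level,
              carrier_band = carrier_band, baseline = baseline,
              amp_jitter = amp_jitter, sigma_grid = sigma_grid)
  counts <- c(cfg$n_subjects, cfg$n_channels, cfg$motions_per_train_exp,
              cfg$train_exps_per_finger, cfg$test_exps,
              cfg$cycles_per_test_exp)
  if (any(counts < 1L)) stop("all counts must be >= 1")
  if (cfg$phase_len <= 0) stop("phase_len must be positive")
  if (!(cfg$crosstalk >= 0 && cfg$crosstalk < 1))
    stop("crosstalk must lie in [0, 1)")
  cfg$carrier_band[2] <- min(cfg$carrier_band[2], 0.45 * cfg$fs_raw)
  if (cfg$fs_raw <= 2 * cfg$carrier_band[2])
    stop("fs_raw must exceed twice the carrier band edge")
  if (cfg$artifact_level < 0) stop("artifact_level must be >= 0")
  structure(cfg, class = "ff_sim_config")
}

#' Generate the instructed phase schedule of one experiment
#'
#' Train experiments: a calibration rest segment, then
#' `motions_per_train_exp` motions of \[flexion, rest, extension, rest\]
#' (each `phase_len` s, so 8 s per motion with the defaults) for a single
#' finger.  Test experiments: the calibration segment, then
#' `cycles_per_test_exp` such cycles sweeping the fingers in Thumb-to-Pinky
#' order, wrapping around (10 cycles = every finger twice).
#'
#' @param cfg An [sim_config()].
#' @param kind `"train"` or `"test"`.
#' @param finger Instructed finger, required for train experiments.
#' @return An [phase_schedule()].
#' @export
generate_protocol <- function(cfg, kind = c("train", "test"), finger = NULL) {
  stopifnot(inherits(cfg, "ff_sim_config"))
  kind <- match.arg(kind)
  if (cfg$phase_len <= 0) stop("phase_len must be positive")
  if (kind == "train") {
    if (is.null(finger) || !(finger %in% .FINGERS))
      stop("train protocol needs a finger from finger_names()")
    cycle_fingers <- rep(finger, cfg$motions_per_train_exp)
  } else {
    cycle_fingers <- rep_len(.FINGERS, cfg$cycles_per_test_exp)
  }
  rows <- list(data.frame(start = 0, end = cfg$calibration_len,
                          kind = "rest", finger = NA_character_,
                          stringsAsFactors = FALSE))
  t <- cfg$calibration_len
  for (f in cycle_fingers) {
    for (k in c("flexion", "rest", "extension", "rest")) {
      rows[[length(rows) + 1L]] <- data.frame(
        start = t, end = t + cfg$phase_len, kind = k,
        finger = if (k == "rest") NA_character_ else f,
        stringsAsFactors = FALSE)
      t <- t + cfg$phase_len
    }
  }
  sch <- phase_schedule(do.call(rbind, rows),
                        calibration_s = cfg$calibration_len)
  attr(sch, "kind") <- kind
  attr(sch, "cycles") <- length(cycle_fingers)
  sch
}

#' Count motion cycles in a schedule
#'
#' @param schedule An [phase_schedule()].
#' @return Number of flexion phases (one per motion cycle).
#' @export
count_cycles <- function(schedule) sum(schedule$kind == "flexion")

## Raised-cosine trapezoid on [0, 1): ramps over the first and last
## ramp_frac, plateau of 1 in between.
burst_shape <- function(len, ramp_frac = 0.25) {
  x <- (seq_len(len) - 0.5) / len
  s <- rep(1, len)
  up <- x < ramp_frac
  dn <- x > 1 - ramp_frac
  s[up] <- 0.5 * (1 - cos(pi * x[up] / ramp_frac))
  s[dn] <- 0.5 * (1 - cos(pi * (1 - x[dn]) / ramp_frac))
  s
}

#' Generate per-finger muscle activations for a schedule
#'
#' The instructed finger's flexor is driven with a smooth raised-cosine
#' trapezoid during its flexion phases and its extensor during extension
#' phases, with a small seeded jitter of the peak amplitude.  Adjacent
#' fingers receive `crosstalk` times the instructed burst (finger
#' interconnection); everything sits on a small resting baseline.
#'
#' @param schedule An [phase_schedule()].
#' @param cfg An [sim_config()].
#' @param rng_seed Integer seed; the output is deterministic given it.
#' @return An `ff_activations` object: `u_flex`, `u_ext` (5 x samples
#'   matrices in `[0, 1]`, finger row names), `fs`.
#' @export
generate_activations <- function(schedule, cfg, rng_seed = 1L) {
  stopifnot(inherits(schedule, "ff_schedule"), inherits(cfg, "ff_sim_config"))
  if (nrow(schedule) == 0L) stop("empty schedule")
  fs <- cfg$fs_raw
  n <- round(schedule_duration(schedule) * fs)
  Bf <- matrix(0, 5, n, dimnames = list(.FINGERS, NULL))
  Be <- matrix(0, 5, n, dimnames = list(.FINGERS, NULL))
  with_seed(rng_seed, {
    for (i in seq_len(nrow(schedule))) {
      k <- schedule$kind[i]
      if (k == "rest") next
      f <- match(schedule$finger[i], .FINGERS)
      i0 <- floor(schedule$start[i] * fs) + 1L
      i1 <- min(n, ceiling(schedule$end[i] * fs))
      amp <- 1 - stats::runif(1, 0, cfg$amp_jitter)
      sh <- amp * burst_shape(i1 - i0 + 1L)
      if (k == "flexion") Bf[f, i0:i1] <- Bf[f, i0:i1] + sh
      else Be[f, i0:i1] <- Be[f, i0:i1] + sh
    }
  })
  leak <- function(B) {
    L <- B * 0
    for (f in 1:5) {
      nb <- c(f - 1L, f + 1L)
      nb <- nb[nb >= 1L & nb <= 5L]
      L[f, ] <- cfg$crosstalk * colSums(B[nb, , drop = FALSE])
    }
    pmin(pmax(B + L, cfg$baseline), 1)
  }
  structure(list(u_flex = leak(Bf), u_ext = leak(Be), fs = fs),
            class = "ff_activations")
}

## ---- subject-level muscle parameters ------------------------------------

## Solve (l0_1, l1_1, l1_2) so that the equilibrium angle hits 0 at rest,
## th_flex at full flexion and th_ext at full extension, given the other
## parameters.  Linear 3x3 system; returns NULL if any length comes out
## non-positive.
solve_msm_lengths <- function(a1, a2, k0, k1, l02, eps, th_flex, th_ext) {
  row_for <- function(u1, u2, target) {
    K1 <- k0[1] + k1[1] * u1
    K2 <- k0[2] + k1[2] * u2
    D <- a1^2 * K1 + a2^2 * K2
    c(coef = c(a1 * K1, a1 * K1 * u1, a2 * K2 * u2),
      rhs = target * D - a2 * K2 * l02)
  }
  m <- rbind(row_for(eps, eps, 0),
             row_for(1, eps, th_flex),
             row_for(eps, 1, th_ext))
  sol <- tryCatch(solve(m[, 1:3], m[, 4]), error = function(e) NULL)
  if (is.null(sol) || any(!is.finite(sol)) || any(sol <= 0)) return(NULL)
  list(l01 = sol[1], l11 = sol[2], l12 = sol[3])
}

## Draw one finger's ground-truth muscle parameters such that the
## equilibrium angle reaches ~th_flex / ~th_ext at full activation and 0 at
## the resting baseline.
draw_finger_params <- function(cfg, max_tries = 200L) {
  for (i in seq_len(max_tries)) {
    a1 <- stats::runif(1, 0.8, 1.2)
    a2 <- -stats::runif(1, 0.8, 1.2)
    k0 <- stats::runif(2, 0.8, 1.2)
    k1 <- stats::runif(2, 0.1, 0.4)
    l02 <- stats::runif(1, 0.8, 1.2)
    lens <- solve_msm_lengths(a1, a2, k0, k1, l02, cfg$baseline,
                              .T_FLEX, .T_EXT)
    if (is.null(lens)) next
    return(msm_params(a = c(a1, a2), k0 = k0, k1 = k1,
                      l0 = c(lens$l01, l02), l1 = c(lens$l11, lens$l12)))
  }
  stop("could not draw feasible muscle parameters")
}

## ---- spatial model -------------------------------------------------------

#' Muscle source locations on the electrode grid
#'
#' One flexor source per finger on the inner panel and one extensor source
#' per finger on the outer panel, centred on the finger's anatomical mask
#' block.
#'
#' @param layout An `ff_layout`.
#' @param mask An `ff_channel_mask` (default mask of the layout).
#' @return data.frame with columns `finger`, `direction`, `side`,
#'   `grid_row`, `grid_col`; flexors (Thumb..Pinky) then extensors.
#' @export
source_locations <- function(layout, mask = default_channel_mask(layout)) {
  rows <- list()
  for (dir in c("flexion", "extension")) {
    side <- if (dir == "flexion") "flexor" else "extensor"
    for (f in .FINGERS) {
      lab <- mask_labels(mask, f, dir)
      li <- match(lab, layout$label)
      rows[[length(rows) + 1L]] <- data.frame(
        finger = f, direction = dir, side = side,
        grid_row = mean(layout$grid_row[li]),
        grid_col = mean(layout$grid_col[li]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Spatial mixing matrix from source locations
#'
#' Gaussian spatial spread of each muscle source over the electrodes of its
#' panel side: `w = exp(-d^2 / (2 sigma^2))` in grid units, zero on the
#' opposite side of the forearm.
#'
#' @param layout An `ff_layout`.
#' @param locs Source locations from [source_locations()].
#' @param sigma Spatial spread in grid units.
#' @return channels x sources matrix.
#' @export
build_mixing <- function(layout, locs, sigma = 1.5) {
  M <- matrix(0, nrow(layout), nrow(locs),
              dimnames = list(layout$label,
                              paste(locs$finger, locs$direction, sep = "_")))
  for (s in seq_len(nrow(locs))) {
    same <- layout$side == locs$side[s]
    d2 <- (layout$grid_row - locs$grid_row[s])^2 +
          (layout$grid_col - locs$grid_col[s])^2
    M[same, s] <- exp(-d2[same] / (2 * sigma^2))
  }
  M
}

## ---- truth + synthesis ---------------------------------------------------

## Assemble the ground truth of one experiment: activations, equilibrium
## angles, normalized displacement.
sim_truth <- function(schedule, params, mixing, locs, cfg, rng_seed) {
  act <- generate_activations(schedule, cfg, rng_seed)
  n <- ncol(act$u_flex)
  ang <- matrix(0, 5, n, dimnames = list(.FINGERS, NULL))
  nr <- ang
  for (f in seq_along(.FINGERS)) {
    ang[f, ] <- msm_equilibrium(act$u_flex[f, ], act$u_ext[f, ],
                                params[[f]])
    td <- t_dir_series(schedule, .FINGERS[f], n, cfg$fs_raw)
    ref <- ifelse(td != 0, abs(td), .T_FLEX)
    nr[f, ] <- pmin(1, pmax(0, abs(ang[f, ]) / ref))
  }
  structure(list(params = params, activations = act, angles = ang,
                 nrmsd = nrmsd_series(nr, cfg$fs_raw),
                 mixing = mixing, source_locations = locs,
                 schedule = schedule, fs = cfg$fs_raw),
            class = "ff_truth")
}

#' Synthesize an array-EMG recording from simulated ground truth
#'
#' Each muscle source is its activation envelope multiplied by a unit-RMS
#' band-limited (20--250 Hz) noise carrier, independent across muscles so
#' the ICA model holds by construction.  Channel signals are the spatial
#' mixture of the sources plus: a `line_freq` sinusoid with per-channel
#' gains, white sensor noise scaled so the broadband source-to-noise power
#' ratio matches `snr_db`, and low-frequency (< 5 Hz) motion-artifact
#' bursts during movement phases, common to the whole array with
#' per-channel gains, scaled by `artifact_level`.  The trigger channel
#' encodes the schedule as integer phase codes.
#'
#' @param truth An `ff_truth` from the generator.
#' @param layout Array layout matching the mixing matrix rows.
#' @param cfg An [sim_config()].
#' @param rng_seed Integer seed for carriers, noise and artifacts.
#' @return An [emg_recording()] with `n_channels` rows.
#' @export
synthesize_emg <- function(truth, layout, cfg, rng_seed = 1L) {
  stopifnot(inherits(truth, "ff_truth"), inherits(cfg, "ff_sim_config"))
  if (nrow(layout) != nrow(truth$mixing))
    stop("layout and mixing dimensions disagree")
  fs <- cfg$fs_raw
  act <- truth$activations
  U <- rbind(act$u_flex, act$u_ext)       # sources x samples, flexors first
  n <- ncol(U)
  ns <- nrow(U)
  bf <- signal::butter(4, cfg$carrier_band / (fs / 2), type = "pass")
  lp_art <- signal::butter(4, min(4, fs / 2 * 0.8) / (fs / 2), type = "low")
  with_seed(rng_seed, {
    carriers <- matrix(0, ns, n)
    for (s in seq_len(ns)) {
      w <- signal::filter(bf, stats::rnorm(n))
      carriers[s, ] <- w / sqrt(mean(w^2))
    }
    S <- U * carriers
    sig <- truth$mixing %*% S
    rms_sig <- sqrt(mean(sig^2))
    t <- (seq_len(n) - 1L) / fs
    line_gain <- stats::runif(nrow(sig), 0.5, 1.5)
    line <- (cfg$line_level * rms_sig * line_gain) %o%
      sin(2 * pi * cfg$line_freq * t)
    noise <- matrix(stats::rnorm(length(sig)), nrow(sig), n)
    noise_sd <- if (is.infinite(cfg$snr_db)) 0
                else rms_sig * 10^(-cfg$snr_db / 20)
    art_gain <- stats::runif(nrow(sig), 0.5, 1.5)
    art_src <- signal::filter(lp_art, stats::rnorm(n))
    art_src <- art_src / sqrt(mean(art_src^2))
    moving <- colSums(U) > ns * cfg$baseline + 0.1
    move_env <- signal::filter(lp_art, as.numeric(moving))
    art <- (cfg$artifact_level * rms_sig * art_gain) %o%
      (art_src * pmax(0, move_env))
    data <- sig + noise_sd * noise + line + art
    emg_recording(data, fs, labels = layout$label,
                  trigger = trigger_code_series(truth$schedule, n, fs))
  })
}

## ---- dataset assembly ----------------------------------------------------

subject_seeds <- function(cfg) {
  with_seed(cfg$seed, sample.int(.Machine$integer.max - 1L, cfg$n_subjects))
}

#' Generate all experiments of one simulated subject
#'
#' Draws subject-specific muscle parameters, then generates
#' `train_exps_per_finger` train experiments per finger (Thumb to Pinky)
#' and `test_exps` mixed test experiments, each with ground truth and a
#' synthesized recording.  Fully reproducible from `cfg$seed` and the
#' subject index.
#'
#' @param cfg An [sim_config()].
#' @param subject Subject index in `1..n_subjects`.
#' @param layout Optional pre-built layout (must match `cfg$n_channels`).
#' @return List with `subject`, `params` (per-finger [msm_params()]),
#'   `mixing`, `source_locations`, `train` and `test` experiment lists;
#'   each experiment holds `id`, `kind`, `finger`, `schedule`, `truth`,
#'   `recording`.
#' @export
generate_subject <- function(cfg, subject,
                             layout = default_layout(cfg$n_channels)) {
  stopifnot(inherits(cfg, "ff_sim_config"),
            subject >= 1L, subject <= cfg$n_subjects)
  mask <- default_channel_mask(layout)
  locs <- source_locations(layout, mask)
  mixing <- build_mixing(layout, locs, cfg$sigma_grid)
  sseed <- subject_seeds(cfg)[subject]
  with_seed(sseed, {
    params <- stats::setNames(
      lapply(.FINGERS, function(f) draw_finger_params(cfg)), .FINGERS)
    n_train <- 5L * cfg$train_exps_per_finger
    exp_seeds <- sample.int(.Machine$integer.max - 1L,
                            n_train + cfg$test_exps)
    train <- list()
    i <- 0L
    for (f in .FINGERS) {
      for (rep in seq_len(cfg$train_exps_per_finger)) {
        i <- i + 1L
        sch <- generate_protocol(cfg, "train", f)
        tr <- sim_truth(sch, params, mixing, locs, cfg, exp_seeds[i])
        train[[i]] <- list(id = sprintf("S%02d_train_%s_%d", subject, f, rep),
                           kind = "train", finger = f, schedule = sch,
                           truth = tr,
                           recording = synthesize_emg(tr, layout, cfg,
                                                      exp_seeds[i] + 1L))
      }
    }
    test <- lapply(seq_len(cfg$test_exps), function(j) {
      sch <- generate_protocol(cfg, "test")
      tr <- sim_truth(sch, params, mixing, locs, cfg,
                      exp_seeds[n_train + j])
      list(id = sprintf("S%02d_test_%d", subject, j), kind = "test",
           finger = NA_character_, schedule = sch, truth = tr,
           recording = synthesize_emg(tr, layout, cfg,
                                      exp_seeds[n_train + j] + 1L))
    })
    list(subject = subject, params = params, mixing = mixing,
         source_locations = locs, train = train, test = test)
  })
}

#' Generate a full synthetic dataset
#'
#' All subjects, all experiments, with ground truth.  Note that a dataset
#' at the full acquisition rate is large; for exploratory work reduce
#' `fs_raw`, the experiment counts or `n_subjects`, or generate one subject
#' at a time with [generate_subject()].
#'
#' @param cfg An [sim_config()].
#' @return An `ff_dataset`: list with `cfg`, `layout`, `mask`, `subjects`.
#' @export
make_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "ff_sim_config"))
  layout <- default_layout(cfg$n_channels)
  structure(list(cfg = cfg, layout = layout,
                 mask = default_channel_mask(layout),
                 subjects = lapply(seq_len(cfg$n_subjects), function(s)
                   generate_subject(cfg, s, layout))),
            class = "ff_dataset")
}
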