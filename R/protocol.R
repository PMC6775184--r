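#' Default options for the decoding pipeline
#'
#' @param band Band-pass edges in Hz (default 5--200).
#' @param fs_proc Processing rate after resampling (default 500 Hz; capped
#'   at the acquisition rate).
#' @param envelope_cutoff Envelope low-pass cut-off in Hz (default 3).
#' @param ica_components `"auto"` or an integer passed to [fit_ica()].
#' @param ica_seed,msm_seed Seeds for the ICA initialisation and the MSM
#'   optimizer restarts.
#' @param restarts MSM optimizer restarts (default 10).
#' @param fit_fs Rate (Hz) to which envelopes and targets are decimated for
#'   model fitting and evaluation; the envelopes are band-limited to
#'   ~3 Hz, so 25 Hz retains their full content while keeping the
#'   nonlinear fits fast (default 25).
#' @param traj_lp,traj_median Ground-truth smoothing: low-pass cut-off (Hz)
#'   and median window (s).
#' @param n_top Ranked IC candidates retained per selection (default 16).
#' @return Named list of options.
#' @export
pipeline_options <- function(band = c(5, 200), fs_proc = 500,
                             envelope_cutoff = 3, ica_components = "auto",
                             ica_seed = 1L, msm_seed = 1L, restarts = 10L,
                             fit_fs = 25, traj_lp = 1, traj_median = 0.5,
                             n_top = 16L) {
  list(band = band, fs_proc = fs_proc, envelope_cutoff = envelope_cutoff,
       ica_components = ica_components, ica_seed = ica_seed,
       msm_seed = msm_seed, restarts = restarts, fit_fs = fit_fs,
       traj_lp = traj_lp, traj_median = traj_median, n_top = n_top)
}

## Preprocess one experiment and derive everything the protocols need:
## channel envelopes, ground-truth trajectory, processed data for ICA.
process_experiment <- function(exp, cfg, opt) {
  fs_proc <- min(opt$fs_proc, cfg$fs_raw)
  proc <- rereference_average(exp$recording)
  proc <- bandpass_filter(proc, opt$band[1], opt$band[2])
  proc <- resample_signal(proc, fs_proc)
  m <- ncol(proc$data)
  idx <- pmin(ncol(exp$truth$nrmsd$values),
              floor((seq_len(m) - 1L) * cfg$fs_raw / fs_proc) + 1L)
  nr <- nrmsd_series(exp$truth$nrmsd$values[, idx, drop = FALSE], fs_proc)
  traj <- finger_angle_from_trigger(nr, exp$schedule)
  traj <- smooth_trajectory(traj, opt$traj_lp, opt$traj_median)
  env_ch <- remove_offset(emg_envelope(proc, cutoff = opt$envelope_cutoff),
                          cfg$calibration_len)
  list(id = exp$id, kind = exp$kind, finger = exp$finger,
       proc = proc, traj = traj, env_ch = env_ch)
}

concat_env <- function(envs) {
  out <- envs[[1L]]
  out$env <- do.call(cbind, lapply(envs, `[[`, "env"))
  out
}

concat_traj <- function(trajs) {
  finger_trajectory(do.call(cbind, lapply(trajs, `[[`, "angles")),
                    trajs[[1L]]$fs)
}

decimate_idx <- function(n, fs, fs_out) {
  k <- max(1L, round(fs / fs_out))
  seq(1L, n, by = k)
}

## Evaluate all methods for one subject under one protocol.
evaluate_subject <- function(sub, cfg, layout, mask, protocol, methods, opt) {
  pe <- lapply(c(sub$train, sub$test), process_experiment, cfg = cfg,
               opt = opt)
  kinds <- vapply(pe, `[[`, character(1), "kind")
  fs_proc <- pe[[1L]]$env_ch$fs

  ## ICA fitted once per subject on all experiments, concatenated
  X <- do.call(cbind, lapply(pe, function(e) e$proc$data))
  decomp <- fit_ica(X, n_components = opt$ica_components,
                    seed = opt$ica_seed, fs = fs_proc)
  env_ic <- lapply(pe, function(e) {
    src <- ica_sources(decomp, e$proc$data)
    remove_offset(emg_envelope(src, fs_proc, cutoff = opt$envelope_cutoff,
                               source_kind = "independent_component"),
                  cfg$calibration_len)
  })
  for (i in seq_along(pe)) pe[[i]]$proc <- NULL   # free the raw matrices

  test_i <- which(kinds == "test")
  if (protocol == "A") {
    sel_i <- which(kinds == "train")
    eval_i <- test_i
  } else {
    if (length(test_i) < 2L)
      stop("protocol B needs at least 2 test experiments")
    sel_i <- test_i[1L]
    eval_i <- test_i[-1L]
  }
  fit_i <- sel_i
  stopifnot(length(intersect(fit_i, eval_i)) == 0L)

  sel_env_ch <- concat_env(lapply(pe[sel_i], `[[`, "env_ch"))
  sel_env_ic <- concat_env(env_ic[sel_i])
  sel_traj <- concat_traj(lapply(pe[sel_i], `[[`, "traj"))

  selections <- list()
  for (f in .FINGERS) for (dir in c("flexion", "extension")) {
    selections[[paste(f, dir, "ch", sep = ".")]] <-
      select_channels(sel_env_ch, sel_traj, mask, f, dir, layout)
    selections[[paste(f, dir, "ic", sep = ".")]] <-
      rank_envelopes_by_cc(sel_env_ic, sel_traj, f, dir, decomp, layout,
                           opt$n_top)
  }

  u_series <- function(route, f, dir, i) {
    sel <- selections[[paste(f, dir, route, sep = ".")]]
    env <- if (route == "ch") pe[[i]]$env_ch else env_ic[[i]]
    env$env[match(sel$chosen, env$ids), ]
  }

  rows <- list()
  for (method in methods) {
    parts <- strsplit(method, "-")[[1L]]
    model <- parts[1L]
    route <- if (parts[2L] == "ICA") "ic" else "ch"
    for (f in .FINGERS) {
      gather <- function(is) {
        u1 <- unlist(lapply(is, function(i) u_series(route, f, "flexion", i)))
        u2 <- unlist(lapply(is, function(i) u_series(route, f, "extension", i)))
        th <- unlist(lapply(is, function(i) pe[[i]]$traj$angles[f, ]))
        d <- decimate_idx(length(th), fs_proc, opt$fit_fs)
        list(u1 = u1[d], u2 = u2[d], th = th[d])
      }
      ft <- gather(fit_i)
      ev <- gather(eval_i)
      fit <- if (model == "MSM")
        fit_msm(ft$u1, ft$u2, ft$th, restarts = opt$restarts,
                seed = opt$msm_seed)
      else fit_lrm(ft$u1, ft$u2, ft$th)
      pred <- predict_angle(fit, ev$u1, ev$u2)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sub$subject, finger = f, method = method,
        protocol = protocol,
        cc = as.numeric(correlation_coefficient(pred, ev$th)),
        rmse_deg = rmse(pred, ev$th) * 180 / pi,
        flex_id = selections[[paste(f, "flexion", route, sep = ".")]]$chosen,
        ext_id = selections[[paste(f, "extension", route, sep = ".")]]$chosen,
        n_eval = length(ev$th), stringsAsFactors = FALSE)
    }
  }
  list(rows = do.call(rbind, rows), selections = selections,
       ica_converged = decomp$converged)
}

#' Run a train/test evaluation protocol over a dataset
#'
#' Protocol A fits each finger's models on that subject's single-finger
#' train experiments and evaluates on all mixed-finger test experiments.
#' Protocol B fits on exactly one mixed test experiment and evaluates on
#' the remaining test experiments (the small-training-set regime).  Both
#' run every requested method: the musculoskeletal model (MSM) and linear
#' regression (LRM), each fed either the selected independent-component
#' envelopes (ICA) or the selected raw-channel envelopes (EMG).  Signal
#' selection uses the same experiments as model fitting; test data used
#' for evaluation never enters fitting.
#'
#' @param dataset An `ff_dataset` from [make_dataset()], or an
#'   [sim_config()] (subjects are then generated one at a time, which
#'   keeps memory flat).
#' @param protocol `"A"` (train-to-test) or `"B"` (one test experiment to
#'   the rest).
#' @param methods Subset of `c("MSM-ICA", "MSM-EMG", "LRM-ICA", "LRM-EMG")`.
#' @param options See [pipeline_options()].
#' @return An EvalTable data.frame with one row per (subject, finger,
#'   method): columns `subject`, `finger`, `method`, `protocol`, `cc`,
#'   `rmse_deg` (degrees), the selected flexor/extensor signal ids and the
#'   evaluation sample count.
#' @export
run_protocol <- function(dataset, protocol = c("A", "B"),
                         methods = c("MSM-ICA", "MSM-EMG",
                                     "LRM-ICA", "LRM-EMG"),
                         options = pipeline_options()) {
  protocol <- match.arg(protocol)
  methods <- match.arg(methods, c("MSM-ICA", "MSM-EMG", "LRM-ICA",
                                  "LRM-EMG"), several.ok = TRUE)
  opt <- utils::modifyList(pipeline_options(), options)
  if (inherits(dataset, "ff_sim_config")) {
    cfg <- dataset
    layout <- default_layout(cfg$n_channels)
    mask <- default_channel_mask(layout)
    get_subject <- function(s) generate_subject(cfg, s, layout)
    n_sub <- cfg$n_subjects
  } else {
    stopifnot(inherits(dataset, "ff_dataset"))
    cfg <- dataset$cfg
    layout <- dataset$layout
    mask <- dataset$mask
    get_subject <- function(s) dataset$subjects[[s]]
    n_sub <- length(dataset$subjects)
  }
  out <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    res <- evaluate_subject(get_subject(s), cfg, layout, mask, protocol,
                            methods, opt)
    out[[s]] <- res$rows
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab
}
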