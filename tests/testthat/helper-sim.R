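## Shared fixtures: all synthetic, generated in code at test time.

## A desk-scale configuration: reduced sampling rate and experiment counts,
## protocol structure (2 s phases, calibration, Thumb..Pinky order) intact.
tiny_cfg <- function(...) {
  args <- utils::modifyList(
    list(seed = 101L, n_subjects = 1L, fs_raw = 512, phase_len = 2,
         motions_per_train_exp = 2L, train_exps_per_finger = 1L,
         test_exps = 1L, cycles_per_test_exp = 5L, crosstalk = 0.1,
         snr_db = 10),
    list(...))
  do.call(sim_config, args)
}

## One cached simulated subject at snr 10 for the selection/pipeline tests.
.sim_cache <- new.env(parent = emptyenv())
cached_subject <- function() {
  if (is.null(.sim_cache$sub))
    .sim_cache$sub <- generate_subject(tiny_cfg(), 1L)
  .sim_cache$sub
}

## Random valid muscle parameters over generous ranges.
rand_params <- function() {
  msm_params(a = c(runif(1, 0.2, 2), -runif(1, 0.2, 2)),
             k0 = runif(2, 0.2, 2), k1 = runif(2, 0.05, 1),
             l0 = runif(2, 0.2, 2), l1 = runif(2, 0.05, 2))
}

## Cached preprocessed + ICA view of the cached subject (selection and
## acceptance tests share it).
processed_view <- function() {
  if (!is.null(.sim_cache$view)) return(.sim_cache$view)
  sub <- cached_subject()
  cfg <- tiny_cfg()
  opt <- pipeline_options(fs_proc = 128, ica_components = 12L, fit_fs = 16)
  pe <- lapply(c(sub$train, sub$test), fingerflex:::process_experiment,
               cfg = cfg, opt = opt)
  X <- do.call(cbind, lapply(pe, function(e) e$proc$data))
  decomp <- fit_ica(X, n_components = 12L, seed = 1L, fs = 128)
  env_ic <- remove_offset(
    emg_envelope(decomp$sources, 128, source_kind = "independent_component"),
    cfg$calibration_len)
  env_ch <- fingerflex:::concat_env(lapply(pe, `[[`, "env_ch"))
  traj <- fingerflex:::concat_traj(lapply(pe, `[[`, "traj"))
  .sim_cache$view <- list(sub = sub, cfg = cfg, decomp = decomp,
                          env_ic = env_ic, env_ch = env_ch, traj = traj,
                          pe = pe)
  .sim_cache$view
}
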