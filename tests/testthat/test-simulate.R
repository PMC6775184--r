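test_that("protocol generation matches the experimental design", {
  cfg <- sim_config()     # study defaults: 6 motions, 10 cycles, 2 s phases
  tr <- generate_protocol(cfg, "train", "Thumb")
  expect_equal(count_cycles(tr), 6L)
  ## each motion = flex/rest/ext/rest, 2 s each = 8 s
  motion <- tr[tr$start >= 4 & tr$end <= 12, ]
  expect_equal(motion$kind, c("flexion", "rest", "extension", "rest"))
  expect_equal(sum(motion$end - motion$start), 8)
  expect_true(all(tr$finger %in% c(NA, "Thumb")))
  expect_equal(schedule_duration(tr), 4 + 6 * 8)

  te <- generate_protocol(cfg, "test")
  expect_equal(count_cycles(te), 10L)
  expect_equal(as.vector(table(te$finger[te$kind == "flexion"])[finger_names()]),
               rep(2L, 5))
  ## trigger values are the three protocol constants
  expect_setequal(unique(tr$t_dir), c(0, 2.094, -0.523))

  expect_error(generate_protocol(cfg, "train", "Palm"), "finger")
  expect_error(generate_protocol(cfg, "train"), "finger")
  expect_error(sim_config(phase_len = 0), "phase_len")
})

test_that("activations are trapezoidal, baseline at rest, crosstalk-scaled", {
  cfg <- tiny_cfg(crosstalk = 0)
  rest_only <- phase_schedule(data.frame(start = 0, end = 6, kind = "rest",
                                         finger = NA_character_))
  act <- generate_activations(rest_only, cfg, 1)
  expect_true(all(act$u_flex == cfg$baseline))
  expect_true(all(act$u_ext == cfg$baseline))

  sch <- generate_protocol(cfg, "train", "Thumb")
  act <- generate_activations(sch, cfg, 1)
  others <- setdiff(finger_names(), "Thumb")
  expect_true(all(act$u_flex[others, ] == cfg$baseline))
  expect_true(all(act$u_ext[others, ] == cfg$baseline))
  expect_gt(max(act$u_flex["Thumb", ]), 0.8)
  expect_true(all(act$u_flex <= 1 & act$u_flex >= 0))

  ## crosstalk: adjacent finger's peak is exactly the configured fraction
  cfg2 <- tiny_cfg(crosstalk = 0.2, amp_jitter = 0)
  act2 <- generate_activations(sch, cfg2, 1)
  i_flex <- act2$u_flex["Thumb", ] > 0.5
  expect_equal(max(act2$u_flex["Index", i_flex]),
               0.2 * max(act2$u_flex["Thumb", i_flex]))
  ## determinism
  act3 <- generate_activations(sch, cfg2, 1)
  expect_identical(act2, act3)
})

test_that("simulated angles are the equilibrium of the true parameters", {
  sub <- cached_subject()
  for (exp in list(sub$train[[1]], sub$test[[1]])) {
    for (f in finger_names()) {
      u <- exp$truth$activations
      tau <- msm_torque(u$u_flex[f, ], u$u_ext[f, ],
                        exp$truth$angles[f, ], sub$params[[f]])
      expect_lt(max(abs(tau)), 1e-8)
    }
  }
  ## flexion peaks approach the trigger-consistent amplitude
  expect_gt(max(sub$train[[1]]$truth$angles["Thumb", ]), 0.8 * 2.094)
  expect_lt(min(sub$train[[1]]$truth$angles["Thumb", ]), 0.5 * -0.523)
})

test_that("synthesized recordings have the contracted shape and trigger", {
  sub <- cached_subject()
  cfg <- tiny_cfg()
  exp <- sub$train[[1]]
  n_expect <- round(schedule_duration(exp$schedule) * cfg$fs_raw)
  expect_equal(dim(exp$recording$data), c(96L, n_expect))
  expect_equal(exp$recording$fs, cfg$fs_raw)
  expect_equal(exp$recording$labels, default_layout()$label)
  ## trigger encodes phases sample-aligned: first flexion phase starts at
  ## floor(calibration * fs) + 1
  trig <- exp$recording$trigger
  i0 <- floor(cfg$calibration_len * cfg$fs_raw) + 1L
  expect_equal(trig[i0 - 1L], 0L)
  expect_equal(trig[i0], 11L)   # Thumb flexion code
  expect_equal(sum(trig == 11L) / cfg$fs_raw,
               cfg$phase_len * cfg$motions_per_train_exp, tolerance = 0.01)
})

test_that("sensor-noise scaling hits the requested SNR", {
  ## power-ratio oracle: same seed with noise disabled isolates the noise
  cfg_on <- tiny_cfg(motions_per_train_exp = 1L, snr_db = 7,
                     line_level = 0, artifact_level = 0)
  cfg_off <- tiny_cfg(motions_per_train_exp = 1L, snr_db = Inf,
                      line_level = 0, artifact_level = 0)
  lay <- default_layout()
  sub <- generate_subject(cfg_off, 1)
  exp <- sub$train[[1]]
  snr_est <- vapply(1:10, function(s) {
    clean <- synthesize_emg(exp$truth, lay, cfg_off, rng_seed = s)
    noisy <- synthesize_emg(exp$truth, lay, cfg_on, rng_seed = s)
    noise <- noisy$data - clean$data
    10 * log10(mean(clean$data^2) / mean(noise^2))
  }, numeric(1))
  expect_true(all(abs(snr_est - 7) < 1))
})

test_that("datasets are reproducible and subject-specific", {
  cfg <- tiny_cfg(n_subjects = 2L, motions_per_train_exp = 1L,
                  cycles_per_test_exp = 1L)
  s1 <- generate_subject(cfg, 1)
  s1b <- generate_subject(cfg, 1)
  expect_identical(s1$train[[1]]$recording$data,
                   s1b$train[[1]]$recording$data)
  s2 <- generate_subject(cfg, 2)
  expect_false(identical(s1$params$Thumb$l0, s2$params$Thumb$l0))
})

test_that("a default-structure dataset has 25 train experiments per subject", {
  ## acquisition rate reduced, protocol counts left at the study defaults
  cfg <- sim_config(seed = 5, n_subjects = 1L, fs_raw = 512,
                    motions_per_train_exp = 1L, cycles_per_test_exp = 1L,
                    test_exps = 1L)
  ds <- make_dataset(cfg)
  expect_length(ds$subjects, 1L)
  expect_length(ds$subjects[[1]]$train, 25L)
  fingers <- vapply(ds$subjects[[1]]$train, `[[`, character(1), "finger")
  expect_equal(as.vector(table(fingers)[finger_names()]), rep(5L, 5))
  ## Thumb -> Pinky blocks of 5
  expect_equal(fingers, rep(finger_names(), each = 5L))
})
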