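one_phase_schedule <- function(kind, dur = 2, finger = "Thumb") {
  phase_schedule(data.frame(start = 0, end = dur, kind = kind,
                            finger = if (kind == "rest") NA_character_
                                     else finger))
}

test_that("NRMSD is RMS joint displacement over finger length", {
  J <- 2; n <- 5
  calib <- list(Thumb = matrix(0, J, 2))
  mk <- function(disp) {
    pos <- array(0, c(n, J, 2))
    pos[, 1, 1] <- disp          # joint 1 displaced along x
    list(Thumb = pos)
  }
  expect_equal(compute_nrmsd(mk(0), calib, c(Thumb = 3), fs = 10)$values[1, ],
               rep(0, n))
  ## every joint displaced by exactly L -> 1
  pos <- array(0, c(n, J, 2)); pos[, , 1] <- 3
  expect_equal(compute_nrmsd(list(Thumb = pos), calib, c(Thumb = 3),
                             fs = 10)$values[1, ], rep(1, n))
  ## one of two joints displaced by d -> sqrt(d^2/2)/L
  d <- 1.2; L <- 3
  expect_equal(compute_nrmsd(mk(d), calib, c(Thumb = L), fs = 10)$values[1, ],
               rep(sqrt(d^2 / 2) / L, n))
  expect_error(compute_nrmsd(mk(1), calib, c(Thumb = 0), fs = 10), "> 0")
  calib_bad <- list(Thumb = matrix(0, 3, 2))
  expect_error(compute_nrmsd(mk(1), calib_bad, c(Thumb = 3), fs = 10),
               "joint count")
})

test_that("ground-truth angle is trigger times normalized displacement", {
  fs <- 100
  nr1 <- nrmsd_series(matrix(1, 1, 200, dimnames = list("Thumb")), fs)
  th_flex <- finger_angle_from_trigger(nr1, one_phase_schedule("flexion"))
  expect_equal(unique(th_flex$angles["Thumb", ]), 2.094)
  th_rest <- finger_angle_from_trigger(nr1, one_phase_schedule("rest"))
  expect_equal(unique(th_rest$angles["Thumb", ]), 0)
  nr05 <- nrmsd_series(matrix(0.5, 1, 200, dimnames = list("Thumb")), fs)
  th_ext <- finger_angle_from_trigger(nr05, one_phase_schedule("extension"))
  expect_equal(unique(th_ext$angles["Thumb", ]), -0.523 * 0.5)
  ## schedule must cover the series
  nr_long <- nrmsd_series(matrix(1, 1, 400, dimnames = list("Thumb")), fs)
  expect_error(finger_angle_from_trigger(nr_long,
                                         one_phase_schedule("flexion")),
               "cover")
})

test_that("angle sign always matches the trigger sign before smoothing", {
  cfg <- tiny_cfg()
  sch <- generate_protocol(cfg, "test")
  n <- round(schedule_duration(sch) * 64)
  nr <- nrmsd_series(matrix(runif(5 * n), 5, n,
                            dimnames = list(finger_names())), 64)
  traj <- finger_angle_from_trigger(nr, sch)
  for (f in finger_names()) {
    td <- fingerflex:::t_dir_series(sch, f, n, 64)
    expect_true(all(sign(traj$angles[f, td == 0]) == 0))
    expect_true(all(traj$angles[f, td > 0] >= 0))
    expect_true(all(traj$angles[f, td < 0] <= 0))
  }
})

test_that("trajectory smoothing removes spikes and high-frequency jitter", {
  fs <- 100
  const <- finger_trajectory(matrix(0.7, 1, 500, dimnames = list("Thumb")), fs)
  expect_equal(smooth_trajectory(const)$angles, const$angles,
               tolerance = 1e-9)
  ## single-sample spike is killed by the median filter
  spiky <- const
  spiky$angles[1, 250] <- 3
  sm <- smooth_trajectory(spiky)
  expect_lt(max(abs(sm$angles - 0.7)), 1e-3)
  ## 5 Hz jitter on a slow component attenuated >= 10 dB
  t <- seq(0, 5 - 1 / fs, by = 1 / fs)
  jit <- finger_trajectory(rbind(Thumb = 0.2 * sin(2 * pi * 5 * t)), fs)
  smj <- smooth_trajectory(jit)
  mid <- 150:350
  expect_lt(20 * log10(max(abs(smj$angles[1, mid])) / 0.2), -10)
  expect_error(smooth_trajectory(const, median_window = 10), "larger")
  expect_error(smooth_trajectory(const, median_window = 0.01), "3 samples")
})
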