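test_that("component ranking returns at most 16 unflagged-first candidates", {
  v <- processed_view()
  lay <- default_layout()
  sel <- rank_components_by_cc(v$decomp, v$traj, "Thumb", "flexion", lay)
  expect_lte(nrow(sel$candidates), 16L)
  expect_true(sel$chosen %in% sel$candidates$id)
  chosen_row <- sel$candidates[sel$candidates$id == sel$chosen, ]
  expect_false(chosen_row$motion_noise || chosen_row$detach)
  expect_true(all(abs(sel$candidates$cc) <= 1, na.rm = TRUE))
  ## ranked by |cc| among the returned list
  expect_true(all(diff(abs(sel$candidates$cc)) <= 1e-12))
})

test_that("a component matching the target exactly ranks first with cc 1", {
  v <- processed_view()
  lay <- default_layout()
  target <- pmax(v$traj$angles["Index", ], 0)
  decomp <- v$decomp
  ## plant the target as an extra source with a clean one-channel topology
  decomp$sources <- rbind(decomp$sources[1:3, , drop = FALSE],
                          planted = target)
  decomp$mixing <- cbind(decomp$mixing[, 1:3], planted = c(rep(0, 95), 1))
  decomp$retained_rank <- 4L
  sel <- fingerflex:::rank_envelopes_by_cc(
    emg_envelope(decomp$sources, v$traj$fs,
                 source_kind = "independent_component"),
    v$traj, "Index", "flexion", decomp, lay, 16L)
  expect_equal(sel$candidates$component[1], 4L)
  expect_gt(sel$candidates$cc[1], 0.99)
})

test_that("equal-correlation ties resolve to the lower component index", {
  lay <- default_layout()
  target <- c(rep(0, 50), burst <- seq(0, 1, length.out = 50))
  src <- rbind(target, target, 0.5 * target)   # identical cc
  decomp <- structure(list(
    sources = src, retained_rank = 3L,
    mixing = cbind(c(1, rep(0, 95)), c(0, 1, rep(0, 94)),
                   c(0, 0, 1, rep(0, 93))),
    unmixing = matrix(0, 3, 96), center = numeric(96), fs = 10),
    class = "ff_ica")
  traj <- finger_trajectory(
    matrix(rep(target, 5), 5, byrow = TRUE,
           dimnames = list(finger_names())), 10)
  sel <- rank_components_by_cc(decomp, traj, "Thumb", "flexion", lay)
  expect_equal(sel$chosen, "IC1")
})

test_that("channel selection is mask-restricted and finds planted channels", {
  v <- processed_view()
  lay <- default_layout()
  mask <- default_channel_mask(lay)
  ## the generator plants each muscle at its mask-block centre, so the
  ## selected channel must fall inside the finger's own block
  for (f in finger_names()) {
    sel <- select_channels(v$env_ch, v$traj, mask, f, "flexion", lay)
    expect_true(sel$chosen %in% mask_labels(mask, f, "flexion"))
    expect_gt(abs(sel$candidates$cc[1]), 0.8)
  }
  ## single-channel mask returns that channel regardless of correlation
  m1 <- mask[mask$finger == "Thumb" & mask$direction == "flexion", ][1, ]
  class(m1) <- class(mask)
  sel1 <- select_channels(v$env_ch, v$traj, m1, "Thumb", "flexion", lay)
  expect_equal(sel1$chosen, m1$label)
  expect_error(select_channels(v$env_ch, v$traj, m1, "Ring", "flexion", lay),
               "Ring")
})

test_that("selection is invariant to positive rescaling of envelopes", {
  v <- processed_view()
  lay <- default_layout()
  mask <- default_channel_mask(lay)
  scaled <- v$env_ch
  scaled$env <- scaled$env * 37.5
  s1 <- select_channels(v$env_ch, v$traj, mask, "Middle", "extension", lay)
  s2 <- select_channels(scaled, v$traj, mask, "Middle", "extension", lay)
  expect_equal(s1$chosen, s2$chosen)
  expect_equal(s1$candidates$cc, s2$candidates$cc)
})
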