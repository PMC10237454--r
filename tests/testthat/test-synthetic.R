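test_that("recorded true speeds are consistent with the trajectory itself", {
  gt <- simulate_trajectory(trial_config())
  b <- gt$boundary_frames
  comps <- c("y", rep("x", 7), "y")
  for (k in 1:9) {
    # independent oracle: arc length of finely sampled *positions* / duration
    tt <- seq(b[k] / gt$fps, b[k + 1] / gt$fps,
              length.out = (b[k + 1] - b[k]) * 1000L + 1L)
    pos <- gt$eval(tt)
    p <- if (comps[k] == "x") pos$x else pos$y
    oracle <- sum(abs(diff(p))) / (tt[length(tt)] - tt[1])
    expect_equal(unname(gt$true_speeds[k]), oracle, tolerance = 1e-6)
  }
})

test_that("scripted phases behave as configured", {
  cfg <- trial_config(walk_out_speed_ms = 1.0, walk_back_speed_ms = 1.0)
  gt <- simulate_trajectory(cfg)
  fr <- gt$frames
  # V3 covers the cruise: scripted speed exactly
  expect_equal(unname(gt$true_speeds["V3"]), 1.0, tolerance = 1e-9)
  # phase labels tile the sync window
  inside <- fr$phase[fr$frame >= gt$sync$start_frame &
                       fr$frame < gt$sync$stop_frame]
  expect_true(all(inside %in% paste0("V", 1:9)))
  expect_equal(unique(fr$phase[fr$frame < gt$sync$start_frame]), "pre")
  # x stays on the walkway and y between seated and standing (plus bob)
  expect_true(all(fr$x_m >= 0 & fr$x_m <= cfg$x_turn_m + 1e-9))
  expect_true(all(fr$y_m >= cfg$y_seated_m - 1e-9 &
                    fr$y_m <= cfg$y_stand_m + cfg$gait_bob_m + 1e-9))
  expect_error(trial_config(ramp_s = 10), "ramps longer")
})

test_that("rendered silhouette centroid matches the analytic centroid", {
  cfg <- quick_config(sp_noise_rate = 0)
  gt <- simulate_trajectory(cfg)
  vid <- render_video(gt)
  idx <- round(seq(1, gt$n_frames, length.out = 12))
  for (i in idx) {
    mask <- subtract_and_threshold(vid$frame(i), vid$background, 50)
    ct <- silhouette_centroid(mask)
    expect_true(ct$valid)
    expect_lt(abs(ct$u_px - vid$centroid_px$u_px[i]), 0.51)
    expect_lt(abs(ct$v_px - vid$centroid_px$v_px[i]), 0.51)
  }
  # a background-only frame yields an empty mask
  empty <- subtract_and_threshold(vid$background, vid$background, 50)
  expect_false(silhouette_centroid(median_denoise(empty))$valid)
})

test_that("rendering is deterministic given the seed", {
  cfg <- quick_config(seed = 42L)  # default noise on
  gt <- simulate_trajectory(cfg)
  v1 <- render_video(gt); v2 <- render_video(gt)
  expect_identical(v1$frame(100), v2$frame(100))
  # evaluation order does not matter
  v3 <- render_video(gt)
  f200 <- v3$frame(200)
  expect_identical(v3$frame(100), v1$frame(100))
  expect_identical(f200, v2$frame(200))
  # different seed, different noise
  gt_b <- simulate_trajectory(quick_config(seed = 43L))
  expect_false(identical(render_video(gt_b)$frame(100), v1$frame(100)))
})

test_that("four-marker mean recovers the COM; noise averages down", {
  cfg <- trial_config(mocap_noise_sd_m = 0)
  gt <- simulate_trajectory(cfg)
  mc <- simulate_mocap(gt, cfg)
  com <- com_mocap(mc)
  t <- (seq_len(nrow(com)) - 1) / cfg$fs_mocap
  truth <- gt$eval(t)
  expect_equal(com$x, truth$x, tolerance = 1e-12)
  expect_equal(com$y, truth$y, tolerance = 1e-12)
  expect_equal(com$z, rep(0, nrow(com)), tolerance = 1e-12)

  # with sd = 2 mm per marker the 4-marker mean has RMS error ~ sd/2
  cfg_n <- trial_config(mocap_noise_sd_m = 0.002, seed = 5L)
  mc_n <- simulate_mocap(simulate_trajectory(cfg_n), cfg_n)
  com_n <- com_mocap(mc_n)
  rms <- sqrt(mean((com_n$x - truth$x)^2))
  expect_equal(rms, 0.002 / 2, tolerance = 0.1)
})

test_that("simulate_paired honours rho, seed and marginals", {
  expect_error(simulate_paired(1.5, 10), "rho")
  expect_error(simulate_paired(0.5, 2), "n must be")

  perfect <- simulate_paired(1, 20, sd_a = 0.1, sd_b = 0.2, seed = 3)
  expect_equal(cor(perfect$value_a, perfect$value_b), 1, tolerance = 1e-12)

  null <- simulate_paired(0, 1e5, seed = 11)
  expect_lt(abs(cor(null$value_a, null$value_b)), 0.01)

  t1 <- simulate_paired(0.7, 50, seed = 21)
  t2 <- simulate_paired(0.7, 50, seed = 21)
  expect_identical(t1, t2)
})
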