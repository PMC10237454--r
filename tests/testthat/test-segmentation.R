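# Segmentation tests run on analytic tracks (ideal tracker), so boundary
# errors reflect the detection rules alone.

test_that("all boundary detectors agree with the scripted ground truth", {
  gt <- simulate_trajectory(trial_config())
  tr <- gt_track(gt)
  b <- gt$boundary_frames
  params <- seg_params()

  expect_lte(abs(detect_stand_complete(tr, gt$sync, params) -
                   b[["stand_complete"]]), 2)
  expect_lte(abs(detect_sit_begin(tr, gt$sync, params) - b[["sit_begin"]]), 2)
  turn <- detect_turn(tr, params, gt$sync)
  expect_lte(abs(turn$turn_start - b[["turn_start"]]), 2)
  expect_lte(abs(turn$turn_end + 1L - b[["turn_end_excl"]]), 2)
  cr <- detect_meter_crossings(tr, sync = gt$sync)
  expect_lte(abs(cr$outbound[[1]] - b[["out1"]]), 1)
  expect_lte(abs(cr$outbound[[2]] - b[["out2"]]), 1)
  expect_lte(abs(cr$inbound[[1]] - b[["in2"]]), 1)
  expect_lte(abs(cr$inbound[[2]] - b[["in1"]]), 1)
})

test_that("the nine intervals tile the sync window for varied tempos", {
  for (c_tempo in c(0.9, 1.0, 1.25)) {
    gt <- simulate_trajectory(tempo_config(c_tempo))
    tr <- gt_track(gt)
    seg <- segment_tug(tr, gt$sync)
    expect_equal(nrow(seg), 9L)
    expect_equal(seg$label, paste0("V", 1:9))
    expect_equal(seg$start_frame[1], gt$sync$start_frame)
    expect_equal(seg$end_frame[9], gt$sync$stop_frame)
    expect_equal(seg$start_frame[-1], seg$end_frame[-9])  # no gaps/overlaps
    expect_true(all(seg$end_frame - seg$start_frame >= 2))
  }
})

test_that("subtask means match the scripted speeds and obey symmetry", {
  cfg <- trial_config(walk_back_speed_ms = 1.1)  # symmetric out/back
  gt <- simulate_trajectory(cfg)
  tr <- gt_track(gt)
  seg <- segment_tug(tr, gt$sync)
  sp <- instantaneous_speed(tr)
  v <- mean_subtask_speeds(seg, sp)
  expect_equal(v$mean_speed_ms, unname(gt$true_speeds), tolerance = 0.05)
  # symmetric trials: outbound metre segments mirror the return ones
  expect_equal(v$mean_speed_ms[3], v$mean_speed_ms[7], tolerance = 0.03)
  expect_equal(v$mean_speed_ms[4], v$mean_speed_ms[6], tolerance = 0.03)
  expect_equal(v$mean_speed_ms[2], v$mean_speed_ms[8], tolerance = 0.12)
})

test_that("scaling the trial tempo scales the walking speeds proportionally", {
  base <- simulate_trajectory(tempo_config(1))
  vb <- mean_subtask_speeds(segment_tug(gt_track(base), base$sync),
                            instantaneous_speed(gt_track(base)))
  for (c_tempo in c(1.3)) {
    fast <- simulate_trajectory(tempo_config(c_tempo))
    vf <- mean_subtask_speeds(segment_tug(gt_track(fast), fast$sync),
                              instantaneous_speed(gt_track(fast)))
    expect_equal(vf$mean_speed_ms[2:8], c_tempo * vb$mean_speed_ms[2:8],
                 tolerance = 0.05)
  }
})

test_that("degenerate inputs raise segmentation errors", {
  gt <- simulate_trajectory(trial_config())
  tr <- gt_track(gt)
  expect_error(sync_events(500, 100), "start_frame")

  # monotone outbound walk with no return
  half <- tr[tr$frame <= gt$boundary_frames[["turn_start"]], ]
  class(half) <- class(tr); attr(half, "fps") <- attr(tr, "fps")
  expect_error(detect_turn(half, seg_params()), "no walk back|overlaps")

  # never reaches the far mark
  stub <- tr[tr$x_m < 1.5, ]
  class(stub) <- class(tr); attr(stub, "fps") <- attr(tr, "fps")
  expect_error(detect_meter_crossings(stub), "never reaches")

  # walkway mapped to the vertical axis: nothing to segment
  flipped <- centroid_track(tr$frame, tr$y_m, tr$x_m, fps = attr(tr, "fps"))
  expect_error(segment_tug(flipped, gt$sync), "segmentation failure")
})

test_that("an instant turn still yields a margin-wide interval", {
  # triangle-wave excursion: up at 1 m/s, down at 1 m/s, apex 2.6 m
  fps <- 60
  up <- seq(0, 2.6, by = 1 / fps)
  x <- c(up, rev(up)[-1])
  n <- length(x)
  y <- c(seq(0.6, 0.9, length.out = 40), rep(0.9, n - 80),
         seq(0.9, 0.6, length.out = 40))
  tr <- centroid_track(seq_len(n) - 1L, x, y, fps = fps)
  turn <- detect_turn(tr, seg_params())
  # 0.2 m margin at 1 m/s covers 0.2 s = 12 frames on each side of the apex
  apex <- which.max(x) - 1L
  expect_lte(abs((apex - turn$turn_start) / fps - 0.2), 0.04)
  expect_lte(abs((turn$turn_end - apex) / fps - 0.2), 0.04)
})
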