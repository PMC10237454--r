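random_track <- function(n = 200, fs = 120) {
  set.seed(77)
  df <- as.data.frame(matrix(rnorm(n * 12, 1, 0.3), n, 12))
  names(df) <- as.vector(outer(c("R_ASIS", "L_ASIS", "R_PSIS", "L_PSIS"),
                               c("x", "y", "z"), paste, sep = "_"))
  marker_track_3d(df, fs = fs)
}

test_that("butterworth gain matches the design at key frequencies", {
  fs <- 120
  t <- (0:(10 * fs - 1)) / fs
  flat <- marker_track_3d(
    as.data.frame(setNames(rep(list(rep(2.5, length(t))), 12),
                           names(random_track()))), fs = fs)
  expect_equal(as.data.frame(butterworth_lowpass(flat)),
               as.data.frame(flat), tolerance = 1e-9)  # DC gain 1

  co <- butter_coeffs(4, 6, fs)
  amp <- function(f_hz) {
    x <- sin(2 * pi * f_hz * t)
    y <- filtfilt_ba(co$b, co$a, x)
    core <- seq(fs, length(t) - fs)  # ignore edges
    max(abs(y[core]))
  }
  expect_gte(amp(1), 0.99)    # passband preserved within 1%
  expect_lte(amp(30), 0.05)   # stopband attenuated > 95%

  expect_error(butter_coeffs(4, 60, 120), "cutoff")
  expect_error(butterworth_lowpass(random_track(), cutoff_hz = 80), "cutoff")
})

test_that("pelvis COM is the marker mean, linear under translation", {
  sq <- data.frame(R_ASIS_x = 2, L_ASIS_x = 0, R_PSIS_x = 2, L_PSIS_x = 0,
                   R_ASIS_y = 0, L_ASIS_y = 2, R_PSIS_y = 2, L_PSIS_y = 0,
                   R_ASIS_z = 1, L_ASIS_z = 1, R_PSIS_z = 1, L_PSIS_z = 1)
  com <- com_mocap(marker_track_3d(sq))
  expect_equal(unlist(com[1, ]), c(x = 1, y = 1, z = 1))

  tk <- random_track()
  com0 <- com_mocap(tk)
  # brute-force mean oracle on a few frames
  for (i in c(1, 50, 200)) {
    expect_equal(com0$x[i],
                 (tk$R_ASIS_x[i] + tk$L_ASIS_x[i] + tk$R_PSIS_x[i] +
                    tk$L_PSIS_x[i]) / 4, tolerance = 1e-12)
  }
  shifted <- tk
  for (ax in c("x", "y", "z"))
    shifted[paste0(c("R_ASIS", "L_ASIS", "R_PSIS", "L_PSIS"), "_", ax)] <-
      shifted[paste0(c("R_ASIS", "L_ASIS", "R_PSIS", "L_PSIS"), "_", ax)] +
      c(x = 0.5, y = -1, z = 2)[[ax]]
  com1 <- com_mocap(marker_track_3d(as.data.frame(shifted)))
  expect_equal(com1$x, com0$x + 0.5, tolerance = 1e-12)
  expect_equal(com1$y, com0$y - 1, tolerance = 1e-12)
  expect_equal(com1$z, com0$z + 2, tolerance = 1e-12)

  expect_error(marker_track_3d(sq[-1]), "missing marker")
})

test_that("filtering and averaging commute (both linear)", {
  tk <- random_track(400)
  a <- com_mocap(butterworth_lowpass(tk))
  b <- as.data.frame(com_mocap(tk))
  co <- butter_coeffs(4, 6, 120)
  b[] <- lapply(b, function(col) filtfilt_ba(co$b, co$a, col))
  expect_equal(as.data.frame(a), b, tolerance = 1e-10)
})

test_that("mocap subtask speeds recover the shared ground truth", {
  cfg <- quick_config(mocap_noise_sd_m = 0)
  gt <- simulate_trajectory(cfg)
  mc <- simulate_mocap(gt, cfg)
  res <- tug_mocap(mc, sync_at(gt, cfg$fs_mocap))
  expect_equal(res$speeds$mean_speed_ms, unname(gt$true_speeds),
               tolerance = 0.05)
  # axis misconfiguration: walkway mapped to "up"
  com <- com_mocap(butterworth_lowpass(mc))
  expect_error(mocap_subtask_speeds(com, sync_at(gt, cfg$fs_mocap),
                                    forward_axis = "y", up_axis = "x"),
               "segmentation failure")
  expect_error(mocap_subtask_speeds(com, sync_at(gt, cfg$fs_mocap),
                                    forward_axis = "x", up_axis = "x"),
               "distinct")
})

test_that("marker CSV round-trips, including millimetre input", {
  tk <- random_track(50)
  p <- withr::local_tempfile(fileext = ".csv")
  write.csv(as.data.frame(tk), p, row.names = FALSE)
  back <- read_marker_csv(p, fs = 120)
  expect_equal(as.data.frame(back), as.data.frame(tk), tolerance = 1e-12)
  mm <- as.data.frame(tk); mm[] <- lapply(mm, function(c) c * 1000)
  write.csv(mm, p, row.names = FALSE)
  back_mm <- read_marker_csv(p, fs = 120, units = "mm")
  expect_equal(as.data.frame(back_mm), as.data.frame(tk), tolerance = 1e-9)
})
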