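# Shared fixtures, built in code at test time.

# Mid-resolution camera (480x270, 8.33 mm/px): accurate enough for
# end-to-end checks at roughly half the cost of the full 640x360 render.
quick_config <- function(...) {
  trial_config(img_w = 480, img_h = 270, m_per_px = 1 / 120,
               origin_u_px = 60, floor_v_px = 250, ...)
}

# Tiny camera (192x108, 20 mm/px) for disk-roundtrip CLI tests.
tiny_config <- function(...) {
  trial_config(img_w = 192, img_h = 108, m_per_px = 0.02,
               origin_u_px = 20, floor_v_px = 95, ...)
}

# Analytic centroid track of a ground truth: what an ideal (noise- and
# quantization-free) tracker would produce. Lets segmentation tests skip
# the renderer entirely.
gt_track <- function(gt) {
  centroid_track(gt$frames$frame, gt$frames$x_m, gt$frames$y_m, fps = gt$fps)
}

# A trial whose overall tempo is scaled by `c`: speeds times c, durations
# times 1/c (the fast-condition analogue).
tempo_config <- function(c = 1, make = trial_config, ...) {
  make(walk_out_speed_ms = 1.1 * c, walk_back_speed_ms = 1.05 * c,
       sit_to_stand_s = 1.2 / c, stand_to_sit_s = 1.3 / c,
       turn_s = 0.8 / c, ramp_s = 0.35 / c, ...)
}

# Renders a rigid blob (0.3 m x 0.5 m rectangle, centre height 0.9 m)
# translating at constant speed v from x0; returns a lazy frame source plus
# the geometry. 320x180 at 12.5 mm/px.
blob_source <- function(v, x0 = 0.2, x1 = 2.8, fps = 60,
                        mpp = 0.0125, w = 320, h = 180,
                        origin_u = 40, floor_v = 150) {
  n <- floor((x1 - x0) / v * fps) + 1L
  bg <- matrix(20, h, w)
  frame_fun <- function(i) {
    x <- x0 + v * (i - 1) / fps
    f <- bg
    c0 <- ceiling(origin_u + (x - 0.15) / mpp)
    c1 <- floor(origin_u + (x + 0.15) / mpp)
    r0 <- ceiling(floor_v - 1.15 / mpp)
    r1 <- floor(floor_v - 0.65 / mpp)
    f[(r0:r1) + 1L, (c0:c1) + 1L] <- 220
    f
  }
  model <- calibration_model(mpp, mpp, origin_u, floor_v)
  list(frame = frame_fun, n_frames = n, background = bg, model = model,
       fps = fps, mpp = mpp)
}

# Independent hand-ANOVA oracle for the ICC tests: explicit elementwise sums,
# no matrix shortcuts shared with the implementation.
hand_icc3k <- function(a, b) {
  m <- cbind(a, b)
  n <- nrow(m); k <- ncol(m)
  grand <- sum(m) / (n * k)
  ssr <- 0
  for (i in seq_len(n)) {
    ri <- sum(m[i, ]) / k
    ssr <- ssr + k * (ri - grand)^2
  }
  ssc <- 0
  for (j in seq_len(k)) {
    cj <- sum(m[, j]) / n
    ssc <- ssc + n * (cj - grand)^2
  }
  sst <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) sst <- sst + (m[i, j] - grand)^2
  msr <- unname(ssr / (n - 1))
  mse <- unname((sst - ssr - ssc) / ((n - 1) * (k - 1)))
  list(icc = (msr - mse) / msr, msr = msr, mse = mse)
}
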