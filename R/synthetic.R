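#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state, so seeded sub-streams (per-frame
#' video noise, mocap noise) are reproducible independently of call order.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Counter-based sub-seed: mixes the trial seed with a purpose tag and index,
# staying below 2^31.
.sub_seed <- function(seed, purpose, i = 0L) {
  as.integer((as.numeric(seed) * 2654435 + purpose * 97003 + i * 7919) %%
               2147483647)
}

#' Configuration of a synthetic TUG trial
#'
#' Describes one rendered trial: the scripted movement (phase durations and
#' speeds), the body silhouette, the camera geometry, the sampling rates and
#' the noise levels. Defaults describe a comfortable-pace trial of an older
#' adult on a 3 m walkway filmed at 60 Hz.
#'
#' @param sit_to_stand_s,stand_to_sit_s chair transfer durations (s).
#' @param walk_out_speed_ms,walk_back_speed_ms cruise walking speeds (m/s).
#' @param turn_s dwell duration at the turn mark (s).
#' @param ramp_s gait acceleration/deceleration ramp (s).
#' @param x_turn_m peak forward excursion of the body centroid (m); below 3 m
#'   because the centroid stays behind the toes at the turn mark.
#' @param seated_x_offset_m forward shift of the seated centroid caused by
#'   the horizontal thighs (m).
#' @param x_home_m centroid position when standing back at the chair (m).
#' @param y_seated_m,y_stand_m centroid heights seated and standing (m).
#' @param gait_bob_m,bob_hz amplitude (m) and frequency (Hz) of the vertical
#'   gait oscillation while on foot.
#' @param body_w_m silhouette torso width (m).
#' @param body_h_stand_m,body_h_seated_m silhouette rectangle heights (m).
#' @param head_r_m head disc radius (m).
#' @param img_w,img_h rendered frame size in pixels.
#' @param m_per_px metres per pixel (both axes).
#' @param origin_u_px,floor_v_px pixel column of the chair-side walkway
#'   marker and pixel row of the floor.
#' @param fps_video video frame rate (Hz).
#' @param fs_mocap marker sampling rate (Hz).
#' @param sp_noise_rate fraction of pixels per frame replaced by
#'   salt-and-pepper noise.
#' @param mocap_noise_sd_m Gaussian noise SD on each marker coordinate (m).
#' @param asis_ap_m,lateral_m marker offsets from the pelvis centre:
#'   anteroposterior and lateral (m).
#' @param lead_s,tail_s seated padding before the start and after the stop (s).
#' @param bg_level,body_level,marker_level grayscale intensities (0-255).
#' @param marker_px_r marker dot radius in pixels.
#' @param seed integer seed fixing all randomness of the trial.
#' @return An object of class `trial_config`.
#' @export
trial_config <- function(sit_to_stand_s = 1.2, stand_to_sit_s = 1.3,
                         walk_out_speed_ms = 1.1, walk_back_speed_ms = 1.05,
                         turn_s = 0.8, ramp_s = 0.35,
                         x_turn_m = 2.85, seated_x_offset_m = 0.08,
                         x_home_m = 0.02,
                         y_seated_m = 0.62, y_stand_m = 0.90,
                         gait_bob_m = 0.015, bob_hz = 1.8,
                         body_w_m = 0.38, body_h_stand_m = 1.62,
                         body_h_seated_m = 0.95, head_r_m = 0.10,
                         img_w = 640, img_h = 360, m_per_px = 0.00625,
                         origin_u_px = 80, floor_v_px = 330,
                         fps_video = 60, fs_mocap = 120,
                         sp_noise_rate = 0.002, mocap_noise_sd_m = 0.002,
                         asis_ap_m = 0.10, lateral_m = 0.12,
                         lead_s = 0.5, tail_s = 0.5,
                         bg_level = 30, body_level = 200, marker_level = 255,
                         marker_px_r = 2, seed = 1L) {
  cfg <- as.list(environment())
  pos <- c("sit_to_stand_s", "stand_to_sit_s", "walk_out_speed_ms",
           "walk_back_speed_ms", "turn_s", "ramp_s", "x_turn_m",
           "y_seated_m", "y_stand_m", "body_w_m", "body_h_stand_m",
           "body_h_seated_m", "head_r_m", "img_w", "img_h", "m_per_px",
           "fps_video", "fs_mocap", "lead_s", "tail_s")
  for (nm in pos) if (cfg[[nm]] <= 0) stop("invalid config: ", nm, " must be positive")
  if (cfg$y_stand_m <= cfg$y_seated_m)
    stop("invalid config: standing centroid must be above seated centroid")
  cruise_out <- cfg$x_turn_m - 0 - cfg$walk_out_speed_ms * cfg$ramp_s
  cruise_back <- cfg$x_turn_m - cfg$x_home_m - cfg$walk_back_speed_ms * cfg$ramp_s
  if (cruise_out <= 0 || cruise_back <= 0)
    stop("invalid config: ramps longer than the walkway")
  far_u <- cfg$origin_u_px + 3 / cfg$m_per_px
  if (far_u >= cfg$img_w || cfg$floor_v_px >= cfg$img_h)
    stop("invalid config: walkway does not fit the rendered frame")
  structure(cfg, class = "trial_config")
}

#' Scene marker set implied by a trial configuration
#'
#' M2 at the chair end of the walkway, M1 3 m further, M3 on the floor by the
#' chair and M4 0.5 m above it.
#'
#' @param config a [trial_config()].
#' @return A [marker_set()].
#' @export
config_markers <- function(config) {
  mpp <- config$m_per_px
  marker_set(
    m1_px = c(config$origin_u_px + 3 / mpp, config$floor_v_px),
    m2_px = c(config$origin_u_px, config$floor_v_px),
    m3_px = c(config$origin_u_px - 16, config$floor_v_px),
    m4_px = c(config$origin_u_px - 16, config$floor_v_px - 0.5 / mpp),
    dist_x_m = 3.0, dist_y_m = 0.5,
    frame_dim = c(config$img_w, config$img_h)
  )
}

# smoothstep and its derivative on u in [0, 1]
.ss <- function(u) 3 * u^2 - 2 * u^3
.ss_d <- function(u) 6 * u * (1 - u)

# Envelope fading in/out over `e` seconds at the ends of [0, L].
.env <- function(s, L, e) {
  u1 <- pmin(pmax(s / e, 0), 1)
  u2 <- pmin(pmax((L - s) / e, 0), 1)
  .ss(u1) * .ss(u2)
}
.env_d <- function(s, L, e) {
  u1 <- pmin(pmax(s / e, 0), 1)
  u2 <- pmin(pmax((L - s) / e, 0), 1)
  d1 <- ifelse(s > 0 & s < e, .ss_d(u1) / e, 0)
  d2 <- ifelse(s > L - e & s < L, -.ss_d(u2) / e, 0)
  d1 * .ss(u2) + .ss(u1) * d2
}

#' Simulate the ground-truth trajectory of a TUG trial
#'
#' Builds the piecewise-smooth centre-of-mass path of a scripted trial:
#' seated hold, smoothstep rise, cosine-ramped walk to the turn mark, dwell,
#' ramped walk back, smoothstep descent, seated hold. Vertical gait bob is
#' superimposed while the subject is on foot. The scripted phase boundaries
#' (frames), per-frame phase labels and true subtask mean speeds (time
#' average of the analytic |velocity| over each phase) are recorded.
#'
#' Boundary frames follow the same geometric rules the segmentation module
#' applies (standing-height threshold, metre-mark sign change assigned to the
#' later frame, peak-excursion margin), evaluated on the analytic path, so
#' they are the frames an ideal tracker would report.
#'
#' @param config a [trial_config()].
#' @param params a [seg_params()] fixing the boundary rules of the recorded
#'   ground truth.
#' @return An object of class `tug_ground_truth`: list with `config`,
#'   `frames` (data.frame `frame`, `t_s`, `x_m`, `y_m`, `phase`), `sync`
#'   ([sync_events()] in video frames), `boundary_frames` (named length-10
#'   integer vector), `true_speeds` (named `V1`..`V9`), `y_stand`, `fps`,
#'   `n_frames`, and `eval(t)` returning `x`, `y`, `vx`, `vy` at arbitrary
#'   times.
#' @export
simulate_trajectory <- function(config = trial_config(), params = seg_params()) {
  stopifnot(inherits(config, "trial_config"))
  cf <- config
  v1 <- cf$walk_out_speed_ms; v2 <- cf$walk_back_speed_ms
  r <- cf$ramp_s
  d_out <- cf$x_turn_m; d_back <- cf$x_turn_m - cf$x_home_m
  t_rise0 <- cf$lead_s
  t_rise1 <- t_rise0 + cf$sit_to_stand_s
  T_out <- 2 * r + (d_out - v1 * r) / v1
  t_turn0 <- t_rise1 + T_out
  t_turn1 <- t_turn0 + cf$turn_s
  T_back <- 2 * r + (d_back - v2 * r) / v2
  t_desc0 <- t_turn1 + T_back
  t_desc1 <- t_desc0 + cf$stand_to_sit_s
  t_end <- t_desc1 + cf$tail_s

  dy <- cf$y_stand_m - cf$y_seated_m
  bobL <- t_desc0 - t_rise1   # on-foot span carrying the gait bob

  # piecewise x(t): out and back as ramp/cruise/ramp in local time
  x_walk <- function(s, v, d) {
    cr <- (d - v * r) / v
    ifelse(s <= 0, 0,
    ifelse(s < r, v * (s / 2 - r / (2 * pi) * sin(pi * s / r)),
    ifelse(s < r + cr, v * r / 2 + v * (s - r),
    ifelse(s < 2 * r + cr, {
      u <- s - r - cr
      d - v * r / 2 + v * (u / 2 + r / (2 * pi) * sin(pi * u / r))
    }, d))))
  }
  vx_walk <- function(s, v, d) {
    cr <- (d - v * r) / v
    ifelse(s <= 0 | s >= 2 * r + cr, 0,
    ifelse(s < r, v * (1 - cos(pi * s / r)) / 2,
    ifelse(s < r + cr, v,
           v * (1 + cos(pi * (s - r - cr) / r)) / 2)))
  }

  eval_xy <- function(t) {
    x <- numeric(length(t)); vx <- numeric(length(t))
    y <- numeric(length(t)); vy <- numeric(length(t))

    seated <- t < t_rise0
    x[seated] <- cf$seated_x_offset_m; y[seated] <- cf$y_seated_m

    i <- t >= t_rise0 & t < t_rise1
    u <- (t[i] - t_rise0) / cf$sit_to_stand_s
    y[i] <- cf$y_seated_m + dy * .ss(u)
    vy[i] <- dy * .ss_d(u) / cf$sit_to_stand_s
    x[i] <- cf$seated_x_offset_m * (1 - .ss(u))
    vx[i] <- -cf$seated_x_offset_m * .ss_d(u) / cf$sit_to_stand_s

    i <- t >= t_rise1 & t < t_turn0
    x[i] <- x_walk(t[i] - t_rise1, v1, d_out)
    vx[i] <- vx_walk(t[i] - t_rise1, v1, d_out)

    i <- t >= t_turn0 & t < t_turn1
    x[i] <- cf$x_turn_m

    i <- t >= t_turn1 & t < t_desc0
    x[i] <- cf$x_turn_m - x_walk(t[i] - t_turn1, v2, d_back)
    vx[i] <- -vx_walk(t[i] - t_turn1, v2, d_back)

    onfoot <- t >= t_rise1 & t < t_desc0
    s <- t[onfoot] - t_rise1
    e <- min(0.3, bobL / 2)
    bob <- cf$gait_bob_m * sin(2 * pi * cf$bob_hz * s)
    bob_d <- cf$gait_bob_m * 2 * pi * cf$bob_hz * cos(2 * pi * cf$bob_hz * s)
    env <- .env(s, bobL, e); env_d <- .env_d(s, bobL, e)
    y[onfoot] <- cf$y_stand_m + bob * env
    vy[onfoot] <- bob_d * env + bob * env_d

    i <- t >= t_desc0 & t < t_desc1
    u <- (t[i] - t_desc0) / cf$stand_to_sit_s
    y[i] <- cf$y_stand_m - dy * .ss(u)
    vy[i] <- -dy * .ss_d(u) / cf$stand_to_sit_s
    x[i] <- cf$x_home_m + (cf$seated_x_offset_m - cf$x_home_m) * .ss(u)
    vx[i] <- (cf$seated_x_offset_m - cf$x_home_m) * .ss_d(u) / cf$stand_to_sit_s

    i <- t >= t_desc1
    x[i] <- cf$seated_x_offset_m; y[i] <- cf$y_seated_m
    list(x = x, y = y, vx = vx, vy = vy)
  }

  fps <- cf$fps_video
  start_frame <- as.integer(round(t_rise0 * fps))
  stop_frame <- as.integer(round(t_desc1 * fps))
  n_frames <- stop_frame + as.integer(round(cf$tail_s * fps)) + 1L

  # analytic boundary times, then frame assignment per the detection rules
  eps <- params$stand_epsilon_m
  u_sc <- stats::uniroot(function(u) .ss(u) - (1 - eps / dy), c(0, 1))$root
  t_stand_c <- t_rise0 + u_sc * cf$sit_to_stand_s
  u_sb <- stats::uniroot(function(u) .ss(u) - eps / dy, c(0, 1))$root
  t_sit_b <- t_desc0 + u_sb * cf$stand_to_sit_s
  xroot <- function(target, lo, hi, sgn) {
    stats::uniroot(function(t) sgn * (eval_xy(t)$x - target), c(lo, hi),
                   tol = 1e-10)$root
  }
  marks <- params$meter_marks_m
  t_out <- vapply(marks, xroot, 0, lo = t_rise1, hi = t_turn0, sgn = 1)
  t_in <- vapply(rev(marks), xroot, 0, lo = t_turn1, hi = t_desc0, sgn = -1)
  x_margin <- cf$x_turn_m - params$turn_margin_m
  t_ts <- xroot(x_margin, t_rise1, t_turn0, 1)
  t_te <- xroot(x_margin, t_turn1, t_desc0, -1)

  b <- c(start = start_frame,
         stand_complete = ceiling(t_stand_c * fps),
         out1 = ceiling(t_out[1] * fps),
         out2 = ceiling(t_out[2] * fps),
         turn_start = ceiling(t_ts * fps),
         turn_end_excl = floor(t_te * fps) + 1L,
         in2 = ceiling(t_in[1] * fps),
         in1 = ceiling(t_in[2] * fps),
         sit_begin = floor(t_sit_b * fps),
         stop = stop_frame)
  b <- as.integer(b)
  names(b) <- c("start", "stand_complete", "out1", "out2", "turn_start",
                "turn_end_excl", "in2", "in1", "sit_begin", "stop")
  if (any(diff(b) < 2))
    stop("invalid config: scripted phases too short to segment")

  # true mean speeds: time average of analytic |v| over each phase interval
  true_speed <- function(f0, f1, comp) {
    tt <- seq(f0 / fps, f1 / fps,
              length.out = max(201L, ceiling((f1 - f0) / fps / 1e-4)) + 1L)
    ev <- eval_xy(tt)
    v <- abs(if (comp == "x") ev$vx else ev$vy)
    mean(v[-length(v)] + diff(v) / 2)  # trapezoid / duration
  }
  comps <- c("y", rep("x", 7), "y")
  speeds <- vapply(seq_len(9), function(k)
    true_speed(b[k], b[k + 1], comps[k]), 0)
  names(speeds) <- paste0("V", 1:9)

  fr <- 0:(n_frames - 1L)
  ev <- eval_xy(fr / fps)
  phase <- rep("pre", n_frames)
  for (k in 1:9)
    phase[fr >= b[k] & fr < b[k + 1]] <- paste0("V", k)
  phase[fr >= b[10]] <- "post"

  structure(list(
    config = cf,
    frames = data.frame(frame = fr, t_s = fr / fps,
                        x_m = ev$x, y_m = ev$y, phase = phase),
    sync = sync_events(start_frame, stop_frame),
    boundary_frames = b,
    true_speeds = speeds,
    y_stand = cf$y_stand_m,
    fps = fps, n_frames = n_frames,
    duration_s = (n_frames - 1L) / fps,
    eval = eval_xy
  ), class = "tug_ground_truth")
}

# silhouette geometry: rectangle + head disc; returns centroid height offset
# (combined centroid above the rectangle bottom) for a given rectangle height
.shape_centroid_offset <- function(H, W, r) {
  a1 <- W * H
  a2 <- pi * r^2
  (a1 * H / 2 + a2 * (H + r)) / (a1 + a2)
}

#' Render a synthetic TUG trial as grayscale video frames
#'
#' The background holds a uniform scene with the four calibration marker dots;
#' each trial frame adds a filled body silhouette (torso rectangle plus head
#' disc, height interpolating seated to standing) positioned so its analytic
#' area centroid coincides with the scripted centre of mass. Frames are
#' rendered lazily through the returned `frame(i)` closure, so a trial never
#' holds all frames in memory. Optional salt-and-pepper noise is seeded per
#' frame and reproducible independently of evaluation order.
#'
#' @param gt a [simulate_trajectory()] result.
#' @param config the matching [trial_config()] (defaults to `gt$config`).
#' @return An object of class `synthetic_video`: list with `background`
#'   (matrix), `frame` (function of 1-based frame number), `n_frames`, `fps`,
#'   `centroid_px` (data.frame of analytic pixel centroids `frame`, `u_px`,
#'   `v_px`), and `markers` (the [config_markers()] set).
#' @export
render_video <- function(gt, config = gt$config) {
  stopifnot(inherits(gt, "tug_ground_truth"))
  cf <- config
  mpp <- cf$m_per_px
  w <- cf$img_w; h <- cf$img_h
  ms <- config_markers(cf)

  bg <- matrix(cf$bg_level, nrow = h, ncol = w)
  draw_dot <- function(m, p) {
    cols <- (round(p[1]) - cf$marker_px_r):(round(p[1]) + cf$marker_px_r) + 1L
    rows <- (round(p[2]) - cf$marker_px_r):(round(p[2]) + cf$marker_px_r) + 1L
    m[rows[rows >= 1 & rows <= h], cols[cols >= 1 & cols <= w]] <- cf$marker_level
    m
  }
  for (p in list(ms$m1_px, ms$m2_px, ms$m3_px, ms$m4_px)) bg <- draw_dot(bg, p)

  dy <- cf$y_stand_m - cf$y_seated_m
  body_h <- function(y) {
    u <- pmin(pmax((y - cf$y_seated_m) / dy, 0), 1)
    cf$body_h_seated_m + (cf$body_h_stand_m - cf$body_h_seated_m) * u
  }
  xm <- gt$frames$x_m; ym <- gt$frames$y_m
  Hs <- body_h(ym)
  cy <- .shape_centroid_offset(Hs, cf$body_w_m, cf$head_r_m)
  top_v <- cf$floor_v_px - (ym - cy + Hs + 2 * cf$head_r_m) / mpp
  left_u <- cf$origin_u_px + xm / mpp - (cf$body_w_m / 2) / mpp
  right_u <- cf$origin_u_px + xm / mpp + (cf$body_w_m / 2) / mpp
  if (any(top_v < 0) || any(left_u < 0) || any(right_u > w - 1))
    stop("invalid config: silhouette clipped by the frame bounds")

  centroid_px <- data.frame(frame = gt$frames$frame,
                            u_px = cf$origin_u_px + xm / mpp,
                            v_px = cf$floor_v_px - ym / mpp)

  frame_fun <- function(i) {
    f <- bg
    H <- Hs[i]; c_y <- cy[i]
    u_c <- cf$origin_u_px + xm[i] / mpp
    y_bot <- ym[i] - c_y
    # rectangle: pixel centres inside the analytic bounds
    c0 <- ceiling(u_c - (cf$body_w_m / 2) / mpp)
    c1 <- floor(u_c + (cf$body_w_m / 2) / mpp)
    r0 <- ceiling(cf$floor_v_px - (y_bot + H) / mpp)
    r1 <- floor(cf$floor_v_px - y_bot / mpp)
    f[(r0:r1) + 1L, (c0:c1) + 1L] <- cf$body_level
    # head disc
    v_h <- cf$floor_v_px - (y_bot + H + cf$head_r_m) / mpp
    rp <- cf$head_r_m / mpp
    hc <- floor(u_c - rp):ceiling(u_c + rp)
    hr <- floor(v_h - rp):ceiling(v_h + rp)
    du2 <- outer((hr - v_h)^2, (hc - u_c)^2, "+")
    sel <- du2 <= rp^2
    f[hr + 1L, hc + 1L][sel] <- cf$body_level
    if (cf$sp_noise_rate > 0) {
      f <- with_seed(.sub_seed(cf$seed, 1L, i), {
        n_noise <- round(cf$sp_noise_rate * length(f))
        idx <- sample.int(length(f), n_noise)
        f[idx] <- sample(c(0, 255), n_noise, replace = TRUE)
        f
      })
    }
    f
  }

  structure(list(background = bg, frame = frame_fun,
                 n_frames = gt$n_frames, fps = gt$fps,
                 centroid_px = centroid_px, markers = ms, config = cf),
            class = "synthetic_video")
}

#' Simulate the four-marker pelvis tracks matching a trial
#'
#' Places the ASIS/PSIS markers at fixed symmetric offsets around the true
#' centre of mass (anteroposterior along the walkway, lateral across it),
#' samples at the mocap rate and adds seeded Gaussian noise. Because the
#' offsets are symmetric, the four-marker mean recovers the true COM exactly
#' in the noiseless case.
#'
#' @param gt a [simulate_trajectory()] result.
#' @param config the matching [trial_config()].
#' @return A [marker_track_3d()] at `fs_mocap`.
#' @export
simulate_mocap <- function(gt, config = gt$config) {
  stopifnot(inherits(gt, "tug_ground_truth"))
  cf <- config
  fs <- cf$fs_mocap
  t <- seq(0, gt$duration_s, by = 1 / fs)
  ev <- gt$eval(t)
  ap <- cf$asis_ap_m; lat <- cf$lateral_m
  off <- list(R_ASIS = c(ap, 0, -lat), L_ASIS = c(ap, 0, lat),
              R_PSIS = c(-ap, 0, -lat), L_PSIS = c(-ap, 0, lat))
  df <- list()
  for (mk in names(off)) {
    df[[paste0(mk, "_x")]] <- ev$x + off[[mk]][1]
    df[[paste0(mk, "_y")]] <- ev$y + off[[mk]][2]
    df[[paste0(mk, "_z")]] <- 0 + off[[mk]][3]
  }
  df <- as.data.frame(df)
  if (cf$mocap_noise_sd_m > 0) {
    df[] <- with_seed(.sub_seed(cf$seed, 2L), {
      lapply(df, function(col)
        col + stats::rnorm(length(col), 0, cf$mocap_noise_sd_m))
    })
  }
  marker_track_3d(df, fs = fs)
}

#' Sync events of a ground truth at an arbitrary sampling rate
#'
#' @param gt a [simulate_trajectory()] result.
#' @param fs target sampling rate (Hz); defaults to the video rate.
#' @return A [sync_events()] in frames of `fs`.
#' @export
sync_at <- function(gt, fs = gt$fps) {
  sync_events(round(gt$sync$start_frame / gt$fps * fs),
              round(gt$sync$stop_frame / gt$fps * fs))
}

#' Simulate a paired per-subject table with known correlation
#'
#' Draws `n` bivariate-normal pairs with correlation `rho` and the given
#' marginal standard deviations -- a fixture for exercising the agreement
#' statistics with a known truth.
#'
#' @param rho true correlation in `[-1, 1]`.
#' @param n number of subjects (>= 3).
#' @param sd_a,sd_b marginal standard deviations.
#' @param seed integer seed.
#' @param mean_a,mean_b marginal means (default 1, a typical speed in m/s).
#' @return A [paired_table()].
#' @export
simulate_paired <- function(rho, n, sd_a = 0.1, sd_b = 0.1, seed = 1L,
                            mean_a = 1, mean_b = 1) {
  if (!is.numeric(rho) || rho < -1 || rho > 1)
    stop("invalid parameter: rho must lie in [-1, 1]")
  if (n < 3) stop("invalid parameter: n must be >= 3")
  with_seed(.sub_seed(seed, 3L), {
    z1 <- stats::rnorm(n)
    z2 <- stats::rnorm(n)
    a <- mean_a + sd_a * z1
    b <- mean_b + sd_b * (rho * z1 + sqrt(1 - rho^2) * z2)
    paired_table(a, b)
  })
}
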