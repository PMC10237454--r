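.MOCAP_MARKERS <- c("R_ASIS", "L_ASIS", "R_PSIS", "L_PSIS")
.MOCAP_AXES <- c("x", "y", "z")

#' Construct a four-marker pelvis trajectory table
#'
#' Holds the 3-D trajectories of the four pelvic landmarks (right/left
#' anterior and posterior superior iliac spine) as a data.frame with one
#' column per marker/axis (`R_ASIS_x`, ..., `L_PSIS_z`), in metres.
#'
#' @param df data.frame with the 12 `<MARKER>_<axis>` columns.
#' @param fs sampling rate in Hz (default 120).
#' @return A data.frame of class `marker_track_3d` with attribute `fs`.
#' @export
marker_track_3d <- function(df, fs = 120) {
  cols <- as.vector(outer(.MOCAP_MARKERS, .MOCAP_AXES, paste, sep = "_"))
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("invalid input: missing marker channels: ",
         paste(missing, collapse = ", "))
  if (fs <= 0) stop("marker_track_3d: fs must be positive")
  df <- df[cols]
  if (any(!vapply(df, function(c) all(is.finite(c)), logical(1))))
    stop("marker_track_3d: coordinates must be finite")
  attr(df, "fs") <- fs
  class(df) <- c("marker_track_3d", "data.frame")
  df
}

#' Read a marker trajectory CSV
#'
#' Expects one header row and columns `<MARKER>_<axis>` for the four pelvic
#' markers; coordinates in metres (or millimetres with `units = "mm"`).
#'
#' @param path CSV file path.
#' @param fs sampling rate in Hz.
#' @param units `"m"` (default) or `"mm"`.
#' @return A [marker_track_3d()].
#' @export
read_marker_csv <- function(path, fs = 120, units = c("m", "mm")) {
  units <- match.arg(units)
  df <- utils::read.csv(path)
  if (units == "mm")
    df[] <- lapply(df, function(c) if (is.numeric(c)) c / 1000 else c)
  marker_track_3d(df, fs = fs)
}

# Polynomial coefficients (highest degree first) from roots, by convolution.
.poly_from_roots <- function(r) {
  p <- 1
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  p
}

#' Digital low-pass Butterworth coefficients
#'
#' Designs an order-`n` low-pass Butterworth filter via the bilinear transform
#' with frequency pre-warping, returning transfer-function coefficients
#' `b` (numerator) and `a` (denominator) as used by [filter_ba()]. This is
#' implemented in-package because no DSP library is available; it matches the
#' standard scipy/Matlab `butter` design.
#'
#' @param order filter order.
#' @param cutoff_hz -3 dB cutoff frequency in Hz; must be below `fs/2`.
#' @param fs sampling rate in Hz.
#' @return A list with numeric vectors `b` and `a` of length `order + 1`.
#' @export
butter_coeffs <- function(order, cutoff_hz, fs) {
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2)
    stop("invalid parameter: cutoff must lie in (0, fs/2)")
  warped <- 2 * fs * tan(pi * cutoff_hz / fs)
  k <- seq_len(order)
  p <- warped * exp(1i * pi * (2 * k + order - 1) / (2 * order))
  fs2 <- 2 * fs
  pz <- (fs2 + p) / (fs2 - p)              # bilinear transform of poles
  gain <- Re(warped^order / prod(fs2 - p)) # zeros at z = -1
  b <- Re(gain * .poly_from_roots(rep(-1 + 0i, order)))
  a <- Re(.poly_from_roots(pz))
  list(b = b, a = a)
}

#' Apply an IIR filter (direct form II transposed)
#'
#' @param b,a transfer-function coefficients, e.g. from [butter_coeffs()].
#' @param x numeric signal.
#' @param zi optional initial filter state of length
#'   `max(length(a), length(b)) - 1`.
#' @return The filtered signal.
#' @export
filter_ba <- function(b, a, x, zi = NULL) {
  b <- b / a[1]; a <- a / a[1]
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  z <- if (is.null(zi)) rep(0, n - 1) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    y[i] <- b[1] * x[i] + z[1]
    if (n > 2)
      z[1:(n - 2)] <- b[2:(n - 1)] * x[i] + z[2:(n - 1)] - a[2:(n - 1)] * y[i]
    z[n - 1] <- b[n] * x[i] - a[n] * y[i]
  }
  y
}

# Steady-state filter state for a unit-amplitude step input, so transients at
# the signal edges vanish (the classical filtfilt initial-condition trick).
.filter_zi <- function(b, a) {
  b <- b / a[1]; a <- a / a[1]
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  A <- diag(n - 1)
  A[, 1] <- A[, 1] + a[2:n]
  if (n > 2) A[1:(n - 2), 2:(n - 1)] <- A[1:(n - 2), 2:(n - 1)] - diag(n - 2)
  solve(A, b[2:n] - a[2:n] * b[1])
}

#' Zero-phase forward-backward filtering
#'
#' Filters the signal forward and backward so events keep their timing
#' (no phase lag), at the cost of doubling the effective filter order.
#' Transients are suppressed by odd reflection padding at both ends, as in
#' the conventional biomechanics implementation.
#'
#' @inheritParams filter_ba
#' @return The zero-phase filtered signal.
#' @export
filtfilt_ba <- function(b, a, x) {
  nfilt <- max(length(a), length(b))
  pad <- min(3 * nfilt, length(x) - 1)
  if (pad > 0) {
    pre <- 2 * x[1] - x[(pad + 1):2]
    post <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - pad)]
    xe <- c(pre, x, post)
  } else xe <- x
  zi <- .filter_zi(b, a)
  y <- filter_ba(b, a, xe, zi * xe[1])
  y <- rev(y)
  y <- rev(filter_ba(b, a, y, zi * y[1]))
  y[(pad + 1):(pad + length(x))]
}

#' Low-pass filter a marker track
#'
#' Applies a zero-phase low-pass Butterworth filter (default 4th order, 6 Hz
#' cutoff -- the conventional choice for gait marker data) to every
#' coordinate channel.
#'
#' @param track a [marker_track_3d()].
#' @param order filter order (default 4).
#' @param cutoff_hz cutoff frequency in Hz (default 6); must be below the
#'   Nyquist frequency of the track.
#' @return A filtered [marker_track_3d()].
#' @export
butterworth_lowpass <- function(track, order = 4, cutoff_hz = 6) {
  stopifnot(inherits(track, "marker_track_3d"))
  fs <- attr(track, "fs")
  co <- butter_coeffs(order, cutoff_hz, fs)
  out <- track
  out[] <- lapply(track, function(col) filtfilt_ba(co$b, co$a, col))
  out
}

#' Pelvis centre of mass from the four markers
#'
#' Per-frame arithmetic mean of the four pelvic markers on each axis. With
#' markers placed symmetrically about the pelvis centre, the mean estimates
#' the body centre of mass at trunk level.
#'
#' @param track a [marker_track_3d()].
#' @return A data.frame of class `com_track` with columns `x`, `y`, `z`
#'   (metres) and attribute `fs`.
#' @export
com_mocap <- function(track) {
  stopifnot(inherits(track, "marker_track_3d"))
  out <- data.frame(
    x = rowMeans(as.data.frame(track)[paste0(.MOCAP_MARKERS, "_x")]),
    y = rowMeans(as.data.frame(track)[paste0(.MOCAP_MARKERS, "_y")]),
    z = rowMeans(as.data.frame(track)[paste0(.MOCAP_MARKERS, "_z")])
  )
  attr(out, "fs") <- attr(track, "fs")
  class(out) <- c("com_track", "data.frame")
  out
}

#' TUG subtask speeds from a motion-capture COM track
#'
#' Projects the 3-D centre of mass onto the sagittal plane (configurable
#' forward and up axes), computes windowed speeds with the window preserving
#' the 1/15 s span of the video pipeline (8 frames at 120 Hz), and reuses the
#' shared segmentation machinery. The two systems are compared only at the
#' subtask-mean level, so the rate difference with the 60 Hz video is never
#' resampled away.
#'
#' @param com a [com_track()][com_mocap()].
#' @param sync a [sync_events()] in mocap frames.
#' @param params a [seg_params()].
#' @param forward_axis,up_axis which COM axis runs along the walkway and
#'   which points up (defaults `"x"` and `"y"`).
#' @param w speed window in frames (default [default_window()] at `fs`).
#' @return A list with `speeds` (the [mean_subtask_speeds()] table),
#'   `segments`, and the sagittal `track`.
#' @export
mocap_subtask_speeds <- function(com, sync, params = seg_params(),
                                 forward_axis = "x", up_axis = "y", w = NULL) {
  stopifnot(inherits(com, "com_track"))
  if (!forward_axis %in% names(com) || !up_axis %in% names(com) ||
      forward_axis == up_axis)
    stop("invalid input: forward_axis and up_axis must be distinct COM axes")
  fs <- attr(com, "fs")
  track <- centroid_track(seq_len(nrow(com)) - 1L,
                          com[[forward_axis]], com[[up_axis]], fps = fs)
  sp <- instantaneous_speed(track, w = w)
  seg <- segment_tug(track, sync, params)
  list(speeds = mean_subtask_speeds(seg, sp), segments = seg, track = track)
}
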