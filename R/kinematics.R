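#' Construct a world-coordinate centroid track
#'
#' @param frame integer vector of 0-based, strictly increasing frame indices.
#' @param x_m,y_m world coordinates in metres (x: chair toward turn mark,
#'   y: height above floor).
#' @param fps frames per second (> 0).
#' @param valid logical vector; positions at invalid frames are regarded as
#'   interpolated/filled rather than observed.
#' @return A data.frame of class `centroid_track` with columns `frame`, `t_s`,
#'   `x_m`, `y_m`, `valid` and attribute `fps`.
#' @export
centroid_track <- function(frame, x_m, y_m, fps, valid = TRUE) {
  if (fps <= 0) stop("centroid_track: fps must be positive")
  n <- length(frame)
  if (length(x_m) != n || length(y_m) != n)
    stop("centroid_track: column lengths differ")
  if (n > 1 && any(diff(frame) <= 0))
    stop("centroid_track: frame indices must be strictly increasing")
  valid <- rep_len(valid, n)
  if (any(!is.finite(x_m[valid])) || any(!is.finite(y_m[valid])))
    stop("centroid_track: valid positions must be finite")
  out <- data.frame(frame = as.integer(frame), t_s = frame / fps,
                    x_m = x_m, y_m = y_m, valid = valid)
  attr(out, "fps") <- fps
  class(out) <- c("centroid_track", "data.frame")
  out
}

#' Map a pixel centroid track into world coordinates
#'
#' Valid frames are mapped through [pixel_to_world()]; invalid frames
#' (empty silhouette) are filled by linear interpolation between the nearest
#' valid neighbours, in world space. Leading and trailing invalid frames have
#' no bracketing observations and are dropped.
#'
#' @param pixel_track data.frame with columns `frame`, `u_px`, `v_px`,
#'   `valid`, as produced by [track_silhouette()].
#' @param model a [calibration_model()].
#' @param fps video frame rate (default 60).
#' @return A [centroid_track()]; interpolated frames keep `valid = FALSE`.
#' @export
track_to_world <- function(pixel_track, model, fps = 60) {
  stopifnot(is.data.frame(pixel_track), inherits(model, "calibration_model"))
  ok <- pixel_track$valid
  if (sum(ok) < 2)
    stop("unusable track: fewer than 2 valid frames")
  first <- min(which(ok)); last <- max(which(ok))
  pt <- pixel_track[first:last, , drop = FALSE]
  ok <- pt$valid
  w <- pixel_to_world(pt$u_px[ok], pt$v_px[ok], model)
  x <- stats::approx(pt$frame[ok], w$x_m, xout = pt$frame)$y
  y <- stats::approx(pt$frame[ok], w$y_m, xout = pt$frame)$y
  centroid_track(pt$frame, x, y, fps = fps, valid = ok)
}

#' Default finite-difference window for a sampling rate
#'
#' The speed window spans 1/15 s: 4 frames of 60 Hz video, 8 frames at the
#' 120 Hz motion-capture rate.
#'
#' @param fps sampling rate in Hz.
#' @return Window length in frames (integer >= 1).
#' @export
default_window <- function(fps) max(1L, as.integer(round(fps / 15)))

#' Windowed instantaneous speeds along both axes
#'
#' `speed_x[i] = (x[i+w] - x[i]) / (t[i+w] - t[i])`, and analogously for the
#' vertical axis. Speeds are signed (positive toward the turn mark /
#' upward); subtask summaries take magnitudes. `speed[i]` describes the
#' interval starting at frame `i`, which is the convention used when
#' assigning samples to subtask intervals.
#'
#' @param track a [centroid_track()].
#' @param w window in frames (default: [default_window()] of the track fps).
#' @return A data.frame of class `speed_series` with columns `frame`, `t_s`,
#'   `vx_ms`, `vy_ms`; attributes `w` and `fps`. Length is
#'   `nrow(track) - w`.
#' @export
instantaneous_speed <- function(track, w = NULL) {
  stopifnot(inherits(track, "centroid_track"))
  fps <- attr(track, "fps")
  if (is.null(w)) w <- default_window(fps)
  if (w < 1) stop("instantaneous_speed: window must be >= 1 frame")
  n <- nrow(track)
  if (n <= w) stop("unusable track: need more than w + 1 frames")
  i <- seq_len(n - w)
  dt <- track$t_s[i + w] - track$t_s[i]
  out <- data.frame(frame = track$frame[i], t_s = track$t_s[i],
                    vx_ms = (track$x_m[i + w] - track$x_m[i]) / dt,
                    vy_ms = (track$y_m[i + w] - track$y_m[i]) / dt)
  attr(out, "w") <- w
  attr(out, "fps") <- fps
  class(out) <- c("speed_series", "data.frame")
  out
}
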