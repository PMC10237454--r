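#' Trial synchronization events
#'
#' The external sync annotation: the trial starts when the subject leaves the
#' chair seat (trigger release) and stops at the end of stand-to-sit (trigger
#' press). The hardware box is abstracted to these two frame annotations.
#'
#' @param start_frame,stop_frame 0-based frame indices, `start < stop`.
#' @return An object of class `sync_events`.
#' @export
sync_events <- function(start_frame, stop_frame) {
  if (!is.numeric(start_frame) || !is.numeric(stop_frame) ||
      start_frame < 0 || start_frame >= stop_frame)
    stop("invalid input: need 0 <= start_frame < stop_frame")
  structure(list(start_frame = as.integer(start_frame),
                 stop_frame = as.integer(stop_frame)),
            class = "sync_events")
}

#' Segmentation parameters
#'
#' @param stand_epsilon_m height tolerance below the standing height that
#'   still counts as standing (default 0.05 m).
#' @param turn_margin_m how far below the peak forward excursion the turn
#'   interval extends (default 0.20 m); must be < 1 so the turn cannot
#'   swallow a metre segment.
#' @param meter_marks_m ordered walkway landmarks splitting the walk
#'   (default 1 m and 2 m).
#' @return An object of class `seg_params`.
#' @export
seg_params <- function(stand_epsilon_m = 0.05, turn_margin_m = 0.20,
                       meter_marks_m = c(1.0, 2.0)) {
  if (stand_epsilon_m <= 0 || turn_margin_m <= 0 || any(meter_marks_m <= 0))
    stop("seg_params: all parameters must be positive")
  if (turn_margin_m >= 1)
    stop("seg_params: turn_margin_m must be < 1 m")
  if (is.unsorted(meter_marks_m, strictly = TRUE))
    stop("seg_params: meter_marks_m must be strictly increasing")
  structure(list(stand_epsilon_m = stand_epsilon_m,
                 turn_margin_m = turn_margin_m,
                 meter_marks_m = meter_marks_m),
            class = "seg_params")
}

# Rows of `track` lying in [start_frame, stop_frame).
.sync_rows <- function(track, sync) {
  rows <- which(track$frame >= sync$start_frame & track$frame < sync$stop_frame)
  if (length(rows) < 9 * 2)
    stop("segmentation failure: sync window holds too few frames")
  rows
}

#' Estimate the standing height of a trial
#'
#' Median vertical centroid position over the middle third (in time) of the
#' outbound walk, i.e. of the span from the sync start to the peak forward
#' excursion. The median is robust to the gait bob and to the rise itself.
#'
#' @param track a [centroid_track()].
#' @param sync a [sync_events()].
#' @return Standing height in metres.
#' @export
standing_height <- function(track, sync) {
  rows <- .sync_rows(track, sync)
  peak <- rows[which.max(track$x_m[rows])]
  out <- rows[1]:peak
  n <- length(out)
  mid <- out[seq.int(floor(n / 3) + 1L, ceiling(2 * n / 3))]
  stats::median(track$y_m[mid])
}

#' Detect the end of sit-to-stand
#'
#' First frame at/after the sync start where the centroid height reaches the
#' standing height minus `stand_epsilon_m`. If the subject is already
#' standing at the start, the minimal two-frame interval is returned with a
#' message.
#'
#' @inheritParams standing_height
#' @param params a [seg_params()].
#' @param y_stand standing height; computed by [standing_height()] if `NULL`.
#' @return The 0-based frame ending subtask V1.
#' @export
detect_stand_complete <- function(track, sync, params = seg_params(),
                                  y_stand = NULL) {
  rows <- .sync_rows(track, sync)
  if (is.null(y_stand)) y_stand <- standing_height(track, sync)
  hit <- which(track$y_m[rows] >= y_stand - params$stand_epsilon_m)
  if (length(hit) == 0)
    stop("segmentation failure: centroid height never reaches standing")
  f <- track$frame[rows[hit[1]]]
  if (f < sync$start_frame + 2L) {
    message("stand detection: already standing at sync start; ",
            "using minimal sit-to-stand interval")
    f <- sync$start_frame + 2L
  }
  f
}

#' Detect the start of stand-to-sit
#'
#' Last frame before the sync stop where the centroid height is still at
#' standing height minus `stand_epsilon_m`; V9 runs from this frame to the
#' sync stop.
#'
#' @inheritParams detect_stand_complete
#' @return The 0-based frame starting subtask V9.
#' @export
detect_sit_begin <- function(track, sync, params = seg_params(),
                             y_stand = NULL) {
  rows <- .sync_rows(track, sync)
  if (is.null(y_stand)) y_stand <- standing_height(track, sync)
  hit <- which(track$y_m[rows] >= y_stand - params$stand_epsilon_m)
  if (length(hit) == 0)
    stop("segmentation failure: centroid height never reaches standing")
  f <- track$frame[rows[hit[length(hit)]]]
  if (f > sync$stop_frame - 2L) {
    message("sit detection: still standing at sync stop; ",
            "using minimal stand-to-sit interval")
    f <- sync$stop_frame - 2L
  }
  f
}

#' Detect the turn interval at peak forward excursion
#'
#' With `x_peak` the maximum forward position, the turn spans the frames with
#' `x > x_peak - turn_margin_m`: from the approach into the turn-around dwell
#' to the departure. V4 ends at `turn_start`; V6 begins after `turn_end`.
#'
#' @inheritParams detect_stand_complete
#' @return A list with 0-based frames `turn_start`, `turn_end` (inclusive).
#' @export
detect_turn <- function(track, params = seg_params(), sync = NULL) {
  rows <- if (is.null(sync)) seq_len(nrow(track)) else .sync_rows(track, sync)
  x <- track$x_m[rows]
  x_peak <- max(x)
  if (x_peak - params$turn_margin_m <= max(params$meter_marks_m))
    stop("segmentation failure: turn interval overlaps the ",
         max(params$meter_marks_m), " m crossing")
  inside <- which(x > x_peak - params$turn_margin_m)
  if (length(inside) == 0)
    stop("segmentation failure: empty turn interval")
  if (inside[length(inside)] == length(rows))
    stop("segmentation failure: no walk back after the peak excursion")
  list(turn_start = track$frame[rows[inside[1]]],
       turn_end = track$frame[rows[inside[length(inside)]]])
}

#' Detect outbound and inbound metre-mark crossings
#'
#' For each mark, the first frame whose forward position crosses it going out
#' (before the peak excursion) and the first frame crossing it going back
#' (after the peak). A crossing is located by the sign change of
#' `x - mark` between consecutive frames and assigned to the later frame.
#'
#' @inheritParams detect_stand_complete
#' @param marks walkway landmarks in metres (default `c(1, 2)`).
#' @return A list with integer vectors `outbound` and `inbound`, named by
#'   mark, in the order encountered during the trial.
#' @export
detect_meter_crossings <- function(track, marks = c(1.0, 2.0), sync = NULL) {
  rows <- if (is.null(sync)) seq_len(nrow(track)) else .sync_rows(track, sync)
  x <- track$x_m[rows]
  if (max(x) <= max(marks))
    stop("segmentation failure: trajectory never reaches ", max(marks), " m")
  peak <- which.max(x)
  outb <- inb <- stats::setNames(integer(length(marks)), marks)
  for (j in seq_along(marks)) {
    m <- marks[j]
    i <- which(x[seq_len(peak - 1)] < m & x[2:peak] >= m)
    if (length(i) == 0)
      stop("segmentation failure: no outbound crossing of ", m, " m")
    outb[j] <- track$frame[rows[i[1] + 1L]]
    k <- which(x[peak:(length(x) - 1)] > m & x[(peak + 1):length(x)] <= m)
    if (length(k) == 0)
      stop("segmentation failure: no inbound crossing of ", m, " m")
    inb[j] <- track$frame[rows[peak + k[1]]]
  }
  list(outbound = outb, inbound = rev(inb))
}

#' Segment a TUG trial into the nine subtasks
#'
#' Combines the stand/sit detectors, the metre-mark crossings and the turn
#' interval into nine contiguous half-open frame intervals V1..V9 tiling
#' `[start_frame, stop_frame)`:
#' sit-to-stand, walk out 0-1 m, 1-2 m, 2 m-turn, turn, turn-2 m, 2-1 m,
#' 1 m-sit, stand-to-sit.
#'
#' @inheritParams detect_stand_complete
#' @return A data.frame of class `tug_segments` with columns `label`,
#'   `start_frame`, `end_frame` (half-open) and attribute `fps` when the
#'   track carries one.
#' @export
segment_tug <- function(track, sync, params = seg_params()) {
  stopifnot(inherits(track, "centroid_track"), inherits(sync, "sync_events"))
  if (sync$stop_frame > track$frame[nrow(track)] + 1L)
    stop("invalid input: sync stop beyond the end of the track")
  y_stand <- standing_height(track, sync)
  stand_c <- detect_stand_complete(track, sync, params, y_stand)
  sit_b <- detect_sit_begin(track, sync, params, y_stand)
  turn <- detect_turn(track, params, sync)
  cross <- detect_meter_crossings(track, params$meter_marks_m, sync)
  b <- c(sync$start_frame, stand_c, cross$outbound,
         turn$turn_start, turn$turn_end + 1L,
         cross$inbound, sit_b, sync$stop_frame)
  labels <- paste0("V", 1:9)
  if (any(diff(b) < 2)) {
    i <- which(diff(b) < 2)[1]
    stop("segmentation failure: boundaries out of order or interval too ",
         "short between ", c("start", labels)[i], " end (frame ", b[i],
         ") and ", labels[i], " end (frame ", b[i + 1], ")")
  }
  out <- data.frame(label = labels,
                    start_frame = as.integer(b[1:9]),
                    end_frame = as.integer(b[2:10]))
  attr(out, "fps") <- attr(track, "fps")
  class(out) <- c("tug_segments", "data.frame")
  out
}

#' Mean speed of each TUG subtask
#'
#' Vertical subtasks (V1 sit-to-stand, V9 stand-to-sit) average the magnitude
#' of the vertical speed; the walking and turning subtasks V2..V8 average
#' the magnitude of the horizontal speed. A speed sample indexed by its
#' starting frame belongs to the interval containing that frame.
#'
#' @param segments a [segment_tug()] result.
#' @param speeds an [instantaneous_speed()] series from the same track.
#' @return A data.frame of class `subtask_speeds` with columns `label`,
#'   `start_frame`, `end_frame`, `duration_s`, `n_samples`, `mean_speed_ms`.
#' @export
mean_subtask_speeds <- function(segments, speeds) {
  stopifnot(inherits(segments, "tug_segments"), inherits(speeds, "speed_series"))
  fps <- attr(speeds, "fps")
  out <- segments
  out$duration_s <- (out$end_frame - out$start_frame) / fps
  out$n_samples <- NA_integer_
  out$mean_speed_ms <- NA_real_
  for (i in seq_len(nrow(out))) {
    sel <- speeds$frame >= out$start_frame[i] & speeds$frame < out$end_frame[i]
    if (!any(sel))
      stop("segmentation failure: no speed samples in ", out$label[i])
    v <- if (out$label[i] %in% c("V1", "V9")) speeds$vy_ms[sel] else speeds$vx_ms[sel]
    out$n_samples[i] <- sum(sel)
    out$mean_speed_ms[i] <- mean(abs(v))
  }
  class(out) <- c("subtask_speeds", "data.frame")
  out
}

#' @export
print.subtask_speeds <- function(x, ...) {
  cat("TUG subtask mean speeds (m/s):\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
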