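#' Scene marker set for planar calibration
#'
#' Bundles the pixel coordinates of the four scene markers together with their
#' known world separations. M1 and M2 sit on the walkway (M2 at the chair end,
#' where the walk starts; M1 at the far end of the 3 m walkway). M3 sits on
#' the floor beside the chair and M4 vertically above it (default 0.5 m apart).
#'
#' Pixel coordinates are image coordinates `(u, v)` with `u` the column and
#' `v` the row, 0-based, rows increasing downward.
#'
#' @param m1_px,m2_px,m3_px,m4_px numeric length-2 vectors `c(u, v)` in pixels.
#' @param dist_x_m known M1--M2 world distance in metres (walkway length).
#' @param dist_y_m known M3--M4 world distance in metres (vertical baseline).
#' @param frame_dim optional `c(width, height)` in pixels; when supplied, all
#'   markers are checked to lie inside the frame.
#' @return An object of class `marker_set`.
#' @examples
#' ms <- marker_set(c(700, 640), c(100, 640), c(80, 650), c(80, 450))
#' build_calibration(ms)
#' @export
marker_set <- function(m1_px, m2_px, m3_px, m4_px,
                       dist_x_m = 3.0, dist_y_m = 0.5,
                       frame_dim = NULL) {
  pts <- list(m1_px = m1_px, m2_px = m2_px, m3_px = m3_px, m4_px = m4_px)
  for (nm in names(pts)) {
    p <- pts[[nm]]
    if (!is.numeric(p) || length(p) != 2L || any(!is.finite(p)))
      stop("marker_set: ", nm, " must be a finite numeric c(u, v) pair")
  }
  if (!is.numeric(dist_x_m) || dist_x_m <= 0 ||
      !is.numeric(dist_y_m) || dist_y_m <= 0)
    stop("marker_set: world distances must be positive")
  if (!is.null(frame_dim)) {
    w <- frame_dim[1]; h <- frame_dim[2]
    for (nm in names(pts)) {
      p <- pts[[nm]]
      if (p[1] < 0 || p[1] >= w || p[2] < 0 || p[2] >= h)
        stop("marker_set: ", nm, " lies outside the frame bounds")
    }
  }
  structure(c(pts, list(dist_x_m = dist_x_m, dist_y_m = dist_y_m)),
            class = "marker_set")
}

#' Build a pixel-to-metre calibration model
#'
#' Converts the pixel geometry of the four markers into metre-per-pixel scale
#' factors and a world frame: the chair-side walkway marker (M2) maps to
#' world `x = 0` with `x` increasing toward the turn mark, and the floor
#' marker (M3) maps to world `y = 0` with `y` increasing upward.
#'
#' The horizontal scale is `dist_x_m` divided by the absolute pixel column
#' separation of M1 and M2; the vertical scale is `dist_y_m` divided by the
#' absolute pixel row separation of M3 and M4. Absolute separations make the
#' model independent of camera left/right orientation; the walk direction in
#' pixels is recorded separately in `dir_x`.
#'
#' @param markers a [marker_set()].
#' @return An object of class `calibration_model` with fields
#'   `one_pixel_x_m`, `one_pixel_y_m` (metres per pixel), `origin_u_px`,
#'   `floor_v_px`, and `dir_x` (+1 if pixel column increases toward the turn
#'   mark, -1 otherwise).
#' @export
build_calibration <- function(markers) {
  stopifnot(inherits(markers, "marker_set"))
  du <- markers$m1_px[1] - markers$m2_px[1]
  dv <- markers$m4_px[2] - markers$m3_px[2]
  if (du == 0)
    stop("calibration degenerate: M1 and M2 share the same pixel column")
  if (dv == 0)
    stop("calibration degenerate: M3 and M4 share the same pixel row")
  calibration_model(
    one_pixel_x_m = markers$dist_x_m / abs(du),
    one_pixel_y_m = markers$dist_y_m / abs(dv),
    origin_u_px = markers$m2_px[1],
    floor_v_px = markers$m3_px[2],
    dir_x = sign(du)
  )
}

#' Construct a calibration model directly
#'
#' @param one_pixel_x_m,one_pixel_y_m metres per pixel along image columns and
#'   rows; both must be positive.
#' @param origin_u_px pixel column mapped to world `x = 0` (chair end).
#' @param floor_v_px pixel row mapped to world `y = 0` (floor).
#' @param dir_x +1 when pixel column increases toward the turn mark.
#' @return An object of class `calibration_model`.
#' @export
calibration_model <- function(one_pixel_x_m, one_pixel_y_m,
                              origin_u_px, floor_v_px, dir_x = 1) {
  if (one_pixel_x_m <= 0 || one_pixel_y_m <= 0)
    stop("calibration_model: scale factors must be positive")
  if (!dir_x %in% c(-1, 1))
    stop("calibration_model: dir_x must be +1 or -1")
  structure(list(one_pixel_x_m = one_pixel_x_m,
                 one_pixel_y_m = one_pixel_y_m,
                 origin_u_px = origin_u_px,
                 floor_v_px = floor_v_px,
                 dir_x = dir_x),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("calibration_model: %.6g m/px (x), %.6g m/px (y); origin u=%g, floor v=%g, dir %+d\n",
              x$one_pixel_x_m, x$one_pixel_y_m, x$origin_u_px, x$floor_v_px, x$dir_x))
  invisible(x)
}

#' Map pixel coordinates to world metres
#'
#' World `x` runs from the chair (0 m) toward the turn mark; world `y` is
#' height above the floor. Image rows increase downward, so
#' `y = (floor_v - v) * one_pixel_y_m`. Points beyond the calibrated span are
#' extrapolated linearly.
#'
#' @param u_px,v_px numeric vectors of pixel coordinates (recycled together).
#' @param model a [calibration_model()].
#' @return A list with numeric vectors `x_m` and `y_m`.
#' @export
pixel_to_world <- function(u_px, v_px, model) {
  stopifnot(inherits(model, "calibration_model"))
  list(x_m = (u_px - model$origin_u_px) * model$one_pixel_x_m * model$dir_x,
       y_m = (model$floor_v_px - v_px) * model$one_pixel_y_m)
}
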