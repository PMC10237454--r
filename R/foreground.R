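#' Convert an RGB frame to grayscale
#'
#' Applies the ITU-R BT.601 luminance weights (0.299, 0.587, 0.114) to a
#' `height x width x 3` array. A plain matrix (already grayscale) passes
#' through unchanged. Intensities are expected on the 0--255 scale.
#'
#' @param frame numeric matrix (grayscale) or 3-channel array.
#' @return A numeric matrix of luminance values.
#' @export
to_grayscale <- function(frame) {
  if (is.matrix(frame)) return(frame)
  if (is.array(frame) && length(dim(frame)) == 3L) {
    nc <- dim(frame)[3]
    if (nc == 1L) return(frame[, , 1L])
    if (nc != 3L)
      stop("invalid frame: expected 1 or 3 channels, got ", nc)
    return(0.299 * frame[, , 1L] + 0.587 * frame[, , 2L] + 0.114 * frame[, , 3L])
  }
  stop("invalid frame: expected a matrix or a height x width x channels array")
}

#' Background subtraction with fixed threshold
#'
#' Marks a pixel as foreground when the absolute grayscale difference between
#' the frame and the static background exceeds `tau` (strictly). The default
#' threshold of 50 intensity levels suits an indoor scene with a clothed
#' subject against a static background.
#'
#' @param frame,background numeric matrices of identical shape.
#' @param tau nonnegative intensity threshold (default 50).
#' @return A logical matrix: `TRUE` for foreground.
#' @export
subtract_and_threshold <- function(frame, background, tau = 50) {
  if (!is.matrix(frame) || !is.matrix(background))
    stop("invalid input: frame and background must be matrices")
  if (!all(dim(frame) == dim(background)))
    stop("invalid input: frame and background shapes differ")
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0)
    stop("invalid input: tau must be a single nonnegative number")
  abs(frame - background) > tau
}

# Shift matrix columns/rows by k with edge replication (clamped indices).
.shift_cols <- function(m, k) {
  nc <- ncol(m)
  m[, pmin(pmax(seq_len(nc) + k, 1L), nc), drop = FALSE]
}
.shift_rows <- function(m, k) {
  nr <- nrow(m)
  m[pmin(pmax(seq_len(nr) + k, 1L), nr), , drop = FALSE]
}

#' Binary median (majority) filter
#'
#' Each output pixel takes the majority value of its `kernel x kernel`
#' neighborhood -- the median of a binary window. Borders are handled by edge
#' replication. A separable shifted-sum implementation keeps this O(kernel)
#' matrix operations per frame.
#'
#' @param mask logical matrix.
#' @param kernel odd window size >= 1 (default 5).
#' @return A logical matrix of the same shape.
#' @export
median_denoise <- function(mask, kernel = 5) {
  if (!is.matrix(mask)) stop("invalid input: mask must be a matrix")
  if (length(kernel) != 1L || kernel < 1 || kernel %% 2 == 0)
    stop("invalid parameter: kernel must be an odd integer >= 1")
  if (kernel == 1) return(mask)
  r <- (kernel - 1L) / 2L
  num <- mask * 1L
  acc <- num * 0L
  for (k in -r:r) acc <- acc + .shift_cols(num, k)
  acc2 <- acc * 0L
  for (k in -r:r) acc2 <- acc2 + .shift_rows(acc, k)
  acc2 > (kernel * kernel) / 2
}

#' Silhouette centroid of a binary mask
#'
#' Geometric centre of mass of the foreground pixels with unit mass per pixel:
#' the mean foreground column and row, in 0-based sub-pixel image coordinates.
#' An empty mask yields `valid = FALSE` rather than an error, so a frame where
#' the subject is lost can be interpolated downstream.
#'
#' @param mask logical matrix.
#' @return An object of class `pixel_centroid`: list with `u_px`, `v_px`,
#'   `n_pixels`, `valid`.
#' @export
silhouette_centroid <- function(mask) {
  if (!is.matrix(mask)) stop("invalid input: mask must be a matrix")
  n <- sum(mask)
  if (n == 0)
    return(structure(list(u_px = NA_real_, v_px = NA_real_,
                          n_pixels = 0L, valid = FALSE),
                     class = "pixel_centroid"))
  cs <- .colSums(mask, nrow(mask), ncol(mask))
  rs <- .rowSums(mask, nrow(mask), ncol(mask))
  structure(list(
    u_px = sum(cs * (seq_len(ncol(mask)) - 1)) / n,
    v_px = sum(rs * (seq_len(nrow(mask)) - 1)) / n,
    n_pixels = as.integer(n),
    valid = TRUE
  ), class = "pixel_centroid")
}

#' Keep only the largest 4-connected foreground component
#'
#' Off by default in the pipeline (the whole-mask centroid is used); useful
#' for noisy inputs where stray blobs survive the median filter.
#'
#' @param mask logical matrix.
#' @return A logical matrix retaining only the largest connected component.
#' @export
largest_component <- function(mask) {
  if (!is.matrix(mask)) stop("invalid input: mask must be a matrix")
  idx <- which(mask)
  if (length(idx) == 0) return(mask)
  nr <- nrow(mask)
  lab <- integer(length(mask))
  lab[idx] <- -1L  # foreground, unlabelled
  cur <- 0L
  best_lab <- 0L; best_size <- 0L
  for (s in idx) {
    if (lab[s] != -1L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    size <- 0L
    while (length(queue)) {
      p <- queue
      size <- size + length(p)
      queue <- integer(0)
      # 4-neighbours in column-major linear indexing
      row <- (p - 1L) %% nr + 1L
      up <- p[row > 1L] - 1L
      dn <- p[row < nr] + 1L
      lf <- p[p > nr] - nr
      rt <- p[p <= length(mask) - nr] + nr
      nb <- c(up, dn, lf, rt)
      nb <- nb[lab[nb] == -1L]
      nb <- unique(nb)
      lab[nb] <- cur
      queue <- nb
    }
    if (size > best_size) { best_size <- size; best_lab <- cur }
  }
  out <- matrix(FALSE, nr, ncol(mask))
  out[lab == best_lab & lab > 0L] <- TRUE
  out
}

#' Track the silhouette centroid through a frame sequence
#'
#' Runs grayscale conversion, background subtraction, median denoising and
#' centroid extraction over every frame, producing the per-frame pixel track
#' consumed by [track_to_world()].
#'
#' @param frames a frame source: a list of frames, or a function
#'   `function(i)` returning frame `i` (1-based), or a `synthetic_video`
#'   object from [render_video()].
#' @param background background frame (matrix or RGB array).
#' @param n_frames required when `frames` is a function.
#' @param tau intensity threshold, see [subtract_and_threshold()].
#' @param kernel median filter window, see [median_denoise()].
#' @param keep_largest keep only the largest connected component before the
#'   centroid (default `FALSE`).
#' @return A data.frame with columns `frame` (0-based), `u_px`, `v_px`,
#'   `n_pixels`, `valid`.
#' @export
track_silhouette <- function(frames, background = NULL, n_frames = NULL,
                             tau = 50, kernel = 5, keep_largest = FALSE) {
  if (inherits(frames, "synthetic_video")) {
    if (is.null(background)) background <- frames$background
    n_frames <- frames$n_frames
    get_frame <- frames$frame
  } else if (is.function(frames)) {
    if (is.null(n_frames)) stop("n_frames is required with a frame function")
    get_frame <- frames
  } else if (is.list(frames)) {
    n_frames <- length(frames)
    get_frame <- function(i) frames[[i]]
  } else stop("invalid input: unsupported frame source")
  if (is.null(background)) stop("invalid input: background frame is required")
  bg <- to_grayscale(background)
  out <- data.frame(frame = seq_len(n_frames) - 1L,
                    u_px = NA_real_, v_px = NA_real_,
                    n_pixels = 0L, valid = FALSE)
  for (i in seq_len(n_frames)) {
    g <- to_grayscale(get_frame(i))
    mask <- median_denoise(subtract_and_threshold(g, bg, tau), kernel)
    if (keep_largest) mask <- largest_component(mask)
    ct <- silhouette_centroid(mask)
    out$u_px[i] <- ct$u_px; out$v_px[i] <- ct$v_px
    out$n_pixels[i] <- ct$n_pixels; out$valid[i] <- ct$valid
  }
  out
}
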