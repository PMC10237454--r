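#' Write a grayscale frame as PNG
#'
#' @param frame numeric matrix on the 0--255 scale.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_frame_png <- function(frame, path) {
  png::writePNG(pmin(pmax(frame / 255, 0), 1), path)
  invisible(path)
}

#' Read a frame image as a 0--255 grayscale matrix
#'
#' RGB images are converted with the BT.601 luminance weights.
#'
#' @param path PNG file path.
#' @return A numeric matrix.
#' @export
read_frame_png <- function(path) {
  to_grayscale(png::readPNG(path) * 255)
}

#' Open a directory of frames as a lazy frame source
#'
#' Frames are the lexicographically ordered files matching `pattern`; each is
#' read on demand so long trials never sit in memory.
#'
#' @param dir directory of PNG frames.
#' @param pattern filename regular expression (default `frame_*.png`).
#' @return A list with `frame(i)` (1-based reader) and `n_frames`.
#' @export
frame_dir_source <- function(dir, pattern = "^frame_.*\\.png$") {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (length(files) == 0)
    stop("invalid input: no frames matching '", pattern, "' in ", dir)
  list(frame = function(i) read_frame_png(files[i]),
       n_frames = length(files), files = files)
}

#' Write the frames of a synthetic video to a directory
#'
#' Writes `background.png` and `frame_0000.png` ... so the directory can be
#' analysed exactly like a recorded trial.
#'
#' @param video a [render_video()] object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_frames <- function(video, dir) {
  stopifnot(inherits(video, "synthetic_video"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_frame_png(video$background, file.path(dir, "background.png"))
  for (i in seq_len(video$n_frames))
    write_frame_png(video$frame(i),
                    file.path(dir, sprintf("frame_%05d.png", i - 1L)))
  invisible(dir)
}

#' Read a wide per-subject subtask speed table
#'
#' Expects columns `subject_id` and `V1` ... `V9` (mean speed in m/s).
#'
#' @param x CSV path or data.frame.
#' @return A validated data.frame.
#' @export
read_subtask_table <- function(x) {
  df <- if (is.character(x)) utils::read.csv(x) else as.data.frame(x)
  need <- c("subject_id", paste0("V", 1:9))
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("invalid input: subtask table missing columns: ",
         paste(missing, collapse = ", "))
  df[need]
}
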