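#' Region-of-interest specification
#'
#' Describes the fixed eye crop applied to every source frame. All coordinates
#' downstream of the crop are expressed relative to its top-left corner,
#' which is pixel `(0, 0)`; x grows rightward, y grows downward.
#'
#' @param x0,y0 Top-left corner of the crop in source-frame pixels (0-based).
#' @param width,height Crop size in pixels; both must be positive.
#' @return An object of class `roi_spec`.
#' @examples
#' roi_spec(0, 0, 240, 160)
#' @export
roi_spec <- function(x0, y0, width, height) {
  stopifnot(width > 0, height > 0, x0 >= 0, y0 >= 0)
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 width = as.integer(width), height = as.integer(height)),
            class = "roi_spec")
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("<roi_spec> origin (%d, %d), %d x %d px\n",
              x$x0, x$y0, x$width, x$height))
  invisible(x)
}

crop_roi <- function(img, roi) {
  if (is.null(roi)) return(img)
  h <- nrow(img); w <- ncol(img)
  if (roi$x0 + roi$width > w || roi$y0 + roi$height > h)
    stop("ROI (", roi$x0, ",", roi$y0, ",", roi$width, "x", roi$height,
         ") does not fit inside a ", w, "x", h, " frame", call. = FALSE)
  img[(roi$y0 + 1):(roi$y0 + roi$height), (roi$x0 + 1):(roi$x0 + roi$width),
      drop = FALSE]
}

#' Convert a colour raster to grayscale
#'
#' Collapses a height x width x 3 RGB array (intensities on \[0, 255\]) to a
#' single-channel intensity matrix using the ITU-R BT.601 luma weights
#' 0.299 R + 0.587 G + 0.114 B.
#'
#' @param color_image Numeric array of dimension `c(h, w, 3)`.
#' @return A numeric `h x w` matrix with values in \[0, 255\].
#' @examples
#' px <- array(c(100, 200, 50), dim = c(1, 1, 3))
#' to_grayscale(px)  # 0.299*100 + 0.587*200 + 0.114*50
#' @export
to_grayscale <- function(color_image) {
  d <- dim(color_image)
  if (length(d) == 2) return(color_image)
  if (length(d) != 3 || d[3] != 3)
    stop("expected a 3-channel (h, w, 3) array, got dimensions ",
         paste(d, collapse = " x "), call. = FALSE)
  0.299 * color_image[, , 1] + 0.587 * color_image[, , 2] +
    0.114 * color_image[, , 3]
}

read_frame_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3 && dim(a)[3] == 4) a <- a[, , 1:3]  # drop alpha
  to_grayscale(a * 255)
}

#' Build a frame table from in-memory images
#'
#' @param images List of grayscale matrices (one per record).
#' @param index Integer source-frame numbers; default `seq_along(images) - 1`.
#' @param fps Frames per second of the source video, used for `time_s`.
#' @param valid Logical vector of per-frame validity flags.
#' @return A tibble with columns `index`, `time_s`, `image` (list column of
#'   matrices) and `valid` — the common currency of the trackers.
#' @export
frame_table <- function(images, index = seq_along(images) - 1L, fps = 30,
                        valid = rep(TRUE, length(images))) {
  stopifnot(length(images) == length(index), length(images) == length(valid))
  dims <- vapply(images, dim, integer(2))
  if (length(images) > 1 && (length(unique(dims[1, ])) > 1 ||
                             length(unique(dims[2, ])) > 1))
    stop("all frames of one sequence must share the same dimensions",
         call. = FALSE)
  tibble::tibble(index = as.integer(index), time_s = as.integer(index) / fps,
                 image = images, valid = valid)
}

#' Extract, subsample and crop frames from a frame directory
#'
#' Reads a directory of per-frame PNG images (sorted lexicographically, so
#' zero-padded names keep temporal order), keeps frames
#' `0, k, 2k, ...` where `k = sampling_interval`, converts each to grayscale
#' and applies a fixed ROI crop. The default interval of 10 turns a 30 fps
#' recording into an effective 3 Hz sample.
#'
#' @param path Directory containing `.png` frames.
#' @param sampling_interval Keep every k-th frame (k >= 1). Default 10.
#' @param roi Optional [roi_spec()] crop; `NULL` keeps the full frame.
#' @param fps Source frame rate used to derive `time_s`. Default 30.
#' @return A frame tibble as produced by [frame_table()].
#' @export
extract_frames <- function(path, sampling_interval = 10L, roi = NULL,
                           fps = 30) {
  stopifnot(sampling_interval >= 1)
  if (!dir.exists(path)) stop("not a readable frame directory: ", path,
                              call. = FALSE)
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("no .png frames found in ", path, call. = FALSE)
  keep <- seq(1L, length(files), by = as.integer(sampling_interval))
  images <- lapply(files[keep], function(f) crop_roi(read_frame_png(f), roi))
  frame_table(images, index = keep - 1L, fps = fps)
}

#' Number of frames kept when sampling every k frames
#'
#' Closed form for the count of indices `0, k, 2k, ...` below `n_frames`:
#' `floor((n_frames - 1) / k) + 1`.
#'
#' @param n_frames Total frames available.
#' @param k Sampling interval.
#' @return Integer count.
#' @export
sampled_frame_count <- function(n_frames, k) {
  stopifnot(n_frames >= 1, k >= 1)
  as.integer((n_frames - 1) %/% k + 1)
}

#' Write a trajectory to CSV
#'
#' Schema: `frame_index,time_s,x,y,valid` with `valid` coded 0/1 and empty
#' `x`/`y` fields on invalid frames. [read_trajectory_csv()] round-trips the
#' file exactly.
#'
#' @param traj Trajectory tibble (see [track_video_cht_tm()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(nrow(traj) > 0)
  out <- tibble::tibble(
    frame_index = as.integer(traj$frame_index),
    time_s = traj$time_s,
    x = traj$x, y = traj$y,
    valid = as.integer(traj$valid)
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory_csv()]
#'
#' @param path CSV path.
#' @return Trajectory tibble with `frame_index`, `time_s`, `x`, `y`, `valid`.
#' @export
read_trajectory_csv <- function(path) {
  out <- readr::read_csv(path, na = "", show_col_types = FALSE,
                         col_types = readr::cols(
                           frame_index = readr::col_integer(),
                           time_s = readr::col_double(),
                           x = readr::col_double(),
                           y = readr::col_double(),
                           valid = readr::col_integer()))
  out$valid <- out$valid == 1L
  new_trajectory(out)
}

new_trajectory <- function(df, method = NULL) {
  if (!is.null(method)) df$method <- method
  class(df) <- c("iris_trajectory", class(df))
  df
}
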