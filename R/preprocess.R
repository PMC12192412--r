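#' Morphological cleanup configuration
#'
#' Controls the erosion/dilation pair applied before circle detection.
#' Erosion (a sliding-window minimum) suppresses small bright structures such
#' as specular glints; the following dilation (window maximum) restores the
#' extent of the remaining dark structures, so the pair acts as a grayscale
#' opening on brightness — equivalently a closing of the dark iris region.
#'
#' @param kernel_shape One of `"ellipse"`, `"rect"`, `"cross"`.
#' @param kernel_size Odd positive kernel side in pixels. Default 3.
#' @param erode_iterations,dilate_iterations Non-negative repeat counts;
#'   0 means the operator is skipped. Default 1 each.
#' @param order `"erode_dilate"` (default) or `"dilate_erode"`.
#' @return A `morphology_config` list.
#' @export
morphology_config <- function(kernel_shape = c("ellipse", "rect", "cross"),
                              kernel_size = 3L,
                              erode_iterations = 1L,
                              dilate_iterations = 1L,
                              order = c("erode_dilate", "dilate_erode")) {
  kernel_shape <- match.arg(kernel_shape)
  stopifnot(kernel_size >= 1, kernel_size %% 2 == 1,
            erode_iterations >= 0, dilate_iterations >= 0)
  structure(list(kernel_shape = kernel_shape,
                 kernel_size = as.integer(kernel_size),
                 erode_iterations = as.integer(erode_iterations),
                 dilate_iterations = as.integer(dilate_iterations),
                 order = match.arg(order)),
            class = "morphology_config")
}

morph_kernel <- function(cfg) {
  shape <- switch(cfg$kernel_shape,
                  ellipse = "disc", rect = "box", cross = "diamond")
  EBImage::makeBrush(cfg$kernel_size, shape = shape)
}

# EBImage works on [0,1]; frames live on [0,255]. Grayscale erosion there is
# the structuring-element minimum with the window clipped at image borders.
apply_morph <- function(img, cfg, op, iterations) {
  if (iterations == 0) return(img)
  k <- morph_kernel(cfg)
  x <- img / 255
  for (i in seq_len(iterations)) x <- op(x, k)
  x * 255
}

#' Grayscale erosion
#'
#' Replaces each pixel by the minimum over the structuring element, repeated
#' `cfg$erode_iterations` times. On a dark-iris image this removes small
#' bright specular spots.
#'
#' @param img Grayscale matrix on \[0, 255\].
#' @param cfg A [morphology_config()].
#' @return Eroded matrix, same dimensions.
#' @export
erode_frame <- function(img, cfg = morphology_config()) {
  apply_morph(img, cfg, EBImage::erode, cfg$erode_iterations)
}

#' Grayscale dilation
#'
#' Structuring-element maximum, repeated `cfg$dilate_iterations` times; the
#' dual of [erode_frame()] under intensity inversion.
#'
#' @inheritParams erode_frame
#' @return Dilated matrix, same dimensions.
#' @export
dilate_frame <- function(img, cfg = morphology_config()) {
  apply_morph(img, cfg, EBImage::dilate, cfg$dilate_iterations)
}

#' Apply the configured erosion/dilation pair
#'
#' @inheritParams erode_frame
#' @return Cleaned matrix.
#' @export
preprocess_frame <- function(img, cfg = morphology_config()) {
  if (cfg$order == "erode_dilate") {
    dilate_frame(erode_frame(img, cfg), cfg)
  } else {
    erode_frame(dilate_frame(img, cfg), cfg)
  }
}

#' Histogram-based binarisation
#'
#' Thresholds a grayscale frame into a black/white mask. By default the
#' threshold maximises Otsu's between-class variance over the intensity
#' histogram; a fixed threshold can be supplied instead. Pixels at or above
#' the threshold map to 255 (white), the rest to 0.
#'
#' A frame whose two classes are not meaningfully separated (class means
#' closer than `min_separation`, e.g. a constant or noise-only image such as
#' a fully closed eyelid) is flagged `degenerate`; downstream circle
#' selection treats that as a detection failure.
#'
#' @param img Grayscale matrix on \[0, 255\].
#' @param threshold Optional fixed threshold; `NULL` (default) uses Otsu.
#' @param min_separation Minimum distance between the below/above-threshold
#'   class means for the split to count as bimodal. Default 25 intensity
#'   units.
#' @return A `binary_frame`: list with `mask` (matrix of 0/255),
#'   `threshold_used`, `degenerate`.
#' @export
binarise <- function(img, threshold = NULL, min_separation = 25) {
  stopifnot(length(img) > 0)
  rng <- range(img)
  degenerate <- FALSE
  if (diff(rng) < .Machine$double.eps^0.5) {
    thr <- rng[1]
    mask <- matrix(0, nrow(img), ncol(img))
    return(structure(list(mask = mask, threshold_used = thr,
                          degenerate = TRUE), class = "binary_frame"))
  }
  thr <- if (is.null(threshold)) {
    as.numeric(EBImage::otsu(img / 255, range = c(0, 1), levels = 256)) * 255
  } else threshold
  mask <- matrix(0, nrow(img), ncol(img))
  mask[img >= thr] <- 255
  lo <- img[mask == 0]; hi <- img[mask == 255]
  if (length(lo) == 0 || length(hi) == 0 ||
      (mean(hi) - mean(lo)) < min_separation) degenerate <- TRUE
  structure(list(mask = mask, threshold_used = thr, degenerate = degenerate),
            class = "binary_frame")
}

#' @export
print.binary_frame <- function(x, ...) {
  cat(sprintf("<binary_frame> %d x %d, threshold %.2f%s\n",
              ncol(x$mask), nrow(x$mask), x$threshold_used,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}
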