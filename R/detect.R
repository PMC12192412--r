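#' Tracker configuration
#'
#' Bundles the tunable parameters of both trackers. Defaults are the
#' package's operating point for eye-sized crops (roughly 240 x 160 px with
#' an iris radius of 15–50 px).
#'
#' @param cht [cht_params()] for circle detection.
#' @param morph [morphology_config()] for pre-cleaning.
#' @param acm_max_iter,acm_tol,acm_smoothing Active-contour controls, see
#'   [fit_snake()].
#' @param white_threshold Circle-acceptance threshold on the fraction of
#'   binarised-white pixels inside a candidate. Default 0.60.
#' @param template_margin Extra border (pixels) around the iris disc kept in
#'   the template patch. Default 4.
#' @param crop_margin Border added around the snake's bounding box when
#'   refining the crop. Default 8.
#' @param use_mask Restrict template similarity to the circular iris mask.
#' @param sim_threshold Keep match candidates within this fraction of the
#'   per-frame maximum similarity. Default 0.98.
#' @param min_similarity Absolute similarity floor below which a frame is
#'   declared invalid (blink or lost track); applies to the `"ncc"` score.
#'   Default 0.5.
#' @param match_method `"ncc"` (zero-mean normalised cross-correlation,
#'   default) or `"ccorr"` (raw product sum).
#' @return A `track_config` list.
#' @export
track_config <- function(cht = cht_params(), morph = morphology_config(),
                         acm_max_iter = 200L, acm_tol = 0.1,
                         acm_smoothing = 1L,
                         white_threshold = 0.60,
                         template_margin = 4L, crop_margin = 8L,
                         use_mask = TRUE, sim_threshold = 0.98,
                         min_similarity = 0.5,
                         match_method = c("ncc", "ccorr")) {
  structure(list(cht = cht, morph = morph,
                 acm_max_iter = as.integer(acm_max_iter), acm_tol = acm_tol,
                 acm_smoothing = as.integer(acm_smoothing),
                 white_threshold = white_threshold,
                 template_margin = as.integer(template_margin),
                 crop_margin = as.integer(crop_margin),
                 use_mask = use_mask, sim_threshold = sim_threshold,
                 min_similarity = min_similarity,
                 match_method = match.arg(match_method)),
            class = "track_config")
}

# Linear indices of in-bounds pixels of the disc centred at (cx, cy), 0-based
disc_indices <- function(cx, cy, r, h, w) {
  x0 <- max(0, floor(cx - r)); x1 <- min(w - 1, ceiling(cx + r))
  y0 <- max(0, floor(cy - r)); y1 <- min(h - 1, ceiling(cy + r))
  if (x1 < x0 || y1 < y0) return(integer(0))
  gx <- x0:x1; gy <- y0:y1
  xm <- matrix(rep(gx, each = length(gy)), length(gy))
  ym <- matrix(rep(gy, times = length(gx)), length(gy))
  inside <- (xm - cx)^2 + (ym - cy)^2 <= r^2
  (xm[inside]) * h + ym[inside] + 1
}

#' Fraction of binarised-white pixels inside each candidate circle
#'
#' @param candidates Candidate tibble from [hough_circles()].
#' @param binary A `binary_frame` from [binarise()] covering the same image.
#' @return `candidates` with a `white_fraction` column appended.
#' @export
white_fraction <- function(candidates, binary) {
  h <- nrow(binary$mask); w <- ncol(binary$mask)
  wf <- vapply(seq_len(nrow(candidates)), function(i) {
    idx <- disc_indices(candidates$cx[i], candidates$cy[i], candidates$r[i],
                        h, w)
    if (length(idx) == 0) return(1)
    mean(binary$mask[idx] == 255)
  }, numeric(1))
  dplyr::mutate(candidates, white_fraction = wf)
}

#' Select the iris circle by the 60% white-pixel rule
#'
#' A candidate is eligible when the fraction of binarised-white pixels
#' inside it is below `white_threshold` — the iris is the dark circle, so
#' its binarised interior is mostly black. Among eligible candidates the one
#' with the lowest white fraction wins; ties break on higher accumulator
#' votes, then on the smaller centre y.
#'
#' @param candidates Candidate tibble; `white_fraction` is computed from
#'   `binary` if absent.
#' @param binary A `binary_frame` over the same image.
#' @param white_threshold Acceptance threshold, default 0.60.
#' @return A one-row tibble, or `NULL` when no candidate qualifies (a
#'   detection failure for the frame).
#' @export
select_iris_circle <- function(candidates, binary, white_threshold = 0.60) {
  if (is.null(candidates) || nrow(candidates) == 0) return(NULL)
  if (!"white_fraction" %in% names(candidates))
    candidates <- white_fraction(candidates, binary)
  ok <- dplyr::filter(candidates, .data$white_fraction < white_threshold)
  if (nrow(ok) == 0) return(NULL)
  ok <- dplyr::arrange(ok, .data$white_fraction, dplyr::desc(.data$votes),
                       .data$cy)
  ok[1, ]
}

# Bounding box of contour points, padded and clamped; kept at least
# min_side on each axis so the circle detector has room to vote.
contour_bbox <- function(contour, h, w, margin, min_side) {
  x0 <- floor(min(contour$points[, 1])) - margin
  x1 <- ceiling(max(contour$points[, 1])) + margin
  y0 <- floor(min(contour$points[, 2])) - margin
  y1 <- ceiling(max(contour$points[, 2])) + margin
  grow <- function(a0, a1, lim) {
    need <- min(min_side, lim) - (a1 - a0 + 1)
    if (need > 0) { a0 <- a0 - ceiling(need / 2); a1 <- a1 + ceiling(need / 2) }
    a0 <- max(0, a0); a1 <- min(lim - 1, a1)
    if (a1 - a0 + 1 < min(min_side, lim)) {
      if (a0 == 0) a1 <- min(lim - 1, min(min_side, lim) - 1)
      else a0 <- max(0, a1 - min(min_side, lim) + 1)
    }
    c(a0, a1)
  }
  xr <- grow(x0, x1, w); yr <- grow(y0, y1, h)
  list(x0 = xr[1], x1 = xr[2], y0 = yr[1], y1 = yr[2])
}

detect_failure <- function(reason) {
  structure(list(ok = FALSE, reason = reason, centre = c(NA_real_, NA_real_),
                 radius = NA_real_, contour = NULL, white_fraction = NA_real_),
            class = "iris_detection")
}

#' Detect the iris in a single frame (CHT_ACM path)
#'
#' Full single-frame chain: morphological cleanup, an active-contour fit
#' that refines the crop to the eye/iris neighbourhood, histogram
#' binarisation of the refined crop, Circular Hough Transform candidate
#' generation, and the 60% white-pixel selection rule. The snake is
#' initialised from the best raw Hough candidate on the cleaned frame, or —
#' when no candidate exists — from a circle at the frame centre with radius
#' 0.4 x the smaller frame side.
#'
#' A failure at any stage (degenerate binarisation on a closed lid, no
#' eligible circle, collapsed contour) yields `ok = FALSE` rather than an
#' error, so a blink frame invalidates itself without aborting a run.
#'
#' @param frame Grayscale matrix on \[0, 255\].
#' @param cfg A [track_config()].
#' @return An `iris_detection`: list with `ok`, `centre` `(x, y)` in frame
#'   coordinates, `radius`, `contour`, `white_fraction`, and on failure a
#'   `reason` string.
#' @export
detect_iris_cht_acm <- function(frame, cfg = track_config()) {
  h <- nrow(frame); w <- ncol(frame)
  pre <- preprocess_frame(frame, cfg$morph)

  raw <- hough_circles(pre, cfg$cht)
  if (nrow(raw) > 0) {
    init_c <- c(raw$cx[1], raw$cy[1]); init_r <- raw$r[1]
  } else {
    init_c <- c((w - 1) / 2, (h - 1) / 2); init_r <- 0.4 * min(h, w)
  }
  # keep the initial circle inside the frame
  init_r <- min(init_r,
                init_c[1] - 1, w - 2 - init_c[1],
                init_c[2] - 1, h - 2 - init_c[2])
  if (init_r <= 2) return(detect_failure("no room for contour initialisation"))

  contour <- tryCatch(
    fit_snake(pre, init_c, init_r, max_iter = cfg$acm_max_iter,
              tol = cfg$acm_tol, smoothing = cfg$acm_smoothing),
    error = function(e) NULL)
  if (is.null(contour)) return(detect_failure("active contour collapsed"))

  bb <- contour_bbox(contour, h, w, cfg$crop_margin,
                     min_side = 2 * cfg$cht$max_radius)
  crop <- pre[(bb$y0 + 1):(bb$y1 + 1), (bb$x0 + 1):(bb$x1 + 1), drop = FALSE]

  bin <- binarise(crop)
  if (bin$degenerate) return(detect_failure("degenerate binarisation"))

  cands <- hough_circles(crop, cfg$cht)
  if (nrow(cands) == 0) return(detect_failure("no circle candidates"))
  cands <- white_fraction(cands, bin)
  sel <- select_iris_circle(cands, bin, cfg$white_threshold)
  if (is.null(sel)) return(detect_failure("no candidate under the white-pixel threshold"))

  structure(list(ok = TRUE,
                 centre = c(sel$cx + bb$x0, sel$cy + bb$y0),
                 radius = sel$r, contour = contour,
                 white_fraction = sel$white_fraction,
                 crop = bb),
            class = "iris_detection")
}

#' @export
print.iris_detection <- function(x, ...) {
  if (x$ok) {
    cat(sprintf("<iris_detection> centre (%.2f, %.2f), radius %.2f px\n",
                x$centre[1], x$centre[2], x$radius))
  } else {
    cat("<iris_detection> failed:", x$reason, "\n")
  }
  invisible(x)
}

#' Extract the first-frame iris template
#'
#' Cuts a square patch centred on the detected iris, of side
#' `2 * (round(radius) + margin) + 1`, together with a circular mask of the
#' iris radius inscribed at its centre. The stored centre offset converts a
#' later match location (patch top-left) back to an iris centre. The circle
#' must lie fully inside the frame — a template cut across the frame border
#' would not be an intact iris.
#'
#' @param frame Grayscale matrix.
#' @param centre Iris centre `(x, y)`, 0-based.
#' @param radius Iris radius in pixels.
#' @param margin Extra border in pixels around the disc. Default 4.
#' @return An `iris_template`: list with `patch`, `mask` (logical), `
#'   iris_radius`, `centre_offset`.
#' @export
extract_template <- function(frame, centre, radius, margin = 4L) {
  h <- nrow(frame); w <- ncol(frame)
  if (centre[1] - radius < 0 || centre[1] + radius > w - 1 ||
      centre[2] - radius < 0 || centre[2] + radius > h - 1)
    stop("non-intact template: iris circle touches the frame border",
         call. = FALSE)
  half <- as.integer(round(radius)) + as.integer(margin)
  cx <- as.integer(round(centre[1])); cy <- as.integer(round(centre[2]))
  if (cx - half < 0 || cx + half > w - 1 || cy - half < 0 || cy + half > h - 1)
    stop("non-intact template: patch (margin included) exceeds the frame",
         call. = FALSE)
  patch <- frame[(cy - half + 1):(cy + half + 1),
                 (cx - half + 1):(cx + half + 1), drop = FALSE]
  side <- 2L * half + 1L
  gx <- matrix(rep(0:(side - 1), each = side), side)
  gy <- matrix(rep(0:(side - 1), times = side), side)
  mask <- (gx - half)^2 + (gy - half)^2 <= radius^2
  structure(list(patch = patch, mask = mask, iris_radius = radius,
                 centre_offset = c(half, half)),
            class = "iris_template")
}

#' @export
print.iris_template <- function(x, ...) {
  cat(sprintf("<iris_template> %d x %d patch, iris radius %.1f px, %d mask px\n",
              ncol(x$patch), nrow(x$patch), x$iris_radius, sum(x$mask)))
  invisible(x)
}
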