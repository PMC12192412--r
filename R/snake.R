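#' Fit a region-based active contour (morphological snake)
#'
#' Evolves a closed contour from a circular initialisation towards the
#' strongest intensity boundary using a morphological active-contour-without-
#' edges scheme: at each step boundary pixels are reassigned to the region
#' (inside/outside) whose mean intensity they match better, followed by a
#' curvature-like morphological smoothing. Parameter-light and robust — no
#' gradient descent step sizes to tune.
#'
#' The scheme is expansive when the initial circle sits inside a uniform
#' region that contrasts with its surround, so an initialisation well inside
#' the iris grows to the iris boundary without an explicit balloon force.
#'
#' @param img Grayscale matrix on \[0, 255\].
#' @param init_centre Numeric `(x, y)`, 0-based pixel coordinates.
#' @param init_radius Initial circle radius in pixels; the circle must lie
#'   inside the image.
#' @param max_iter Iteration cap. Default 200.
#' @param tol Convergence tolerance: mean boundary displacement per
#'   iteration, in pixels (changed pixels per unit contour length), held for
#'   3 consecutive iterations. Default 0.1.
#' @param smoothing Number of morphological smoothing passes per iteration.
#' @return An `iris_contour`: list with `points` (n x 2 matrix of ordered
#'   `(x, y)` contour vertices, sub-pixel, closed), `converged`,
#'   `iterations_used`, and the final region `mask` (logical matrix).
#' @export
fit_snake <- function(img, init_centre, init_radius,
                      max_iter = 200L, tol = 0.1, smoothing = 1L) {
  h <- nrow(img); w <- ncol(img)
  stopifnot(init_radius > 1)
  if (init_centre[1] - init_radius < 0 || init_centre[1] + init_radius > w - 1 ||
      init_centre[2] - init_radius < 0 || init_centre[2] + init_radius > h - 1)
    stop("initial circle must lie inside the image", call. = FALSE)
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), times = w), h, w)
  u <- (xs - init_centre[1])^2 + (ys - init_centre[2])^2 <= init_radius^2

  converged <- FALSE; stable <- 0L; it <- 0L
  for (it in seq_len(max_iter)) {
    n_in <- sum(u)
    if (n_in == 0 || n_in == length(u))
      stop("active contour collapsed (region vanished or filled the frame)",
           call. = FALSE)
    c_in <- mean(img[u]); c_out <- mean(img[!u])
    boundary <- binary_dilate3(u) & !binary_erode3(u)
    force <- (img - c_in)^2 - (img - c_out)^2
    u_new <- u
    u_new[boundary & force < 0] <- TRUE
    u_new[boundary & force > 0] <- FALSE
    for (s in seq_len(smoothing)) {
      u_new <- if ((it + s) %% 2 == 0) si_is(u_new) else is_si(u_new)
    }
    changed <- sum(xor(u_new, u))
    blen <- max(1, sum(boundary) / 2)  # rough contour length in pixels
    u <- u_new
    if (changed / blen < tol) stable <- stable + 1L else stable <- 0L
    if (stable >= 3L) { converged <- TRUE; break }
  }
  n_in <- sum(u)
  if (n_in == 0 || n_in == length(u))
    stop("active contour collapsed (region vanished or filled the frame)",
         call. = FALSE)

  cl <- grDevices::contourLines(x = 0:(w - 1), y = 0:(h - 1),
                                z = t(u * 1), levels = 0.5)
  if (length(cl) == 0)
    stop("active contour produced no closed boundary", call. = FALSE)
  best <- cl[[which.max(vapply(cl, function(p) length(p$x), numeric(1)))]]
  pts <- cbind(x = best$x, y = best$y)
  structure(list(points = pts, converged = converged, iterations_used = it,
                 mask = u),
            class = "iris_contour")
}

#' @export
print.iris_contour <- function(x, ...) {
  cat(sprintf("<iris_contour> %d points, %d iterations%s\n",
              nrow(x$points), x$iterations_used,
              if (x$converged) ", converged" else ", iteration cap reached"))
  invisible(x)
}

# 3x3 binary dilation / erosion via clamped shifts
binary_dilate3 <- function(u) {
  out <- u
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    out <- out | shift_mat(u, dy, dx)
  }
  out
}

binary_erode3 <- function(u) {
  out <- u
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    out <- out & shift_mat(u, dy, dx)
  }
  out
}

# Curvature-like smoothing operators built from sup/inf over 4 line
# structuring elements of length 3 (horizontal, vertical, two diagonals).
line_dirs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))

sup_inf <- function(u) {
  out <- matrix(FALSE, nrow(u), ncol(u))
  for (d in line_dirs) {
    out <- out | (u & shift_mat(u, d[1], d[2]) & shift_mat(u, -d[1], -d[2]))
  }
  out
}

inf_sup <- function(u) !sup_inf(!u)

si_is <- function(u) sup_inf(inf_sup(u))
is_si <- function(u) inf_sup(sup_inf(u))
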