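#' Circular Hough Transform parameters
#'
#' Defaults follow the tracker's operating point for eye-sized crops:
#' `min_dist = 40`, `canny_high = 180`, `accumulator_threshold = 10`,
#' radius window 15–50 px.
#'
#' @param min_dist Minimum distance in pixels between accepted centres.
#' @param canny_high Upper edge threshold on the Sobel gradient magnitude
#'   (the detector's "param1").
#' @param accumulator_threshold Minimum centre votes ("param2").
#' @param min_radius,max_radius Radius search window in pixels.
#' @return A `cht_params` list.
#' @export
cht_params <- function(min_dist = 40, canny_high = 180,
                       accumulator_threshold = 10,
                       min_radius = 15, max_radius = 50) {
  stopifnot(min_dist > 0, min_radius > 0, min_radius < max_radius)
  structure(list(min_dist = min_dist, canny_high = canny_high,
                 accumulator_threshold = accumulator_threshold,
                 min_radius = min_radius, max_radius = max_radius),
            class = "cht_params")
}

# Neighbour sample with clamped (replicate) borders: out[y, x] = m[y+dy, x+dx]
shift_mat <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) + dy, 1L), h)
  ci <- pmin(pmax(seq_len(w) + dx, 1L), w)
  m[ri, ci, drop = FALSE]
}

# Sobel gradients; border ring zeroed (clamped padding is meaningless there)
sobel_gradients <- function(img) {
  gx <- (shift_mat(img, -1, 1) + 2 * shift_mat(img, 0, 1) +
           shift_mat(img, 1, 1)) -
        (shift_mat(img, -1, -1) + 2 * shift_mat(img, 0, -1) +
           shift_mat(img, 1, -1))
  gy <- (shift_mat(img, 1, -1) + 2 * shift_mat(img, 1, 0) +
           shift_mat(img, 1, 1)) -
        (shift_mat(img, -1, -1) + 2 * shift_mat(img, -1, 0) +
           shift_mat(img, -1, 1))
  gx[c(1, nrow(img)), ] <- 0; gx[, c(1, ncol(img))] <- 0
  gy[c(1, nrow(img)), ] <- 0; gy[, c(1, ncol(img))] <- 0
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

#' Detect circles with a gradient-voting Circular Hough Transform
#'
#' Edge pixels (Sobel magnitude at or above `canny_high`) vote along their
#' gradient direction for candidate centres at every radius in the search
#' window. The detector assumes dark discs on a lighter surround — the iris
#' in a visible-light eye crop — so each edge pixel votes only towards its
#' darker side. Accumulator peaks at or above `accumulator_threshold`
#' become candidates; peaks closer than `min_dist` to a stronger peak are
#' suppressed. Each surviving candidate is refined to sub-pixel precision
#' by a least-squares circle fit to the supporting edge pixels, gated to
#' the modal centre-distance ring and to radially outward gradients (which
#' screens out eyelash and eyelid edges at ring distance).
#'
#' @param img Grayscale matrix on \[0, 255\].
#' @param params A [cht_params()].
#' @return Tibble of candidates sorted by votes (descending) with columns
#'   `cx`, `cy`, `r` (pixels, 0-based image coordinates) and `votes`. Empty
#'   when no edge structure passes the thresholds.
#' @export
hough_circles <- function(img, params = cht_params()) {
  h <- nrow(img); w <- ncol(img)
  empty <- tibble::tibble(cx = double(), cy = double(), r = double(),
                          votes = double())
  g <- sobel_gradients(img)
  edge <- which(g$mag >= params$canny_high)
  if (length(edge) == 0) return(empty)
  ey <- (edge - 1) %% h          # 0-based row (y)
  ex <- (edge - 1) %/% h         # 0-based col (x)
  ux <- g$gx[edge] / g$mag[edge]
  uy <- g$gy[edge] / g$mag[edge]

  # dark-disc prior: the gradient at the boundary points from the dark
  # interior to the light surround, so the centre lies at p - u * r
  radii <- seq(params$min_radius, params$max_radius, by = 1)
  cx <- round(matrix(ex, length(ex), length(radii)) - outer(ux, radii))
  cy <- round(matrix(ey, length(ey), length(radii)) - outer(uy, radii))
  ok <- cx >= 0 & cx < w & cy >= 0 & cy < h
  acc <- matrix(tabulate(cx[ok] * h + cy[ok] + 1, nbins = h * w), h, w)

  # candidate cells must clear the vote threshold; rank them on a 3x3
  # box-smoothed accumulator so a peak split across adjacent cells by
  # gradient-direction rounding still comes out on top
  sm <- acc * 0
  for (dy in -1:1) for (dx in -1:1) sm <- sm + shift_mat(acc, dy, dx)
  peaks <- which(acc >= params$accumulator_threshold)
  if (length(peaks) == 0) return(empty)
  ord <- order(sm[peaks], acc[peaks], decreasing = TRUE)
  peaks <- peaks[ord]
  py <- (peaks - 1) %% h; px <- (peaks - 1) %/% h
  keep_x <- numeric(0); keep_y <- numeric(0); keep_v <- numeric(0)
  for (i in seq_along(peaks)) {
    if (length(keep_x) &&
        any((px[i] - keep_x)^2 + (py[i] - keep_y)^2 < params$min_dist^2))
      next
    keep_x <- c(keep_x, px[i]); keep_y <- c(keep_y, py[i])
    keep_v <- c(keep_v, acc[peaks[i]])
  }

  res <- purrr::map_dfr(seq_along(keep_x), function(i) {
    # refine centre and radius from the supporting edge pixels: gate to the
    # modal distance ring, then an algebraic (Kasa) circle fit, iterated
    cx <- keep_x[i]; cy <- keep_y[i]; r <- NA_real_
    bands <- c(2, 1.5, 1.25, 1)
    for (iter in seq_along(bands)) {
      d <- sqrt((ex - cx)^2 + (ey - cy)^2)
      # keep edge pixels whose gradient is radially outward (dark interior):
      # screens out eyelash and lid edges that happen to sit at ring distance
      align <- ((ex - cx) * ux + (ey - cy) * uy) / pmax(d, 1e-9)
      sel <- d >= params$min_radius - 2 & d <= params$max_radius + 2 &
        align > 0.7
      if (sum(sel) < 6) return(NULL)
      db <- round(d[sel])
      tab <- table(db)
      bins <- as.numeric(names(tab))
      # windowed mode: the bin whose +/- 1 px neighbourhood holds the most
      # support, robust to the ring straddling a bin boundary
      wc <- vapply(bins, function(b) sum(tab[abs(bins - b) <= 1]),
                   numeric(1))
      mode_bin <- bins[which.max(wc)]
      inl <- which(sel)[abs(d[sel] - mode_bin) <= bands[iter]]
      if (length(inl) < 6) return(NULL)
      fit <- kasa_fit(ex[inl], ey[inl])
      if (is.null(fit) ||
          abs(fit$cx - keep_x[i]) > 5 || abs(fit$cy - keep_y[i]) > 5) {
        # degenerate or runaway fit: keep the vote peak, radius = ring mean
        r <- mean(d[inl]); break
      }
      cx <- fit$cx; cy <- fit$cy; r <- fit$r
    }
    if (!is.na(r) && (r < params$min_radius - 1 || r > params$max_radius + 1))
      return(NULL)
    tibble::tibble(cx = cx, cy = cy, r = r, votes = keep_v[i])
  })
  dplyr::arrange(res, dplyr::desc(.data$votes))
}

# least-squares circle through (x, y): linear in (a, b, c) for
# x^2 + y^2 = 2ax + 2by + c
kasa_fit <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  z <- x^2 + y^2
  co <- tryCatch(solve(crossprod(A), crossprod(A, z)),
                 error = function(e) NULL)
  if (is.null(co)) return(NULL)
  r2 <- co[3] + co[1]^2 + co[2]^2
  if (r2 <= 0) return(NULL)
  list(cx = co[1], cy = co[2], r = sqrt(r2))
}
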