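# Independent brute-force oracles. Each reimplements the checked operation
# from its definition, by direct looping, sharing no code with the package.

# sliding-window min/max with the window clipped at the borders
window_filter_oracle <- function(img, k, fun) {
  h <- nrow(img); w <- ncol(img); half <- (k - 1) %/% 2
  out <- img
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ii <- max(1, i - half):min(h, i + half)
    jj <- max(1, j - half):min(w, j + half)
    out[i, j] <- fun(img[ii, jj])
  }
  out
}

# masked zero-mean NCC / raw CC at a single placement (0-based px, py)
ncc_oracle_at <- function(frame, patch, mask, px, py, raw = FALSE) {
  h <- nrow(patch); w <- ncol(patch)
  fs <- ts <- numeric(0)
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!mask[i, j]) next
    fs <- c(fs, frame[py + i, px + j])
    ts <- c(ts, patch[i, j])
  }
  if (raw) return(sum(fs * ts))
  fc <- fs - mean(fs); tc <- ts - mean(ts)
  den <- sqrt(sum(fc^2) * sum(tc^2))
  if (den <= 1e-12) return(0)
  sum(fc * tc) / den
}

ncc_oracle_map <- function(frame, patch, mask, raw = FALSE) {
  oh <- nrow(frame) - nrow(patch) + 1
  ow <- ncol(frame) - ncol(patch) + 1
  out <- matrix(NA_real_, oh, ow)
  for (px in 0:(ow - 1)) for (py in 0:(oh - 1))
    out[py + 1, px + 1] <- ncc_oracle_at(frame, patch, mask, px, py, raw)
  out
}

# independent Sobel edge map (direct kernel application, interior only)
sobel_edges_oracle <- function(img, thresh) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3)   # [dy, dx] layout
  ky <- t(kx)
  h <- nrow(img); w <- ncol(img)
  pts <- NULL
  for (i in 2:(h - 1)) for (j in 2:(w - 1)) {
    win <- img[(i - 1):(i + 1), (j - 1):(j + 1)]
    g <- sqrt(sum(win * kx)^2 + sum(win * ky)^2)
    if (g >= thresh) pts <- rbind(pts, c(x = j - 1, y = i - 1))
  }
  pts
}

# full 3-D accumulator CHT: count edge pixels on each (cx, cy, r) shell,
# return the (cx, cy) of the best-voted cell
hough3d_oracle <- function(img, thresh, radii) {
  pts <- sobel_edges_oracle(img, thresh)
  h <- nrow(img); w <- ncol(img)
  best <- c(NA, NA); best_v <- -1
  for (cx in 0:(w - 1)) for (cy in 0:(h - 1)) {
    d <- sqrt((pts[, "x"] - cx)^2 + (pts[, "y"] - cy)^2)
    for (r in radii) {
      v <- sum(abs(d - r) <= 0.5)
      if (v > best_v) { best_v <- v; best <- c(cx, cy) }
    }
  }
  list(centre = best, votes = best_v)
}

# metric re-implementations straight from their formulas
mae_oracle <- function(a, m) sum(abs(a - m)) / length(a)
mpe_oracle <- function(a, m, eps = 1e-6) {
  s <- 0
  for (i in seq_along(a)) s <- s + abs(a[i] - m[i]) / (a[i] + eps)
  s / length(a) * 100
}
rmse_oracle <- function(a, m) sqrt(sum((a - m)^2) / length(a))
pearson_oracle <- function(a, m) {
  n <- length(a)
  r <- sum((a - mean(a)) * (m - mean(m))) /
    sqrt(sum((a - mean(a))^2) * sum((m - mean(m))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  # survival function via the incomplete-beta identity, independent of pt()
  p <- pbeta((n - 2) / ((n - 2) + t^2), (n - 2) / 2, 0.5)
  list(r = r, t = t, p = p)
}

# plain dark disc on a light field, matrix[y, x] with 0-based coordinates
render_disc <- function(h, w, cx, cy, r, fg = 60, bg = 220) {
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), times = w), h, w)
  img <- matrix(bg, h, w)
  img[(xs - cx)^2 + (ys - cy)^2 <= r^2] <- fg
  img
}
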