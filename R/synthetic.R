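#' Synthetic eye-scene configuration
#'
#' Parameterises the rendered eye: a light sclera field, a dark iris disc
#' with a darker pupil, elliptical eyelids occluding the top and bottom of
#' the iris, small bright specular glints, eyelash strokes below the upper
#' lid, and seeded Gaussian intensity noise. Iris tones map to mean
#' intensities — brown 60, green 110, gray 140 on the 0–255 scale, against
#' a 220 sclera — so darker irises give the strongest contrast.
#'
#' @param width,height Frame size in pixels. Default 240 x 160 (an eye-sized
#'   crop whose default iris radius of 30 px sits inside the detector's
#'   15–50 px radius window).
#' @param fps Frames per second. Default 30.
#' @param iris_radius Iris radius in pixels. Default 30.
#' @param iris_tone `"brown"`, `"green"` or `"gray"`.
#' @param pupil_fraction Pupil radius as a fraction of the iris radius.
#' @param sclera_intensity,lid_intensity,pupil_intensity Mean intensities of
#'   the sclera, eyelid skin and pupil.
#' @param coverage_top,coverage_bottom Eyelid occlusion as a fraction of the
#'   iris height covered from above/below, in `[0, 1)`. Defaults 0.15 / 0.05
#'   (lids naturally open).
#' @param coverage_jitter Per-frame lid-aperture fluctuation: each rendered
#'   frame deepens the top coverage by a seeded uniform draw on
#'   `[0, coverage_jitter]`, emulating the natural frame-to-frame variation
#'   of the palpebral aperture (sag, partial closure). Frame 0 keeps the
#'   base coverage so the first-frame template is as intact as the scene
#'   allows. Default 0.10.
#' @param glint_count,glint_radius,glint_intensity Specular highlight spots
#'   rendered inside the iris.
#' @param lid_follow Gaze-following gain of the eyelids: the lids are
#'   anchored to the face, not the eyeball, and track a vertical gaze shift
#'   only partially, so looking up or down buries more of the iris under a
#'   lid — the occlusion mechanism behind the larger vertical tracking
#'   errors seen in practice. 0 = lids fixed in the frame, 1 = lids ride
#'   the iris. The upper lid physiologically tracks vertical gaze almost
#'   completely (levator synergy), so the default is 0.9.
#' @param lash_count Number of eyelash strokes below the upper lid.
#' @param noise_sd Additive Gaussian noise standard deviation (intensity
#'   units), clipped to \[0, 255\]. Default 3.
#' @param seed Integer seed fixing all stochastic scene elements.
#' @return A `scene_config` list.
#' @export
scene_config <- function(width = 240L, height = 160L, fps = 30,
                         iris_radius = 30,
                         iris_tone = c("brown", "green", "gray"),
                         pupil_fraction = 0.4,
                         sclera_intensity = 220, lid_intensity = 190,
                         pupil_intensity = 30,
                         coverage_top = 0.15, coverage_bottom = 0.05,
                         coverage_jitter = 0.10, lid_follow = 0.9,
                         glint_count = 2L, glint_radius = 1.5,
                         glint_intensity = 250,
                         lash_count = 6L, noise_sd = 3, seed = 1L) {
  iris_tone <- match.arg(iris_tone)
  stopifnot(coverage_top >= 0, coverage_top < 1,
            coverage_bottom >= 0, coverage_bottom < 1,
            iris_radius > 0, pupil_fraction > 0, pupil_fraction < 1)
  tone_map <- c(brown = 60, green = 110, gray = 140)
  structure(list(width = as.integer(width), height = as.integer(height),
                 fps = fps, iris_radius = iris_radius,
                 iris_tone = iris_tone,
                 iris_intensity = unname(tone_map[iris_tone]),
                 pupil_fraction = pupil_fraction,
                 sclera_intensity = sclera_intensity,
                 lid_intensity = lid_intensity,
                 pupil_intensity = pupil_intensity,
                 coverage_top = coverage_top,
                 coverage_bottom = coverage_bottom,
                 coverage_jitter = coverage_jitter,
                 lid_follow = lid_follow,
                 glint_count = as.integer(glint_count),
                 glint_radius = glint_radius,
                 glint_intensity = glint_intensity,
                 lash_count = as.integer(lash_count),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scene_config")
}

#' Gaze-task specification
#'
#' The four stimulus tasks: `vertical` and `horizontal` move the target out
#' and back along a line (a single triangular cycle — out to one side,
#' across to the other, back to centre), `circular` completes one full
#' revolution at constant angular speed, `fixation` holds one point.
#' Durations of 1 s and 5 s emulate fast and slow movements.
#'
#' @param task One of `"vertical"`, `"horizontal"`, `"circular"`,
#'   `"fixation"`.
#' @param duration_s Movement duration in seconds, 1 or 5.
#' @param amplitude Peak displacement (or circle radius) in pixels.
#' @param centre Motion centre `(x, y)`; `NULL` means the frame centre.
#' @return A `task_spec` list.
#' @export
task_spec <- function(task = c("vertical", "horizontal", "circular",
                               "fixation"),
                      duration_s = 5, amplitude = 35, centre = NULL) {
  task <- match.arg(task)
  stopifnot(duration_s %in% c(1, 5), amplitude >= 0)
  structure(list(task = task, duration_s = duration_s,
                 amplitude = amplitude, centre = centre),
            class = "task_spec")
}

# single triangular cycle on [0,1]: 0 -> +1 -> -1 -> 0
triangular_cycle <- function(u) {
  ifelse(u < 0.25, 4 * u, ifelse(u < 0.75, 2 - 4 * u, -4 + 4 * u))
}

#' Generate the per-frame target trajectory of a task
#'
#' @param spec A [task_spec()].
#' @param fps Frames per second.
#' @param cfg Optional [scene_config()]; when given, the motion centre
#'   defaults to the frame centre and the trajectory is checked to keep the
#'   iris at least `margin` px inside the frame.
#' @param margin Border clearance in pixels used for that check. Default 5.
#' @return Tibble with `frame_index`, `x`, `y` — one row per frame,
#'   `duration_s * fps` rows in total.
#' @export
make_trajectory <- function(spec, fps = 30, cfg = NULL, margin = 5) {
  n <- as.integer(round(spec$duration_s * fps))
  centre <- spec$centre
  if (is.null(centre)) {
    if (is.null(cfg)) stop("supply spec$centre or cfg", call. = FALSE)
    centre <- c((cfg$width - 1) / 2, (cfg$height - 1) / 2)
  }
  u <- if (n == 1) 0 else (seq_len(n) - 1) / (n - 1)
  xy <- switch(spec$task,
    fixation = cbind(rep(centre[1], n), rep(centre[2], n)),
    horizontal = cbind(centre[1] + spec$amplitude * triangular_cycle(u),
                       rep(centre[2], n)),
    vertical = cbind(rep(centre[1], n),
                     centre[2] + spec$amplitude * triangular_cycle(u)),
    circular = cbind(centre[1] + spec$amplitude * cos(2 * pi * u),
                     centre[2] + spec$amplitude * sin(2 * pi * u)))
  if (!is.null(cfg)) {
    lim <- cfg$iris_radius + margin
    if (min(xy[, 1]) < lim || max(xy[, 1]) > cfg$width - 1 - lim ||
        min(xy[, 2]) < lim || max(xy[, 2]) > cfg$height - 1 - lim)
      stop("amplitude pushes the iris within ", margin,
           " px of the frame border", call. = FALSE)
  }
  tibble::tibble(frame_index = seq_len(n) - 1L, x = xy[, 1], y = xy[, 2])
}

# Seeded per-video layout of glint offsets and lash strokes. Glints ride
# with the iris (offsets relative to its centre); lashes hang from the top
# lid, expressed relative to the iris centre as well.
scene_layout <- function(cfg) {
  with_seed(cfg$seed, {
    ang <- runif(cfg$glint_count, 0, 2 * pi)
    rad <- runif(cfg$glint_count, 0.2, 0.55) * cfg$iris_radius
    glints <- cbind(dx = rad * cos(ang), dy = rad * sin(ang))
    lx <- runif(cfg$lash_count, -1.6, 1.6) * cfg$iris_radius
    lang <- runif(cfg$lash_count, pi / 3, 2 * pi / 3)  # roughly downward
    llen <- runif(cfg$lash_count, 4, 9)
    list(glints = glints,
         lashes = data.frame(dx = lx, angle = lang, len = llen))
  })
}

# run expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# top lid is the interior of a wide ellipse whose lowest point dips
# `coverage * 2r` into the iris; bottom lid mirrored
lid_mask <- function(xs, ys, cx, cy, r, coverage, side = c("top", "bottom")) {
  side <- match.arg(side)
  if (coverage <= 0) return(matrix(FALSE, nrow(xs), ncol(xs)))
  rx <- 2.5 * r; ry <- 2.0 * r
  depth <- if (side == "top") cy - r + coverage * 2 * r
           else cy + r - coverage * 2 * r
  ecy <- if (side == "top") depth - ry else depth + ry
  ((xs - cx) / rx)^2 + ((ys - ecy) / ry)^2 <= 1
}

#' Render one synthetic eye frame
#'
#' Layers, in order: sclera field, iris disc at the requested centre, pupil
#' disc, eyelid ellipses per the configured coverage (the top lid deepened
#' by the per-frame aperture jitter), glints, lash strokes, additive seeded
#' noise clipped to \[0, 255\]. A blink frame renders the lids fully closed
#' (no iris visible). Noise and jitter are seeded from `cfg$seed` and
#' `frame_index`, so identical inputs give bit-identical frames.
#'
#' @param cfg A [scene_config()].
#' @param centre Iris centre `(x, y)` for this frame.
#' @param blink Render a fully closed eye. Default `FALSE`.
#' @param frame_index Frame number, used only to derive the per-frame noise
#'   stream. Default 0.
#' @param layout Scene layout from the internal seeded draw; passed in by
#'   [simulate_eye_video()] so all frames of one video share glint and lash
#'   geometry.
#' @param eye_centre Resting (primary-gaze) eye position the lids are
#'   anchored to; defaults to the frame centre. Lids follow the iris away
#'   from it with gain `cfg$lid_follow`.
#' @return List with `image` (grayscale matrix), `truth` (one-row tibble
#'   `frame_index`, `x`, `y`, `blink`), `disc_mask` (logical matrix of the
#'   geometric iris disc) and `iris_mask` (disc pixels actually visible,
#'   i.e. not under a lid).
#' @export
render_eye_frame <- function(cfg, centre, blink = FALSE, frame_index = 0L,
                             layout = NULL, eye_centre = NULL) {
  if (is.null(layout)) layout <- scene_layout(cfg)
  h <- cfg$height; w <- cfg$width
  if (is.null(eye_centre)) eye_centre <- c((w - 1) / 2, (h - 1) / 2)
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), times = w), h, w)
  img <- matrix(cfg$sclera_intensity, h, w)
  cx <- centre[1]; cy <- centre[2]; r <- cfg$iris_radius
  disc_mask <- iris_mask <- matrix(FALSE, h, w)

  frame_seed <- (cfg$seed * 100003L + as.integer(frame_index)) %%
    .Machine$integer.max
  jitter <- if (frame_index > 0 && cfg$coverage_jitter > 0)
    with_seed(frame_seed + 1L, runif(1, 0, cfg$coverage_jitter)) else 0
  cov_top <- min(cfg$coverage_top + jitter, 0.95)

  if (!blink) {
    d2 <- (xs - cx)^2 + (ys - cy)^2
    disc_mask <- d2 <= r^2
    img[disc_mask] <- cfg$iris_intensity
    img[d2 <= (cfg$pupil_fraction * r)^2] <- cfg$pupil_intensity
    for (g in seq_len(nrow(layout$glints))) {
      gx <- cx + layout$glints[g, "dx"]; gy <- cy + layout$glints[g, "dy"]
      img[(xs - gx)^2 + (ys - gy)^2 <= cfg$glint_radius^2] <-
        cfg$glint_intensity
    }
    # lids are anchored to the face and follow vertical gaze only partially
    lid_cx <- eye_centre[1]
    lid_cy <- eye_centre[2] + cfg$lid_follow * (cy - eye_centre[2])
    top <- lid_mask(xs, ys, lid_cx, lid_cy, r, cov_top, "top")
    bot <- lid_mask(xs, ys, lid_cx, lid_cy, r, cfg$coverage_bottom,
                    "bottom")
    img[top | bot] <- cfg$lid_intensity
    iris_mask <- disc_mask & !(top | bot)
    lid_edge_y <- lid_cy - r + cov_top * 2 * r
    img <- draw_lashes(img, layout$lashes, lid_cx, lid_edge_y)
  } else {
    img[] <- cfg$lid_intensity
    # closed-lid crease: a faint dark horizontal band at mid-height
    img[abs(ys - cy) <= 1] <- cfg$lid_intensity - 40
    img <- draw_lashes(img, layout$lashes, cx, cy)
  }

  if (cfg$noise_sd > 0) {
    img <- img + with_seed(frame_seed, matrix(rnorm(h * w, 0, cfg$noise_sd),
                                              h, w))
  }
  img <- pmin(pmax(img, 0), 255)
  list(image = img,
       truth = tibble::tibble(frame_index = as.integer(frame_index),
                              x = centre[1], y = centre[2], blink = blink),
       disc_mask = disc_mask, iris_mask = iris_mask)
}

# short dark strokes hanging from the top lid edge
draw_lashes <- function(img, lashes, cx, lid_edge_y) {
  h <- nrow(img); w <- ncol(img)
  for (i in seq_len(nrow(lashes))) {
    x0 <- cx + lashes$dx[i]; y0 <- lid_edge_y - 1
    steps <- seq(0, lashes$len[i], by = 0.5)
    px <- round(x0 + steps * cos(lashes$angle[i]))
    py <- round(y0 + steps * sin(lashes$angle[i]))
    ok <- px >= 0 & px < w & py >= 0 & py < h
    img[cbind(py[ok] + 1, px[ok] + 1)] <- 45
  }
  img
}

#' Simulate a ground-truth-annotated eye video
#'
#' Renders `duration_s * fps` frames following the task trajectory, with
#' optional injected blink frames, and returns them with per-frame ground
#' truth. Optionally writes per-frame PNGs, a `truth.csv`
#' (`frame_index,x,y,blink`) and the scene configuration as YAML to
#' `out_dir`.
#'
#' @param cfg A [scene_config()].
#' @param spec A [task_spec()].
#' @param blink_frames Integer frame indices rendered as blinks.
#' @param out_dir Optional output directory.
#' @param sampling_interval Keep every k-th frame (applied after rendering,
#'   aligned with [extract_frames()]'s convention of starting at frame 0).
#'   Default 1 keeps all frames.
#' @return List with `frames` (frame tibble), `truth` (tibble
#'   `frame_index`, `x`, `y`, `blink`, `valid`), `cfg`, `spec`.
#' @export
simulate_eye_video <- function(cfg = scene_config(), spec = task_spec(),
                               blink_frames = integer(0), out_dir = NULL,
                               sampling_interval = 1L) {
  traj <- make_trajectory(spec, fps = cfg$fps, cfg = cfg)
  layout <- scene_layout(cfg)
  keep <- traj$frame_index %% sampling_interval == 0
  rest <- spec$centre
  if (is.null(rest)) rest <- c((cfg$width - 1) / 2, (cfg$height - 1) / 2)
  rendered <- purrr::map(which(keep), function(i) {
    render_eye_frame(cfg, c(traj$x[i], traj$y[i]),
                     blink = traj$frame_index[i] %in% blink_frames,
                     frame_index = traj$frame_index[i], layout = layout,
                     eye_centre = rest)
  })
  truth <- purrr::map_dfr(rendered, "truth")
  truth$valid <- !truth$blink
  frames <- frame_table(purrr::map(rendered, "image"),
                        index = truth$frame_index, fps = cfg$fps)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(frames))) {
      png::writePNG(frames$image[[i]] / 255,
                    file.path(out_dir, sprintf("frame_%05d.png",
                                               frames$index[i])))
    }
    readr::write_csv(truth, file.path(out_dir, "truth.csv"))
    yaml::write_yaml(unclass(cfg), file.path(out_dir, "scene.yaml"))
  }
  list(frames = frames, truth = truth, cfg = cfg, spec = spec)
}
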