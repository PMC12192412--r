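#' Track a video with CHT_TM (template matching after the first frame)
#'
#' The first frame runs the full CHT_ACM detection and yields the iris
#' template; every later frame is localised by masked template matching
#' followed by darkest-region selection. The template is never updated.
#' Frames whose best similarity falls below the validity floor (blinks,
#' lost track) are marked invalid and skipped, never dropped.
#'
#' @param frames Frame tibble from [frame_table()], [extract_frames()] or
#'   [simulate_eye_video()].
#' @param cfg A [track_config()].
#' @return An `iris_trajectory` tibble: `frame_index`, `time_s`, `x`, `y`,
#'   `valid`, `similarity` (NA for the detection frame), `method`.
#' @export
track_video_cht_tm <- function(frames, cfg = track_config()) {
  stopifnot(nrow(frames) >= 1)
  first <- frames$image[[1]]
  det <- detect_iris_cht_acm(first, cfg)
  if (!det$ok)
    stop("first-frame iris detection failed (", det$reason,
         "): no template obtainable", call. = FALSE)
  tmpl <- extract_template(first, det$centre, det$radius,
                           margin = cfg$template_margin)

  n <- nrow(frames)
  x <- rep(NA_real_, n); y <- rep(NA_real_, n)
  valid <- rep(FALSE, n); sim <- rep(NA_real_, n)
  method <- c("CHT_ACM", rep("CHT_TM", max(0, n - 1)))
  x[1] <- det$centre[1]; y[1] <- det$centre[2]; valid[1] <- TRUE

  for (i in seq_len(n)[-1]) {
    if (!frames$valid[i]) next
    cands <- match_template(frames$image[[i]], tmpl,
                            use_mask = cfg$use_mask,
                            sim_threshold = cfg$sim_threshold,
                            method = cfg$match_method)
    if (attr(cands, "degenerate") || nrow(cands) == 0) next
    if (cfg$match_method == "ncc" &&
        attr(cands, "max_similarity") < cfg$min_similarity) next
    sel <- select_darkest(frames$image[[i]], cands, tmpl)
    x[i] <- sel$centre[1]; y[i] <- sel$centre[2]
    sim[i] <- sel$similarity; valid[i] <- TRUE
  }
  traj <- tibble::tibble(frame_index = frames$index, time_s = frames$time_s,
                         x = x, y = y, valid = valid, similarity = sim,
                         method = method)
  attr(traj, "template") <- tmpl
  attr(traj, "tracker") <- "CHT_TM"
  new_trajectory(traj)
}

#' Track a video with CHT_ACM on every frame
#'
#' Applies [detect_iris_cht_acm()] independently to each frame; per-frame
#' failures become invalid records.
#'
#' @inheritParams track_video_cht_tm
#' @return An `iris_trajectory` tibble (see [track_video_cht_tm()]).
#' @export
track_video_cht_acm <- function(frames, cfg = track_config()) {
  stopifnot(nrow(frames) >= 1)
  n <- nrow(frames)
  x <- rep(NA_real_, n); y <- rep(NA_real_, n); valid <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (!frames$valid[i]) next
    det <- detect_iris_cht_acm(frames$image[[i]], cfg)
    if (!det$ok) next
    x[i] <- det$centre[1]; y[i] <- det$centre[2]; valid[i] <- TRUE
  }
  traj <- tibble::tibble(frame_index = frames$index, time_s = frames$time_s,
                         x = x, y = y, valid = valid,
                         similarity = NA_real_,
                         method = "CHT_ACM")
  attr(traj, "tracker") <- "CHT_ACM"
  new_trajectory(traj)
}

#' Re-apply validity flags to a trajectory
#'
#' Marks records invalid when they carry no centre or when their match
#' similarity falls below the absolute floor. Valid-frame centres are never
#' modified; invalidated records get `NA` centres.
#'
#' @param traj An `iris_trajectory`.
#' @param frames Optional frame tibble aligned with `traj`; frames flagged
#'   invalid there are propagated.
#' @param cfg A [track_config()] supplying `min_similarity`.
#' @return The re-flagged trajectory.
#' @export
flag_invalid_frames <- function(traj, frames = NULL, cfg = track_config()) {
  bad <- is.na(traj$x) | is.na(traj$y)
  has_sim <- !is.na(traj$similarity)
  bad <- bad | (has_sim & traj$similarity < cfg$min_similarity)
  if (!is.null(frames)) {
    m <- match(traj$frame_index, frames$index)
    bad <- bad | (!is.na(m) & !frames$valid[m])
  }
  traj$valid <- traj$valid & !bad
  traj$x[!traj$valid] <- NA_real_
  traj$y[!traj$valid] <- NA_real_
  traj
}
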