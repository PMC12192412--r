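#' Per-axis trajectory error metrics
#'
#' The four validation metrics used to compare an algorithm trajectory with
#' ground truth, computed independently per axis:
#' mean absolute error `MAE = mean(|a - m|)` (pixels), mean percentage
#' error `MPE = mean(|a - m| / (a + epsilon)) * 100` (percent, relative to
#' the raw pixel coordinate, so origin-dependent by construction), root mean
#' square error `RMSE = sqrt(mean((a - m)^2))` (pixels), and the Pearson
#' correlation with its t statistic (`t = r * sqrt((n - 2) / (1 - r^2))`)
#' and two-tailed p-value from the Student-t survival function on `n - 2`
#' degrees of freedom.
#'
#' @param actual Numeric vector of ground-truth coordinates (pixels).
#' @param measured Numeric vector of algorithm coordinates, same length.
#' @param epsilon Guard added to the denominator of MPE so a coordinate of
#'   zero cannot divide by zero. Default `1e-6` pixels.
#' @return `mae`, `rmse` return pixels; `mpe` percent; `pearson_cc` a list
#'   with `r`, `t`, `p`.
#' @name axis-metrics
NULL

check_series <- function(actual, measured, min_n = 1) {
  stopifnot(length(actual) == length(measured))
  if (length(actual) < min_n)
    stop("series too short: need at least ", min_n, " paired frames",
         call. = FALSE)
  if (anyNA(actual) || anyNA(measured))
    stop("series contain NA; pair only co-valid frames first", call. = FALSE)
}

#' @rdname axis-metrics
#' @export
mae <- function(actual, measured) {
  check_series(actual, measured)
  mean(abs(actual - measured))
}

#' @rdname axis-metrics
#' @export
mpe <- function(actual, measured, epsilon = 1e-6) {
  check_series(actual, measured)
  mean(abs(actual - measured) / (actual + epsilon)) * 100
}

#' @rdname axis-metrics
#' @export
rmse <- function(actual, measured) {
  check_series(actual, measured)
  sqrt(mean((actual - measured)^2))
}

#' @rdname axis-metrics
#' @export
pearson_cc <- function(actual, measured) {
  check_series(actual, measured, min_n = 3)
  n <- length(actual)
  da <- actual - mean(actual); dm <- measured - mean(measured)
  den <- sqrt(sum(da^2) * sum(dm^2))
  if (den == 0)
    stop("correlation undefined: at least one series is constant",
         call. = FALSE)
  r <- sum(da * dm) / den
  if (abs(r) >= 1 - 1e-12) {
    # perfectly linear: t diverges; report the limit rather than 0/0
    return(list(r = sign(r), t = Inf * sign(r), p = 0))
  }
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(abs(t), df = n - 2, lower.tail = FALSE)
  list(r = r, t = t, p = p)
}

#' Evaluate a trajectory against ground truth
#'
#' Pairs the trajectory with the truth on frame index, keeps only frames
#' valid in both (blink or failed frames are excluded pairwise), and
#' computes all four per-axis metrics.
#'
#' On tasks where one axis is constant in the truth (a fixation, or a purely
#' horizontal/vertical movement) the correlation is undefined; those fields
#' are reported as `NA` rather than raising, since the error metrics remain
#' meaningful.
#'
#' @param traj Trajectory tibble (`frame_index`, `x`, `y`, `valid`).
#' @param truth Ground-truth tibble with the same columns (a `blink` column
#'   is treated as the negation of `valid` if `valid` is absent).
#' @param epsilon MPE guard, see [mpe()].
#' @return An `iris_eval` object; see [tidy.iris_eval()] and
#'   [glance.iris_eval()].
#' @export
evaluate_trajectory <- function(traj, truth, epsilon = 1e-6) {
  if (!"valid" %in% names(truth)) {
    truth$valid <- if ("blink" %in% names(truth)) !truth$blink else TRUE
  }
  j <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(traj), "frame_index", mx = "x", my = "y",
                  mvalid = "valid"),
    dplyr::select(tibble::as_tibble(truth), "frame_index", ax = "x", ay = "y",
                  avalid = "valid"),
    by = "frame_index")
  if (nrow(j) == 0)
    stop("trajectory and truth share no frame indices", call. = FALSE)
  ok <- j$mvalid & j$avalid
  if (!any(ok))
    stop("no co-valid frames to evaluate", call. = FALSE)
  jv <- j[ok, ]

  axis_metrics <- function(a, m) {
    pcc <- tryCatch(pearson_cc(a, m),
                    error = function(e) list(r = NA_real_, t = NA_real_,
                                             p = NA_real_))
    list(mae = mae(a, m), mpe = mpe(a, m, epsilon), rmse = rmse(a, m),
         pearson_r = pcc$r, t_stat = pcc$t, p_value = pcc$p)
  }
  structure(list(x = axis_metrics(jv$ax, jv$mx),
                 y = axis_metrics(jv$ay, jv$my),
                 n_valid = sum(ok), n_invalid = sum(!ok),
                 epsilon = epsilon),
            class = "iris_eval")
}

#' @export
print.iris_eval <- function(x, ...) {
  cat(sprintf(
    "<iris_eval> %d co-valid frames (%d excluded)\n", x$n_valid, x$n_invalid))
  for (ax in c("x", "y")) {
    m <- x[[ax]]
    cat(sprintf(
      "  %s: MAE %.3f px  MPE %.3f%%  RMSE %.3f px  r %.4f (p %.3g)\n",
      ax, m$mae, m$mpe, m$rmse, m$pearson_r, m$p_value))
  }
  invisible(x)
}

#' Tidy an evaluation into one row per axis
#'
#' @param x An `iris_eval`.
#' @param ... Unused.
#' @return Tibble with columns `axis`, `mae`, `mpe`, `rmse`, `pearson_r`,
#'   `t_stat`, `p_value`, `n`.
#' @export
#' @exportS3Method generics::tidy
tidy.iris_eval <- function(x, ...) {
  purrr::map_dfr(c("x", "y"), function(ax) {
    tibble::tibble(axis = ax, !!!x[[ax]], n = x$n_valid)
  })
}

#' One-line summary of an evaluation
#'
#' @param x An `iris_eval`.
#' @param ... Unused.
#' @return One-row tibble with per-axis MAE/RMSE, the pooled mean MAE, and
#'   frame counts.
#' @export
#' @exportS3Method generics::glance
glance.iris_eval <- function(x, ...) {
  tibble::tibble(mae_x = x$x$mae, mae_y = x$y$mae,
                 rmse_x = x$x$rmse, rmse_y = x$y$rmse,
                 mae_mean = (x$x$mae + x$y$mae) / 2,
                 n_valid = x$n_valid, n_invalid = x$n_invalid)
}

#' Grouped comparison table
#'
#' Arranges a set of evaluations (one per experimental condition) into a
#' long table with one row per axis and group, columns `MAE`, `MPE`,
#' `RMSE`, `PCC_r`, `PCC_p`, and flags marking the best performer — lowest
#' error, highest correlation — within each row family.
#'
#' @param reports Tibble with one or more grouping columns (e.g.
#'   `condition`, `task`, `speed`, `method`, `subject`) and a `metrics` list
#'   column of `iris_eval` objects.
#' @param compare Name of the grouping column whose levels are compared for
#'   the best-performer flags; rows are grouped by `axis` and all remaining
#'   key columns. `NULL` (default) compares across all rows per axis. With a
#'   single report, flags are `NA`.
#' @return Long tibble with the keys, `axis`, metric columns and logical
#'   `best_mae`, `best_mpe`, `best_rmse`, `best_pcc` flags.
#' @export
compare_groups <- function(reports, compare = NULL) {
  stopifnot(nrow(reports) >= 1, "metrics" %in% names(reports))
  keys <- setdiff(names(reports), "metrics")
  long <- purrr::map_dfr(seq_len(nrow(reports)), function(i) {
    td <- tidy(reports$metrics[[i]])
    dplyr::bind_cols(reports[rep(i, nrow(td)), keys, drop = FALSE],
                     tibble::tibble(axis = td$axis, MAE = td$mae,
                                    MPE = td$mpe, RMSE = td$rmse,
                                    PCC_r = td$pearson_r, PCC_p = td$p_value,
                                    n = td$n))
  })
  fam <- c("axis", if (!is.null(compare)) setdiff(keys, compare))
  long <- dplyr::group_by(long, dplyr::across(dplyr::all_of(fam)))
  flag <- function(v, best) {
    if (dplyr::n() < 2 || all(is.na(v))) return(rep(NA, length(v)))
    v == best(v, na.rm = TRUE)
  }
  long <- dplyr::mutate(long,
                        best_mae = flag(.data$MAE, min),
                        best_mpe = flag(.data$MPE, min),
                        best_rmse = flag(.data$RMSE, min),
                        best_pcc = flag(.data$PCC_r, max))
  dplyr::ungroup(long)
}

#' Evaluate several videos together
#'
#' Two aggregations over a set of trajectory/truth pairs: `"pooled"`
#' concatenates the co-valid frame pairs of all videos and computes one set
#' of metrics over them (the mean over all frames of all videos), while
#' `"per_video"` evaluates each video separately and averages the per-video
#' metric values.
#'
#' @param trajs List of trajectory tibbles.
#' @param truths List of matching ground-truth tibbles.
#' @param aggregate `"pooled"` (default) or `"per_video"`.
#' @param epsilon MPE guard, see [mpe()].
#' @return For `"pooled"`, an `iris_eval`; for `"per_video"`, a tibble with
#'   one row per axis of averaged metrics plus the video count.
#' @export
evaluate_videos <- function(trajs, truths, aggregate = c("pooled",
                                                         "per_video"),
                            epsilon = 1e-6) {
  aggregate <- match.arg(aggregate)
  stopifnot(length(trajs) == length(truths), length(trajs) >= 1)
  if (aggregate == "per_video") {
    td <- purrr::map_dfr(seq_along(trajs), function(i) {
      dplyr::mutate(tidy(evaluate_trajectory(trajs[[i]], truths[[i]],
                                             epsilon)), video = i)
    })
    out <- dplyr::summarise(
      dplyr::group_by(td, .data$axis),
      dplyr::across(c("mae", "mpe", "rmse", "pearson_r"),
                    ~mean(.x, na.rm = TRUE)),
      n_videos = dplyr::n(), .groups = "drop")
    return(out)
  }
  # pooled: offset frame indices so videos cannot collide, then evaluate once
  off <- 0L
  all_t <- list(); all_g <- list()
  for (i in seq_along(trajs)) {
    tr <- tibble::as_tibble(trajs[[i]]); gt <- tibble::as_tibble(truths[[i]])
    tr$frame_index <- tr$frame_index + off
    gt$frame_index <- gt$frame_index + off
    off <- off + max(tr$frame_index, gt$frame_index) + 1L
    all_t[[i]] <- tr[c("frame_index", "x", "y", "valid")]
    if (!"valid" %in% names(gt))
      gt$valid <- if ("blink" %in% names(gt)) !gt$blink else TRUE
    all_g[[i]] <- gt[c("frame_index", "x", "y", "valid")]
  }
  evaluate_trajectory(dplyr::bind_rows(all_t), dplyr::bind_rows(all_g),
                      epsilon)
}
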