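#' Benchmark both trackers on a shared frame set
#'
#' Times CHT_ACM and CHT_TM on the first 10/40/100/400 frames (the default
#' grid) of the same in-memory sequence, with optional repetitions. Because
#' frames are in memory, the figures exclude file I/O; absolute times are
#' hardware-dependent, so the headline quantity is the per-frame ratio.
#'
#' @param frames Frame tibble with at least `max(sizes)` rows.
#' @param cfg A [track_config()].
#' @param sizes Frame-count grid. Default `c(10, 40, 100, 400)`.
#' @param repetitions Repeats per cell; reported times are means, the
#'   spread is retained in the per-repetition table. Default 1.
#' @return List with `timings` (method, n_frames, rep, total_s,
#'   per_frame_s), `summary` (mean per-frame seconds per method and size)
#'   and `speed_ratio` (mean ACM / mean TM per-frame time over the largest
#'   size).
#' @export
run_benchmark <- function(frames, cfg = track_config(),
                          sizes = c(10L, 40L, 100L, 400L),
                          repetitions = 1L) {
  if (nrow(frames) < max(sizes))
    stop("insufficient frames: have ", nrow(frames), ", the largest ",
         "requested size needs ", max(sizes), call. = FALSE)
  trackers <- list(CHT_ACM = track_video_cht_acm,
                   CHT_TM = track_video_cht_tm)
  grid <- expand.grid(method = names(trackers), n_frames = sizes,
                      rep = seq_len(repetitions), stringsAsFactors = FALSE)
  timings <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    n <- grid$n_frames[i]
    f <- trackers[[grid$method[i]]]
    el <- system.time(f(frames[seq_len(n), ], cfg))[["elapsed"]]
    tibble::tibble(method = grid$method[i], n_frames = n, rep = grid$rep[i],
                   total_s = el, per_frame_s = el / n)
  })
  summ <- dplyr::summarise(
    dplyr::group_by(timings, .data$method, .data$n_frames),
    mean_total_s = mean(.data$total_s),
    mean_per_frame_s = mean(.data$per_frame_s),
    sd_per_frame_s = stats::sd(.data$per_frame_s),
    .groups = "drop")
  big <- dplyr::filter(summ, .data$n_frames == max(sizes))
  ratio <- big$mean_per_frame_s[big$method == "CHT_ACM"] /
    big$mean_per_frame_s[big$method == "CHT_TM"]
  list(timings = timings, summary = summ, speed_ratio = ratio)
}

#' Run the full pipeline: simulate, track, evaluate
#'
#' Renders a synthetic task video, samples it at the configured interval,
#' tracks it with both CHT_TM and CHT_ACM, evaluates both against the
#' ground truth and writes every artifact — frames, two trajectory CSVs,
#' the comparison report CSV and a JSON run manifest — to one output
#' directory. With the same seed the outputs are byte-identical across
#' runs.
#'
#' @param out_dir Output directory (created if missing).
#' @param scene A [scene_config()].
#' @param task A [task_spec()].
#' @param cfg A [track_config()].
#' @param sampling_interval Keep every k-th rendered frame. Default 10.
#' @param blink_frames Frame indices rendered as blinks.
#' @param write_frames Write per-frame PNGs. Default `TRUE`.
#' @return List with `trajectories` (named list of tibbles), `reports`
#'   (named list of `iris_eval`), `comparison` (tibble), `paths`.
#' @export
run_end_to_end <- function(out_dir, scene = scene_config(),
                           task = task_spec(), cfg = track_config(),
                           sampling_interval = 10L,
                           blink_frames = integer(0),
                           write_frames = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_eye_video(scene, task, blink_frames = blink_frames,
                            out_dir = if (write_frames) out_dir else NULL,
                            sampling_interval = sampling_interval)
  if (!write_frames)
    readr::write_csv(sim$truth, file.path(out_dir, "truth.csv"))

  run_stage <- function(label, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", label, conditionMessage(e)), call. = FALSE))
  }
  trajs <- list(
    CHT_TM = run_stage("track/cht_tm", track_video_cht_tm(sim$frames, cfg)),
    CHT_ACM = run_stage("track/cht_acm", track_video_cht_acm(sim$frames, cfg)))
  paths <- list(truth = file.path(out_dir, "truth.csv"))
  for (m in names(trajs)) {
    p <- file.path(out_dir, paste0("trajectory_", tolower(m), ".csv"))
    write_trajectory_csv(trajs[[m]], p)
    paths[[m]] <- p
  }
  reports <- purrr::imap(trajs, function(tr, m)
    run_stage(paste0("evaluate/", m), evaluate_trajectory(tr, sim$truth)))
  comparison <- compare_groups(
    tibble::tibble(method = names(reports), metrics = unname(reports)),
    compare = "method")
  readr::write_csv(comparison, file.path(out_dir, "report.csv"))
  paths$report <- file.path(out_dir, "report.csv")

  manifest <- list(
    subcommand = "end_to_end",
    scene = unclass(scene), task = unclass(task),
    config = unclass_deep(cfg),
    sampling_interval = as.integer(sampling_interval),
    blink_frames = as.integer(blink_frames),
    seed = scene$seed,
    output_paths = lapply(paths, basename),
    version = as.character(utils::packageVersion("iristrack")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths$manifest <- file.path(out_dir, "manifest.json")
  list(trajectories = trajs, reports = reports, comparison = comparison,
       paths = paths)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
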