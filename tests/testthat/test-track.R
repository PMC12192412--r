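sim_short <- function(task = "horizontal", seed = 1, ...) {
  simulate_eye_video(scene_config(seed = seed, ...), task_spec(task, 5),
                     sampling_interval = 10)
}

test_that("CHT_TM recovers a task trajectory within 2 px per axis", {
  sim <- sim_short("horizontal", seed = 1)
  traj <- track_video_cht_tm(sim$frames)
  expect_s3_class(traj, "iris_trajectory")
  expect_identical(traj$method[1], "CHT_ACM")  # first frame is the detector
  expect_true(all(traj$method[-1] == "CHT_TM"))
  ev <- evaluate_trajectory(traj, sim$truth)
  expect_lt(ev$x$mae, 2)
  expect_lt(ev$y$mae, 2)
})

test_that("CHT_ACM tracks every frame independently within the same budget", {
  sim <- sim_short("vertical", seed = 2)
  traj <- track_video_cht_acm(sim$frames)
  ev <- evaluate_trajectory(traj, sim$truth)
  expect_lt(ev$x$mae, 2)
  expect_lt(ev$y$mae, 2)
  # identical frames give identical centres
  rep10 <- frame_table(rep(sim$frames$image[1], 5))
  tr <- track_video_cht_acm(rep10)
  expect_identical(length(unique(tr$x)), 1L)
  expect_identical(length(unique(tr$y)), 1L)
})

test_that("a single-frame input yields a length-1 trajectory via the detector", {
  sim <- sim_short(seed = 3)
  traj <- track_video_cht_tm(sim$frames[1, ])
  expect_identical(nrow(traj), 1L)
  expect_true(traj$valid)
  expect_identical(traj$method, "CHT_ACM")
})

test_that("injected blink frames are flagged invalid, and only those", {
  sim <- simulate_eye_video(scene_config(seed = 4), task_spec("vertical", 5),
                            blink_frames = c(60, 70, 80),
                            sampling_interval = 10)
  traj <- track_video_cht_tm(sim$frames)
  expect_identical(traj$frame_index[!traj$valid], c(60L, 70L, 80L))
  ev <- evaluate_trajectory(traj, sim$truth)
  expect_identical(ev$n_valid, 12L)
  expect_identical(ev$n_invalid, 3L)
})

test_that("a first-frame blink aborts tracking with a diagnostic", {
  sim <- simulate_eye_video(scene_config(seed = 5), task_spec("fixation", 1),
                            blink_frames = 0:29, sampling_interval = 10)
  expect_error(track_video_cht_tm(sim$frames), "no template obtainable")
})

test_that("the template is never updated during tracking", {
  sim <- sim_short("circular", seed = 6)
  traj <- track_video_cht_tm(sim$frames)
  tmpl_used <- attr(traj, "template")
  det <- detect_iris_cht_acm(sim$frames$image[[1]])
  tmpl_fresh <- extract_template(sim$frames$image[[1]], det$centre,
                                 det$radius)
  expect_identical(tmpl_used$patch, tmpl_fresh$patch)
  expect_identical(tmpl_used$mask, tmpl_fresh$mask)
})

test_that("the mask curbs the lid bias of raw cross-correlation matching", {
  # the raw product-sum score is dominated by bright regions, so deep lid
  # occlusion drags unmasked matches towards the exposed lower half; the
  # circular mask removes the bright corners and reduces the y error
  sim <- simulate_eye_video(scene_config(seed = 1, coverage_top = 0.25),
                            task_spec("vertical", 5), sampling_interval = 10)
  ev_m <- evaluate_trajectory(
    track_video_cht_tm(sim$frames, track_config(use_mask = TRUE,
                                                match_method = "ccorr")),
    sim$truth)
  ev_u <- evaluate_trajectory(
    track_video_cht_tm(sim$frames, track_config(use_mask = FALSE,
                                                match_method = "ccorr")),
    sim$truth)
  expect_lte(ev_m$y$mae, ev_u$y$mae)
})

test_that("validity re-flagging respects the similarity floor and keeps centres", {
  traj <- tibble::tibble(frame_index = 0:3, time_s = 0:3 / 3,
                         x = c(10, 20, 30, NA), y = c(1, 2, 3, NA),
                         valid = c(TRUE, TRUE, TRUE, FALSE),
                         similarity = c(NA, 0.9, 0.3, NA),
                         method = "CHT_TM")
  out <- flag_invalid_frames(traj)
  expect_identical(out$valid, c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(out$x[1:2], c(10, 20))      # untouched
  expect_true(is.na(out$x[3]))
})
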