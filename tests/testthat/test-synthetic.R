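test_that("task trajectories follow their geometric definitions", {
  cfg <- scene_config()
  fixa <- make_trajectory(task_spec("fixation", 5), cfg = cfg)
  expect_identical(nrow(fixa), 150L)
  expect_identical(length(unique(fixa$x)), 1L)
  expect_identical(length(unique(fixa$y)), 1L)

  hor <- make_trajectory(task_spec("horizontal", 5, amplitude = 35),
                         cfg = cfg)
  x0 <- hor$x[1]
  # apex is attained up to one sampling step (the profile peaks between
  # frames unless n - 1 is divisible by 4)
  step <- 4 * 35 / (nrow(hor) - 1)
  expect_lte(max(abs(hor$x - x0)), 35)
  expect_gte(max(hor$x - x0), 35 - step)
  expect_lte(min(hor$x - x0), -(35 - step))
  expect_equal(hor$x[nrow(hor)], x0)           # returns to the start
  expect_identical(length(unique(hor$y)), 1L)

  circ <- make_trajectory(task_spec("circular", 5, amplitude = 35),
                          cfg = cfg)
  expect_identical(nrow(circ), 150L)
  d <- sqrt((circ$x - (cfg$width - 1) / 2)^2 +
              (circ$y - (cfg$height - 1) / 2)^2)
  expect_true(all(abs(d - 35) < 1e-9))
  expect_equal(c(circ$x[1], circ$y[1]),
               c(circ$x[150], circ$y[150]), tolerance = 1e-9)

  expect_error(make_trajectory(task_spec("vertical", 5, amplitude = 60),
                               cfg = cfg), "border")
})

test_that("rendering is seed-deterministic", {
  cfg <- scene_config(seed = 14)
  f1 <- render_eye_frame(cfg, c(120, 80), frame_index = 3)
  f2 <- render_eye_frame(cfg, c(120, 80), frame_index = 3)
  expect_identical(f1$image, f2$image)
  other <- render_eye_frame(scene_config(seed = 15), c(120, 80),
                            frame_index = 3)
  expect_false(identical(f1$image, other$image))
  sim1 <- simulate_eye_video(cfg, task_spec("fixation", 1))
  sim2 <- simulate_eye_video(cfg, task_spec("fixation", 1))
  expect_identical(sim1$frames$image, sim2$frames$image)
})

test_that("the rendered disc centroid matches the recorded centre within 0.5 px", {
  cfg <- scene_config(seed = 16)
  set.seed(16)
  for (i in 1:5) {
    centre <- c(runif(1, 60, 180), runif(1, 50, 110))
    fr <- render_eye_frame(cfg, centre)
    idx <- which(fr$disc_mask, arr.ind = TRUE)
    centroid <- c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1)  # 0-based (x, y)
    expect_lt(abs(centroid[1] - centre[1]), 0.5)
    expect_lt(abs(centroid[2] - centre[2]), 0.5)
    expect_equal(fr$truth$x, centre[1])
  }
})

test_that("blink frames hide the iris entirely", {
  fr <- render_eye_frame(scene_config(seed = 17), c(120, 80), blink = TRUE)
  expect_false(any(fr$iris_mask))
  expect_true(fr$truth$blink)
})

test_that("videos written to disk align with the sampling convention", {
  dir <- withr::local_tempdir()
  cfg <- scene_config(seed = 18)
  sim <- simulate_eye_video(cfg, task_spec("vertical", 5), out_dir = dir)
  expect_identical(nrow(sim$truth), 150L)
  expect_length(list.files(dir, pattern = "\\.png$"), 150L)
  expect_true(file.exists(file.path(dir, "truth.csv")))
  expect_true(file.exists(file.path(dir, "scene.yaml")))
  fr <- extract_frames(dir, sampling_interval = 10)
  expect_identical(nrow(fr), 15L)
  expect_identical(fr$index, seq(0L, 140L, 10L))
  # frames read back equal the rendered ones up to PNG 8-bit quantisation
  expect_lt(max(abs(fr$image[[2]] - sim$frames$image[[11]])), 0.51)
  # truth subset matches by frame index
  sub <- sim$truth[sim$truth$frame_index %in% fr$index, ]
  expect_identical(nrow(sub), 15L)
})

test_that("deeper eyelid coverage does not improve vertical tracking", {
  err_y <- function(cov, seed) {
    cfg <- scene_config(seed = seed, coverage_top = cov)
    sim <- simulate_eye_video(cfg, task_spec("vertical", 5),
                              sampling_interval = 10)
    evaluate_trajectory(track_video_cht_tm(sim$frames), sim$truth)$y$mae
  }
  seeds <- 1:5
  open_lid <- mean(vapply(seeds, function(s) err_y(0, s), numeric(1)))
  droopy <- mean(vapply(seeds, function(s) err_y(0.4, s), numeric(1)))
  expect_gte(droopy, open_lid)
})
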