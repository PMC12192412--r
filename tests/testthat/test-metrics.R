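test_that("error metrics reproduce hand-computed values", {
  expect_equal(mae(c(10, 20, 30), c(11, 19, 33)), 5 / 3)
  expect_equal(mae(100, 97), 3)
  expect_equal(mae(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(10, 20, 30), c(11, 19, 33)), sqrt(11 / 3))
  expect_equal(rmse(c(5, 5), c(5, 5)), 0)
  expect_equal(mpe(100, 101), 1, tolerance = 1e-6)
  expect_equal(mpe(c(4, 4), c(4, 4)), 0)
  # the epsilon guard keeps a zero coordinate finite
  guarded <- mpe(0, 1, epsilon = 1e-6)
  expect_true(is.finite(guarded))
  expect_equal(guarded, 1e8, tolerance = 1e-6)
  expect_error(mae(numeric(0), numeric(0)), "at least")
})

test_that("all four metrics match brute-force oracles on 100 seeded series pairs", {
  set.seed(61)
  for (i in 1:100) {
    n <- sample(3:50, 1)
    a <- runif(n, 0, 300)
    m <- a + rnorm(n, 0, 5)
    expect_lt(abs(mae(a, m) - mae_oracle(a, m)), 1e-9)
    expect_lt(abs(mpe(a, m) - mpe_oracle(a, m)), 1e-9)
    expect_lt(abs(rmse(a, m) - rmse_oracle(a, m)), 1e-9)
    expect_gte(rmse(a, m), mae(a, m))
    pc <- pearson_cc(a, m); po <- pearson_oracle(a, m)
    expect_lt(abs(pc$r - po$r), 1e-9)
    expect_lt(abs(pc$t - po$t), 1e-9)
    expect_lt(abs(pc$p - po$p), 1e-9)
  }
})

test_that("the correlation handles its edge cases as defined", {
  a <- 1:5
  perfect <- pearson_cc(a, 2 * a)
  expect_identical(perfect$r, 1)
  expect_identical(perfect$p, 0)
  # sample correlation exactly zero -> t = 0, p = 1
  zero <- pearson_cc(c(-1, 0, 1), c(1, -2, 1))
  expect_equal(zero$r, 0)
  expect_equal(zero$t, 0)
  expect_equal(zero$p, 1)
  expect_error(pearson_cc(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(pearson_cc(c(1, 2), c(1, 2)), "at least 3")
  # agreement with the reference implementation in stats
  ct <- stats::cor.test(c(1, 2, 3, 4, 5), c(1, 2, 3, 5, 4))
  pc <- pearson_cc(c(1, 2, 3, 4, 5), c(1, 2, 3, 5, 4))
  expect_lt(abs(pc$r - unname(ct$estimate)), 1e-9)
  expect_lt(abs(pc$t - unname(ct$statistic)), 1e-9)
  expect_lt(abs(pc$p - ct$p.value), 1e-9)
})

test_that("the correlation is invariant under positive affine transforms", {
  set.seed(62)
  a <- runif(20, 0, 100); m <- a + rnorm(20, 0, 10)
  base <- pearson_cc(a, m)
  shifted <- pearson_cc(3 * a + 7, 0.5 * m + 11)
  expect_equal(base$r, shifted$r, tolerance = 1e-12)
  expect_equal(base$p, shifted$p, tolerance = 1e-12)
})

test_that("trajectory evaluation pairs co-valid frames and matches piecewise metrics", {
  truth <- tibble::tibble(frame_index = seq(0L, 90L, 10L),
                          x = seq(100, 145, 5), y = seq(80, 35, -5),
                          valid = c(TRUE, TRUE, FALSE, rep(TRUE, 6), FALSE))
  traj <- tibble::tibble(frame_index = truth$frame_index,
                         x = truth$x + rep(c(1, -1), 5),
                         y = truth$y + rep(c(0.5, -0.5), 5),
                         valid = rep(TRUE, 10))
  ev <- evaluate_trajectory(traj, truth)
  expect_identical(ev$n_valid, 8L)
  expect_identical(ev$n_invalid, 2L)
  keep <- truth$valid
  expect_equal(ev$x$mae, mae(truth$x[keep], traj$x[keep]))
  expect_equal(ev$y$rmse, rmse(truth$y[keep], traj$y[keep]))
  expect_equal(ev$x$pearson_r, pearson_cc(truth$x[keep], traj$x[keep])$r)
  # identical trajectories: zero error, perfect correlation
  same <- evaluate_trajectory(dplyr::mutate(truth, valid = TRUE),
                              dplyr::mutate(truth, valid = TRUE))
  expect_equal(same$x$mae, 0)
  expect_identical(same$x$pearson_r, 1)
  expect_error(evaluate_trajectory(dplyr::mutate(traj, frame_index = 1000L +
                                                   frame_index), truth),
               "share no frame")
  td <- tidy(ev)
  expect_identical(td$axis, c("x", "y"))
  expect_equal(td$mae[1], ev$x$mae)
  expect_identical(glance(ev)$n_valid, 8L)
})

test_that("pooled multi-video evaluation equals metrics over concatenated pairs", {
  mk <- function(seed) {
    set.seed(seed)
    tr <- tibble::tibble(frame_index = 0:9, x = runif(10, 50, 150),
                         y = runif(10, 40, 120), valid = TRUE)
    list(truth = tr,
         traj = dplyr::mutate(tr, x = x + rnorm(10), y = y + rnorm(10)))
  }
  v1 <- mk(71); v2 <- mk(72)
  pooled <- evaluate_videos(list(v1$traj, v2$traj),
                            list(v1$truth, v2$truth))
  expect_equal(pooled$x$mae,
               mae(c(v1$truth$x, v2$truth$x), c(v1$traj$x, v2$traj$x)))
  expect_identical(pooled$n_valid, 20L)
  per <- evaluate_videos(list(v1$traj, v2$traj), list(v1$truth, v2$truth),
                         aggregate = "per_video")
  e1 <- evaluate_trajectory(v1$traj, v1$truth)
  e2 <- evaluate_trajectory(v2$traj, v2$truth)
  expect_equal(per$mae[per$axis == "x"], mean(c(e1$x$mae, e2$x$mae)))
})

test_that("comparison tables flag best performers like an exhaustive oracle", {
  mk_eval <- function(scale) {
    set.seed(81)
    a <- runif(15, 50, 150)
    traj <- tibble::tibble(frame_index = 0:14, x = a + rnorm(15, 0, scale),
                           y = a + rnorm(15, 0, scale), valid = TRUE)
    truth <- tibble::tibble(frame_index = 0:14, x = a, y = a, valid = TRUE)
    evaluate_trajectory(traj, truth)
  }
  reports <- tibble::tibble(method = c("CHT_TM", "CHT_ACM"),
                            metrics = list(mk_eval(0.5), mk_eval(3)))
  cmp <- compare_groups(reports, compare = "method")
  expect_identical(nrow(cmp), 4L)              # 2 methods x 2 axes
  better <- cmp[cmp$method == "CHT_TM", ]
  expect_true(all(better$best_mae))
  expect_true(all(better$best_rmse))
  expect_false(any(cmp$best_mae[cmp$method == "CHT_ACM"]))
  # single group: no flags
  single <- compare_groups(reports[1, ], compare = "method")
  expect_true(all(is.na(single$best_mae)))
  # flag pattern equals the enumeration oracle per axis
  for (ax in c("x", "y")) {
    sub <- cmp[cmp$axis == ax, ]
    expect_identical(sub$best_mae, sub$MAE == min(sub$MAE))
    expect_identical(sub$best_pcc, sub$PCC_r == max(sub$PCC_r))
  }
})
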