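disc_mask <- function(side, r) {
  half <- (side - 1) / 2
  outer((0:(side - 1) - half)^2, (0:(side - 1) - half)^2, "+") <= r^2
}

mk_tmpl <- function(patch, mask, r) {
  structure(list(patch = patch, mask = mask, iris_radius = r,
                 centre_offset = c((ncol(patch) - 1) / 2,
                                   (nrow(patch) - 1) / 2)),
            class = "iris_template")
}

test_that("the similarity map equals the brute-force oracle everywhere", {
  set.seed(51)
  frame <- matrix(runif(24 * 24, 0, 255), 24, 24)
  patch <- matrix(runif(8 * 8, 0, 255), 8, 8)
  mask <- disc_mask(8, 3.6)
  for (masked in c(TRUE, FALSE)) {
    got <- iristrack:::match_map_cpp(frame, patch, mask, masked, 0L)$map
    want <- ncc_oracle_map(frame, patch,
                           if (masked) mask else mask | TRUE)
    expect_lt(max(abs(got - want)), 1e-9)
    raw_got <- iristrack:::match_map_cpp(frame, patch, mask, masked, 1L)$map
    raw_want <- ncc_oracle_map(frame, patch,
                               if (masked) mask else mask | TRUE, raw = TRUE)
    expect_lt(max(abs(raw_got - raw_want)), 1e-9)
  }
})

test_that("a patch cut from the frame matches its own location exactly", {
  cfg <- scene_config(seed = 12, noise_sd = 2)
  frame <- render_eye_frame(cfg, c(120, 80))$image
  patch <- frame[41:100, 81:150]               # top-left (80, 40) 0-based
  tmpl <- mk_tmpl(patch, matrix(TRUE, nrow(patch), ncol(patch)), 25)
  cands <- match_template(frame, tmpl, use_mask = FALSE)
  expect_equal(cands$x[1], 80)
  expect_equal(cands$y[1], 40)
  expect_equal(cands$similarity[1], 1, tolerance = 1e-12)
  # unique argmax
  expect_identical(sum(cands$similarity >= 1 - 1e-12), 1L)
})

test_that("zero-variance frames are flagged degenerate, not NaN", {
  frame <- matrix(100, 30, 30)
  patch <- matrix(100, 8, 8)
  tmpl <- mk_tmpl(patch, matrix(TRUE, 8, 8), 3)
  cands <- match_template(frame, tmpl, use_mask = FALSE)
  expect_true(attr(cands, "degenerate"))
  expect_false(anyNA(cands$similarity))
  expect_error(match_template(patch, mk_tmpl(frame, matrix(TRUE, 30, 30), 3)),
               "smaller")
})

test_that("matching is translation-equivariant on interior placements", {
  cfg <- scene_config(seed = 13, noise_sd = 0, coverage_jitter = 0)
  f1 <- render_eye_frame(cfg, c(110, 75), eye_centre = c(110, 75))$image
  f2 <- render_eye_frame(cfg, c(119, 69), eye_centre = c(119, 69))$image
  det <- detect_iris_cht_acm(f1)
  tmpl <- extract_template(f1, det$centre, det$radius)
  s1 <- select_darkest(f1, match_template(f1, tmpl), tmpl)
  s2 <- select_darkest(f2, match_template(f2, tmpl), tmpl)
  expect_equal(s2$centre - s1$centre, c(9, -6))
})

test_that("darkest-region selection minimises the circular region mean", {
  # gradient frame: intensity grows with x, so the left-most candidate wins
  frame <- matrix(rep(seq(0, 255, length.out = 120), each = 80), 80, 120)
  tmpl <- mk_tmpl(matrix(0, 21, 21), disc_mask(21, 9), 9)
  set.seed(52)
  for (i in 1:5) {
    n <- sample(2:6, 1)
    cands <- tibble::tibble(x = sample(0:(120 - 22), n),
                            y = sample(0:(80 - 22), n),
                            similarity = runif(n, 0.9, 1))
    got <- select_darkest(frame, cands, tmpl)
    # exhaustive oracle over candidate region means
    means <- vapply(seq_len(n), function(k) {
      cx <- cands$x[k] + 10; cy <- cands$y[k] + 10
      px <- 0:119; py <- 0:79
      sel <- outer((py - cy)^2, (px - cx)^2, "+") <= 81
      mean(frame[sel])
    }, numeric(1))
    expect_equal(got$region_mean, min(means), tolerance = 1e-9)
  }
  one <- tibble::tibble(x = 40, y = 30, similarity = 0.99)
  expect_equal(select_darkest(frame, one, tmpl)$centre, c(50, 40))
  expect_error(select_darkest(frame, one[0, ], tmpl), "invalid")
})
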