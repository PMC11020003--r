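green_disk_frame <- function(w = 200, h = 160, cx = 100, cy = 120, r = 10,
                             extra = NULL) {
  spec <- marker_scene_spec(frame_width = w, frame_height = h, n_frames = 1,
                            trajectory = "linear", start = c(cx, cy),
                            velocity = c(0, 0), marker_radius = r, seed = 1)
  fr <- generate_marker_frames(spec)$frames[[1]]
  if (!is.null(extra)) {
    px <- matrix(rep(seq_len(w), each = h), h, w)
    py <- matrix(rep(seq_len(h), times = w), h, w)
    mask <- (px - extra$cx)^2 + (py - extra$cy)^2 <= extra$r^2
    marker <- grDevices::col2rgb(grDevices::hsv(120 / 360, 0.85, 0.85)) / 255
    for (ch in 1:3) {
      plane <- fr[, , ch]; plane[mask] <- marker[ch]; fr[, , ch] <- plane
    }
  }
  fr
}

test_that("HSV segmentation finds the disk centroid", {
  fr <- green_disk_frame(cx = 100, cy = 120, r = 10)
  det <- segment_marker(fr)
  expect_true(det$valid)
  expect_lt(abs(det$x - 100), 1)
  expect_lt(abs(det$y - 120), 1)
  expect_gt(det$area, pi * 8^2)
})

test_that("frames without in-range pixels yield an invalid detection", {
  fr <- array(rep(c(0.5, 0.4, 0.35), each = 100 * 120), c(100, 120, 3))
  det <- segment_marker(fr)
  expect_false(det$valid)
  expect_equal(det$area, 0)
})

test_that("the largest qualifying blob wins", {
  fr <- green_disk_frame(cx = 60, cy = 60, r = 12,
                         extra = list(cx = 150, cy = 100, r = 5))
  det <- segment_marker(fr)
  expect_lt(abs(det$x - 60), 1)
  expect_lt(abs(det$y - 60), 1)
  # blobs below min_blob_area are ignored
  det2 <- segment_marker(green_disk_frame(cx = 60, cy = 60, r = 3),
                         hsv_range(min_blob_area = 50))
  expect_false(det2$valid)
})

test_that("Kalman filter is exact for noise-free constant velocity", {
  st <- track_init(tibble::tibble(x = 0, y = 5, valid = TRUE))
  expect_equal(st$mean[3:4], c(0, 0))
  expect_true(all(diag(st$cov)[1:2] >= 100))
  for (i in 1:10) {
    st <- kalman_step(st, tibble::tibble(x = 2 * i, y = 5, valid = TRUE),
                      q = 1e-12, r = 1e-12)
  }
  expect_lt(abs(st$mean[1] - 20), 1e-6)
  expect_lt(abs(st$mean[2] - 5), 1e-6)
  expect_lt(abs(st$mean[3] - 2), 1e-6)
})

test_that("a missed detection advances the state by its velocity", {
  st <- track_init(tibble::tibble(x = 10, y = 10, valid = TRUE))
  st$mean[3:4] <- c(3, -1)
  st2 <- kalman_step(st, NULL)
  expect_equal(st2$mean[1:2], c(13, 9))
  expect_equal(st2$frames_since_detection, 1L)
  expect_error(
    kalman_step(structure(list(mean = rep(0, 4), cov = diag(c(1, 1, 1, -1)),
                               frames_since_detection = 0L, initialized = TRUE),
                          class = "track_state"), NULL),
    class = "drspec_numeric_error"
  )
})

test_that("covariance stays symmetric positive-definite over many steps", {
  set.seed(14)
  st <- track_init(tibble::tibble(x = 0, y = 0, valid = TRUE))
  for (i in 1:1000) {
    det <- if (runif(1) < 0.2) NULL else {
      tibble::tibble(x = rnorm(1, i, 2), y = rnorm(1, i / 2, 2), valid = TRUE)
    }
    st <- kalman_step(st, det, q = runif(1, 0.1, 5), r = runif(1, 0.5, 5))
    expect_true(isSymmetric(st$cov, tol = 1e-8))
    expect_true(all(eigen(st$cov, symmetric = TRUE, only.values = TRUE)$values > 0))
  }
})

test_that("tracking a linear trajectory beats the marker radius", {
  spec <- marker_scene_spec(n_frames = 40, trajectory = "linear",
                            start = c(40, 40), velocity = c(4, 3),
                            marker_radius = 9, seed = 2)
  vid <- generate_marker_frames(spec)
  tr <- track_sequence(vid$frames)
  ok <- !is.na(tr$x)
  expect_true(all(ok))
  rmse <- sqrt(mean((tr$x - vid$trajectory$x)^2 + (tr$y - vid$trajectory$y)^2))
  expect_lt(rmse, spec$marker_radius)
})

test_that("occluded frames are bridged by prediction", {
  spec <- marker_scene_spec(n_frames = 50, trajectory = "linear",
                            start = c(30, 30), velocity = c(4, 3),
                            marker_radius = 9, seed = 3)
  occ <- seq(8, 50, by = 10)  # 10% of frames occluded
  vid <- generate_marker_frames(spec, occlude_frames = occ)
  tr <- track_sequence(vid$frames)
  expect_true(all(!is.na(tr$x)))  # continuous, no gaps
  rmse <- sqrt(mean((tr$x - vid$trajectory$x)^2 + (tr$y - vid$trajectory$y)^2))
  expect_lt(rmse, 2 * spec$marker_radius)
})

test_that("an all-background video never initialises a track", {
  fr <- array(rep(c(0.5, 0.4, 0.35), each = 40 * 50), c(40, 50, 3))
  tr <- track_sequence(rep(list(fr), 10))
  expect_true(all(!tr$tracked))
  expect_true(all(is.na(tr$x)))
})

test_that("translating the scene translates the estimated trajectory", {
  base <- marker_scene_spec(frame_width = 400, frame_height = 300, n_frames = 20,
                            trajectory = "linear", start = c(50, 50),
                            velocity = c(3, 2), marker_radius = 8, seed = 5)
  shifted <- marker_scene_spec(frame_width = 400, frame_height = 300, n_frames = 20,
                               trajectory = "linear", start = c(50 + 40, 50 + 25),
                               velocity = c(3, 2), marker_radius = 8, seed = 5)
  t1 <- track_sequence(generate_marker_frames(base)$frames)
  t2 <- track_sequence(generate_marker_frames(shifted)$frames)
  expect_equal(t2$x, t1$x + 40, tolerance = 0.6)
  expect_equal(t2$y, t1$y + 25, tolerance = 0.6)
})

test_that("frame sequences round-trip through PNG files", {
  spec <- marker_scene_spec(n_frames = 3, frame_width = 60, frame_height = 40,
                            marker_radius = 6, seed = 6)
  vid <- generate_marker_frames(spec)
  dir <- withr::local_tempdir()
  write_frames(vid$frames, dir)
  back <- read_frames(dir)
  expect_length(back, 3)
  expect_equal(back[[1]], vid$frames[[1]], tolerance = 1 / 255)
})
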