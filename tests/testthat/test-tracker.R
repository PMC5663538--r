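tcfg <- tracker_config()

test_that("background update follows the exponential moving average exactly", {
  f0 <- matrix(0, 10, 12)
  F1 <- matrix(100, 10, 12)
  # alpha = 1 degenerates to the current frame
  m <- background_model(f0, alpha = 1)
  m <- update_background(m, F1)
  expect_equal(m$accumulator, F1)
  # constant frame from zero init: accumulator = F * (1 - (1 - a)^n),
  # checked against iterative evaluation
  a <- 0.05
  m <- background_model(f0, alpha = a)
  acc_iter <- f0
  for (n in 1:50) {
    m <- update_background(m, F1)
    acc_iter <- (1 - a) * acc_iter + a * F1
  }
  expect_equal(m$accumulator, 100 * (1 - (1 - a)^50) + 0 * F1,
               tolerance = 1e-12)
  expect_equal(m$accumulator, acc_iter, tolerance = 1e-12)
  expect_error(update_background(m, matrix(0, 5, 5)), "shape")
})

test_that("the default background weight gives an 80 s time constant at 25 fps", {
  expect_equal(background_time_constant(0.0005, 25), 80)
  expect_equal(background_time_constant(tcfg$alpha, tcfg$frame_rate), 80)
})

test_that("the background converges to a static scene within five time constants", {
  set.seed(3)
  scene <- matrix(sample(20:60, 40 * 50, replace = TRUE), 40, 50)
  a <- 0.05  # time constant 20 updates
  m <- background_model(matrix(0, 40, 50), alpha = a)
  for (i in 1:200) m <- update_background(m, scene)  # 10 time constants
  expect_lt(max(abs(m$accumulator - scene)), 1)
})

test_that("detection finds nothing on a background-only frame and applies the size filter", {
  bg <- matrix(40L, 376, 500)
  m <- background_model(bg, alpha = 0.0005)
  m <- update_background(m, bg)
  expect_equal(nrow(detect_objects(bg, m, tcfg)), 0L)

  # a blob below the 5 um diameter filter is discarded
  small_tbl <- tibble::tibble(cell_id = 1L, frame = 0L, t_s = 0,
                              x_um = 300, y_um = 250)
  cfg_small <- render_config(noise_sigma = 0, cell_diameter = 3,
                             psf_sigma = 0.8, cell_amplitude = 60)
  fr <- render_video(small_tbl, cfg_small, 1)[[1]]
  det <- detect_objects(fr, m, tracker_config(blur_kernel = 3))
  expect_equal(nrow(det), 0L)
})

test_that("a rendered 12 um cell is detected once with sub-half-pixel centroid accuracy", {
  bg_cfg <- render_config(noise_sigma = 0)
  bg <- render_video(tibble::tibble(cell_id = integer(), frame = integer(),
                                    t_s = numeric(), x_um = numeric(),
                                    y_um = numeric()), bg_cfg, 1)[[1]]
  m <- background_model(bg, alpha = 0.0005)
  m <- update_background(m, bg)
  truth <- tibble::tibble(cell_id = 1L, frame = 0L, t_s = 0,
                          x_um = 325.6, y_um = 244.7)
  fr <- render_video(truth, bg_cfg, 1)[[1]]
  det <- detect_objects(fr, m, tcfg)
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$x_px - truth$x_um / 1.3), 0.5)
  expect_lt(abs(det$y_px - truth$y_um / 1.3), 0.5)
  expect_gt(det$diameter_um, 5)
  expect_error(detect_objects(fr, structure(list(accumulator = NULL),
                                            class = "background_model"),
                              tcfg),
               "uninitialized")
})

test_that("linking joins gated detections and splits beyond the gate", {
  det <- function(frame, x, y, d = 12) tibble::tibble(
    frame = frame, x_px = x / 1.3, y_px = y / 1.3, x_um = x, y_um = y,
    area_px = 70L, diameter_um = d)
  # one step of v * dt inside the gate -> a single track of length 2
  d2 <- dplyr::bind_rows(det(0, 100, 200), det(1, 100 + 1059 / 25, 200))
  tr <- link_tracks(d2, tcfg)
  expect_equal(length(unique(tr$track_id)), 1L)
  expect_equal(nrow(tr), 2L)
  # displacement beyond max_link_distance -> two single-detection tracks
  d3 <- dplyr::bind_rows(det(0, 100, 200), det(1, 100 + 80, 200))
  tr3 <- link_tracks(d3, tracker_config(max_link_distance = 50,
                                        flow_axis_bias = 12))
  expect_equal(length(unique(tr3$track_id)), 2L)
  # empty input -> empty output
  expect_equal(nrow(link_tracks(d2[0, ], tcfg)), 0L)
})

test_that("equidistant candidates resolve to the earlier track id", {
  det <- function(frame, x, y) tibble::tibble(
    frame = frame, x_px = x / 1.3, y_px = y / 1.3, x_um = x, y_um = y,
    area_px = 70L, diameter_um = 12)
  # two tracks started at frame 0 (ids 1, 2 by y order of appearance), one
  # detection at frame 1 exactly between them
  d <- dplyr::bind_rows(det(0, 100, 180), det(0, 100, 220), det(1, 110, 200))
  tr <- link_tracks(d, tracker_config(max_link_distance = 60,
                                      flow_axis_bias = 50))
  by_id <- split(tr, tr$track_id)
  expect_equal(nrow(by_id[[1]]), 2L)  # earliest track got the detection
  expect_equal(nrow(by_id[[2]]), 1L)
})

test_that("upstream displacement beyond the flow-axis bias is not linked", {
  det <- function(frame, x, y) tibble::tibble(
    frame = frame, x_px = x / 1.3, y_px = y / 1.3, x_um = x, y_um = y,
    area_px = 70L, diameter_um = 12)
  d <- dplyr::bind_rows(det(0, 100, 200), det(1, 60, 200))  # 40 um upstream
  tr <- link_tracks(d, tracker_config(max_link_distance = 60,
                                      flow_axis_bias = 12))
  expect_equal(length(unique(tr$track_id)), 2L)
})

test_that("step speeds invert displacement per frame", {
  fps <- 25
  tr <- tibble::tibble(track_id = 1L, frame = 0:9,
                       x_um = (0:9) * 1059 / fps, y_um = 100)
  sp <- track_speeds(tr, tcfg)
  expect_equal(sp$step_speed_um_s, rep(1059, 9))
  # stationary object
  tr0 <- tibble::tibble(track_id = 1L, frame = 0:5, x_um = 50, y_um = 50)
  expect_equal(track_speeds(tr0, tcfg)$step_speed_um_s, rep(0, 5))
  # single-detection tracks carry no speed
  ts <- track_summaries(tibble::tibble(track_id = 1L, frame = 3L,
                                       x_um = 1, y_um = 1), tcfg)
  expect_false(ts$has_speed)
  expect_true(is.na(ts$v_inst_median))
})

test_that("a noiseless single-cell stack is recovered within one pixel per frame", {
  fps <- 25
  v <- 150
  f <- 30:70
  truth <- tibble::tibble(cell_id = 1L, frame = f, t_s = f / fps,
                          x_um = 40 + (f - 30) * v / fps, y_um = 250)
  st <- render_video(truth, render_config(noise_sigma = 0, seed = 1),
                     max(f) + 2)
  tr <- track_stack(st, tcfg)
  expect_equal(length(unique(tr$track_id)), 1L)
  joined <- dplyr::inner_join(tr, truth, by = "frame",
                              suffix = c("_rec", "_true"))
  expect_gt(nrow(joined), 30)
  expect_true(all(abs(joined$x_um_rec - joined$x_um_true) < 1.3))
  expect_true(all(abs(joined$y_um_rec - joined$y_um_true) < 1.3))
  s <- track_summaries(tr, tcfg)
  expect_lt(abs(s$v_inst_median - v), 1.3 * fps)
})

test_that("simultaneous well-separated cells are not merged into one track", {
  fps <- 25
  f <- 30:60
  truth <- dplyr::bind_rows(
    tibble::tibble(cell_id = 1L, frame = f, t_s = f / fps,
                   x_um = 30 + (f - 30) * 120 / fps, y_um = 150),
    tibble::tibble(cell_id = 2L, frame = f, t_s = f / fps,
                   x_um = 30 + (f - 30) * 120 / fps, y_um = 350))
  st <- render_video(truth, render_config(noise_sigma = 0, seed = 2),
                     max(f) + 2)
  tr <- track_stack(st, tcfg)
  expect_equal(length(unique(tr$track_id)), 2L)
  # each frame has two distinct detections
  per_frame <- table(tr$frame)
  expect_true(all(per_frame == 2))
})

test_that("track tables round-trip losslessly through the CSV writer", {
  tr <- tibble::tibble(track_id = c(1L, 1L, 2L), frame = c(0L, 1L, 5L),
                       t_s = c(0, 0.04, 0.2),
                       x_um = c(1.25, 43.61, 100.033),
                       y_um = c(200.5, 200.75, 31.2),
                       diameter_um = c(12.1, 12.3, 9.8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_table_csv(tr, path, "tracks")
  back <- read_table_csv(path, "tracks")
  expect_equal(as.data.frame(back), as.data.frame(tr))
  expect_error(read_table_csv(path, "cells"), "schema")
})
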