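# Video post-processing: running-average background subtraction, square-box
# blurring, absolute-difference thresholding, connected-component detection
# with a minimum-size filter, and greedy frame-to-frame linking with a
# look-ahead window and an object-overlap fallback.

# windowed (2r+1)-row sums with edge truncation, via cumulative sums
win_sum_rows <- function(m, r) {
  n <- nrow(m)
  cs <- rbind(0, apply(m, 2, cumsum))
  idx <- seq_len(n)
  cs[pmin(n, idx + r) + 1L, , drop = FALSE] - cs[pmax(1L, idx - r), , drop = FALSE]
}

# k x k box mean filter, normalized by the in-bounds window size at edges
box_blur <- function(m, k) {
  if (k <= 1) return(m)
  r <- (k - 1L) %/% 2L
  s <- t(win_sum_rows(t(win_sum_rows(m, r)), r))
  cnt <- outer(
    pmin(nrow(m), seq_len(nrow(m)) + r) - pmax(1L, seq_len(nrow(m)) - r) + 1L,
    pmin(ncol(m), seq_len(ncol(m)) + r) - pmax(1L, seq_len(ncol(m)) - r) + 1L)
  s / cnt
}

#' Running-average background model
#'
#' An exponentially weighted moving average of frames. With weight `alpha`
#' each update does `accumulator <- (1 - alpha) * accumulator + alpha * frame`,
#' an e-folding time constant of `1 / (alpha * frame_rate)` seconds — 80 s
#' for the default weight 0.0005 at 25 fps.
#'
#' @param init_frame Matrix used to initialize the accumulator.
#' @param alpha Update weight in (0, 1].
#' @return An object of class `background_model`.
#' @export
background_model <- function(init_frame, alpha = 0.0005) {
  if (alpha <= 0 || alpha > 1) stopf("alpha must be in (0, 1]")
  if (!is.matrix(init_frame)) stopf("init_frame must be a matrix")
  structure(list(alpha = alpha,
                 accumulator = matrix(as.numeric(init_frame),
                                      nrow(init_frame), ncol(init_frame)),
                 n_updates = 0L),
            class = "background_model")
}

#' Update the running-average background with one frame
#'
#' @param model A [background_model()].
#' @param frame Matrix with the same shape as the accumulator.
#' @return The updated model.
#' @export
update_background <- function(model, frame) {
  stopifnot(inherits(model, "background_model"))
  if (!identical(dim(model$accumulator), dim(frame)))
    stopf("frame shape (%s) does not match accumulator (%s)",
          paste(dim(frame), collapse = "x"),
          paste(dim(model$accumulator), collapse = "x"))
  a <- model$alpha
  model$accumulator <- (1 - a) * model$accumulator + a * frame
  model$n_updates <- model$n_updates + 1L
  model
}

#' Time constant of the background moving average
#'
#' @param alpha Update weight.
#' @param frame_rate Frame rate (Hz).
#' @return e-folding time constant in seconds: `1 / (alpha * frame_rate)`.
#' @export
background_time_constant <- function(alpha = 0.0005, frame_rate = 25) {
  if (alpha <= 0 || frame_rate <= 0) stopf("alpha and frame_rate must be > 0")
  1 / (alpha * frame_rate)
}

#' Detect moving objects in one frame
#'
#' The frame and the background accumulator are both blurred with a square
#' box kernel; pixels where the absolute difference meets the intensity
#' threshold form the foreground mask. Connected components are extracted and
#' those with equivalent diameter at or below `min_diameter` (um) discarded.
#' Centroids are intensity-weighted by the blurred difference image.
#'
#' @param frame Integer matrix (8-bit intensities; rows = y, columns = x,
#'   x along the flow axis, pixel coordinates 0-based).
#' @param model An initialized [background_model()].
#' @param cfg A [tracker_config()].
#' @return A tibble `x_px, y_px, x_um, y_um, area_px, diameter_um`.
#' @export
detect_objects <- function(frame, model, cfg) {
  stopifnot(inherits(model, "background_model"),
            inherits(cfg, "tracker_config"))
  if (is.null(model$accumulator))
    stopf("background model is uninitialized")
  diff <- abs(box_blur(frame, cfg$blur_kernel) -
              box_blur(model$accumulator, cfg$blur_kernel))
  mask <- diff >= cfg$intensity_threshold
  empty <- tibble(x_px = numeric(), y_px = numeric(), x_um = numeric(),
                  y_um = numeric(), area_px = integer(),
                  diameter_um = numeric())
  if (!any(mask)) return(empty)
  labels <- EBImage::bwlabel(mask)
  lab <- as.integer(labels)
  keep <- lab > 0L
  lab <- lab[keep]
  w <- diff[keep]
  rows <- ((which(keep) - 1L) %% nrow(frame))       # 0-based y
  cols <- ((which(keep) - 1L) %/% nrow(frame))      # 0-based x
  area <- tabulate(lab)
  wsum <- as.numeric(rowsum(w, lab))
  x_px <- as.numeric(rowsum(w * cols, lab)) / wsum
  y_px <- as.numeric(rowsum(w * rows, lab)) / wsum
  diameter_um <- 2 * sqrt(area / pi) * cfg$pixel_size
  out <- tibble(x_px = x_px, y_px = y_px,
                x_um = x_px * cfg$pixel_size, y_um = y_px * cfg$pixel_size,
                area_px = as.integer(area), diameter_um = diameter_um)
  out[out$diameter_um > cfg$min_diameter, , drop = FALSE]
}

#' Link per-frame detections into tracks
#'
#' Greedy per-frame assignment: each detection joins the active track whose
#' predicted position (last position plus last velocity times the frame gap;
#' zero velocity for fresh tracks) is nearest, provided the distance is
#' within `max_link_distance` per frame of gap or the detection overlaps the
#' track's last object footprint, and the displacement against the flow does
#' not exceed `flow_axis_bias`. Ties break by smallest distance, then
#' earliest track id. Unmatched detections open new tracks; tracks unmatched
#' for more than `lookahead_frames` frames are closed.
#'
#' @param detections Tibble of detections with a `frame` column (0-based) and
#'   the columns produced by [detect_objects()], sorted by frame.
#' @param cfg A [tracker_config()].
#' @return A tibble `track_id, frame, t_s, x_um, y_um, diameter_um`.
#' @export
link_tracks <- function(detections, cfg) {
  stopifnot(inherits(cfg, "tracker_config"))
  out_cols <- tibble(track_id = integer(), frame = integer(), t_s = numeric(),
                     x_um = numeric(), y_um = numeric(),
                     diameter_um = numeric())
  if (nrow(detections) == 0) return(out_cols)
  fps <- cfg$frame_rate
  detections <- arrange(detections, .data$frame)
  frames <- unique(detections$frame)
  active <- list()   # id, last_frame, x, y, vx, vy, radius, rows (list of row tibbles)
  done <- list()
  next_id <- 1L

  close_tracks <- function(idx) {
    for (i in idx) done[[length(done) + 1L]] <<- active[[i]]
    if (length(idx)) active <<- active[-idx]
  }

  for (f in frames) {
    if (length(active)) {
      stale <- which(vapply(active, function(a) f - a$last_frame,
                            numeric(1)) > cfg$lookahead_frames)
      close_tracks(stale)
    }
    dets <- detections[detections$frame == f, , drop = FALSE]
    nd <- nrow(dets)
    assigned_det <- rep(FALSE, nd)
    if (length(active) && nd) {
      cand <- list()
      for (ai in seq_along(active)) {
        a <- active[[ai]]
        gap <- f - a$last_frame
        px <- a$x + a$vx * gap / fps
        py <- a$y + a$vy * gap / fps
        d_pred <- sqrt((dets$x_um - px)^2 + (dets$y_um - py)^2)
        d_last <- sqrt((dets$x_um - a$x)^2 + (dets$y_um - a$y)^2)
        overlap <- d_last < (a$radius + dets$diameter_um / 2)
        gated <- d_pred <= cfg$max_link_distance * gap
        upstream_ok <- (dets$x_um - a$x) >= -cfg$flow_axis_bias
        ok <- (gated | overlap) & upstream_ok
        if (any(ok)) {
          cand[[length(cand) + 1L]] <- tibble(
            ai = ai, di = which(ok), dist = d_pred[ok], id = a$id)
        }
      }
      if (length(cand)) {
        cand <- list_rbind(cand)
        cand <- cand[order(cand$dist, cand$id), , drop = FALSE]
        used_track <- rep(FALSE, length(active))
        for (r in seq_len(nrow(cand))) {
          ai <- cand$ai[r]; di <- cand$di[r]
          if (used_track[ai] || assigned_det[di]) next
          used_track[ai] <- TRUE
          assigned_det[di] <- TRUE
          a <- active[[ai]]
          gap <- f - a$last_frame
          a$vx <- (dets$x_um[di] - a$x) * fps / gap
          a$vy <- (dets$y_um[di] - a$y) * fps / gap
          a$x <- dets$x_um[di]; a$y <- dets$y_um[di]
          a$radius <- dets$diameter_um[di] / 2
          a$last_frame <- f
          a$rows[[length(a$rows) + 1L]] <- dets[di, , drop = FALSE]
          a$frames <- c(a$frames, f)
          active[[ai]] <- a
        }
      }
    }
    for (di in which(!assigned_det)) {
      active[[length(active) + 1L]] <- list(
        id = next_id, last_frame = f,
        x = dets$x_um[di], y = dets$y_um[di], vx = 0, vy = 0,
        radius = dets$diameter_um[di] / 2,
        rows = list(dets[di, , drop = FALSE]), frames = f)
      next_id <- next_id + 1L
    }
  }
  close_tracks(seq_along(active))
  if (!length(done)) return(out_cols)
  res <- list_rbind(lapply(done, function(a) {
    rows <- list_rbind(a$rows)
    tibble(track_id = a$id, frame = as.integer(a$frames),
           t_s = a$frames / fps, x_um = rows$x_um, y_um = rows$y_um,
           diameter_um = rows$diameter_um)
  }))
  arrange(res, .data$track_id, .data$frame)
}

#' Track an image stack end to end
#'
#' Initializes the background from the first frame, suppresses detections
#' during the warm-up period, detects objects against the background of past
#' frames only, and links detections into tracks.
#'
#' @param stack An `image_stack` (see [render_video()], [read_stack()]).
#' @param cfg A [tracker_config()].
#' @return A track table as from [link_tracks()].
#' @export
track_stack <- function(stack, cfg) {
  stopifnot(inherits(cfg, "tracker_config"))
  model <- background_model(stack[[1]], cfg$alpha)
  dets <- vector("list", length(stack))
  for (f in seq_along(stack) - 1L) {
    frame <- stack[[f + 1L]]
    if (f >= cfg$warmup_frames) {
      d <- detect_objects(frame, model, cfg)
      if (nrow(d)) {
        d$frame <- f
        dets[[f + 1L]] <- d
      }
    }
    model <- update_background(model, frame)
  }
  dets <- list_rbind(dets[!vapply(dets, is.null, logical(1))])
  if (is.null(dets) || nrow(dets) == 0) {
    return(tibble(track_id = integer(), frame = integer(), t_s = numeric(),
                  x_um = numeric(), y_um = numeric(), diameter_um = numeric()))
  }
  link_tracks(dets, cfg)
}

#' Per-step speeds along tracks
#'
#' Step speed is the Euclidean displacement (um) between consecutive
#' detections times the frame rate, divided by the frame gap.
#'
#' @param tracks Track table (`track_id, frame, x_um, y_um`).
#' @param cfg A [tracker_config()] (supplies the frame rate).
#' @return A tibble `track_id, frame, step_speed_um_s` (one row per step,
#'   stamped with the step's end frame).
#' @export
track_speeds <- function(tracks, cfg) {
  stopifnot(inherits(cfg, "tracker_config"))
  tracks |>
    arrange(.data$track_id, .data$frame) |>
    group_by(.data$track_id) |>
    mutate(step_speed_um_s =
             sqrt((.data$x_um - dplyr::lag(.data$x_um))^2 +
                  (.data$y_um - dplyr::lag(.data$y_um))^2) *
             cfg$frame_rate / (.data$frame - dplyr::lag(.data$frame))) |>
    ungroup() |>
    filter(!is.na(.data$step_speed_um_s)) |>
    select("track_id", "frame", "step_speed_um_s")
}

#' Per-track summaries
#'
#' @param tracks Track table.
#' @param cfg A [tracker_config()].
#' @return One row per track: `track_id`, `n_detections`, `entry_frame`,
#'   `exit_frame`, `t_entry_s`, `v_inst_median` (um/s; `NA` and
#'   `has_speed = FALSE` for single-detection tracks).
#' @export
track_summaries <- function(tracks, cfg) {
  speeds <- track_speeds(tracks, cfg) |>
    group_by(.data$track_id) |>
    summarise(v_inst_median = median(.data$step_speed_um_s))
  tracks |>
    group_by(.data$track_id) |>
    summarise(n_detections = n(),
              entry_frame = min(.data$frame),
              exit_frame = max(.data$frame),
              t_entry_s = min(.data$frame) / cfg$frame_rate) |>
    left_join(speeds, by = "track_id") |>
    mutate(has_speed = !is.na(.data$v_inst_median))
}
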