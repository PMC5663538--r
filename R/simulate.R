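# Two-state stochastic transit simulator. Each cell alternates between a
# bound (rolling) state at its own rolling speed and a free-flow state at the
# shear-dependent free-flow speed, with exponential holding times, until it
# has covered the distance from the channel inlet to the imaging field of
# view. The same sample path is continued across the FOV so rendered videos
# contain the in-FOV motion the tracker measures.

lnorm_pars <- function(mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

draw_lognormal <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  p <- lnorm_pars(mean, cv)
  rlnorm(n, p$meanlog, p$sdlog)
}

# one sample path of the bound/free alternation until cumulative distance
# reaches `target` (um); the final interval is truncated so distance is exact
sim_path <- function(bound0, k_on, k_off, v_roll, v_ff, target) {
  states <- logical(0)
  durs <- numeric(0)
  bound <- bound0
  pos <- 0
  repeat {
    rate <- if (bound) k_off else k_on
    v <- if (bound) v_roll else v_ff
    dur <- if (rate <= 0) Inf else rexp(1, rate)
    if (pos + v * dur >= target) {
      states <- c(states, bound)
      durs <- c(durs, (target - pos) / v)
      break
    }
    pos <- pos + v * dur
    states <- c(states, bound)
    durs <- c(durs, dur)
    bound <- !bound
  }
  tibble(state = ifelse(states, "bound", "free"),
         duration = durs,
         velocity = ifelse(states, v_roll, v_ff))
}

# split an interval table at cumulative distance `d` (um)
split_path <- function(path, d) {
  dist <- path$duration * path$velocity
  cum <- cumsum(dist)
  i <- which(cum >= d - 1e-12)[1]
  before <- path[seq_len(i), , drop = FALSE]
  excess <- cum[i] - d
  after <- path[seq(i, nrow(path)), , drop = FALSE]
  before$duration[i] <- before$duration[i] - excess / path$velocity[i]
  after$duration[1] <- excess / after$velocity[1]
  after <- after[after$duration > 0, , drop = FALSE]
  list(before = before, after = after)
}

#' Simulate ground-truth cell transits through the channel
#'
#' Each cell follows a continuous-time two-state Markov process: bound
#' (rolling, at a per-cell rolling speed drawn once from a lognormal
#' distribution) or free-flowing (at the condition's free-flow speed), with
#' transition rates `k_off` and `k_on`. The path is advanced until the
#' cumulative distance reaches the FOV entry position; elution time is the
#' settling-feature offset plus the transit time. The path is continued
#' across the FOV and recorded separately so downstream rendering and
#' tracking see in-FOV motion.
#'
#' @param params A [simulation_params()] object.
#' @param condition A [flow_condition()] object.
#' @param geometry A [channel_geometry()] object.
#' @return A tibble of class `transit_tbl`, one row per cell:
#'   `cell_id`, `v_roll` (um/s), `t_offset` (s), `t_elution` (s),
#'   `transit_time` (s), `true_binding_fraction` (time-weighted fraction of
#'   the channel transit spent bound), `censored` (did not reach the FOV
#'   within the acquisition window), and list-columns `intervals`
#'   (state/duration/velocity up to the FOV entry; durations times velocities
#'   sum exactly to `fov_position`) and `fov_intervals` (the continuation
#'   across the FOV).
#' @export
#' @examples
#' g <- channel_geometry()
#' fc <- flow_condition(1.0)
#' p <- simulation_params(n_cells = 5, seed = 1)
#' simulate_transits(p, fc, g)
simulate_transits <- function(params, condition, geometry) {
  stopifnot(inherits(params, "simulation_params"),
            inherits(condition, "flow_condition"),
            inherits(geometry, "channel_geometry"))
  if (geometry$fov_position <= 0)
    stopf("fov_position must be > 0: a zero-length transit has no elution time")
  if (params$v_roll_mean >= condition$v_free_flow)
    stopf("v_roll_mean (%g) must be below v_free_flow (%g)",
          params$v_roll_mean, condition$v_free_flow)
  v_ff <- condition$v_free_flow
  fov_end <- min(geometry$fov_position + geometry$fov_length,
                 geometry$channel_length)

  with_seed(params$seed, {
    n <- params$n_cells
    t_offset <- if (params$t_offset_mean == 0) rep(0, n) else
      draw_lognormal(n, params$t_offset_mean, params$t_offset_cv)

    rows <- vector("list", n)
    for (i in seq_len(n)) {
      v_roll <- draw_lognormal(1, params$v_roll_mean, params$v_roll_cv)
      tries <- 1L
      while (v_roll >= v_ff) {
        if (tries >= 100L)
          stopf("could not draw a rolling speed below v_free_flow in 100 tries")
        v_roll <- draw_lognormal(1, params$v_roll_mean, params$v_roll_cv)
        tries <- tries + 1L
      }
      bound0 <- stats::runif(1) < params$p_start_bound
      path <- sim_path(bound0, params$k_on, params$k_off, v_roll, v_ff, fov_end)
      parts <- split_path(path, geometry$fov_position)
      channel <- parts$before
      transit_time <- sum(channel$duration)
      t_off_i <- t_offset[i]
      rows[[i]] <- tibble(
        cell_id = i,
        v_roll = v_roll,
        t_offset = t_off_i,
        transit_time = transit_time,
        t_elution = t_off_i + transit_time,
        true_binding_fraction =
          sum(channel$duration[channel$state == "bound"]) / transit_time,
        intervals = list(channel),
        fov_intervals = list(parts$after)
      )
    }
    out <- list_rbind(rows)
    out$censored <- out$t_elution > params$acquisition_duration
    class(out) <- c("transit_tbl", class(out))
    out
  })
}

# along-flow position (um, absolute from inlet) at times `t_rel` (s) after
# FOV entry, from the in-FOV interval table
fov_position_at <- function(fov_intervals, fov_start, t_rel) {
  ct <- c(0, cumsum(fov_intervals$duration))
  cd <- c(0, cumsum(fov_intervals$duration * fov_intervals$velocity))
  i <- findInterval(t_rel, ct, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), nrow(fov_intervals))
  fov_start + cd[i] + fov_intervals$velocity[i] * (t_rel - ct[i])
}

fov_state_at <- function(fov_intervals, t_rel) {
  ct <- c(0, cumsum(fov_intervals$duration))
  i <- findInterval(t_rel, ct, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), nrow(fov_intervals))
  fov_intervals$state[i]
}

#' Per-frame in-FOV positions of one transit
#'
#' Samples a cell's along-flow position on a frame grid anchored at its
#' elution time: the first frame is at `t_elution`, at the FOV entry
#' position, and frames continue every `1/frame_rate` seconds until the cell
#' leaves the FOV (or the channel ends).
#'
#' @param transit One row of a [simulate_transits()] table (a one-row tibble
#'   or a list with `t_elution` and `fov_intervals`).
#' @param geometry The [channel_geometry()] used for the simulation.
#' @param frame_rate Sampling rate (Hz).
#' @return A tibble with `frame` (0-based, relative to FOV entry), `t_s`
#'   (absolute time), and `x_um` (absolute along-flow position).
#' @export
fov_positions <- function(transit, geometry, frame_rate = 25) {
  if (frame_rate <= 0) stopf("frame_rate must be > 0")
  if (is_tibble(transit)) {
    stopifnot(nrow(transit) == 1)
    transit <- as.list(transit)
    transit$fov_intervals <- transit$fov_intervals[[1]]
  }
  fi <- transit$fov_intervals
  dwell <- sum(fi$duration)
  k <- 0:max(0, ceiling(dwell * frame_rate))
  t_rel <- k / frame_rate
  keep <- t_rel < dwell | k == 0
  t_rel <- t_rel[keep]
  tibble(frame = k[keep],
         t_s = transit$t_elution + t_rel,
         x_um = fov_position_at(fi, geometry$fov_position, t_rel))
}

#' Ground-truth track table on the acquisition frame grid
#'
#' Places every non-censored transit on the global video frame grid
#' (frame `f` at time `f / frame_rate`, with time zero at pulse injection)
#' and reports in-FOV coordinates: `x_um` measured from the FOV start along
#' the flow, `y_um` a per-cell lane drawn uniformly across the frame height.
#'
#' @param transits A [simulate_transits()] table.
#' @param geometry The matching [channel_geometry()].
#' @param cfg A [render_config()]; supplies frame rate, frame size, pixel
#'   size, and the seed for lane assignment.
#' @param n_frames Video length in frames; default covers the last exit.
#' @return A tibble `cell_id, frame, t_s, x_um, y_um, state`.
#' @export
fov_track_table <- function(transits, geometry, cfg, n_frames = NULL) {
  stopifnot(inherits(cfg, "render_config"))
  fps <- cfg$frame_rate
  live <- transits[!transits$censored, , drop = FALSE]
  if (nrow(live) == 0) {
    return(tibble(cell_id = integer(), frame = integer(), t_s = numeric(),
                  x_um = numeric(), y_um = numeric(), state = character()))
  }
  height_um <- cfg$image_height * cfg$pixel_size
  margin <- cfg$cell_diameter
  lanes <- with_seed(cfg$seed,
                     stats::runif(nrow(live), margin, height_um - margin))
  rows <- vector("list", nrow(live))
  for (i in seq_len(nrow(live))) {
    fi <- live$fov_intervals[[i]]
    t0 <- live$t_elution[i]
    dwell <- sum(fi$duration)
    f0 <- ceiling(t0 * fps - 1e-9)
    f1 <- floor((t0 + dwell) * fps - 1e-9)
    if (f1 < f0) next
    f <- f0:f1
    t_rel <- f / fps - t0
    x_abs <- fov_position_at(fi, geometry$fov_position, t_rel)
    rows[[i]] <- tibble(
      cell_id = live$cell_id[i], frame = f, t_s = f / fps,
      x_um = x_abs - geometry$fov_position,
      y_um = lanes[i],
      state = fov_state_at(fi, t_rel))
  }
  out <- list_rbind(rows)
  if (!is.null(n_frames)) out <- out[out$frame < n_frames, , drop = FALSE]
  arrange(out, .data$frame, .data$cell_id)
}
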