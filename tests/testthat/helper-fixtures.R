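# Fixtures and independent oracles shared across the suite. Everything is
# generated in code; no binary fixtures.

# Constant-velocity ground-truth track table: n cells crossing the FOV at
# known speeds on separated lanes with staggered entry frames.
make_constant_tracks <- function(n_cells = 20, fps = 25,
                                 speeds = seq(100, 480, length.out = n_cells),
                                 fov_um = 650, seed = 42,
                                 entry_range = 30:110) {
  set.seed(seed)
  lanes <- sample(seq(25, 465, length.out = n_cells))
  entry <- sample(entry_range, n_cells)
  rows <- lapply(seq_len(n_cells), function(i) {
    x <- seq(8, fov_um - 8, by = speeds[i] / fps)
    f <- entry[i] + seq_along(x) - 1L
    tibble::tibble(cell_id = i, frame = f, t_s = f / fps,
                   x_um = x, y_um = lanes[i])
  })
  list(tracks = dplyr::bind_rows(rows),
       truth = tibble::tibble(cell_id = seq_len(n_cells), speed = speeds,
                              lane = lanes, entry_frame = entry))
}

# Independent discrete-time oracle for the two-state transit model: advance a
# bound/free chain in steps of dt until the covered distance reaches L.
# Returns the time-weighted bound fraction of one transit.
discrete_transit_oracle <- function(k_on, k_off, v_roll, v_ff, L,
                                    p_start_bound = 0.5, dt = 5e-4) {
  bound <- runif(1) < p_start_bound
  pos <- 0; t_bound <- 0; t_total <- 0
  while (pos < L) {
    v <- if (bound) v_roll else v_ff
    pos <- pos + v * dt
    t_total <- t_total + dt
    if (bound) t_bound <- t_bound + dt
    p_switch <- if (bound) k_off * dt else k_on * dt
    if (runif(1) < p_switch) bound <- !bound
  }
  t_bound / t_total
}

# Closed-form normal-equation oracle for simple OLS with slope t-test and
# Pearson r, independent of stats::lm.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  s2 <- sum(resid^2) / (n - 2)
  slope_se <- sqrt(s2 / sxx)
  tval <- slope / slope_se
  r <- sxy / sqrt(sxx * syy)
  list(slope = slope, intercept = intercept, slope_se = slope_se,
       p_slope = 2 * stats::pt(-abs(tval), df = n - 2), pearson_r = r)
}

# Match recovered track summaries back to constant-velocity ground truth by
# lane; returns per-cell relative speed error (NA when no track on the lane).
match_speed_errors <- function(track_tbl, summaries, truth, lane_tol = 10) {
  laneof <- vapply(split(track_tbl$y_um, track_tbl$track_id), median,
                   numeric(1))
  summaries$lane <- laneof[as.character(summaries$track_id)]
  vapply(seq_len(nrow(truth)), function(i) {
    cand <- summaries[!is.na(summaries$lane) &
                        abs(summaries$lane - truth$lane[i]) < lane_tol, ]
    cand <- cand[!is.na(cand$v_inst_median), ]
    if (!nrow(cand)) return(NA_real_)
    best <- cand[which.max(cand$n_detections), ]
    abs(best$v_inst_median - truth$speed[i]) / truth$speed[i]
  }, numeric(1))
}
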