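# Adhesion chromatography metrics. A cell's whole-channel behavior is read
# off its elution time: average velocity is channel length over corrected
# transit time, and the percent binding time follows from a mass balance —
# during a transit of duration t = t_elution - t_offset a cell covers
# v_inst * t_bound + v_free_flow * (t - t_bound) = L_channel, which solved
# for the bound-time fraction t_bound / t gives
#   %BT = [v_ff * (t_e - t_o) - L] / [(v_ff - v_inst) * (t_e - t_o)].

#' Classify a cell's adhesion phenotype from its median instantaneous velocity
#'
#' Rolling is slow, non-zero forward motion: `0 < v < threshold(tau)`
#' (125/250/375 um/s at 0.5/1.0/1.5 dyn/cm2). Speeds at or above the
#' threshold are free flow; speeds indistinguishable from zero (within
#' `zero_tol`) are arrested.
#'
#' @param v_inst Median instantaneous velocity (um/s), vectorized.
#' @param condition A [flow_condition()].
#' @param zero_tol Zero-motion tolerance (um/s); the pixel-equivalent default
#'   lives in [analysis_config()]. Default 0 (exact zero is arrested).
#' @return Character vector: `"rolling"`, `"free_flow"` or `"arrested"`.
#' @export
#' @examples
#' classify_adhesion(c(0, 200, 400), flow_condition(1.0))
classify_adhesion <- function(v_inst, condition, zero_tol = 0) {
  stopifnot(inherits(condition, "flow_condition"))
  if (any(v_inst < 0, na.rm = TRUE)) stopf("v_inst must be >= 0")
  dplyr::case_when(
    is.na(v_inst) ~ NA_character_,
    v_inst <= zero_tol ~ "arrested",
    v_inst < condition$v_roll_threshold ~ "rolling",
    TRUE ~ "free_flow")
}

#' Whole-channel average velocity from the elution time
#'
#' `V_avg = L_channel / (t_elution - t_offset)`: the functionalized channel
#' length divided by the transit time corrected for the mean settling-feature
#' dwell.
#'
#' @param t_elution Elution time (s), vectorized.
#' @param t_offset Mean settling time (s).
#' @param L_channel Channel length (um).
#' @return Average velocity (um/s).
#' @export
#' @examples
#' average_velocity(300, 20, 140000) # 500 um/s
average_velocity <- function(t_elution, t_offset, L_channel) {
  if (L_channel <= 0) stopf("L_channel must be > 0")
  if (any(t_elution <= t_offset, na.rm = TRUE))
    stopf("t_elution must exceed t_offset; check the offset calibration")
  L_channel / (t_elution - t_offset)
}

#' Percent binding time from the elution mass balance
#'
#' The fraction of the corrected transit time a cell spent adhesively bound,
#' assuming two transport speeds (bound at `v_inst`, free at `v_free_flow`):
#' `[v_ff (t_e - t_o) - L] / [(v_ff - v_inst) (t_e - t_o)]`. A cell that never
#' bound elutes at `L / v_ff` and scores 0; a cell that rolled the whole
#' channel elutes at `L / v_inst` and scores 1. Measurement noise can push
#' the raw value outside `[0, 1]`; by default it is clamped (the quantity is
#' a time fraction by derivation) — use `clamp = FALSE` for the raw value.
#'
#' @param v_free_flow Free-flow velocity (um/s).
#' @param t_elution Elution time (s), vectorized.
#' @param t_offset Mean settling time (s).
#' @param L_channel Channel length (um).
#' @param v_inst Bound-state (instantaneous) velocity (um/s), strictly below
#'   `v_free_flow`.
#' @param clamp Clamp the result to `[0, 1]`.
#' @return Binding-time fraction (dimensionless).
#' @export
#' @examples
#' percent_binding_time(1059, 60, 0, 13000, 100) # 0.8783...
percent_binding_time <- function(v_free_flow, t_elution, t_offset, L_channel,
                                 v_inst, clamp = TRUE) {
  if (L_channel <= 0) stopf("L_channel must be > 0")
  if (any(v_inst >= v_free_flow, na.rm = TRUE))
    stopf("v_inst must be below v_free_flow: the mass balance is undefined at or above it")
  if (any(t_elution <= t_offset, na.rm = TRUE))
    stopf("t_elution must exceed t_offset")
  dt <- t_elution - t_offset
  raw <- (v_free_flow * dt - L_channel) / ((v_free_flow - v_inst) * dt)
  if (any(raw < -0.05, na.rm = TRUE))
    warn("raw binding-time fractions well below 0: v_free_flow or t_offset may be mis-calibrated")
  if (clamp) pmin(pmax(raw, 0), 1) else raw
}

#' Estimate the settling-feature offset time from a blank run
#'
#' In a non-functionalized (blank) channel cells transit at the free-flow
#' speed, so the mean elution time exceeds `L_channel / v_free_flow` by the
#' mean settling dwell. The estimate is floored at zero.
#'
#' @param blank_elution_times Elution times (s) from a blank run, `n >= 10`
#'   recommended.
#' @param v_free_flow Free-flow velocity (um/s).
#' @param L_channel Channel length (um).
#' @return Estimated `t_offset` (s).
#' @export
estimate_offset_time <- function(blank_elution_times, v_free_flow, L_channel) {
  if (length(blank_elution_times) == 0) stopf("no blank elution times supplied")
  if (length(blank_elution_times) < 10)
    warn("fewer than 10 blank elution times; the offset estimate will be noisy")
  est <- mean(blank_elution_times) - L_channel / v_free_flow
  if (est < -1)
    warn(sprintf("offset estimate %.2f s is negative: v_free_flow may be inconsistent with the blank run", est))
  max(est, 0)
}

#' Residence-time distribution of eluting cells
#'
#' Histogram of elution times, normalized to unit mass over eluted cells;
#' censored cells (not eluted within the acquisition window) are counted
#' separately.
#'
#' @param t_elution Elution times (s). `NA` counts as censored.
#' @param bin_width Bin width (s).
#' @param acquisition_duration Acquisition window (s); times beyond it are
#'   censored.
#' @return A tibble of class `residence_distribution` with `bin_start`,
#'   `bin_mid`, `count`, `prop` (sums to 1 over eluted cells) and attributes
#'   `n_eluted`, `n_censored`, `bin_width`.
#' @export
residence_distribution <- function(t_elution, bin_width = 60,
                                   acquisition_duration = 7200) {
  if (bin_width <= 0) stopf("bin_width must be > 0")
  censored <- is.na(t_elution) | t_elution > acquisition_duration
  t_in <- t_elution[!censored]
  if (length(t_in) == 0) {
    out <- tibble(bin_start = numeric(), bin_mid = numeric(),
                  count = integer(), prop = numeric())
  } else {
    bin <- floor(t_in / bin_width)
    tab <- table(bin)
    starts <- as.numeric(names(tab)) * bin_width
    out <- tibble(bin_start = starts, bin_mid = starts + bin_width / 2,
                  count = as.integer(tab),
                  prop = as.integer(tab) / length(t_in))
  }
  structure(out, class = c("residence_distribution", class(out)),
            n_eluted = length(t_in), n_censored = sum(censored),
            bin_width = bin_width)
}

#' Build per-cell chromatography records
#'
#' Combines per-cell elution times and median instantaneous velocities into
#' the full per-cell analysis record: adhesion class, average velocity,
#' percent binding time (clamped and raw), and the average-to-instantaneous
#' velocity ratio.
#'
#' Cells with no elution time inside the acquisition window, or flagged in a
#' `censored` column, are classed `"censored"` and excluded from the
#' elution-based metrics. The mass balance is undefined for `v_inst` at or
#' above `v_free_flow`; such cells keep their class but get `NA` binding
#' time.
#'
#' @param cells Tibble with `cell_id`, `t_elution` (s), `v_inst_median`
#'   (um/s), optional logical `censored`.
#' @param condition A [flow_condition()].
#' @param geometry A [channel_geometry()] (supplies `L_channel`).
#' @param config An [analysis_config()] (supplies `t_offset`, the acquisition
#'   window, clamping, and the arrest tolerance).
#' @return A tibble of class `cell_records`: the input columns plus
#'   `adhesion_class`, `v_avg`, `pct_binding_time`, `pct_binding_time_raw`,
#'   `v_ratio`.
#' @export
cell_records <- function(cells, condition, geometry,
                         config = analysis_config()) {
  stopifnot(inherits(condition, "flow_condition"),
            inherits(geometry, "channel_geometry"),
            inherits(config, "analysis_config"))
  need <- c("cell_id", "t_elution", "v_inst_median")
  miss <- setdiff(need, names(cells))
  if (length(miss)) stopf("cells is missing columns: %s",
                          paste(miss, collapse = ", "))
  censored <- if ("censored" %in% names(cells)) cells$censored else
    rep(FALSE, nrow(cells))
  censored <- censored | is.na(cells$t_elution) |
    cells$t_elution > config$acquisition_duration
  cls <- classify_adhesion(cells$v_inst_median, condition,
                           zero_tol = config$zero_motion_tol)
  cls[censored] <- "censored"

  ok <- !censored
  v_avg <- rep(NA_real_, nrow(cells))
  v_avg[ok] <- average_velocity(cells$t_elution[ok], config$t_offset,
                                geometry$channel_length)
  bt_ok <- ok & cells$v_inst_median < condition$v_free_flow
  raw <- rep(NA_real_, nrow(cells))
  raw[bt_ok] <- percent_binding_time(
    condition$v_free_flow, cells$t_elution[bt_ok], config$t_offset,
    geometry$channel_length, cells$v_inst_median[bt_ok], clamp = FALSE)
  out <- cells |>
    mutate(adhesion_class = cls,
           v_avg = v_avg,
           pct_binding_time_raw = raw,
           pct_binding_time = if (config$clamp_binding_time)
             pmin(pmax(raw, 0), 1) else raw,
           v_ratio = .data$v_avg / .data$v_inst_median)
  class(out) <- c("cell_records", class(out))
  out
}

#' Convert ground-truth transits to the per-cell table the analysis consumes
#'
#' The in-FOV median instantaneous velocity is the time-weighted median speed
#' across the cell's FOV intervals — the quantity frame-wise tracking
#' estimates. The per-cell rolling speed `v_roll` is carried through so
#' two-velocity identities can be evaluated against ground truth.
#'
#' @param transits A [simulate_transits()] table.
#' @return Tibble `cell_id, t_elution, v_inst_median, v_roll,
#'   true_binding_fraction, censored`.
#' @export
transits_to_cells <- function(transits) {
  v_med <- map_dbl(transits$fov_intervals, function(fi) {
    o <- order(fi$velocity)
    v <- fi$velocity[o]
    wt <- cumsum(fi$duration[o]) / sum(fi$duration)
    v[which(wt >= 0.5)[1]]
  })
  tibble(cell_id = transits$cell_id,
         t_elution = transits$t_elution,
         v_inst_median = v_med,
         v_roll = transits$v_roll,
         true_binding_fraction = transits$true_binding_fraction,
         censored = transits$censored)
}

#' Population summary of a run
#'
#' Aggregates per-cell records: percent rolling (rolling cells over classified
#' cells, arrested in the denominator, censored excluded), median rolling
#' instantaneous velocity, mean percent binding time with its standard error,
#' mean average velocity, the average/instantaneous velocity ratio summarized
#' separately for rolling and free-flowing cells, and the residence-time
#' histogram.
#'
#' @param records A [cell_records()] table.
#' @param bin_width Residence histogram bin width (s).
#' @param acquisition_duration Acquisition window (s).
#' @return An object of class `population_summary`.
#' @export
summarize_population <- function(records, bin_width = 60,
                                 acquisition_duration = 7200) {
  if (nrow(records) == 0) stopf("no cell records to summarize")
  cls <- records$adhesion_class
  eluted <- records[cls != "censored", , drop = FALSE]
  n_classified <- nrow(eluted)
  n_rolling <- sum(eluted$adhesion_class == "rolling")
  sem <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    sd(x) / sqrt(length(x))
  }
  mean_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  roll <- eluted[eluted$adhesion_class == "rolling", , drop = FALSE]
  free <- eluted[eluted$adhesion_class == "free_flow", , drop = FALSE]
  structure(list(
    n_total = nrow(records),
    n_censored = sum(cls == "censored"),
    n_classified = n_classified,
    n_rolling = n_rolling,
    n_arrested = sum(eluted$adhesion_class == "arrested"),
    n_free_flow = nrow(free),
    pct_rolling = if (n_classified) 100 * n_rolling / n_classified else NA_real_,
    median_v_inst_rolling = if (nrow(roll)) median(roll$v_inst_median) else NA_real_,
    mean_pct_binding_time = mean_na(eluted$pct_binding_time),
    sem_pct_binding_time = sem(eluted$pct_binding_time),
    mean_v_avg = mean_na(eluted$v_avg),
    sem_v_avg = sem(eluted$v_avg),
    mean_v_ratio_rolling = mean_na(roll$v_ratio),
    mean_v_ratio_free = mean_na(free$v_ratio),
    residence = residence_distribution(records$t_elution, bin_width,
                                       acquisition_duration)),
    class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("<population_summary> n = %d (%d censored)\n", x$n_total,
              x$n_censored))
  cat(sprintf("  %% rolling: %.1f (n = %d of %d)\n", x$pct_rolling,
              x$n_rolling, x$n_classified))
  cat(sprintf("  median rolling V_inst: %.1f um/s\n", x$median_v_inst_rolling))
  cat(sprintf("  mean %% binding time: %.3f +/- %.3f\n",
              x$mean_pct_binding_time, x$sem_pct_binding_time))
  cat(sprintf("  mean V_avg: %.1f +/- %.1f um/s\n", x$mean_v_avg, x$sem_v_avg))
  cat(sprintf("  V_avg/V_inst rolling: %.2f | free flow: %.2f\n",
              x$mean_v_ratio_rolling, x$mean_v_ratio_free))
  invisible(x)
}

#' @rdname summarize_population
#' @param x A `population_summary`.
#' @param ... Unused.
#' @method glance population_summary
#' @export
glance.population_summary <- function(x, ...) {
  as_tibble(x[setdiff(names(x), "residence")])
}

#' @rdname summarize_population
#' @method tidy population_summary
#' @export
tidy.population_summary <- function(x, ...) {
  g <- glance.population_summary(x)
  tidyr::pivot_longer(g, dplyr::everything(), names_to = "metric",
                      values_to = "value")
}
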