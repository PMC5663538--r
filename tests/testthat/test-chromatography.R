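cond <- flow_condition(1.0)

test_that("adhesion classes follow the printed thresholds with strict zero exclusion", {
  expect_identical(classify_adhesion(200, cond), "rolling")
  expect_identical(classify_adhesion(400, cond), "free_flow")
  expect_identical(classify_adhesion(0, cond), "arrested")
  expect_identical(classify_adhesion(250, cond), "free_flow")  # boundary
  expect_identical(classify_adhesion(124.9, flow_condition(0.5)), "rolling")
  expect_identical(classify_adhesion(370, flow_condition(1.5)), "rolling")
  expect_error(classify_adhesion(-5, cond), "v_inst")
})

test_that("average velocity is channel length over corrected transit time", {
  expect_equal(average_velocity(300, 20, 140000), 500)
  # pure free flow: corrected time L / v_ff returns v_ff
  expect_equal(average_velocity(20 + 13000 / 1059, 20, 13000), 1059)
  expect_error(average_velocity(20, 20, 13000), "t_offset")
})

test_that("percent binding time evaluates the mass balance", {
  expect_equal(percent_binding_time(1059, 60, 0, 13000, 100),
               (1059 * 60 - 13000) / ((1059 - 100) * 60))
  expect_equal(percent_binding_time(1059, 60, 0, 13000, 100), 0.87834,
               tolerance = 1e-5)
  # boundary identities: pure free flow -> 0, rolled the whole channel -> 1
  expect_equal(percent_binding_time(1059, 13000 / 1059, 0, 13000, 100), 0)
  expect_equal(percent_binding_time(1059, 130, 0, 13000, 100), 1)
  expect_error(percent_binding_time(1059, 60, 0, 13000, 1200), "v_inst")
  expect_error(percent_binding_time(1059, 10, 20, 13000, 100), "t_elution")
})

test_that("binding time is monotone in elution time; average velocity is anti-monotone", {
  t_e <- seq(15, 200, by = 5)
  bt <- percent_binding_time(1059, t_e, 0, 13000, 100, clamp = FALSE)
  expect_true(all(diff(bt) > 0))
  expect_true(all(diff(average_velocity(t_e, 0, 13000)) < 0))
})

test_that("two-velocity transits satisfy the mass-balance identity to machine precision", {
  geom <- channel_geometry()
  p <- simulation_params(n_cells = 100, k_on = 0.7, k_off = 1.1,
                         v_roll_mean = 100, v_roll_cv = 0,
                         t_offset_mean = 0, seed = 21)
  tr <- simulate_transits(p, cond, geom)
  bt <- percent_binding_time(cond$v_free_flow, tr$t_elution, 0,
                             geom$fov_position, tr$v_roll)
  expect_equal(bt, tr$true_binding_fraction, tolerance = 1e-12)
})

test_that("offset estimation recovers the settling time from a blank run", {
  geom <- channel_geometry()
  blank <- simulation_params(n_cells = 400, k_on = 0, p_start_bound = 0,
                             t_offset_mean = 30, t_offset_cv = 0.2, seed = 5)
  tr <- simulate_transits(blank, cond, geom)
  est <- estimate_offset_time(tr$t_elution, cond$v_free_flow,
                              geom$fov_position)
  expect_equal(est, 30, tolerance = 0.1 * 30)
  # exact free-flow times estimate zero offset
  expect_equal(
    estimate_offset_time(rep(13000 / 1059, 20), 1059, 13000), 0)
  expect_error(estimate_offset_time(numeric(0), 1059, 13000), "blank")
})

test_that("offset estimator standard error matches the bootstrap", {
  set.seed(31)
  n <- 1000
  blank_times <- 13000 / 1059 + 30 + rnorm(n, 0, 4)
  boot <- replicate(400, estimate_offset_time(
    sample(blank_times, replace = TRUE), 1059, 13000))
  expect_equal(sd(boot), sd(blank_times) / sqrt(n), tolerance = 0.15)
})

test_that("residence distributions normalize, separate censored cells, and shift with binding", {
  t_e <- c(10, 20, 30, 8000, NA)
  h <- residence_distribution(t_e, bin_width = 60, acquisition_duration = 7200)
  expect_equal(sum(h$prop), 1)
  expect_equal(attr(h, "n_censored"), 2L)
  expect_equal(attr(h, "n_eluted"), 3L)
  # blank channel: all mass in the first bins
  geom <- channel_geometry()
  blank <- simulate_transits(
    simulation_params(n_cells = 200, k_on = 0, p_start_bound = 0,
                      t_offset_mean = 5, seed = 6), cond, geom)
  hb <- residence_distribution(blank$t_elution, bin_width = 60)
  expect_true(all(hb$bin_start < 180))
  # nothing eluted
  h0 <- residence_distribution(rep(NA_real_, 4), 60)
  expect_equal(nrow(h0), 0L)
  expect_equal(attr(h0, "n_censored"), 4L)
})

test_that("cell records bridge the two velocity scales consistently", {
  geom <- channel_geometry(channel_length = 13000, fov_length = 650)
  cfg <- analysis_config(t_offset = 0, zero_motion_tol = 0)
  # %BT = 0 cell: elutes at L/v_ff, so v_avg equals v_free_flow
  # %BT = 1 cell: elutes at L/v_inst, so v_avg equals v_inst
  cells <- tibble::tibble(cell_id = 1:2,
                          t_elution = c(13000 / 1059, 13000 / 100),
                          v_inst_median = c(1000, 100))
  rec <- cell_records(cells, cond, geom, cfg)
  expect_equal(rec$pct_binding_time, c(0, 1), tolerance = 1e-12)
  expect_equal(rec$v_avg, c(1059, 100), tolerance = 1e-12)
  expect_equal(rec$v_ratio, rec$v_avg / rec$v_inst_median)
  expect_identical(rec$adhesion_class, c("free_flow", "rolling"))
})

test_that("cell records censor non-eluting cells and skip the undefined mass balance", {
  geom <- channel_geometry(channel_length = 13000, fov_length = 650)
  cfg <- analysis_config(t_offset = 0, acquisition_duration = 100,
                         zero_motion_tol = 0)
  cells <- tibble::tibble(cell_id = 1:3,
                          t_elution = c(50, 150, 40),
                          v_inst_median = c(100, 100, 1200))
  rec <- cell_records(cells, cond, geom, cfg)
  expect_identical(rec$adhesion_class, c("rolling", "censored", "free_flow"))
  expect_true(is.na(rec$v_avg[2]))
  expect_true(is.na(rec$pct_binding_time[3]))  # v_inst above v_free_flow
  expect_false(is.na(rec$v_avg[3]))
})

test_that("population summaries aggregate the documented way", {
  geom <- channel_geometry(channel_length = 13000, fov_length = 650)
  cfg <- analysis_config(t_offset = 0, zero_motion_tol = 0)
  cells <- tibble::tibble(
    cell_id = 1:10,
    t_elution = c(rep(100, 4), rep(14, 6)),
    v_inst_median = c(rep(100, 4), rep(900, 6)))
  rec <- cell_records(cells, cond, geom, cfg)
  s <- summarize_population(rec)
  expect_equal(s$pct_rolling, 40)
  expect_equal(s$n_classified, 10)
  expect_equal(s$median_v_inst_rolling, 100)
  expect_s3_class(glance(s), "tbl_df")
  expect_true("pct_rolling" %in% tidy(s)$metric)
  expect_error(summarize_population(rec[0, ]), "no cell records")
  # mean/SEM of binding times {0.8, 1.0}
  expect_equal(mean(c(0.8, 1)), 0.9)
  sub <- rec[1:2, ]
  sub$pct_binding_time <- c(0.8, 1.0)
  s2 <- summarize_population(sub)
  expect_equal(s2$mean_pct_binding_time, 0.9)
  expect_equal(s2$sem_pct_binding_time, 0.1, tolerance = 1e-12)
})

test_that("known bound fraction is recovered through the full record pipeline", {
  geom <- channel_geometry()
  p <- simulation_params(n_cells = 1000, k_on = 1, k_off = 1,
                         v_roll_mean = 100, v_roll_cv = 0,
                         p_start_bound = 0.5, t_offset_mean = 0, seed = 8)
  tr <- simulate_transits(p, cond, geom)
  cells <- transits_to_cells(tr)
  # evaluate the mass balance at the elution distance with the known
  # two-velocity rolling speed
  g_eff <- channel_geometry(channel_length = geom$fov_position,
                            fov_length = geom$fov_length,
                            fov_position = geom$fov_position - geom$fov_length)
  bt <- percent_binding_time(cond$v_free_flow, cells$t_elution, 0,
                             geom$fov_position, cells$v_roll)
  expect_lt(abs(mean(bt) - 0.5), 0.02)
})
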