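# rollchrom

Cell adhesion chromatography for rolling cells in selectin-functionalized
microchannels: a tested R pipeline that simulates, tracks and analyses
pulses of cells transiting a flow channel while stochastically switching
between rolling adhesion and free flow.

## The problem

Selectins (P-, E-, L-) capture circulating cells — leukocytes, metastatic
tumor cells — under shear flow through fast, force-dependent bonds,
producing *rolling adhesion*: slow, unsteady forward motion along the wall.
Conventional flow-chamber analysis watches a single field of view (FOV) and
reports the fraction of rolling cells and their instantaneous velocities.
Adhesion chromatography adds a whole-channel, elution-based readout: a pulse
of cells is injected upstream of a functionalized channel (1.3 or 14 cm)
and each cell's arrival time in a FOV at the channel end is recorded over a
2 h acquisition at 25 fps.

For each cell with elution time $t_e$, settling-feature offset $t_o$ and
in-FOV median instantaneous velocity $V_{inst}$, the package computes

$$V_{avg} = \frac{L_{channel}}{t_e - t_o}$$

and, from a mass balance over a transit that alternates between a bound
state at $V_{inst}$ and free flow at $v_{ff}$,

$$\%BT = \frac{v_{ff}\,(t_e - t_o) - L_{channel}}{(v_{ff} - V_{inst})\,(t_e - t_o)}$$

the *percent binding time* — the fraction of the transit the cell spent
adhesively engaged, 0 for pure free flow and 1 for rolling the entire
channel. Free-flow velocities (529/1059/1588 um/s) and rolling
classification thresholds (125/250/375 um/s) at 0.5/1.0/1.5 dyn/cm² are
built-in calibration constants.

The package provides, as tidyverse-style functions over tibbles:

* `simulate_transits()` — a two-state continuous-time Markov transit
  simulator (ground truth for every downstream stage), plus
  `render_video()` to emit noisy 8-bit TIFF stacks at the acquisition
  settings (25 fps, 500×376 px);
* `track_stack()` — the video post-processing: running-average background
  (weight 0.0005 ≈ 80 s moving average), 13 px blur, threshold 15, >5 um
  contour filter, greedy look-ahead/overlap linking;
* `cell_records()` / `summarize_population()` — per-cell metrics and
  population summaries (% rolling, median rolling $V_{inst}$, mean %BT ±
  SEM, $V_{avg}/V_{inst}$ ratios, residence-time distributions);
* `linear_regression()` / `dose_response_table()` — cross-condition
  comparisons with broom-style `tidy()`/`glance()` and ggplot2
  `autoplot()` methods;
* `run_pipeline()` and a thin CLI (`inst/cli/rollchrom`) binding the
  stages end to end from a YAML/JSON config.

## Worked example

Simulate a P-selectin run at 1.0 dyn/cm² in a 1.3 cm channel, calibrate the
settling offset from a blank run, and summarize the population:

```r
library(rollchrom)

cond <- flow_condition(tau_wall = 1.0, selectin = "P", selectin_conc = 25)
geom <- channel_geometry(channel_length = 13000)

transits <- simulate_transits(
  simulation_params(n_cells = 500, k_on = 0.5, k_off = 1,
                    t_offset_mean = 5, seed = 42), cond, geom)

blank <- simulate_transits(
  simulation_params(n_cells = 200, k_on = 0, p_start_bound = 0,
                    t_offset_mean = 5, seed = 43), cond, geom)
t_off <- estimate_offset_time(blank$t_elution, cond$v_free_flow,
                              geom$channel_length)   # 4.46 s

records <- transits_to_cells(transits) |>
  cell_records(cond, geom, analysis_config(t_offset = t_off,
                                           zero_motion_tol = 0))
summarize_population(records)
#> <population_summary> n = 500 (0 censored)
#>   % rolling: 14.8 (n = 74 of 500)
#>   median rolling V_inst: 94.4 um/s
#>   mean % binding time: 0.310 +/- 0.016
#>   mean V_avg: 758.2 +/- 5.8 um/s
#>   V_avg/V_inst rolling: 8.40 | free flow: 0.72
```

With `k_on = 0.5`, `k_off = 1` the stationary bound fraction is 1/3, and
the mean percent binding time recovered from elution times alone (0.31)
agrees with it. Only ~15% of cells are *classified* rolling because
classification reflects the short FOV dwell, while %BT integrates binding
over the whole channel — exactly the gap between instantaneous and average
measures the chromatography statistic is designed to expose. Rolling cells
show $V_{avg}/V_{inst} \gg 1$ (they spent much of the channel in free
flow); free-flow-classified cells show a ratio below 1 (they bound
somewhere upstream).

`autoplot(summarize_population(records))` draws the residence-time
histogram; `plot_velocity_distribution(records, cond)` shows the velocity
distribution against the rolling threshold.

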