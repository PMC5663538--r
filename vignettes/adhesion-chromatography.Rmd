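---
title: "Cell adhesion chromatography: model, metrics, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell adhesion chromatography: model, metrics, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rollchrom)
```

## The measurement

Circulating cells interact with selectins — P-, E- and L-selectin — on
vessel walls through fast, force-dependent bonds that produce *rolling
adhesion*: slow, unsteady forward translation under flow. In an adhesion
chromatography experiment a pulse of cells (by default 50 uL of 5×10^5
cells/mL, i.e. 2.5×10^4 cells) is injected upstream of a
selectin-functionalized microchannel (1.3 or 14 cm long, 2 mm wide, 100 um
deep). Cells first pass a circular settling feature that brings them to the
substrate, then transit the functionalized channel, and are finally imaged
in a field of view (FOV) at the channel end at 25 frames per second
(500 × 376 px, 2×2 binned) for up to two hours.

Two velocity scales describe each cell:

* **Instantaneous velocity** `V_inst` — the median frame-to-frame speed
  measured inside the FOV. A cell is classified *rolling* when
  `0 < V_inst < threshold(tau)`, with thresholds 125, 250 and 375 um/s at
  wall shear stresses of 0.5, 1.0 and 1.5 dyn/cm²; at or above the
  threshold it is in *free flow* (free-flow speeds are taken as 529, 1059
  and 1588 um/s at those shear stresses), and a speed indistinguishable
  from zero is *arrested*.
* **Average velocity** — a whole-channel, elution-based speed:
  `V_avg = L_channel / (t_elution − t_offset)`, where `t_elution` is the
  arrival time in the FOV and `t_offset` the mean time spent in the
  settling feature.

Because a cell may switch between rolling and free flow many times along
the channel, `V_avg` and `V_inst` disagree, and their disagreement is
informative. A mass balance over the transit — bound at `V_inst`, free at
`v_free_flow`, total distance `L_channel` — gives the **percent binding
time**, the fraction of the corrected transit the cell spent adhesively
engaged:

```
%BT = [v_ff (t_e − t_o) − L] / [(v_ff − V_inst)(t_e − t_o)]
```

It is 0 for a cell that never bound (elutes at `L / v_ff`) and 1 for a cell
that rolled the whole channel (elutes at `L / V_inst`). The residence-time
distribution (histogram of elution times) is the chromatography readout at
the population level.

## The generative model

`simulate_transits()` implements the minimal stochastic model consistent
with the two-phenotype picture: a continuous-time two-state Markov process.
A cell is either *bound* (moving at its own rolling speed) or *free*
(moving at the shear-set free-flow speed); holding times are exponential
with rates `k_off` (bound to free) and `k_on` (free to bound). The path is
advanced until the covered distance reaches the FOV entry position; the
final interval is truncated so distances are conserved exactly, which is
what makes the mass-balance identity testable to machine precision: for a
run with a single rolling speed, `%BT` applied to `(t_elution, v_roll)`
*equals* the recorded bound-time fraction algebraically.

Modeling choices, each made once:

* **Per-cell rolling speed**, drawn once per cell from a lognormal
  distribution parameterized by mean and coefficient of variation (CV),
  rather than per interval. This produces the per-cell median `V_inst` the
  analysis uses; draws at or above the free-flow speed are rejected and
  redrawn (bounded retries). Default mean 100 um/s, CV 0.3 — mid-range
  rolling at 1.0 dyn/cm², well below the 250 um/s threshold.
* **Settling time** is per-cell lognormal (mean 30 s, CV 0.2 by default)
  but recorded, so the analysis can use the population mean exactly as a
  chromatograph would calibrate it.
* **Censoring**: cells whose elution time exceeds the acquisition window
  (default 7200 s, the two-hour video) are emitted flagged as censored;
  they are excluded from elution-based metrics and reported as a count.
* **Rates are user parameters.** The defaults (`k_on` 0.5/s, `k_off` 1/s)
  give a stationary bound fraction of 1/3 with several switches per transit
  of the 1.3 cm channel — enough to exercise every downstream branch. They
  are not estimates of any particular cell line's kinetics.
* The same sample path is continued across the FOV (`fov_intervals`), so a
  rendered video shows the in-FOV motion a tracker must measure, while the
  distance-conservation invariant is kept on the channel intervals proper.

Rendering (`render_video()`) draws each cell as a Gaussian spot of
configurable width and amplitude on a uniform static background with
additive Gaussian read noise, quantized to 8 bits — enough structure to
exercise the background model, blurring, thresholding, the size filter and
linking. It deliberately omits illumination drift, debris, cell deformation,
intensity variation between cells, and cell–cell collisions or secondary
capture; a tracker that passes the round-trip tests here is validated
against geometry and noise, not against those real-world nuisances. The
pixel size defaults to 1.3 um/px, a plausible figure for a 10× objective
with 2×2 binning; it is configurable everywhere because the acquisition
metadata does not pin it down.

## The tracker

The video post-processing follows a running-average background pipeline:

1. **Background**: an exponentially weighted moving average with weight
   0.0005 per frame — at 25 fps an e-folding time constant of
   `1/(0.0005 × 25) = 80 s`. It is initialized from the first frame and
   detections are suppressed for a 25-frame (1 s) warm-up.
2. **Blur and threshold**: both the frame and the accumulator are smoothed
   with a 13 px square box kernel and pixels where the absolute difference
   reaches 15 counts (8-bit) form the foreground mask. The original
   description gives these as dimensionless "factors"; a kernel side in
   pixels and an absolute intensity threshold are the dimensionally
   consistent reading, and both remain configuration values
   (`tracker_config()`).
3. **Detection**: connected components of the mask (labelled via EBImage);
   components with equivalent diameter at or below 5 um are discarded;
   centroids are intensity-weighted by the blurred difference.
4. **Linking**: greedy per-frame assignment to the nearest predicted
   position (last position plus last velocity times the gap), gated at
   1.2× the expected free-flow displacement per frame so free-flowing cells
   remain linkable, with an object-overlap criterion as a fallback for
   large/slow objects and an upstream-displacement allowance of one cell
   diameter (rolling is forward motion; small retrograde jitter is real,
   large retrograde jumps are mismatches). Ties break by smallest distance,
   then earliest track id — the tracker is fully deterministic. Tracks
   unmatched for more than 3 frames (the look-ahead window; the original
   length is unstated) are closed.

Greedy nearest-neighbour assignment, not global optimization, is used on
purpose: it matches the simple tracker the pipeline reimplements, and with
the stated tie-breaks it is reproducible. Pixel coordinates are 0-based
with x along the flow axis; conversions to um use the pixel size.

## Numerical and policy choices

* **Elution distance vs channel length.** The simulator defines elution as
  arrival at the FOV *start*, `fov_position = L_channel − fov_length` by
  default (650 um short of the end, a 5% difference for the 1.3 cm
  channel). The whole-channel formulas use `L_channel`, as the method
  prescribes; the small resulting bias is absorbed by the offset-time
  calibration in practice (see below), and exact identities in the test
  suite are evaluated at the elution distance itself.
* **Offset calibration.** `estimate_offset_time()` uses a blank
  (non-functionalized) run: `t_offset = mean(blank elutions) − L / v_ff`,
  floored at zero, with a warning when the estimate is substantially
  negative (a sign the assumed free-flow speed is wrong).
* **Clamping.** Raw `%BT` values outside `[0, 1]` arise from measurement
  noise and calibration error; the quantity is a time fraction by
  derivation, so records clamp by default while always retaining the raw
  value (`pct_binding_time_raw`). Raw values well below zero trigger a
  calibration warning rather than silent truncation.
* **Arrest tolerance.** "Zero" motion is judged against one pixel per
  frame (`pixel_size × frame_rate` um/s) when analyzing tracked data, and
  exactly zero for ground-truth transits.
* **Aggregation.** `pct_rolling` counts rolling cells over classified
  (eluted) cells, with arrested cells in the denominator and censored cells
  excluded; median `V_inst` is reported over rolling cells; `V_avg/V_inst`
  is summarized separately for rolling and free-flow populations. SEM is
  across cells within a run; experiment-level aggregation (mean ± SEM
  across independent runs, the unit plotted in dose-response figures) is
  the job of `dose_response_table()`, which deliberately stops at tidy
  group summaries — factorial ANOVA with multiplicity correction is left to
  the standard machinery (`stats::aov`, `multcomp`) on the exported tables.

## What the tests establish, at what sizes

The suite runs entirely on synthetic data at desk scale: mass-balance
identities on 100 two-velocity transits; stationary bound-fraction recovery
(`k_on = k_off`, 1000 cells, within 0.02 of 0.5, cross-checked against an
independent small-step discrete-time simulation); blank-run offset recovery
at n = 500 with a bootstrap check of the estimator's standard error;
tracking round trips on rendered stacks of 20 simultaneous cells at
moderate noise (≥ 95% of cells recovered with median speed error < 5%);
background convergence against the closed-form geometric recursion; and
regression against the closed-form normal equations with a 1000-replicate
null calibration of the slope test. These sizes keep the full suite around
a minute on one CPU while leaving Monte-Carlo error well inside each
tolerance. Passing them validates the pipeline's internal consistency on
data the generator can produce — it does not certify performance on real
videos with debris, drift, or dense fields of touching cells.

## Limitations

The free-flow speeds and rolling thresholds are calibration constants, not
computed from hydrodynamics; near-wall velocity profiles, cell deformation
and secondary capture are out of scope. Bond kinetic parameters are inputs
to the simulator, never inferred from data. The tracker handles moderate
densities; in crowded scenes merged detections degrade both `%` rolling and
speed estimates before linking fails outright.
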