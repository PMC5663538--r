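# Configuration constructors. Each returns a validated classed list; all
# downstream functions accept these objects so invalid settings fail early
# with the offending field named.

# printed calibration: (tau_wall dyn/cm^2, v_free_flow um/s, v_roll_threshold um/s)
.TAU_TABLE <- data.frame(
  tau_wall    = c(0.5, 1.0, 1.5),
  v_free_flow = c(529, 1059, 1588),
  v_threshold = c(125, 250, 375)
)

#' Free-flow cell velocity for a wall shear stress
#'
#' Near-wall free-flow cell speeds are taken as calibration constants:
#' 529, 1059 and 1588 um/s at 0.5, 1.0 and 1.5 dyn/cm2. Other shear stresses
#' use the linear extension 1059 um/s per dyn/cm2.
#'
#' @param tau_wall Wall shear stress (dyn/cm2), positive.
#' @return Free-flow velocity (um/s).
#' @export
#' @examples
#' free_flow_velocity(1.0) # 1059
free_flow_velocity <- function(tau_wall) {
  if (any(tau_wall <= 0)) stopf("tau_wall must be > 0")
  hit <- match(tau_wall, .TAU_TABLE$tau_wall)
  out <- ifelse(is.na(hit), 1059 * tau_wall, .TAU_TABLE$v_free_flow[hit])
  unname(out)
}

#' Rolling-velocity classification threshold for a wall shear stress
#'
#' Cells with median instantaneous velocity strictly between zero and this
#' threshold are classified as rolling: 125, 250 and 375 um/s at 0.5, 1.0 and
#' 1.5 dyn/cm2, extended linearly (250 um/s per dyn/cm2) elsewhere.
#'
#' @inheritParams free_flow_velocity
#' @return Rolling threshold velocity (um/s).
#' @export
rolling_threshold <- function(tau_wall) {
  if (any(tau_wall <= 0)) stopf("tau_wall must be > 0")
  hit <- match(tau_wall, .TAU_TABLE$tau_wall)
  out <- ifelse(is.na(hit), 250 * tau_wall, .TAU_TABLE$v_threshold[hit])
  unname(out)
}

#' Flow condition
#'
#' Wall shear stress with its derived free-flow velocity and rolling
#' threshold, plus substrate metadata (selectin type and concentration,
#' heparin dose).
#'
#' @param tau_wall Wall shear stress (dyn/cm2).
#' @param v_free_flow Free-flow cell velocity (um/s); defaults to the
#'   calibration for `tau_wall`.
#' @param v_roll_threshold Rolling classification threshold (um/s); defaults
#'   to the calibration for `tau_wall`.
#' @param selectin One of "P", "E", "L", "none".
#' @param selectin_conc Immobilized selectin concentration (ug/mL).
#' @param heparin_dose Heparin dose (U/mL).
#' @return An object of class `flow_condition`.
#' @export
#' @examples
#' flow_condition(1.0)
flow_condition <- function(tau_wall = 1.0,
                           v_free_flow = free_flow_velocity(tau_wall),
                           v_roll_threshold = rolling_threshold(tau_wall),
                           selectin = c("P", "E", "L", "none"),
                           selectin_conc = 25,
                           heparin_dose = 0) {
  selectin <- match.arg(selectin)
  if (tau_wall <= 0) stopf("tau_wall must be > 0, got %g", tau_wall)
  if (!(v_roll_threshold > 0 && v_roll_threshold < v_free_flow))
    stopf("need 0 < v_roll_threshold (%g) < v_free_flow (%g)",
          v_roll_threshold, v_free_flow)
  if (selectin_conc < 0) stopf("selectin_conc must be >= 0")
  if (heparin_dose < 0) stopf("heparin_dose must be >= 0")
  structure(list(tau_wall = tau_wall, v_free_flow = v_free_flow,
                 v_roll_threshold = v_roll_threshold, selectin = selectin,
                 selectin_conc = selectin_conc, heparin_dose = heparin_dose),
            class = "flow_condition")
}

#' Channel geometry
#'
#' Microchannel dimensions in micrometres. Presets for the functionalized
#' channel length are 13,000 um (1.3 cm) and 140,000 um (14 cm). The imaging
#' field of view (FOV) sits by default at the channel end.
#'
#' @param channel_length Functionalized channel length (um).
#' @param channel_width,channel_depth Cross-section (um).
#' @param settling_inner_radius,settling_outer_radius Upstream settling
#'   feature radii (um).
#' @param fov_length FOV extent along the flow axis (um).
#' @param fov_position Distance of the FOV start from the channel inlet (um);
#'   default `channel_length - fov_length`.
#' @return An object of class `channel_geometry`.
#' @export
channel_geometry <- function(channel_length = 13000,
                             channel_width = 2000,
                             channel_depth = 100,
                             settling_inner_radius = 10500,
                             settling_outer_radius = 11750,
                             fov_length = 650,
                             fov_position = channel_length - fov_length) {
  vals <- c(channel_length = channel_length, channel_width = channel_width,
            channel_depth = channel_depth,
            settling_inner_radius = settling_inner_radius,
            settling_outer_radius = settling_outer_radius,
            fov_length = fov_length)
  bad <- names(vals)[vals <= 0]
  if (length(bad)) stopf("geometry fields must be > 0: %s",
                         paste(bad, collapse = ", "))
  if (fov_position < 0) stopf("fov_position must be >= 0")
  if (fov_position + fov_length > channel_length + 1e-9)
    stopf("fov_position + fov_length (%g) exceeds channel_length (%g)",
          fov_position + fov_length, channel_length)
  structure(c(as.list(vals), list(fov_position = fov_position)),
            class = "channel_geometry")
}

#' Two-state transit simulation parameters
#'
#' Parameters of the continuous-time two-state (bound/free) stochastic model
#' each cell follows while transiting the channel. Holding times are
#' exponential with rates `k_on` (free to bound) and `k_off` (bound to free);
#' each cell's rolling speed is drawn once from a lognormal distribution with
#' the given mean and coefficient of variation.
#'
#' @param n_cells Number of cells in the injected pulse. The default is the
#'   pulse used throughout: 50 uL of 5e5 cells/mL (see [pulse_cell_count()]).
#' @param k_on Free-to-bound transition rate (1/s).
#' @param k_off Bound-to-free transition rate (1/s).
#' @param v_roll_mean Mean per-cell rolling speed (um/s).
#' @param v_roll_cv Coefficient of variation of the per-cell rolling speed.
#' @param p_start_bound Probability a cell enters the channel bound.
#' @param t_offset_mean Mean settling-feature transit time (s).
#' @param t_offset_cv Coefficient of variation of the settling time.
#' @param acquisition_duration Video length (s); cells not reaching the FOV
#'   within it are flagged censored. Default 7200 (2 h).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(n_cells = pulse_cell_count(),
                              k_on = 0.5, k_off = 1.0,
                              v_roll_mean = 100, v_roll_cv = 0.3,
                              p_start_bound = 0.5,
                              t_offset_mean = 30, t_offset_cv = 0.2,
                              acquisition_duration = 7200,
                              seed = NULL) {
  if (n_cells < 1) stopf("n_cells must be >= 1")
  if (k_on < 0 || k_off < 0) stopf("rates k_on/k_off must be >= 0")
  if (p_start_bound < 0 || p_start_bound > 1)
    stopf("p_start_bound must be in [0, 1]")
  if (v_roll_mean <= 0) stopf("v_roll_mean must be > 0")
  if (v_roll_cv < 0 || t_offset_cv < 0) stopf("CVs must be >= 0")
  if (t_offset_mean < 0) stopf("t_offset_mean must be >= 0")
  if (acquisition_duration <= 0) stopf("acquisition_duration must be > 0")
  structure(list(n_cells = as.integer(n_cells), k_on = k_on, k_off = k_off,
                 v_roll_mean = v_roll_mean, v_roll_cv = v_roll_cv,
                 p_start_bound = p_start_bound, t_offset_mean = t_offset_mean,
                 t_offset_cv = t_offset_cv,
                 acquisition_duration = acquisition_duration, seed = seed),
            class = "simulation_params")
}

#' Number of cells in an injected pulse
#'
#' @param volume_ul Pulse volume (uL); default 50.
#' @param conc_per_ml Cell suspension concentration (cells/mL); default 5e5.
#' @return Cell count (default 2.5e4).
#' @export
pulse_cell_count <- function(volume_ul = 50, conc_per_ml = 5e5) {
  if (volume_ul <= 0 || conc_per_ml <= 0) stopf("pulse parameters must be > 0")
  as.integer(round(volume_ul / 1000 * conc_per_ml))
}

#' Video rendering configuration
#'
#' Settings emulating the acquisition: 25 frames per second, 500 x 376 px
#' images. Cells are rendered as Gaussian spots on a uniform background with
#' additive Gaussian read noise, clipped to 8 bits. The pixel size default of
#' 1.3 um/px is a plausible value for a 10x objective with 2x2 binning and is
#' fully configurable.
#'
#' @param pixel_size Pixel size (um/px).
#' @param image_width,image_height Frame size (px); width is along the flow.
#' @param frame_rate Acquisition rate (Hz).
#' @param cell_diameter Nominal cell diameter (um).
#' @param psf_sigma Gaussian spot width (px).
#' @param background_level,cell_amplitude 8-bit intensities.
#' @param noise_sigma Read-noise standard deviation (intensity counts).
#' @param seed Integer seed for the noise; `NULL` uses the current stream.
#' @return An object of class `render_config`.
#' @export
render_config <- function(pixel_size = 1.3,
                          image_width = 500, image_height = 376,
                          frame_rate = 25,
                          cell_diameter = 12, psf_sigma = 2.5,
                          background_level = 40, cell_amplitude = 90,
                          noise_sigma = 3, seed = NULL) {
  if (pixel_size <= 0) stopf("pixel_size must be > 0")
  if (frame_rate <= 0) stopf("frame_rate must be > 0")
  if (image_width < 1 || image_height < 1) stopf("image size must be >= 1 px")
  if (background_level < 0 || background_level > 255 ||
      cell_amplitude < 0 || cell_amplitude > 255)
    stopf("background_level and cell_amplitude must be 8-bit (0..255)")
  if (noise_sigma < 0) stopf("noise_sigma must be >= 0")
  if (psf_sigma <= 0) stopf("psf_sigma must be > 0")
  structure(list(pixel_size = pixel_size,
                 image_width = as.integer(image_width),
                 image_height = as.integer(image_height),
                 frame_rate = frame_rate, cell_diameter = cell_diameter,
                 psf_sigma = psf_sigma, background_level = background_level,
                 cell_amplitude = cell_amplitude, noise_sigma = noise_sigma,
                 seed = seed),
            class = "render_config")
}

#' Tracker configuration
#'
#' Video post-processing parameters: running-average background weight
#' (0.0005, an ~80 s moving average at 25 fps), a 13-px square blur, an
#' absolute 8-bit difference threshold of 15 counts, and a minimum detected
#' object diameter of 5 um.
#'
#' @param alpha Background update weight in (0, 1].
#' @param blur_kernel Square smoothing kernel side (px, odd).
#' @param intensity_threshold Foreground threshold (8-bit counts).
#' @param min_diameter Minimum object equivalent diameter (um); objects at or
#'   below it are discarded.
#' @param pixel_size Pixel size (um/px).
#' @param frame_rate Frame rate (Hz).
#' @param lookahead_frames Frames a track survives unmatched before closing.
#' @param v_free_flow Expected free-flow speed (um/s), used for the default
#'   linking gate.
#' @param max_link_distance Maximum detection-to-prediction distance per frame
#'   gap (um); default 1.2 x the free-flow displacement per frame.
#' @param flow_axis_bias Allowed upstream (against-flow) displacement (um);
#'   default one cell diameter (12 um).
#' @param warmup_frames Initial frames with detection suppressed while the
#'   background model settles; default 25 (1 s).
#' @return An object of class `tracker_config`.
#' @export
tracker_config <- function(alpha = 0.0005,
                           blur_kernel = 13,
                           intensity_threshold = 15,
                           min_diameter = 5,
                           pixel_size = 1.3,
                           frame_rate = 25,
                           lookahead_frames = 3,
                           v_free_flow = free_flow_velocity(1.0),
                           max_link_distance = 1.2 * v_free_flow / frame_rate,
                           flow_axis_bias = 12,
                           warmup_frames = 25) {
  if (alpha <= 0 || alpha > 1) stopf("alpha must be in (0, 1]")
  blur_kernel <- as.integer(blur_kernel)
  if (blur_kernel < 1 || blur_kernel %% 2 == 0)
    stopf("blur_kernel must be odd and >= 1, got %d", blur_kernel)
  if (intensity_threshold <= 0) stopf("intensity_threshold must be > 0")
  if (min_diameter <= 0) stopf("min_diameter must be > 0")
  if (pixel_size <= 0) stopf("pixel_size must be > 0")
  if (frame_rate <= 0) stopf("frame_rate must be > 0")
  if (lookahead_frames < 0) stopf("lookahead_frames must be >= 0")
  if (max_link_distance <= 0) stopf("max_link_distance must be > 0")
  if (flow_axis_bias < 0) stopf("flow_axis_bias must be >= 0")
  if (warmup_frames < 0) stopf("warmup_frames must be >= 0")
  structure(list(alpha = alpha, blur_kernel = blur_kernel,
                 intensity_threshold = intensity_threshold,
                 min_diameter = min_diameter, pixel_size = pixel_size,
                 frame_rate = frame_rate,
                 lookahead_frames = as.integer(lookahead_frames),
                 v_free_flow = v_free_flow,
                 max_link_distance = max_link_distance,
                 flow_axis_bias = flow_axis_bias,
                 warmup_frames = as.integer(warmup_frames)),
            class = "tracker_config")
}

#' Chromatography analysis configuration
#'
#' @param t_offset Population mean settling time (s); subtracted from elution
#'   times before the transit-time metrics.
#' @param acquisition_duration Acquisition window (s); default 7200.
#' @param clamp_binding_time Clamp the mass-balance binding-time fraction to
#'   `[0, 1]` (raw value retained alongside). Default `TRUE`.
#' @param zero_motion_tol Speed below which a cell counts as arrested (um/s);
#'   default one pixel per frame: `pixel_size * frame_rate`.
#' @param pixel_size,frame_rate Used only for the arrest tolerance default.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(t_offset = 0,
                            acquisition_duration = 7200,
                            clamp_binding_time = TRUE,
                            pixel_size = 1.3, frame_rate = 25,
                            zero_motion_tol = pixel_size * frame_rate) {
  if (t_offset < 0) stopf("t_offset must be >= 0")
  if (acquisition_duration <= 0) stopf("acquisition_duration must be > 0")
  if (zero_motion_tol < 0) stopf("zero_motion_tol must be >= 0")
  structure(list(t_offset = t_offset,
                 acquisition_duration = acquisition_duration,
                 clamp_binding_time = isTRUE(clamp_binding_time),
                 zero_motion_tol = zero_motion_tol),
            class = "analysis_config")
}

#' @export
print.flow_condition <- function(x, ...) {
  cat(sprintf(
    "<flow_condition> tau = %g dyn/cm2 | v_free = %g um/s | threshold = %g um/s | %s-selectin %g ug/mL | heparin %g U/mL\n",
    x$tau_wall, x$v_free_flow, x$v_roll_threshold, x$selectin,
    x$selectin_conc, x$heparin_dose))
  invisible(x)
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf("<channel_geometry> L = %g um, FOV [%g, %g] um, %g x %g um section\n",
              x$channel_length, x$fov_position, x$fov_position + x$fov_length,
              x$channel_width, x$channel_depth))
  invisible(x)
}
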