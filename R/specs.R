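#' Flow-field specification for the bead-transport simulator
#'
#' Describes the advective flow experienced by tracer beads on the luminal
#' surface. The field is divided into square patches; each patch carries a
#' fixed direction drawn around `base_direction` with spread
#' `patch_direction_sd`. A coherent epithelium (healthy) corresponds to
#' `patch_direction_sd` near 0; spatially heterogeneous, erratic transport
#' (injured) to large values. A fraction of beads may be immobile (trapped in
#' mucus or adherent), experiencing diffusion only.
#'
#' @param base_speed Advective speed in um/s (>= 0).
#' @param base_direction Mean flow direction in radians, `[0, 2*pi)`.
#' @param angular_jitter_sd Per-step direction noise, radians (>= 0).
#' @param patch_size Side of the square flow patches, um (> 0).
#' @param patch_direction_sd Spread of fixed patch directions around
#'   `base_direction`, radians (>= 0). 0 = fully coherent flow.
#' @param diffusion_coeff Brownian diffusion coefficient, um^2/s (>= 0).
#' @param immobile_fraction Fraction of beads with zero advection, in `[0, 1]`.
#' @return An object of class `flow_field_spec`.
#' @export
#' @examples
#' flow_field_spec()                       # coherent "healthy" flow
#' flow_field_spec(patch_direction_sd = 1.5, base_speed = 8)  # erratic flow
flow_field_spec <- function(base_speed = 15,
                            base_direction = 0,
                            angular_jitter_sd = 0.1,
                            patch_size = 30,
                            patch_direction_sd = 0,
                            diffusion_coeff = 0.2,
                            immobile_fraction = 0) {
  check_num(base_speed, "base_speed", lower = 0)
  check_num(base_direction, "base_direction")
  check_num(angular_jitter_sd, "angular_jitter_sd", lower = 0)
  check_num(patch_size, "patch_size")
  if (patch_size <= 0) stop_field("patch_size", "must be > 0")
  check_num(patch_direction_sd, "patch_direction_sd", lower = 0)
  check_num(diffusion_coeff, "diffusion_coeff", lower = 0)
  check_num(immobile_fraction, "immobile_fraction", lower = 0, upper = 1)
  structure(list(base_speed = base_speed,
                 base_direction = base_direction %% (2 * pi),
                 angular_jitter_sd = angular_jitter_sd,
                 patch_size = patch_size,
                 patch_direction_sd = patch_direction_sd,
                 diffusion_coeff = diffusion_coeff,
                 immobile_fraction = immobile_fraction),
            class = "flow_field_spec")
}

#' Acquisition specification for the time-lapse recording
#'
#' Defaults follow the recording protocol of the assay this package
#' implements: frames every 136 ms over a 258.33 x 64.20 um field containing
#' 300-600 detectable beads.
#'
#' @param frame_interval Time between frames, seconds.
#' @param n_frames Number of frames (>= 7 so at least one full seven-frame
#'   analysis window exists).
#' @param field_width,field_height Field of view in um.
#' @param n_beads Number of beads; `NA` (default) draws uniformly in
#'   `[300, 600]` at simulation time.
#' @param dropout_prob Per-bead per-frame probability of a missed detection,
#'   in `[0, 1)`.
#' @param localization_noise_sd Localization error added to reported
#'   positions, um (>= 0).
#' @param pixel_size Pixel size for rendering, um/px (> 0).
#' @param psf_sigma Gaussian spot sigma for rendering, um (> 0).
#' @param bead_amplitude Peak spot intensity above background, counts.
#' @param background_level Constant image background, counts.
#' @param noise_sd Additive Gaussian readout noise, counts.
#' @param seed Integer seed controlling all simulator randomness.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(frame_interval = 0.136,
                             n_frames = 30,
                             field_width = 258.33,
                             field_height = 64.20,
                             n_beads = NA,
                             dropout_prob = 0.1,
                             localization_noise_sd = 0.05,
                             pixel_size = 0.2523,
                             psf_sigma = 0.4,
                             bead_amplitude = 300,
                             background_level = 100,
                             noise_sd = 5,
                             seed = 1L) {
  check_num(frame_interval, "frame_interval")
  if (frame_interval <= 0) stop_field("frame_interval", "must be > 0")
  check_num(n_frames, "n_frames", lower = 7)
  check_num(field_width, "field_width")
  check_num(field_height, "field_height")
  if (field_width <= 0 || field_height <= 0)
    stop_field("field_width/field_height", "field dimensions must be positive")
  if (!is.na(n_beads)) check_num(n_beads, "n_beads", lower = 1)
  check_num(dropout_prob, "dropout_prob", lower = 0)
  if (dropout_prob >= 1) stop_field("dropout_prob", "must be < 1")
  check_num(localization_noise_sd, "localization_noise_sd", lower = 0)
  check_num(pixel_size, "pixel_size")
  if (pixel_size <= 0) stop_field("pixel_size", "must be > 0")
  check_num(psf_sigma, "psf_sigma")
  if (psf_sigma <= 0) stop_field("psf_sigma", "must be > 0")
  check_num(bead_amplitude, "bead_amplitude", lower = 0)
  check_num(background_level, "background_level", lower = 0)
  check_num(noise_sd, "noise_sd", lower = 0)
  check_num(seed, "seed")
  structure(list(frame_interval = frame_interval,
                 n_frames = as.integer(n_frames),
                 field_width = field_width,
                 field_height = field_height,
                 n_beads = if (is.na(n_beads)) NA_integer_ else as.integer(n_beads),
                 dropout_prob = dropout_prob,
                 localization_noise_sd = localization_noise_sd,
                 pixel_size = pixel_size,
                 psf_sigma = psf_sigma,
                 bead_amplitude = bead_amplitude,
                 background_level = background_level,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "acquisition_spec")
}

#' Track eligibility and random-selection rule
#'
#' The assay selects, per recording, `n_select` beads among those recorded for
#' more than `min_intervals` continuous inter-frame intervals. With the default
#' 136 ms frame interval, the default 6 intervals span 0.816 s, i.e. a track
#' must carry at least 7 consecutive frame observations.
#'
#' @param n_select Number of beads selected per recording (default 10).
#' @param min_intervals Minimum continuous inter-frame intervals (default 6).
#' @param seed Integer seed driving the random selection.
#' @return An object of class `selection_spec`.
#' @export
selection_spec <- function(n_select = 10, min_intervals = 6, seed = 1L) {
  check_num(n_select, "n_select", lower = 1)
  check_num(min_intervals, "min_intervals", lower = 1)
  check_num(seed, "seed")
  structure(list(n_select = as.integer(n_select),
                 min_intervals = as.integer(min_intervals),
                 seed = as.integer(seed)),
            class = "selection_spec")
}

#' Duration spanned by the analysis window
#'
#' @param sel A [selection_spec()].
#' @param acq An [acquisition_spec()].
#' @return Window span in seconds (`min_intervals * frame_interval`).
#' @export
window_duration <- function(sel = selection_spec(), acq = acquisition_spec()) {
  sel$min_intervals * acq$frame_interval
}

#' @export
print.flow_field_spec <- function(x, ...) {
  cat("Flow field: speed", x$base_speed, "um/s, direction",
      signif(x$base_direction, 3), "rad\n")
  cat("  patch size", x$patch_size, "um, patch direction sd",
      x$patch_direction_sd, "rad, step jitter sd", x$angular_jitter_sd, "rad\n")
  cat("  D =", x$diffusion_coeff, "um^2/s, immobile fraction",
      x$immobile_fraction, "\n")
  invisible(x)
}

#' @export
print.acquisition_spec <- function(x, ...) {
  cat("Acquisition:", x$n_frames, "frames @", x$frame_interval, "s,",
      x$field_width, "x", x$field_height, "um field\n")
  cat("  beads:", if (is.na(x$n_beads)) "300-600 (drawn)" else x$n_beads,
      "| dropout", x$dropout_prob, "| pixel", x$pixel_size, "um\n")
  invisible(x)
}
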