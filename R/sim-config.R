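#' Simulation configuration for the virtual live-cell sample
#'
#' Bundles every knob of the synthetic phase-contrast/fluorescence movie
#' generator. Defaults encode the experimental regime the framework targets:
#' organelle contacts arriving as a Poisson process at one event per 3.1 min
#' with a 20 s duration, divisions at one per 3.2 min, movies at 1 Hz.
#'
#' @param height,width field size in pixels
#' @param pixel_size micrometres per pixel (0.1 um/px: a 1.5 um radius is 15 px)
#' @param frame_rate frames per second
#' @param duration movie length in seconds
#' @param n_mito number of tubular organelles (mitochondria)
#' @param n_spheres number of spherical organelles (droplets/lysosomes)
#' @param contact_rate contact events per minute (default 1/3.1)
#' @param contact_duration contact event duration in seconds (default 20)
#' @param near_miss_rate rate (events/min) of near-miss sphere passes: a
#'   sphere approaches a tube to a 1.2-2.5 px gap for a few seconds without
#'   touching or deforming it. Statically these are nearly indistinguishable
#'   from contacts under the psf; only relative motion separates them, which
#'   is what makes the detection task dynamics-limited. Recorded as negative
#'   event records. Defaults to `contact_rate`.
#' @param division_rate division events per minute (default 1/3.2)
#' @param pre_constriction_window frames of visible constriction before scission
#' @param n_ruffles long-lived curvilinear distractors (membrane folds/ruffles)
#' @param psf_sigma Gaussian blur sd in pixels
#' @param noise_sd additive Gaussian read-noise sd (intensity units)
#' @param halo_gain brightness of the phase-contrast halo ring (relative to
#'   background)
#' @param absorption fractional darkening of organelle interiors in phase
#' @param bleach_rate fluorophore pool fraction lost per fluorescence exposure
#' @param hazard_coeff deaths per dose unit (dose unit = mW/mm2 x ms); the
#'   default places 50% mortality near 5 min of continuous fluorescence at
#'   1 fps, 100 ms, 35 mW/mm2
#' @param phase_dose_factor phototoxic weight of a phase frame relative to a
#'   fluorescence frame (1/500 so the >= 100-fold excess-mortality contrast
#'   emerges with margin)
#' @param tube_halfwidth,sphere_radius organelle sizes in pixels
#' @param deform_px local tube deformation amplitude during a contact
#' @param recoil_px range (min, max) of post-division daughter recoil in px
#' @param background background intensity (camera counts)
#' @param seed master seed; sub-streams are derived per concern
#' @return an object of class `sim_config`
#' @export
sim_config <- function(height = 256L, width = 256L,
                       pixel_size = 0.1, frame_rate = 1,
                       duration = 600,
                       n_mito = 6L, n_spheres = 6L,
                       contact_rate = 1 / 3.1, contact_duration = 20,
                       near_miss_rate = contact_rate,
                       division_rate = 1 / 3.2, pre_constriction_window = 10L,
                       n_ruffles = 3L,
                       psf_sigma = 1.5, noise_sd = 2,
                       halo_gain = 0.6, absorption = 0.35,
                       bleach_rate = 0.002,
                       hazard_coeff = 6.6e-7,
                       phase_dose_factor = 1 / 500,
                       tube_halfwidth = 3, sphere_radius = 4,
                       deform_px = 1.5, recoil_px = c(3, 8),
                       background = 100,
                       seed = 1L) {
  cfg <- list(height = as.integer(height), width = as.integer(width),
              pixel_size = pixel_size, frame_rate = frame_rate,
              duration = duration,
              n_mito = as.integer(n_mito), n_spheres = as.integer(n_spheres),
              contact_rate = contact_rate, contact_duration = contact_duration,
              near_miss_rate = near_miss_rate,
              division_rate = division_rate,
              pre_constriction_window = as.integer(pre_constriction_window),
              n_ruffles = as.integer(n_ruffles),
              psf_sigma = psf_sigma, noise_sd = noise_sd,
              halo_gain = halo_gain, absorption = absorption,
              bleach_rate = bleach_rate, hazard_coeff = hazard_coeff,
              phase_dose_factor = phase_dose_factor,
              tube_halfwidth = tube_halfwidth, sphere_radius = sphere_radius,
              deform_px = deform_px, recoil_px = recoil_px,
              background = background,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  pos <- c("height", "width", "pixel_size", "frame_rate", "duration",
           "contact_duration", "psf_sigma", "tube_halfwidth", "sphere_radius",
           "background")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      stop("sim_config: `", f, "` must be a single strictly positive number")
  }
  nonneg <- c("n_mito", "n_spheres", "contact_rate", "near_miss_rate",
              "division_rate",
              "pre_constriction_window", "n_ruffles", "noise_sd", "halo_gain",
              "absorption", "bleach_rate", "hazard_coeff", "phase_dose_factor",
              "deform_px")
  for (f in nonneg) {
    if (!is.numeric(cfg[[f]]) || any(cfg[[f]] < 0))
      stop("sim_config: `", f, "` must be non-negative")
  }
  if (cfg$contact_duration * cfg$frame_rate < 1)
    stop("sim_config: contact_duration x frame_rate must be >= 1 frame")
  if (length(cfg$recoil_px) != 2L || any(cfg$recoil_px <= 0) ||
      cfg$recoil_px[1] > cfg$recoil_px[2])
    stop("sim_config: recoil_px must be an increasing positive pair")
  # rough capacity check: organelles must fit the field (tube length adapts
  # to small fields; see simulate_sample)
  len_est <- min(60, max(10, min(cfg$height, cfg$width) - 30))
  area_needed <- cfg$n_mito * len_est * 2 * cfg$tube_halfwidth +
    cfg$n_spheres * pi * cfg$sphere_radius^2
  if (area_needed > 0.8 * cfg$height * cfg$width)
    stop("sim_config: organelle counts exceed what fits in the field")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %dx%d px, %.0f frames @ %g Hz, %g um/px\n",
              x$height, x$width, x$duration * x$frame_rate, x$frame_rate,
              x$pixel_size))
  cat(sprintf("  contacts %.3g/min x %gs, divisions %.3g/min, %d mito / %d spheres / %d ruffles, seed %d\n",
              x$contact_rate, x$contact_duration, x$division_rate,
              x$n_mito, x$n_spheres, x$n_ruffles, x$seed))
  invisible(x)
}

n_frames <- function(cfg) as.integer(round(cfg$duration * cfg$frame_rate))

# Channel vocabulary shared across the package.
CHANNELS <- c("phase", "mito_fluo", "ld_fluo", "lyso_fluo", "drp1_fluo",
              "tmre", "sytox", "hoechst")
FLUOR_CHANNELS <- setdiff(CHANNELS, "phase")

#' Exposure specification for one acquisition time point
#'
#' @param modality "surveillance" (phase only) or "correlative" (phase plus at
#'   least one fluorescence channel)
#' @param channels channel tags to expose
#' @param exposure_time per-channel exposure in ms (default 100 ms)
#' @param irradiance fluorescence irradiance in mW/mm2 (default 35, i.e. 10%
#'   laser power)
#' @return an object of class `exposure_spec`
#' @export
exposure_spec <- function(modality = c("surveillance", "correlative"),
                          channels = "phase",
                          exposure_time = 100, irradiance = 35) {
  modality <- match.arg(modality)
  channels <- unique(as.character(channels))
  if (!all(channels %in% CHANNELS))
    stop("exposure_spec: unknown channel tag(s): ",
         paste(setdiff(channels, CHANNELS), collapse = ", "))
  if (exposure_time < 0 || irradiance < 0)
    stop("exposure_spec: exposure_time and irradiance must be non-negative")
  fl <- setdiff(channels, "phase")
  if (modality == "surveillance" && length(fl) > 0)
    stop("exposure_spec: surveillance exposes only phase")
  if (modality == "correlative" && length(fl) < 1)
    stop("exposure_spec: correlative requires >= 1 fluorescence channel")
  if (!"phase" %in% channels) channels <- c("phase", channels)
  structure(list(modality = modality, channels = channels,
                 exposure_time = exposure_time, irradiance = irradiance),
            class = "exposure_spec")
}
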