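# Light-dose accounting and the virtual microscope.
#
# Dose unit: irradiance (mW/mm2) x exposure time (ms), summed over the
# fluorescence channels of an exposure; a phase frame contributes the same
# product weighted by `phase_dose_factor` (default 1/500), so the >= 100-fold
# fluorescence/phase excess-mortality contrast emerges with margin.

#' Create a fresh cell sample (viability + fluorophore state)
#'
#' Death is realized via a single pre-drawn uniform threshold per cell: the
#' cell dies at the first exposure where the accumulated hazard
#' `hazard_coeff x accumulated_dose` exceeds `-log(1 - U)`. Conditionally on
#' the past this reproduces exactly the per-exposure death probability
#' `1 - exp(-hazard_coeff x dose_increment)`, and it makes survival a
#' deterministic function of (config, seed, exposure history).
#'
#' @param config a [sim_config()]
#' @param cell_id integer used to decorrelate cells within one config
#' @return object of class `cell_sample`
#' @export
new_cell_sample <- function(config, cell_id = 1L) {
  u <- with_seed(substream_seed(config$seed, paste0("death-", cell_id)),
                 stats::runif(1))
  pool <- stats::setNames(rep(1, length(FLUOR_CHANNELS)), FLUOR_CHANNELS)
  structure(list(cell_id = cell_id, accumulated_dose = 0,
                 cum_hazard = 0, death_threshold = -log(1 - u),
                 alive = TRUE, death_dose = NA_real_, death_time = NA_real_,
                 fluorophore_pool = pool, dose_ledger = numeric(0),
                 config = config),
            class = "cell_sample")
}

#' Apply one acquisition exposure to a cell sample
#'
#' Accumulates light dose (fluorescence channels at full weight, phase at
#' `phase_dose_factor`), realizes the per-exposure death probability
#' `1 - exp(-hazard_coeff x dose_increment)`, and bleaches the fluorophore
#' pool of each exposed fluorescence channel by `(1 - bleach_rate)`.
#' Dose keeps accumulating after death; `alive = FALSE` never reverts.
#'
#' @param sample a [new_cell_sample()]
#' @param spec an [exposure_spec()]
#' @param time acquisition time in seconds (recorded as death time if the
#'   cell dies during this exposure)
#' @return the updated `cell_sample`
#' @export
apply_exposure <- function(sample, spec, time = NA_real_) {
  stopifnot(inherits(sample, "cell_sample"), inherits(spec, "exposure_spec"))
  if (spec$exposure_time < 0 || spec$irradiance < 0)
    stop("apply_exposure: negative exposure or irradiance")
  cfg <- sample$config
  fl <- intersect(spec$channels, FLUOR_CHANNELS)
  inc <- length(fl) * spec$irradiance * spec$exposure_time
  if ("phase" %in% spec$channels)
    inc <- inc + cfg$phase_dose_factor * spec$irradiance * spec$exposure_time
  sample$accumulated_dose <- sample$accumulated_dose + inc
  sample$dose_ledger <- c(sample$dose_ledger, inc)
  sample$cum_hazard <- sample$cum_hazard + cfg$hazard_coeff * inc
  if (sample$alive && sample$cum_hazard >= sample$death_threshold) {
    sample$alive <- FALSE
    sample$death_dose <- sample$accumulated_dose
    sample$death_time <- time
  }
  for (ch in fl)
    sample$fluorophore_pool[ch] <- sample$fluorophore_pool[ch] * (1 - cfg$bleach_rate)
  sample
}

#' A virtual microscope over a simulated trajectory
#'
#' Wraps a trajectory and a live `cell_sample` into an acquisition interface
#' the controller can drive: each call renders the requested channels at one
#' time point and applies exactly one exposure.
#'
#' @param traj an [simulate_sample()] trajectory
#' @param cell_id forwarded to [new_cell_sample()]
#' @return object of class `virtual_microscope` (an environment)
#' @export
virtual_microscope <- function(traj, cell_id = 1L) {
  stopifnot(inherits(traj, "eda_trajectory"))
  vm <- new.env(parent = emptyenv())
  vm$traj <- traj
  vm$config <- traj$config
  vm$sample <- new_cell_sample(traj$config, cell_id)
  class(vm) <- "virtual_microscope"
  vm
}

#' Acquire one time point on the virtual microscope
#'
#' @param vm a [virtual_microscope()]
#' @param t 0-based frame index
#' @param spec an [exposure_spec()]
#' @param render if FALSE, skip pixel rendering (dose/viability bookkeeping
#'   only; frames are returned as NULL). Used by oracle-detector control runs
#'   where no component consumes pixels.
#' @return list with `frames` (named by channel), `t`, `time` (s), and the
#'   updated `sample` snapshot
#' @export
vm_acquire <- function(vm, t, spec, render = TRUE) {
  stopifnot(inherits(vm, "virtual_microscope"), inherits(spec, "exposure_spec"))
  if (t >= vm$traj$n_frames || t < 0) {
    cond <- structure(class = c("eda_end_of_acquisition", "error", "condition"),
                      list(message = "acquisition past trajectory end",
                           call = sys.call()))
    stop(cond)
  }
  time_s <- t / vm$config$frame_rate
  vm$sample <- apply_exposure(vm$sample, spec, time = time_s)
  frames <- NULL
  if (render) {
    st <- state_at(vm$traj, t)
    frames <- lapply(stats::setNames(spec$channels, spec$channels), function(ch) {
      if (ch == "phase") render_phase_frame(st, vm$config)
      else render_fluorescence_frame(st, ch, vm$config, traj = vm$traj,
                                     fluorophore_pool = vm$sample$fluorophore_pool[ch],
                                     sample_dead = !vm$sample$alive)
    })
  }
  list(t = as.integer(t), time = time_s, frames = frames, sample = vm$sample)
}

#' Simulate a phototoxicity cohort (no imaging pixels)
#'
#' Exposes `n_cells` independent cells to `n_frames_total` repeated exposures
#' of the given spec and records death times — the survival ground truth used
#' by the downstream survival pipeline.
#'
#' @param config a [sim_config()]
#' @param spec an [exposure_spec()]
#' @param n_cells cohort size
#' @param n_frames_total exposures per cell
#' @param replicate replicate id (decorrelates cells across replicates)
#' @param condition condition label stored in the table
#' @return a `survival table` data.frame (`cell_id, condition, death_time,
#'   censored, replicate`), death_time in seconds (frame / frame_rate)
#' @export
simulate_death_cohort <- function(config, spec, n_cells = 500L,
                                  n_frames_total = n_frames(config),
                                  replicate = 1L,
                                  condition = spec$modality) {
  out <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    s <- new_cell_sample(config, cell_id = i + 100000L * replicate)
    death <- NA_real_
    # closed-form inversion: constant per-frame hazard, death at first frame
    # where cumulative hazard crosses the cell's threshold
    fl <- intersect(spec$channels, FLUOR_CHANNELS)
    inc <- length(fl) * spec$irradiance * spec$exposure_time
    if ("phase" %in% spec$channels)
      inc <- inc + config$phase_dose_factor * spec$irradiance * spec$exposure_time
    hz <- config$hazard_coeff * inc
    if (hz > 0) {
      k <- ceiling(s$death_threshold / hz)          # frame at which it dies
      if (k <= n_frames_total) death <- k / config$frame_rate
    }
    out[[i]] <- data.frame(cell_id = s$cell_id, condition = condition,
                           death_time = death, censored = is.na(death),
                           replicate = replicate)
  }
  tab <- do.call(rbind, out)
  tab$death_time[tab$censored] <- n_frames_total / config$frame_rate
  tab
}
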