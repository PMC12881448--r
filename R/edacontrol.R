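# Two-state acquisition control: analyzer -> interpreter -> scheduler,
# run closed-loop against the virtual microscope.

#' Controller configuration
#'
#' @param score_threshold_up score above which surveillance switches to
#'   correlative imaging
#' @param score_threshold_down score below which (after the minimum burst) the
#'   controller returns to surveillance; defaults to `score_threshold_up`
#'   (no hysteresis)
#' @param min_correlative_frames minimum correlative frames per trigger
#' @param buffer_length analyzer frame buffer (= detector `n_time_points`)
#' @param frame_rate acquisition rate in Hz
#' @param correlative_channels fluorescence channels added in the correlative
#'   state (phase is always acquired)
#' @param exposure_time,irradiance forwarded to [exposure_spec()]
#' @param retrigger "extend" (default): the burst persists while scores stay
#'   at or above `score_threshold_down` and the frame counter runs from the
#'   first trigger; "reset": a new super-threshold score resets the counter
#' @return object of class `controller_config`
#' @export
controller_config <- function(score_threshold_up = 0.8,
                              score_threshold_down = score_threshold_up,
                              min_correlative_frames = 20L,
                              buffer_length = 3L,
                              frame_rate = 1,
                              correlative_channels = "mito_fluo",
                              exposure_time = 100, irradiance = 35,
                              retrigger = c("extend", "reset")) {
  retrigger <- match.arg(retrigger)
  stopifnot(score_threshold_up >= 0, score_threshold_up <= 1,
            score_threshold_down >= 0,
            score_threshold_down <= score_threshold_up,
            min_correlative_frames >= 1, buffer_length >= 1, frame_rate > 0)
  stopifnot(all(correlative_channels %in% FLUOR_CHANNELS))
  structure(list(score_threshold_up = score_threshold_up,
                 score_threshold_down = score_threshold_down,
                 min_correlative_frames = as.integer(min_correlative_frames),
                 buffer_length = as.integer(buffer_length),
                 frame_rate = frame_rate,
                 correlative_channels = correlative_channels,
                 exposure_time = exposure_time, irradiance = irradiance,
                 retrigger = retrigger),
            class = "controller_config")
}

#' Initial acquisition state
#' @param config a [controller_config()]
#' @return object of class `acquisition_state` (starts in SURVEILLANCE)
#' @export
acquisition_state <- function(config) {
  structure(list(mode = "SURVEILLANCE", frames_since_trigger = 0L,
                 frame_buffer = list(), buffer_length = config$buffer_length),
            class = "acquisition_state")
}

# ---- reference detectors (no pixels needed) --------------------------------

#' Oracle detector emitting the ground-truth event indicator
#'
#' Returns, for frame `t`, a score map with a unit-peak Gaussian at the center
#' of every positive event whose span contains `t`. Used for controller and
#' duty-cycle analyses that isolate the acquisition logic from detection
#' quality.
#'
#' @param events event table
#' @param shape c(height, width)
#' @param sigma Gaussian sd in pixels
#' @return object of class `c("oracle_detector", "eda_detector")`
#' @export
oracle_detector <- function(events, shape, sigma = 4) {
  structure(list(events = events[events$polarity == "positive", , drop = FALSE],
                 shape = as.integer(shape), sigma = sigma,
                 needs_pixels = FALSE),
            class = c("oracle_detector", "eda_detector"))
}

#' Zero detector (never triggers)
#' @param shape c(height, width)
#' @return detector emitting all-zero score maps
#' @export
zero_detector <- function(shape) {
  structure(list(shape = as.integer(shape), needs_pixels = FALSE),
            class = c("zero_detector", "eda_detector"))
}

#' Run detector inference on one buffered window
#'
#' @param detector an `eda_detector`
#' @param window list of frames (oldest first) or 3D array \[H, W, T\]
#' @param t 0-based index of the newest frame (used by pixel-free detectors)
#' @return score matrix for the newest frame
#' @export
eda_infer <- function(detector, window, t = NULL) UseMethod("eda_infer")

#' @export
eda_infer.oracle_detector <- function(detector, window, t = NULL) {
  stopifnot(!is.null(t))
  ev <- detector$events
  ev <- ev[ev$t_start <= t & ev$t_end >= t, , drop = FALSE]
  m <- matrix(0, detector$shape[1], detector$shape[2])
  for (i in seq_len(nrow(ev))) {
    m <- pmax(m, gaussian_spot(detector$shape, ev$x[i], ev$y[i], detector$sigma))
  }
  m
}

#' @export
eda_infer.zero_detector <- function(detector, window, t = NULL)
  matrix(0, detector$shape[1], detector$shape[2])

#' Reset a detector's internal state
#' @param detector an `eda_detector`
#' @return the reset detector
#' @export
reset_state <- function(detector) UseMethod("reset_state")

#' @export
reset_state.default <- function(detector) detector

# ---- the automaton ---------------------------------------------------------

#' Analyzer: buffer the newest phase frame and run inference
#'
#' Pushes the frame into the rolling buffer (evicting the oldest), left-pads
#' by repeating the first frame until the buffer is full, and returns the
#' score map for the newest frame. Pixel frames are percentile-normalized
#' before inference.
#'
#' @param state an [acquisition_state()]
#' @param new_phase_frame phase frame matrix (may be NULL for pixel-free
#'   detectors)
#' @param detector an `eda_detector`
#' @param t 0-based frame index
#' @return list(`score_map`, `state`)
#' @export
analyzer_step <- function(state, new_phase_frame, detector, t) {
  needs_px <- isTRUE(detector$needs_pixels) || is.null(detector$needs_pixels)
  if (needs_px) {
    if (is.null(new_phase_frame))
      stop("analyzer_step: detector requires pixel frames")
    if (length(state$frame_buffer) &&
        !identical(dim(new_phase_frame), dim(state$frame_buffer[[1]])))
      stop("analyzer_step: frame shape mismatch")
    state$frame_buffer <- c(state$frame_buffer,
                            list(normalize_frame(new_phase_frame)))
    if (length(state$frame_buffer) > state$buffer_length)
      state$frame_buffer <- state$frame_buffer[-1]
    buf <- state$frame_buffer
    while (length(buf) < state$buffer_length) buf <- c(buf[1], buf)
    window <- array(unlist(buf), c(dim(buf[[1]]), length(buf)))
  } else {
    window <- NULL
  }
  list(score_map = eda_infer(detector, window, t = t), state = state)
}

#' Interpreter: memory + thresholding
#'
#' In SURVEILLANCE, a score above `score_threshold_up` switches to
#' CORRELATIVE and starts the burst counter. In CORRELATIVE the counter
#' increments each frame; once it reaches `min_correlative_frames` and the
#' score has dropped below `score_threshold_down`, the controller returns to
#' surveillance — so a sustained event extends the burst for exactly its
#' duration. With `retrigger = "reset"`, any new super-threshold score also
#' resets the counter.
#'
#' @param score_map score matrix (its global max drives the decision)
#' @param state an [acquisition_state()]
#' @param config a [controller_config()]
#' @return list(`decision` in stay/to_correlative/to_surveillance, `state`)
#' @export
interpret <- function(score_map, state, config) {
  s <- max(score_map)
  decision <- "stay"
  if (state$mode == "SURVEILLANCE") {
    if (s >= config$score_threshold_up) {    # inclusive: threshold 0 gives the
                                             # continuous-fluorescence limit
      decision <- "to_correlative"
      state$mode <- "CORRELATIVE"
      state$frames_since_trigger <- 0L
    }
  } else {
    state$frames_since_trigger <- state$frames_since_trigger + 1L
    if (config$retrigger == "reset" && s >= config$score_threshold_up)
      state$frames_since_trigger <- 0L
    if (state$frames_since_trigger >= config$min_correlative_frames &&
        s < config$score_threshold_down) {
      decision <- "to_surveillance"
      state$mode <- "SURVEILLANCE"
      state$frames_since_trigger <- 0L
    }
  }
  list(decision = decision, state = state)
}

#' Scheduler: exposure spec for the next time point
#'
#' Phase is acquired in both states; the correlative state adds the
#' configured fluorescence channels. Timestamps advance by `1/frame_rate`.
#'
#' @param decision output of [interpret()] (unused beyond the updated state;
#'   kept for the analyzer-interpreter-scheduler contract)
#' @param state the updated [acquisition_state()]
#' @param config a [controller_config()]
#' @return an [exposure_spec()]
#' @export
scheduler_next <- function(decision, state, config) {
  if (state$mode == "CORRELATIVE") {
    exposure_spec("correlative", c("phase", config$correlative_channels),
                  config$exposure_time, config$irradiance)
  } else {
    exposure_spec("surveillance", "phase",
                  config$exposure_time, config$irradiance)
  }
}

#' Run a closed-loop event-driven acquisition
#'
#' Per frame: acquire per the scheduler, analyze the phase frame, interpret
#' the score, and schedule the next frame's modality (one-frame actuation
#' latency). Returns the full audit log.
#'
#' @param traj an [simulate_sample()] trajectory
#' @param detector an `eda_detector` (reset before the run)
#' @param controller a [controller_config()]
#' @param render render pixel frames (FALSE is valid only for pixel-free
#'   detectors; identical dose/mode bookkeeping, much faster)
#' @param keep_frames retain acquired frames in the result (memory-heavy)
#' @return object of class `acquisition_log`: data.frame (`t, mode, channels,
#'   max_score, dose_increment, cumulative_dose`) with the final `cell_sample`
#'   and config attached as attributes
#' @export
run_eda <- function(traj, detector, controller, render = TRUE,
                    keep_frames = FALSE) {
  stopifnot(inherits(traj, "eda_trajectory"),
            inherits(controller, "controller_config"))
  detector <- reset_state(detector)
  vm <- virtual_microscope(traj)
  state <- acquisition_state(controller)
  TT <- traj$n_frames
  rows <- vector("list", TT)
  movies <- if (keep_frames) list() else NULL
  prev_dose <- 0
  for (t in 0:(TT - 1L)) {
    spec <- scheduler_next("stay", state, controller)
    acq <- vm_acquire(vm, t, spec, render = render)
    if (keep_frames) movies[[length(movies) + 1L]] <- acq$frames
    an <- analyzer_step(state, acq$frames[["phase"]], detector, t)
    state <- an$state
    it <- interpret(an$score_map, state, controller)
    state <- it$state
    dose <- acq$sample$accumulated_dose
    rows[[t + 1L]] <- data.frame(
      t = t, mode = spec$modality,
      channels = paste(spec$channels, collapse = "+"),
      max_score = max(an$score_map),
      dose_increment = dose - prev_dose, cumulative_dose = dose)
    prev_dose <- dose
  }
  log <- do.call(rbind, rows)
  attr(log, "sample") <- vm$sample
  attr(log, "controller") <- controller
  attr(log, "frames") <- movies
  class(log) <- c("acquisition_log", class(log))
  log
}

#' Capture statistics of an acquisition log
#'
#' @param log an [run_eda()] log
#' @param events the positive ground-truth events of the same run
#' @return list: `duty_cycle` (correlative frames / total frames),
#'   `events_captured_fraction`, `fluorescence_frames_per_captured_event`
#'   (total correlative frames / captured events), `dose_per_event`, plus raw
#'   counts and the per-event burst frame counts
#' @export
capture_stats <- function(log, events) {
  corr <- log$mode == "correlative"
  n_corr <- sum(corr)
  pos <- events[events$polarity == "positive", , drop = FALSE]
  n_pos <- nrow(pos)
  # maximal correlative runs (bursts)
  r <- rle(corr)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  bursts <- data.frame(t0 = log$t[starts[r$values]],
                       t1 = log$t[ends[r$values]])
  captured <- logical(n_pos); per_event_frames <- integer(n_pos)
  for (i in seq_len(n_pos)) {
    ov <- which(bursts$t1 >= pos$t_start[i] & bursts$t0 <= pos$t_end[i])
    captured[i] <- length(ov) > 0
    per_event_frames[i] <- sum(bursts$t1[ov] - bursts$t0[ov] + 1L)
  }
  n_cap <- sum(captured)
  list(duty_cycle = n_corr / nrow(log),
       events_captured_fraction = if (n_pos) n_cap / n_pos else NA_real_,
       fluorescence_frames_per_captured_event =
         if (n_cap) n_corr / n_cap else NA_real_,
       dose_per_event = if (n_cap) max(log$cumulative_dose) / n_cap else NA_real_,
       n_correlative_frames = n_corr, n_frames = nrow(log),
       n_events = n_pos, n_captured = n_cap,
       per_event_frames = per_event_frames)
}
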