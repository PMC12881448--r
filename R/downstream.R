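# Downstream quantification: death scoring, survival curves + decay fits,
# duty-cycle arithmetic, image quality, DRP1 tip ratios, TMRE tracking.

#' Per-cell SYTOX/Hoechst death scoring
#'
#' Nuclei are segmented from the Hoechst channel (global Otsu + size filter);
#' each channel is normalized within a local window of twice the nucleus
#' bounding box (0 at the window median — the background level — and 1 at the
#' window maximum), and the per-nucleus ratio of normalized SYTOX to
#' normalized Hoechst intensity is compared to the 0.5 onset cutoff.
#'
#' @param sytox_frame,hoechst_frame registered matrices of the two channels
#' @param cutoff death-onset ratio cutoff
#' @param min_size minimum nucleus size in pixels
#' @return data.frame (`nucleus_id, x, y, ratio, dead`); zero rows (with a
#'   warning) if no nuclei are found
#' @export
nucleus_death_ratio <- function(sytox_frame, hoechst_frame, cutoff = 0.5,
                                min_size = 50L) {
  stopifnot(identical(dim(sytox_frame), dim(hoechst_frame)))
  thr <- otsu_threshold(hoechst_frame)
  mask <- hoechst_frame > thr
  lab <- label_components(mask)
  n <- max(lab, 0L)
  out <- list()
  H <- nrow(mask); W <- ncol(mask)
  for (i in seq_len(n)) {
    px <- which(lab == i)
    if (length(px) < min_size) next
    ri <- (px - 1L) %% H + 1L; ci <- (px - 1L) %/% H + 1L
    # local window: bounding box scaled 2x about its center
    r0 <- min(ri); r1 <- max(ri); c0 <- min(ci); c1 <- max(ci)
    hh <- r1 - r0 + 1L; ww <- c1 - c0 + 1L
    wr <- max(1L, r0 - hh %/% 2L):min(H, r1 + hh %/% 2L)
    wc <- max(1L, c0 - ww %/% 2L):min(W, c1 + ww %/% 2L)
    # normalized nucleus intensity within the local window: 0 at the window
    # background level (median), 1 at the window maximum; a channel with no
    # local signal therefore normalizes to ~0 rather than to mid-noise
    norm_mean <- function(ch) {
      win <- ch[wr, wc]
      lo <- stats::median(win); hi <- max(win)
      if (hi - lo <= 0) return(0)
      clamp((mean(ch[px]) - lo) / (hi - lo), 0, 1)
    }
    sy <- norm_mean(sytox_frame)
    ho <- norm_mean(hoechst_frame)
    ratio <- sy / max(ho, .Machine$double.eps)
    out[[length(out) + 1L]] <- data.frame(
      nucleus_id = i, x = mean(ci) - 1, y = mean(ri) - 1,
      ratio = ratio, dead = ratio >= cutoff)
  }
  if (!length(out)) {
    warning("nucleus_death_ratio: no nuclei found")
    return(data.frame(nucleus_id = integer(0), x = numeric(0), y = numeric(0),
                      ratio = numeric(0), dead = logical(0)))
  }
  res <- do.call(rbind, out)
  res$nucleus_id <- seq_len(nrow(res))
  res
}

#' Survival curve (mean +/- SD across replicates)
#'
#' @param table survival table (`cell_id, condition, death_time, censored,
#'   replicate`)
#' @param time_grid times (s) at which to evaluate the survival fraction
#' @return data.frame (`time, mean, sd`) plus per-replicate columns
#' @export
survival_curve <- function(table, time_grid) {
  stopifnot(nrow(table) > 0)
  reps <- sort(unique(table$replicate))
  mat <- sapply(reps, function(r) {
    tb <- table[table$replicate == r, ]
    sapply(time_grid, function(tt)
      mean(tb$censored | tb$death_time > tt))
  })
  mat <- matrix(mat, nrow = length(time_grid))
  data.frame(time = time_grid,
             mean = rowMeans(mat),
             sd = if (ncol(mat) > 1) apply(mat, 1, stats::sd) else 0)
}

#' Fit an exponential decay to a survival curve
#'
#' Least-squares fit of `S(t) = exp(-k t)`; `half_life = ln 2 / k`.
#' A non-decaying curve yields `k` clipped at a small positive epsilon and is
#' flagged.
#'
#' @param curve data.frame with `time` and `mean` (survival fraction)
#' @param condition label stored in the fit
#' @return object of class `decay_fit`: list(`k`, `half_life`, `condition`,
#'   `goodness` = residual sd, `clipped`)
#' @export
fit_decay <- function(curve, condition = NA_character_) {
  stopifnot(all(curve$mean >= 0), all(curve$mean <= 1.000001))
  t <- curve$time; s <- pmin(curve$mean, 1)
  eps <- 1e-12
  # log-linear start, then Gauss-Newton via nls on the original scale
  ok <- s > 0
  k0 <- if (sum(ok) >= 2) {
    max(eps, -stats::coef(stats::lm(log(s[ok]) ~ t[ok] - 1))[[1]])
  } else eps
  k <- tryCatch({
    # warnOnly + suppress: a zero-residual curve trips nls's convergence
    # test even though the log-linear start is already exact
    fit <- suppressWarnings(
      stats::nls(s ~ exp(-k * t), start = list(k = k0),
                 control = stats::nls.control(warnOnly = TRUE)))
    max(eps, stats::coef(fit)[["k"]])
  }, error = function(e) k0)
  clipped <- k <= eps
  resid <- s - exp(-k * t)
  structure(list(k = k, half_life = log(2) / k, condition = condition,
                 goodness = stats::sd(resid), clipped = clipped),
            class = "decay_fit")
}

#' Excess mortality of condition a relative to condition b at time t
#'
#' `(1 - S_a(t)) / (1 - S_b(t))` from two [fit_decay()] results.
#'
#' @param fit_a,fit_b `decay_fit` objects
#' @param t time in seconds
#' @return fold ratio
#' @export
excess_mortality <- function(fit_a, fit_b, t) {
  (1 - exp(-fit_a$k * t)) / (1 - exp(-fit_b$k * t))
}

#' Duty-cycle arithmetic: frames per event under continuous imaging
#'
#' With one event per `event_interval` minutes and imaging at `frame_rate`,
#' continuous fluorescence spends `event_interval x 60 x frame_rate` frames
#' per event (rounded to the nearest integer).
#'
#' @param model list/`duty_cycle_model` with `event_interval` (min),
#'   `event_duration` (s), `frame_rate` (Hz)
#' @return integer frame count
#' @export
continuous_frames_per_event <- function(model) {
  stopifnot(model$event_interval > 0, model$frame_rate > 0)
  as.integer(round(model$event_interval * 60 * model$frame_rate))
}

#' @rdname continuous_frames_per_event
#' @param event_interval event spacing in minutes
#' @param event_duration event duration in seconds
#' @param frame_rate imaging rate in Hz
#' @export
duty_cycle_model <- function(event_interval, event_duration, frame_rate) {
  stopifnot(event_interval > 0, event_duration > 0, frame_rate > 0)
  structure(list(event_interval = event_interval,
                 event_duration = event_duration, frame_rate = frame_rate),
            class = "duty_cycle_model")
}

#' Fold reduction in fluorescence frames from event-driven triggering
#'
#' @param model a [duty_cycle_model()]
#' @param triggered_frames fluorescence frames actually spent per event
#' @return `continuous_frames_per_event(model) / triggered_frames`
#' @export
fold_reduction <- function(model, triggered_frames) {
  if (triggered_frames == 0) stop("fold_reduction: triggered_frames is zero")
  continuous_frames_per_event(model) / triggered_frames
}

#' Image-quality metrics from marked regions
#'
#' @param mito_regions vector of intensities inside mitochondria
#' @param background_regions vector of background intensities
#' @return list(`snr` = mean(mito)/sd(background), `intensity_ratio`,
#'   `contrast` = (m - b)/(m + b))
#' @export
image_quality <- function(mito_regions, background_regions) {
  sdb <- stats::sd(background_regions)
  if (!is.finite(sdb) || sdb == 0)
    stop("image_quality: zero-variance background")
  m <- mean(mito_regions); b <- mean(background_regions)
  list(snr = m / sdb, intensity_ratio = m / b, contrast = (m - b) / (m + b))
}

#' DRP1 daughter-tip intensity ratio
#'
#' Integrated intensity of each 3x3 ROI minus 9x the camera offset (floored
#' at 0); the ratio divides the higher intensity by the lower one.
#'
#' @param fluo_frame fluorescence matrix
#' @param tips list of two centers `c(x, y)` (0-based) of the daughter tips
#' @param camera_offset per-pixel camera offset (intensity units)
#' @return list(`ratio` >= 1 — Inf (flagged) if the lower intensity is 0 —,
#'   `intensities`, `flagged`)
#' @export
drp1_tip_ratio <- function(fluo_frame, tips, camera_offset = 100) {
  stopifnot(length(tips) == 2L)
  H <- nrow(fluo_frame); W <- ncol(fluo_frame)
  roi_sum <- function(center) {
    cx <- round(center[1]) + 1L; cy <- round(center[2]) + 1L
    if (cx < 2L || cy < 2L || cx > W - 1L || cy > H - 1L)
      stop("drp1_tip_ratio: 3x3 ROI outside image")
    sum(fluo_frame[(cy - 1L):(cy + 1L), (cx - 1L):(cx + 1L)])
  }
  if (max(abs(round(tips[[1]]) - round(tips[[2]]))) < 3)
    stop("drp1_tip_ratio: ROIs overlap")
  ii <- vapply(tips, function(tp) max(0, roi_sum(tp) - 9 * camera_offset),
               numeric(1))
  lo <- min(ii); hi <- max(ii)
  if (lo == 0) return(list(ratio = Inf, intensities = ii, flagged = TRUE))
  list(ratio = hi / lo, intensities = ii, flagged = FALSE)
}

# ---- TMRE tracking ---------------------------------------------------------

segment_tmre <- function(frame, min_size = 10L) {
  thr <- li_threshold(frame)
  mask <- frame > thr
  lab <- label_components(mask)
  if (max(lab, 0L) == 0L) return(lab)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size)
  lab[!(lab %in% keep)] <- 0L
  lab[lab > 0] <- match(lab[lab > 0], keep)
  lab
}

#' Track mitochondria in a TMRE movie and classify by event proximity
#'
#' Mitochondria are segmented per frame by minimum cross-entropy
#' thresholding, tracked frame-to-frame by maximal mask overlap, and each
#' track is classified as contact-positive iff its centroid at the event
#' frame lies within `radius_um` of the event center. Per-track mean
#' intensity series support flicker analysis via [detect_flicker()].
#'
#' @param tmre_movie list of TMRE matrices (frames)
#' @param event_center c(x, y) in 0-based pixels
#' @param event_t 0-based frame of the event detection
#' @param radius_um classification radius in micrometres (default 1.5)
#' @param pixel_size micrometres per pixel
#' @return data.frame per track (`track_id, contact_positive, dist_px,
#'   x, y`) with the intensity series in `attr(,"intensity")` (tracks x
#'   frames matrix, NA where absent)
#' @export
tmre_track_classify <- function(tmre_movie, event_center, event_t,
                                radius_um = 1.5, pixel_size = 0.1) {
  TT <- length(tmre_movie)
  stopifnot(event_t >= 0, event_t < TT)
  labs <- lapply(tmre_movie, segment_tmre)
  # frame-to-frame identity by maximal overlap with previous frame's tracks
  n0 <- max(labs[[1]], 0L)
  track_of <- vector("list", TT)          # object label -> track id, per frame
  track_of[[1]] <- seq_len(n0)
  next_track <- n0
  for (f in 2:TT) {
    prev <- labs[[f - 1L]]; cur <- labs[[f]]
    ncur <- max(cur, 0L)
    ids <- integer(ncur)
    for (o in seq_len(ncur)) {
      px <- cur == o
      ov <- prev[px]
      ov <- ov[ov > 0]
      if (length(ov)) {
        best <- as.integer(names(which.max(table(ov))))
        ids[o] <- track_of[[f - 1L]][best]
      } else {
        next_track <- next_track + 1L
        ids[o] <- next_track
      }
    }
    # two objects claiming one track: keep the larger overlap, fork the other
    if (anyDuplicated(ids[ids > 0])) {
      for (d in unique(ids[duplicated(ids)])) {
        claimants <- which(ids == d)
        sizes <- vapply(claimants, function(o) sum(cur == o), numeric(1))
        for (o in claimants[-which.max(sizes)]) {
          next_track <- next_track + 1L
          ids[o] <- next_track
        }
      }
    }
    track_of[[f]] <- ids
  }
  n_tracks <- next_track
  if (n_tracks == 0L) {
    warning("tmre_track_classify: no objects found")
    return(data.frame(track_id = integer(0), contact_positive = logical(0),
                      dist_px = numeric(0), x = numeric(0), y = numeric(0)))
  }
  intensity <- matrix(NA_real_, n_tracks, TT)
  cx <- matrix(NA_real_, n_tracks, TT); cy <- matrix(NA_real_, n_tracks, TT)
  for (f in seq_len(TT)) {
    lab <- labs[[f]]; H <- nrow(lab)
    for (o in seq_len(max(lab, 0L))) {
      px <- which(lab == o)
      tr <- track_of[[f]][o]
      intensity[tr, f] <- mean(tmre_movie[[f]][px])
      cy[tr, f] <- mean((px - 1L) %% H)
      cx[tr, f] <- mean((px - 1L) %/% H)
    }
  }
  fe <- event_t + 1L
  present <- !is.na(cx[, fe])
  if (!any(present)) {
    warning("tmre_track_classify: no objects at the event frame")
    return(data.frame(track_id = integer(0), contact_positive = logical(0),
                      dist_px = numeric(0), x = numeric(0), y = numeric(0)))
  }
  radius_px <- radius_um / pixel_size
  res <- data.frame(track_id = which(present))
  res$x <- cx[present, fe]; res$y <- cy[present, fe]
  res$dist_px <- sqrt((res$x - event_center[1])^2 + (res$y - event_center[2])^2)
  res$contact_positive <- res$dist_px <= radius_px
  attr(res, "intensity") <- intensity
  res
}

#' Detect flicker dips in a track intensity series
#'
#' A flicker is a run of frames more than `n_sd` standard deviations below
#' the track's rolling-median baseline.
#'
#' @param series numeric intensity series (NAs allowed)
#' @param n_sd dip depth in baseline SDs
#' @param window rolling baseline window (frames)
#' @return data.frame (`f0, f1, duration`) of dips (0-based frames)
#' @export
detect_flicker <- function(series, n_sd = 3, window = 30L) {
  ok <- !is.na(series)
  baseline <- stats::runmed(ifelse(ok, series, stats::median(series, na.rm = TRUE)),
                            k = min(window %/% 2L * 2L + 1L,
                                    length(series) %/% 2L * 2L + 1L))
  resid <- series - baseline
  s <- stats::mad(resid[ok], constant = 1.4826)
  if (!is.finite(s) || s == 0) s <- stats::sd(resid[ok])
  dip <- ok & resid < -n_sd * s
  r <- rle(as.logical(dip))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  data.frame(f0 = starts[idx] - 1L, f1 = ends[idx] - 1L,
             duration = r$lengths[idx])
}
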