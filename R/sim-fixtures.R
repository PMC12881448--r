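# Desk-scale training fixtures: small cropped movies with one scripted event
# class, rendered on the fly (64x64 by default).

#' Generate small event-crop movies for detector training
#'
#' Repeatedly simulates small fields (defaults: 64x64 px, ~1 Hz, short
#' movies with a couple of tubes and spheres) until `n_events` positive
#' events of the requested class have been realized. Movies without positive
#' events are kept occasionally (1 in 4) as pure-negative material.
#'
#' @param type "contact" or "division"
#' @param n_events positive events to accumulate
#' @param seed master seed
#' @param size crop side in pixels
#' @param duration movie length in seconds
#' @param with_ruffles include curvilinear distractors (default TRUE for
#'   divisions — the false-positive bait of interest — and FALSE for contacts)
#' @param ... overrides forwarded to [sim_config()]
#' @return list of `list(movie, events, traj)` entries
#' @export
make_event_movies <- function(type = c("contact", "division"), n_events = 20L,
                              seed = 1L, size = 64L, duration = 40,
                              with_ruffles = (type == "division"), ...) {
  type <- match.arg(type)
  got <- 0L; out <- list(); i <- 0L; kept_neg <- 0L
  base <- list(height = size, width = size, duration = duration,
               n_mito = 2L, n_spheres = 2L,
               n_ruffles = if (isTRUE(with_ruffles)) 2L else 0L,
               contact_rate = if (type == "contact") 1.5 else 0,
               division_rate = if (type == "division") 1.5 else 0,
               ...)
  while (got < n_events) {
    i <- i + 1L
    if (i > 40L * n_events) stop("make_event_movies: event yield too low")
    cfg <- do.call(sim_config, c(base, list(seed = substream_seed(seed, paste0("movie-", i)))))
    traj <- simulate_sample(cfg)
    npos <- sum(traj$events$polarity == "positive")
    if (npos == 0L && (kept_neg >= length(out) %/% 4L)) next
    TT <- traj$n_frames
    mv <- array(0, c(cfg$height, cfg$width, TT))
    for (t in 0:(TT - 1L))
      mv[, , t + 1L] <- render_phase_frame(state_at(traj, t), cfg)
    out[[length(out) + 1L]] <- list(movie = mv, events = traj$events,
                                    traj = traj, config = cfg)
    got <- got + npos
    if (npos == 0L) kept_neg <- kept_neg + 1L
  }
  out
}

#' Build a merged training set from event-crop movies
#'
#' @param movies result of [make_event_movies()]
#' @param n_time_points window length
#' @param sigma_label label Gaussian sd
#' @param windows_per_event windows per event
#' @return a `training_set` plus `attr(,"events")` (list of per-movie event
#'   tables) for evaluation
#' @export
make_crop_dataset <- function(movies, n_time_points = 3L, sigma_label = 4,
                              windows_per_event = 5L) {
  sets <- lapply(movies, function(m)
    make_training_set(m$movie, m$events, n_time_points, sigma_label,
                      windows_per_event))
  keep <- which(vapply(sets, function(s) dim(s$x)[3] > 0, logical(1)))
  ts <- merge_training_sets(sets[keep])
  ev <- do.call(rbind, lapply(seq_along(keep), function(k) {
    e <- movies[[keep[k]]]$events
    e$event_id <- e$event_id + k * 100000L      # match merge_training_sets
    e
  }))
  attr(ts, "events") <- ev
  attr(ts, "movies") <- keep
  ts
}
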