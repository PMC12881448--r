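# Seeded architecture-comparison experiments: the desk-scale replication of
# the detector grid (time points x loss x statefulness), used by the
# acceptance suite and reusable from the CLI.

#' Train one detector configuration on a prepared training set
#'
#' @param training_set a `training_set` (with `attr(,"events")`)
#' @param n_time_points,stateful,loss,seed forwarded to [detector_config()]
#' @param epochs,learning_rate,batch_size optimizer settings
#' @param beta F_beta weight for threshold optimization
#' @return list(`detector`, `scores`, `threshold`)
#' @export
train_and_score <- function(training_set, n_time_points, stateful = FALSE,
                            loss = "soft_focal", seed = 1L, epochs = 4L,
                            learning_rate = 1.5e-3, batch_size = 4L,
                            beta = 0.1) {
  cfg <- detector_config(n_time_points = n_time_points, stateful = stateful,
                         loss = loss, seed = seed, epochs = epochs,
                         learning_rate = learning_rate,
                         batch_size = batch_size)
  det <- train_detector(build_detector(cfg), training_set)
  opt <- evaluate_on_validation(det, training_set, attr(training_set, "events"),
                                beta = beta)
  list(detector = det, scores = opt$scores, threshold = opt$threshold)
}

#' Contact-detector comparison: 1 vs 3 input time points (soft focal loss)
#'
#' Trains `length(seeds)` runs per configuration on the same event-crop
#' dataset (identical event-basis split), selects the best model per
#' configuration by validation F_0.1, and reports its recall at the
#' optimized threshold — the desk-scale analogue of the multi-time-point
#' recall gain.
#'
#' @param n_events positive contact events in the dataset (>= 150 for the
#'   acceptance run)
#' @param seeds training seeds
#' @param dataset_seed seed of the shared fixture dataset
#' @param epochs training epochs per run
#' @param windows_per_event labeled windows per event
#' @param time_points configurations to compare
#' @return list(`runs` data.frame, `best` data.frame one row per
#'   configuration)
#' @export
compare_contact_time_points <- function(n_events = 150L, seeds = 1:3,
                                        dataset_seed = 1000L, epochs = 3L,
                                        windows_per_event = 2L,
                                        time_points = c(1L, 3L)) {
  movies <- make_event_movies("contact", n_events, seed = dataset_seed)
  runs <- list()
  for (ntp in time_points) {
    ts <- make_crop_dataset(movies, n_time_points = ntp,
                            windows_per_event = windows_per_event)
    for (s in seeds) {
      r <- train_and_score(ts, ntp, stateful = FALSE, loss = "soft_focal",
                           seed = s, epochs = epochs)
      runs[[length(runs) + 1L]] <- data.frame(
        n_time_points = ntp, seed = s,
        f_beta = r$scores$f_beta, precision = r$scores$precision,
        recall = r$scores$recall, threshold = r$threshold)
    }
  }
  runs <- do.call(rbind, runs)
  best <- do.call(rbind, lapply(split(runs, runs$n_time_points), function(g)
    g[which.max(g$f_beta), , drop = FALSE]))
  list(runs = runs, best = best)
}

#' Division-detector comparison: stateful vs non-stateful (5 time points)
#'
#' Trains both architectures on division crops with long-lived ruffle
#' distractors, optimizes each model's threshold on its validation windows,
#' and counts false positives per movie on fresh held-out movies.
#'
#' @param n_events positive division events in the training dataset
#' @param seeds training seeds
#' @param dataset_seed,eval_seed fixture seeds (training vs held-out movies)
#' @param size crop side (48 px keeps the recurrent runs desk-scale)
#' @param epochs training epochs
#' @param n_eval_movies held-out movies for FP counting
#' @return list(`runs` data.frame with per-seed FP/movie, `median_fp` named
#'   vector)
#' @export
compare_division_statefulness <- function(n_events = 40L, seeds = 1:3,
                                          dataset_seed = 2000L,
                                          eval_seed = 3000L, size = 48L,
                                          epochs = 4L, n_eval_movies = 6L) {
  movies <- make_event_movies("division", n_events, seed = dataset_seed,
                              size = size, with_ruffles = TRUE)
  ts <- make_crop_dataset(movies, n_time_points = 5L, windows_per_event = 2L)
  eval_movies <- make_event_movies("division", n_eval_movies * 2L,
                                   seed = eval_seed, size = size,
                                   with_ruffles = TRUE)
  eval_movies <- eval_movies[seq_len(min(n_eval_movies, length(eval_movies)))]
  runs <- list()
  for (stateful in c(FALSE, TRUE)) {
    for (s in seeds) {
      r <- train_and_score(ts, 5L, stateful = stateful, loss = "soft_focal",
                           seed = s, epochs = epochs)
      fp <- vapply(eval_movies, function(m) {
        maps <- infer_sequence(r$detector, m$movie)
        det <- do.call(rbind, lapply(seq_along(maps), function(i)
          extract_peaks(maps[[i]], r$threshold, t = i - 1L)))
        if (is.null(det) || !nrow(det)) return(0)
        det <- group_detections(det)
        match_events(det, m$events)$n_fp
      }, numeric(1))
      runs[[length(runs) + 1L]] <- data.frame(
        stateful = stateful, seed = s, fp_per_movie = mean(fp),
        f_beta = r$scores$f_beta, recall = r$scores$recall,
        threshold = r$threshold)
    }
  }
  runs <- do.call(rbind, runs)
  med <- tapply(runs$fp_per_movie, runs$stateful, stats::median)
  list(runs = runs,
       median_fp = c(non_stateful = unname(med[["FALSE"]]),
                     stateful = unname(med[["TRUE"]])))
}

#' Oracle-detector duty-cycle experiment
#'
#' Runs closed-loop acquisition with the ground-truth (oracle) detector on
#' Poisson contact movies at the reference rates (one event per 3.1 min,
#' 20 s duration, 1 Hz) and summarizes duty cycle and the per-event
#' fluorescence fold reduction versus continuous imaging.
#'
#' @param seeds one run per seed
#' @param duration_min movie length in minutes
#' @param min_correlative_frames controller burst minimum
#' @return data.frame per seed plus aggregate means as attributes
#' @export
run_duty_cycle_experiment <- function(seeds = 1:5, duration_min = 60,
                                      min_correlative_frames = 20L) {
  model <- duty_cycle_model(3.1, 20, 1)
  cont_frames <- continuous_frames_per_event(model)
  out <- lapply(seeds, function(s) {
    cfg <- sim_config(duration = duration_min * 60, frame_rate = 1,
                      contact_rate = 1 / 3.1, contact_duration = 20,
                      division_rate = 0, seed = s)
    traj <- simulate_sample(cfg)
    det <- oracle_detector(traj$events, c(cfg$height, cfg$width))
    ctrl <- controller_config(min_correlative_frames = min_correlative_frames,
                              correlative_channels = "ld_fluo")
    log <- run_eda(traj, det, ctrl, render = FALSE)
    st <- capture_stats(log, traj$events)
    data.frame(seed = s, duty_cycle = st$duty_cycle,
               captured_fraction = st$events_captured_fraction,
               frames_per_event = st$fluorescence_frames_per_captured_event,
               fold_reduction = cont_frames / st$fluorescence_frames_per_captured_event,
               n_events = st$n_events)
  })
  do.call(rbind, out)
}
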