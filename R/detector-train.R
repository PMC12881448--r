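# Heatmap labels, the soft focal loss, training, and 36%-consistency label
# refinement.

#' Unit-peak Gaussian spot image
#' @param shape c(height, width)
#' @param x,y spot center, 0-based pixels
#' @param sigma Gaussian sd in pixels
#' @return matrix with value 1 at the center pixel
#' @export
gaussian_spot <- function(shape, x, y, sigma) {
  xs <- 0:(shape[2] - 1L); ys <- 0:(shape[1] - 1L)
  exp(-outer((ys - y)^2, (xs - x)^2, "+") / (2 * sigma^2))
}

#' Render the heatmap label for one frame
#'
#' Every positive event whose last five frames contain `t` contributes a
#' unit-peak Gaussian at its center; overlapping spots combine by pixelwise
#' maximum. Negative/event-free frames give an all-zero map.
#'
#' @param events event table
#' @param t 0-based frame index
#' @param shape c(height, width)
#' @param sigma_label Gaussian sd in pixels
#' @return matrix in \[0,1\]
#' @export
render_labels <- function(events, t, shape, sigma_label = 4) {
  m <- matrix(0, shape[1], shape[2])
  pos <- events[events$polarity == "positive", , drop = FALSE]
  for (i in seq_len(nrow(pos))) {
    if (pos$x[i] < 0 || pos$y[i] < 0 || pos$x[i] > shape[2] - 1 ||
        pos$y[i] > shape[1] - 1)
      stop("render_labels: event center outside shape")
    lab0 <- max(pos$t_start[i], pos$t_end[i] - 4L)   # last five frames
    if (t >= lab0 && t <= pos$t_end[i])
      m <- pmax(m, gaussian_spot(shape, pos$x[i], pos$y[i], sigma_label))
  }
  clamp(m, 0, 1)
}

#' Soft focal loss
#'
#' Mean over pixels of `|target - pred|^gamma * [-target log(pred)
#' - (1 - target) log(1 - pred)]`. Reduces to plain binary cross-entropy at
#' `gamma = 0` and accepts continuous (soft) targets. Predictions are clamped
#' to `[eps, 1 - eps]` inside the logs, never NaN.
#'
#' @param pred score map (matrix or array), values in (0,1)
#' @param target heatmap label, same shape
#' @param gamma focusing exponent (>= 0)
#' @param alpha positive-pixel balancing weight: each pixel's term is
#'   multiplied by `1 + alpha x target`. The default 0 is the plain soft
#'   focal loss; training uses a positive alpha because unit-peak Gaussians
#'   occupy a vanishing fraction of each frame
#' @param eps numerical clamp
#' @return scalar loss
#' @export
soft_focal_loss <- function(pred, target, gamma = 2, alpha = 0, eps = 1e-7) {
  stopifnot(identical(dim(pred), dim(target)) ||
              length(pred) == length(target), gamma >= 0, alpha >= 0)
  p <- clamp(pred, eps, 1 - eps)
  ce <- -target * log(p) - (1 - target) * log1p(-p)
  w <- if (gamma == 0) 1 else abs(target - pred)^gamma
  if (alpha > 0) w <- w * (1 + alpha * target)
  mean(w * ce)
}

# Gradient of the loss wrt the sigmoid pre-activation z (p = sigmoid(z)).
# The focal modulation |t - p|^gamma is treated as constant (detached), the
# standard numerically-safe choice; at gamma = 0 this is exact BCE backprop:
# dL/dz = (p - t) / n.
soft_focal_grad_z <- function(pred, target, gamma, alpha = 0, eps = 1e-7) {
  p <- clamp(pred, eps, 1 - eps)
  w <- if (gamma == 0) 1 else abs(target - pred)^gamma
  if (alpha > 0) w <- w * (1 + alpha * target)
  w * (p - target) / length(pred)
}

# ---- training sets ----------------------------------------------------------

# Deterministic event-basis split: two multiplicative-congruential rounds of
# the event id (independent of R's RNG; ids offset by 1e5 in merged sets must
# still mix), then a percentile cut.
event_split_of <- function(id, val_fraction = 0.25) {
  h <- ((id %% 2147483647) * 48271) %% 2147483647
  h <- (h * 16807) %% 2147483647
  ifelse(h %% 100 < val_fraction * 100, "validation", "train")
}

#' Assemble a training set of windows from a movie + events
#'
#' Positive windows end on each of the labeled last five frames of each
#' positive event; negative windows end on the labeled frames of negative
#' records. Windows never straddle the movie start (frames are clamped, i.e.
#' repeat-first padding) and all windows of one event share its split, which
#' is assigned 75/25 train/validation by a deterministic hash of the event id
#' ("split on an event basis").
#'
#' @param movie \[H, W, T\] array of raw frames (normalized internally)
#' @param events event table
#' @param n_time_points window length
#' @param sigma_label label Gaussian sd
#' @param windows_per_event cap on windows drawn per event (from the last
#'   labeled frame backwards)
#' @param val_fraction validation share of events
#' @return object of class `training_set`: list(`x` \[H,W,N,T\],
#'   `y` \[H,W,N\], `event_id`, `split`, `t_end`)
#' @export
make_training_set <- function(movie, events, n_time_points = 3L,
                              sigma_label = 4, windows_per_event = 5L,
                              val_fraction = 0.25) {
  d <- dim(movie)
  H <- d[1]; W <- d[2]; TT <- d[3]
  norm <- movie
  for (t in seq_len(TT)) norm[, , t] <- normalize_frame(movie[, , t])
  split_of <- function(id) event_split_of(id, val_fraction)
  xs <- list(); ys <- list(); eid <- integer(0); spl <- character(0)
  tend <- integer(0)
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    lab0 <- max(ev$t_start, ev$t_end - 4L)
    frames <- lab0:ev$t_end
    if (length(frames) > windows_per_event)
      frames <- utils::tail(frames, windows_per_event)
    for (t in frames) {
      if (t >= TT) next
      idx <- pmax(1L, (t - n_time_points + 2L):(t + 1L))   # 1-based
      xs[[length(xs) + 1L]] <- norm[, , idx, drop = FALSE]
      ys[[length(ys) + 1L]] <-
        if (ev$polarity == "positive")
          render_labels(ev, t, c(H, W), sigma_label)
        else matrix(0, H, W)
      eid <- c(eid, ev$event_id)
      spl <- c(spl, split_of(ev$event_id))
      tend <- c(tend, t)
    }
  }
  n <- length(xs)
  x <- array(0, c(H, W, n, n_time_points))
  y <- array(0, c(H, W, n))
  for (i in seq_len(n)) {
    x[, , i, ] <- xs[[i]]
    y[, , i] <- ys[[i]]
  }
  structure(list(x = x, y = y, event_id = eid, split = spl, t_end = tend),
            class = "training_set")
}

#' Merge training sets (e.g. windows from several movies)
#'
#' Event ids are offset per source set and the train/validation split is
#' recomputed from the merged (globally unique) ids, so the event-basis split
#' stays balanced across movies.
#'
#' @param ... `training_set` objects with identical window geometry
#' @param val_fraction validation share of merged events
#' @return a combined `training_set`
#' @export
merge_training_sets <- function(..., val_fraction = 0.25) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "training_set")) sets <- sets[[1]]
  d <- dim(sets[[1]]$x)
  n <- sum(vapply(sets, function(s) dim(s$x)[3], numeric(1)))
  x <- array(0, c(d[1], d[2], n, d[4]))
  y <- array(0, c(d[1], d[2], n))
  eid <- integer(0); spl <- character(0); tend <- integer(0)
  at <- 0L
  for (k in seq_along(sets)) {
    s <- sets[[k]]
    m <- dim(s$x)[3]
    x[, , at + seq_len(m), ] <- s$x
    y[, , at + seq_len(m)] <- s$y
    # offset ids so events from different movies stay distinct
    eid <- c(eid, s$event_id + k * 100000L)
    spl <- c(spl, s$split); tend <- c(tend, s$t_end)
    at <- at + m
  }
  spl <- event_split_of(eid, val_fraction)
  structure(list(x = x, y = y, event_id = eid, split = spl, t_end = tend),
            class = "training_set")
}

#' Train a detector
#'
#' Minimizes the configured loss (BCE or soft focal) with adaptive moment
#' estimation over the training-split windows; deterministic given the
#' detector seed. Never touches validation-split windows.
#'
#' @param detector a built detector
#' @param training_set a [make_training_set()] result
#' @param epochs,learning_rate,batch_size override the detector config
#' @param verbose print per-epoch loss
#' @return the trained detector, with `$loss_history` (mean training loss per
#'   epoch)
#' @export
train_detector <- function(detector, training_set,
                           epochs = detector$config$epochs,
                           learning_rate = detector$config$learning_rate,
                           batch_size = detector$config$batch_size,
                           verbose = FALSE) {
  stopifnot(inherits(detector, "unet_detector"),
            inherits(training_set, "training_set"))
  cfg <- detector$config
  tr <- which(training_set$split == "train")
  if (!length(tr)) stop("train_detector: empty training split")
  d <- dim(training_set$x)
  if (d[4] != cfg$n_time_points)
    stop("train_detector: training windows have ", d[4],
         " time points, config expects ", cfg$n_time_points)
  params <- detector$params
  opt <- adam_init(params)
  history <- numeric(epochs)
  gamma <- if (cfg$loss == "bce") 0 else cfg$gamma
  alpha <- cfg$alpha %||% 0
  for (ep in seq_len(epochs)) {
    ord <- with_seed(substream_seed(cfg$seed, paste0("epoch-", ep)),
                     sample(tr))
    ep_loss <- 0; nb <- 0L
    for (b0 in seq(1L, length(ord), by = batch_size)) {
      idx <- ord[b0:min(b0 + batch_size - 1L, length(ord))]
      B <- length(idx)
      x <- array(training_set$x[, , idx, , drop = FALSE],
                 c(d[1], d[2], B, cfg$n_time_points))
      fw <- if (cfg$stateful) stateful_fwd(params, x, cfg$depth)
            else unet_fwd(params, x, cfg$depth)
      target <- array(training_set$y[, , idx, drop = FALSE], c(d[1], d[2], B, 1L))
      pred <- fw$y
      ep_loss <- ep_loss + soft_focal_loss(pred, target, gamma, alpha)
      nb <- nb + 1L
      dz <- soft_focal_grad_z(pred, target, gamma, alpha)
      grads <- if (cfg$stateful) stateful_bwd(params, fw, dz, cfg$depth)
               else unet_bwd(params, fw, dz, cfg$depth)
      upd <- adam_step(params, lapply(grads, function(g)
        list(W = g$W, b = g$b)), opt, lr = learning_rate)
      params <- upd$params; opt <- upd$state
    }
    history[ep] <- ep_loss / nb
    if (verbose) message(sprintf("epoch %d/%d  loss %.5f", ep, epochs, history[ep]))
  }
  detector$params <- params
  detector$trained <- TRUE
  detector$loss_history <- c(detector$loss_history, history)
  reset_state(detector)
}

#' Consistency decision on per-frame peak scores
#'
#' @param peaks per-frame peak scores of one candidate event
#' @param threshold retention threshold (default 0.36)
#' @param statistic "mean" (default) or "min"
#' @return TRUE iff the aggregated peak score exceeds the threshold
#' @export
consistency_retain <- function(peaks, threshold = 0.36,
                               statistic = c("mean", "min")) {
  statistic <- match.arg(statistic)
  agg <- if (statistic == "mean") mean(peaks) else min(peaks)
  agg > threshold
}

#' Multi-step label refinement: the 36% consistency filter
#'
#' Scores every labeled frame of each candidate event with an already-trained
#' detector, takes the peak score within `match_radius` of the event center
#' per frame, and retains the event iff the mean (or minimum) per-frame peak
#' exceeds `consistency_threshold`.
#'
#' @param candidate_events event table (positive candidates)
#' @param detector a trained detector
#' @param movie \[H, W, T\] raw movie the events live in
#' @param consistency_threshold retention threshold (default 0.36)
#' @param match_radius peak search radius in pixels
#' @param statistic "mean" (default) or "min" per-frame aggregation
#' @return the retained subset of `candidate_events`, with a
#'   `consistency_score` column added
#' @export
refine_labels <- function(candidate_events, detector, movie,
                          consistency_threshold = 0.36, match_radius = 10,
                          statistic = c("mean", "min")) {
  statistic <- match.arg(statistic)
  maps <- infer_sequence(detector, movie)
  scores <- numeric(nrow(candidate_events))
  H <- dim(movie)[1]; W <- dim(movie)[2]
  for (i in seq_len(nrow(candidate_events))) {
    ev <- candidate_events[i, ]
    lab0 <- max(ev$t_start, ev$t_end - 4L)
    frames <- lab0:ev$t_end
    frames <- frames[frames >= 0 & frames < length(maps)]
    if (!length(frames)) stop("refine_labels: event ", ev$event_id,
                              " has no labeled frames in the movie")
    peaks <- vapply(frames, function(t) {
      m <- maps[[t + 1L]]
      ys <- pmax(1L, round(ev$y) + 1L - match_radius):
        pmin(H, round(ev$y) + 1L + match_radius)
      xs <- pmax(1L, round(ev$x) + 1L - match_radius):
        pmin(W, round(ev$x) + 1L + match_radius)
      max(m[ys, xs])
    }, numeric(1))
    scores[i] <- if (statistic == "mean") mean(peaks) else min(peaks)
  }
  out <- candidate_events[scores > consistency_threshold, , drop = FALSE]
  out$consistency_score <- scores[scores > consistency_threshold]
  rownames(out) <- NULL
  out
}
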