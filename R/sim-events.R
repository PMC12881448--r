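# Event scheduling: homogeneous Poisson processes for contacts and divisions.

empty_events <- function() {
  data.frame(event_id = integer(0), class = character(0),
             polarity = character(0), t_start = integer(0),
             t_end = integer(0), x = numeric(0), y = numeric(0),
             stringsAsFactors = FALSE)
}

validate_events <- function(ev, height = Inf, width = Inf) {
  need <- c("event_id", "class", "polarity", "t_start", "t_end", "x", "y")
  if (!all(need %in% names(ev))) {
    stop("event table missing column(s): ",
         paste(setdiff(need, names(ev)), collapse = ", "))
  }
  bad <- which(ev$t_end < ev$t_start)
  if (length(bad)) stop("event record ", bad[1], ": t_end < t_start")
  bad <- which(ev$x < 0 | ev$y < 0 | ev$x > width - 1 | ev$y > height - 1)
  if (length(bad)) stop("event record ", bad[1], ": center outside image bounds")
  if (!all(ev$class %in% c("contact", "division")))
    stop("event class must be 'contact' or 'division'")
  if (!all(ev$polarity %in% c("positive", "negative")))
    stop("event polarity must be 'positive' or 'negative'")
  invisible(ev)
}

#' Schedule synthetic rare events for a movie
#'
#' Contact events are drawn from a homogeneous Poisson process at
#' `contact_rate` (events/min) with fixed duration `contact_duration`;
#' division events likewise at `division_rate`, each preceded by
#' `pre_constriction_window` frames of visible constriction. Events are kept
#' only if their full span (including the approach/constriction lead-in) fits
#' inside the movie. Deterministic given `seed`.
#'
#' Provisional event centers are drawn uniformly inside the field with a
#' margin; [simulate_sample()] steers organelles to realize each event and
#' rewrites the centers to the realized positions.
#'
#' @param config a [sim_config()]
#' @param seed integer seed (defaults to the config's event sub-stream)
#' @return a data.frame of event records (`event_id, class, polarity,
#'   t_start, t_end, x, y`; frame indices 0-based inclusive)
#' @export
schedule_events <- function(config, seed = substream_seed(config$seed, "events")) {
  validate_sim_config(config)
  TT <- n_frames(config)
  fr <- config$frame_rate
  # contact span in frames; >= 3 frames so positive contacts honor the
  # "no visible separation for at least three frames" persistence rule
  span_contact <- max(3L, as.integer(round(config$contact_duration * fr)))
  lead_contact <- 5L                               # sphere approach frames
  pre_div <- config$pre_constriction_window
  post_div <- 5L                                   # recoil frames
  mx <- min(20, (config$width - 1) * 0.25)
  my <- min(20, (config$height - 1) * 0.25)
  mxd <- min(30, (config$width - 1) * 0.3)
  myd <- min(30, (config$height - 1) * 0.3)
  with_seed(seed, {
    draw_starts <- function(rate_per_min) {
      if (rate_per_min <= 0) return(numeric(0))
      rate_s <- rate_per_min / 60
      # exponential inter-arrival times until the movie ends
      tt <- numeric(0); t <- 0
      repeat {
        t <- t + stats::rexp(1, rate_s)
        if (t >= config$duration) break
        tt <- c(tt, t)
      }
      tt
    }
    ev <- empty_events()
    ct <- draw_starts(config$contact_rate)
    for (t0 in ct) {
      f0 <- as.integer(floor(t0 * fr))
      f1 <- f0 + span_contact - 1L
      if (f0 < lead_contact || f1 > TT - 1L) next
      ev <- rbind(ev, data.frame(
        event_id = NA_integer_, class = "contact", polarity = "positive",
        t_start = f0, t_end = f1,
        x = stats::runif(1, mx, config$width - 1 - mx),
        y = stats::runif(1, my, config$height - 1 - my)))
    }
    nm <- draw_starts(config$near_miss_rate %||% 0)
    for (t0 in nm) {
      f0 <- as.integer(floor(t0 * fr))
      f1 <- f0 + as.integer(stats::runif(1, 4, 10))
      if (f0 < lead_contact || f1 > TT - 1L) next
      ev <- rbind(ev, data.frame(
        event_id = NA_integer_, class = "contact", polarity = "negative",
        t_start = f0, t_end = f1,
        x = stats::runif(1, mx, config$width - 1 - mx),
        y = stats::runif(1, my, config$height - 1 - my)))
    }
    dt <- draw_starts(config$division_rate)
    for (t0 in dt) {
      f1 <- as.integer(floor(t0 * fr))               # scission frame
      f0 <- f1 - pre_div + 1L                        # first constriction frame
      if (f0 < 1L || f1 + post_div > TT - 1L) next
      ev <- rbind(ev, data.frame(
        event_id = NA_integer_, class = "division", polarity = "positive",
        t_start = f0, t_end = f1,
        x = stats::runif(1, mxd, config$width - 1 - mxd),
        y = stats::runif(1, myd, config$height - 1 - myd)))
    }
    if (nrow(ev)) {
      ev <- ev[order(ev$t_start), , drop = FALSE]
      ev$event_id <- seq_len(nrow(ev))
      rownames(ev) <- NULL
    }
    validate_events(ev, config$height, config$width)
    ev
  })
}
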