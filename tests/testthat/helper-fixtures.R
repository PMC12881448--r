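# Shared lightweight fixtures. Anything heavier is built inside the tests
# that need it (and scaled to seconds, not minutes).

tiny_sim_config <- function(...) {
  args <- utils::modifyList(
    list(height = 96L, width = 96L, duration = 60, n_mito = 2L,
         n_spheres = 2L, n_ruffles = 1L, contact_rate = 0,
         division_rate = 0, noise_sd = 1),
    list(...))
  do.call(sim_config, args)
}

# A small contact-bearing trajectory reused by several tests (memoised per
# session).
contact_traj <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- tiny_sim_config(duration = 120, contact_rate = 1.2, seed = 11L)
      cache <<- simulate_sample(cfg)
    }
    cache
  }
})

division_traj <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- tiny_sim_config(duration = 150, division_rate = 1.2, seed = 5L)
      cache <<- simulate_sample(cfg)
    }
    cache
  }
})

# Simple synthetic event table.
mk_events <- function(t_start, t_end, x, y, class = "contact",
                      polarity = "positive") {
  n <- length(t_start)
  data.frame(event_id = seq_len(n), class = rep(class, length.out = n),
             polarity = rep(polarity, length.out = n),
             t_start = t_start, t_end = t_end, x = x, y = y)
}

# Exhaustive maximum-bipartite-matching TP count (oracle for match_events).
brute_force_tp <- function(eligible) {
  nd <- nrow(eligible)
  rec <- function(i, used) {
    if (i > nd) return(0L)
    best <- rec(i + 1L, used)
    for (j in which(eligible[i, ] & !used)) {
      used2 <- used; used2[j] <- TRUE
      best <- max(best, 1L + rec(i + 1L, used2))
    }
    best
  }
  if (nd == 0L || ncol(eligible) == 0L) return(0L)
  rec(1L, rep(FALSE, ncol(eligible)))
}

eligibility_matrix <- function(det, ev, dist_tol, time_tol) {
  nd <- nrow(det); ne <- nrow(ev)
  el <- matrix(FALSE, nd, ne)
  for (i in seq_len(nd)) for (j in seq_len(ne)) {
    sdist <- sqrt((det$x[i] - ev$x[j])^2 + (det$y[i] - ev$y[j])^2)
    lab0 <- max(ev$t_start[j], ev$t_end[j] - 4L)
    dt <- if (det$t[i] < lab0) lab0 - det$t[i]
          else if (det$t[i] > ev$t_end[j]) det$t[i] - ev$t_end[j] else 0
    el[i, j] <- sdist <= dist_tol && dt <= time_tol
  }
  el
}
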