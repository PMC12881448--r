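# Synthetic cell sample: organelle trajectories realizing the scheduled events.
#
# Geometry lives in continuous 0-based pixel coordinates (x = column,
# y = row, origin top-left); pixel centers sit at integer coordinates.

reflect_into <- function(v, lo, hi) {
  span <- hi - lo
  v <- (v - lo) %% (2 * span)
  lo + ifelse(v > span, 2 * span - v, v)
}

brownian_2d <- function(TT, sd, start, lo, hi) {
  dx <- c(0, stats::rnorm(TT - 1L, 0, sd))
  dy <- c(0, stats::rnorm(TT - 1L, 0, sd))
  cbind(reflect_into(start[1] + cumsum(dx), lo[1], hi[1]),
        reflect_into(start[2] + cumsum(dy), lo[2], hi[2]))
}

# Densify a polyline (with per-vertex halfwidths) to ~1 px arclength spacing.
densify_polyline <- function(pts, hw, step = 1) {
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  s <- c(0, cumsum(seg))
  if (s[length(s)] < step) {
    return(list(x = pts[, 1], y = pts[, 2], hw = rep(hw, length.out = nrow(pts))))
  }
  ss <- seq(0, s[length(s)], by = step)
  list(x = stats::approx(s, pts[, 1], ss)$y,
       y = stats::approx(s, pts[, 2], ss)$y,
       hw = stats::approx(s, rep(hw, length.out = nrow(pts)), ss)$y)
}

# Signed distance-like field for a tube: min over centerline samples of
# (euclidean distance - halfwidth). Negative inside; +Inf beyond `pad` px of
# the boundary (far values are irrelevant to absorption, halo, and masks).
field_polyline <- function(H, W, pts, hw, pad = 6) {
  d <- densify_polyline(pts, hw)
  f <- matrix(Inf, H, W)
  bx0 <- W; bx1 <- -1L; by0 <- H; by1 <- -1L
  for (i in seq_along(d$x)) {
    r <- d$hw[i] + pad
    x0 <- max(0L, floor(d$x[i] - r)); x1 <- min(W - 1L, ceiling(d$x[i] + r))
    y0 <- max(0L, floor(d$y[i] - r)); y1 <- min(H - 1L, ceiling(d$y[i] + r))
    if (x1 < x0 || y1 < y0) next
    ri <- (y0:y1) + 1L; ci <- (x0:x1) + 1L
    sub <- sqrt(outer((y0:y1 - d$y[i])^2, (x0:x1 - d$x[i])^2, "+")) - d$hw[i]
    f[ri, ci] <- pmin(f[ri, ci], sub)
    bx0 <- min(bx0, x0); bx1 <- max(bx1, x1)
    by0 <- min(by0, y0); by1 <- max(by1, y1)
  }
  attr(f, "bbox") <- c(by0, by1, bx0, bx1)
  f
}

field_disk <- function(H, W, center, radius, pad = 8) {
  f <- matrix(Inf, H, W)
  x0 <- max(0L, floor(center[1] - radius - pad))
  x1 <- min(W - 1L, ceiling(center[1] + radius + pad))
  y0 <- max(0L, floor(center[2] - radius - pad))
  y1 <- min(H - 1L, ceiling(center[2] + radius + pad))
  if (x1 < x0 || y1 < y0) return(f)
  xs <- x0:x1; ys <- y0:y1
  f[ys + 1L, xs + 1L] <- sqrt(outer((ys - center[2])^2, (xs - center[1])^2, "+")) - radius
  attr(f, "bbox") <- c(y0, y1, x0, x1)
  f
}

min_boundary_distance <- function(tube_pts, tube_hw, center, radius) {
  d <- densify_polyline(tube_pts, tube_hw, step = 0.25)
  min(sqrt((d$x - center[1])^2 + (d$y - center[2])^2) - d$hw) - radius
}

#' Simulate a full synthetic cell sample trajectory
#'
#' Tubular organelles (mitochondria) and spherical organelles (droplets /
#' lysosomes) move smoothly through the field; scheduled contact events steer
#' a sphere onto a tube so the boundary distance is zero for the whole event
#' span (>= 3 frames), with a local tube deformation; scheduled divisions
#' narrow the tube at the event site over the pre-constriction window and then
#' split it into two recoiling daughters. Ruffles persist for the whole movie
#' as long-lived curvilinear false-positive bait. Deterministic given the
#' config seed.
#'
#' @param config a [sim_config()]
#' @return an object of class `eda_trajectory` with the realized event table
#'   (`$events`, including negative records) and per-frame geometry accessible
#'   via [state_at()]
#' @export
simulate_sample <- function(config) {
  validate_sim_config(config)
  TT <- n_frames(config)
  H <- config$height; W <- config$width
  K <- 7L                                    # control points per tube
  margin <- 15
  events <- schedule_events(config)

  geom_seed <- substream_seed(config$seed, "geometry")
  traj <- with_seed(geom_seed, {
    tubes <- vector("list", config$n_mito)
    lmax <- min(H, W) - 2 * margin            # tubes must fit the field
    for (i in seq_len(config$n_mito)) {
      len <- stats::runif(1, min(40, 0.75 * lmax), min(60, 0.95 * lmax))
      ang0 <- stats::runif(1, 0, 2 * pi)
      angs <- ang0 + cumsum(c(0, stats::rnorm(K - 1L, 0, 0.25)))
      step <- len / (K - 1L)
      base <- cbind(cumsum(c(0, step * cos(angs[-K]))),
                    cumsum(c(0, step * sin(angs[-K]))))
      base <- sweep(base, 2, colMeans(base))
      start <- c(stats::runif(1, margin + len / 2, W - margin - len / 2),
                 stats::runif(1, margin + len / 2, H - margin - len / 2))
      drift <- brownian_2d(TT, 0.4, start,
                           lo = c(margin + len / 2, margin + len / 2),
                           hi = c(W - margin - len / 2, H - margin - len / 2))
      wig_amp <- stats::runif(K, 0.3, 0.9)
      wig_ph <- stats::runif(K, 0, 2 * pi)
      wig_per <- stats::runif(1, 40, 90)
      cp <- array(0, c(K, 2L, TT))
      tt <- seq_len(TT) - 1L
      for (k in seq_len(K)) {
        w <- wig_amp[k] * sin(2 * pi * tt / wig_per + wig_ph[k])
        cp[k, 1L, ] <- base[k, 1] + drift[, 1] + w * cos(angs[k] + pi / 2)
        cp[k, 2L, ] <- base[k, 2] + drift[, 2] + w * sin(angs[k] + pi / 2)
      }
      tubes[[i]] <- list(id = i, cp = cp,
                         hw = matrix(config$tube_halfwidth, K, TT),
                         active = rep(TRUE, TT), parent = NA_integer_)
    }
    spheres <- vector("list", config$n_spheres)
    for (i in seq_len(config$n_spheres)) {
      start <- c(stats::runif(1, margin, W - margin),
                 stats::runif(1, margin, H - margin))
      spheres[[i]] <- list(id = i,
                           center = t(brownian_2d(TT, 0.5, start,
                                                  c(margin, margin),
                                                  c(W - margin, H - margin))),
                           radius = config$sphere_radius,
                           type = c("ld", "lyso")[1L + (i %% 2L)])
    }
    ruffles <- vector("list", config$n_ruffles)
    for (i in seq_len(config$n_ruffles)) {
      M <- 12L
      len <- stats::runif(1, min(60, 1.1 * lmax), min(100, 1.6 * lmax))
      ang0 <- stats::runif(1, 0, 2 * pi)
      angs <- ang0 + cumsum(c(0, stats::rnorm(M - 1L, 0, 0.45)))
      step <- len / (M - 1L)
      pts <- cbind(cumsum(c(0, step * cos(angs[-M]))),
                   cumsum(c(0, step * sin(angs[-M]))))
      pts <- sweep(pts, 2, colMeans(pts))
      pts[, 1] <- pts[, 1] + stats::runif(1, 0.3 * W, 0.7 * W)
      pts[, 2] <- pts[, 2] + stats::runif(1, 0.3 * H, 0.7 * H)
      drift_amp <- stats::runif(1, 0.3, 0.8)
      drift_ph <- stats::runif(2, 0, 2 * pi)
      # pinched width profile: static constriction-like waists along the fold
      # (the false-positive bait for division detectors)
      n_pinch <- stats::runif(1, 2, 4)
      ph_pinch <- stats::runif(1, 0, 2 * pi)
      hw_prof <- 1 + (config$tube_halfwidth - 1) *
        (0.5 + 0.5 * cos(seq(0, n_pinch * 2 * pi, length.out = M) + ph_pinch))
      ruffles[[i]] <- list(pts = pts, hw = pmax(hw_prof, 1),
                           drift_amp = drift_amp, drift_ph = drift_ph,
                           drift_per = stats::runif(1, 100, 200))
    }
    nucleus <- list(center = c(W / 2 + stats::runif(1, -15, 15),
                               H / 2 + stats::runif(1, -15, 15)),
                    rx = stats::runif(1, 16, 20), ry = stats::runif(1, 14, 18))
    list(tubes = tubes, spheres = spheres, ruffles = ruffles, nucleus = nucleus)
  })
  tubes <- traj$tubes; spheres <- traj$spheres

  # --- assign and realize events -------------------------------------------
  lead_contact <- 5L
  post_div <- 5L
  assign_seed <- substream_seed(config$seed, "event-realization")
  realized <- with_seed(assign_seed, {
    sphere_busy <- matrix(FALSE, length(spheres), TT)
    tube_divided <- rep(FALSE, length(tubes))
    tube_busy <- matrix(FALSE, max(1L, length(tubes)), TT)
    keep <- logical(nrow(events))
    events$tube <- rep(NA_integer_, nrow(events))
    events$sphere <- rep(NA_integer_, nrow(events))
    div_info <- list()
    next_tube_id <- length(tubes)

    for (e in seq_len(nrow(events))) {
      ev <- events[e, ]
      f0 <- ev$t_start; f1 <- ev$t_end
      if (ev$class == "contact") {
        is_pass <- ev$polarity == "negative"       # near-miss: gap, no deform
        gap <- if (is_pass) stats::runif(1, 1.2, 2.5) else 0
        win <- max(1L, f0 + 1L - lead_contact):(f1 + 1L)
        cand_s <- which(!apply(sphere_busy[, win, drop = FALSE], 1, any))
        cand_t <- which(!tube_divided &
                          !apply(tube_busy[, win, drop = FALSE], 1, any))
        if (!length(cand_s) || !length(cand_t)) next
        si <- cand_s[sample.int(length(cand_s), 1L)]
        ti <- cand_t[sample.int(length(cand_t), 1L)]
        sphere_busy[si, win] <- TRUE
        tube_busy[ti, win] <- TRUE
        events$tube[e] <- ti; events$sphere[e] <- si
        keep[e] <- TRUE
        mid <- (K + 1L) %/% 2L
        side <- sample(c(-1, 1), 1L)
        contact_pos <- matrix(0, 2L, length((f0 + 1L):(f1 + 1L)))
        jj <- 0L
        for (fi in (f0 + 1L):(f1 + 1L)) {          # 1-based frame index
          cp <- tubes[[ti]]$cp[, , fi]
          tang <- cp[min(mid + 1L, K), ] - cp[max(mid - 1L, 1L), ]
          tang <- tang / sqrt(sum(tang^2))
          normal <- side * c(-tang[2], tang[1])
          # local deformation of the tube toward the sphere (contacts only),
          # then place the sphere against the deformed tube; near-misses sit
          # at `gap` px with small independent jitter (the dynamic tell)
          ramp <- if (is_pass) 0 else min(1, (fi - f0) / 3, (f1 + 1L - fi + 1L) / 3)
          tubes[[ti]]$cp[mid, , fi] <- cp[mid, ] +
            normal * config$deform_px * ramp
          cp <- tubes[[ti]]$cp[, , fi]
          hw <- tubes[[ti]]$hw[, fi]
          pos <- cp[mid, ] + normal * (hw[mid] + spheres[[si]]$radius)
          # corrector steps: place at boundary distance `gap`
          for (it in 1:3) {
            b <- min_boundary_distance(cp, hw, pos, spheres[[si]]$radius)
            pos <- pos + normal * (gap - b)
          }
          if (is_pass)
            pos <- pos + stats::rnorm(2, 0, 0.35)
          jj <- jj + 1L
          contact_pos[, jj] <- pos
        }
        # approach: interpolate from the free position to the first contact
        a0 <- max(1L, f0 + 1L - lead_contact)
        free_pos <- spheres[[si]]$center[, a0]
        nap <- (f0 + 1L) - a0
        if (nap > 0) {
          w <- seq_len(nap) / (nap + 1)
          for (j in seq_len(nap)) {
            spheres[[si]]$center[, a0 + j - 1L] <-
              (1 - w[j]) * free_pos + w[j] * contact_pos[, 1L]
          }
        }
        spheres[[si]]$center[, (f0 + 1L):(f1 + 1L)] <- contact_pos
        # resume Brownian path from the detachment point
        if (f1 + 2L <= TT) {
          shift <- contact_pos[, jj] - spheres[[si]]$center[, f1 + 2L]
          later <- (f1 + 2L):TT
          spheres[[si]]$center[, later] <- spheres[[si]]$center[, later] + shift
          spheres[[si]]$center[1, later] <-
            reflect_into(spheres[[si]]$center[1, later], margin, W - margin)
          spheres[[si]]$center[2, later] <-
            reflect_into(spheres[[si]]$center[2, later], margin, H - margin)
        }
        events$x[e] <- contact_pos[1, 1L]
        events$y[e] <- contact_pos[2, 1L]
      } else {                                     # division
        win <- (f0 + 1L):min(TT, f1 + 1L + post_div)
        cand_t <- which(!tube_divided &
                          !apply(tube_busy[, win, drop = FALSE], 1, any))
        if (!length(cand_t)) next
        ti <- cand_t[sample.int(length(cand_t), 1L)]
        tube_divided[ti] <- TRUE
        tube_busy[ti, win[1]:TT] <- TRUE
        events$tube[e] <- ti
        keep[e] <- TRUE
        mid <- (K + 1L) %/% 2L
        # constriction ramp over [t_start, t_end]: halfwidth -> 1 px
        for (fi in (f0 + 1L):(f1 + 1L)) {
          prog <- (fi - f0) / (f1 + 1L - f0)
          hw_min <- config$tube_halfwidth -
            prog * (config$tube_halfwidth - 1.0)
          tubes[[ti]]$hw[mid, fi] <- hw_min
          tubes[[ti]]$hw[mid - 1L, fi] <-
            (tubes[[ti]]$hw[mid - 1L, fi] + hw_min) / 2
          tubes[[ti]]$hw[mid + 1L, fi] <-
            (tubes[[ti]]$hw[mid + 1L, fi] + hw_min) / 2
        }
        site <- tubes[[ti]]$cp[mid, , f1 + 1L]
        events$x[e] <- site[1]; events$y[e] <- site[2]
        # daughters exist from t_end+1 on; parent deactivates there
        if (f1 + 2L <= TT) {
          tubes[[ti]]$active[(f1 + 2L):TT] <- FALSE
          recoil_total <- stats::runif(1, config$recoil_px[1], config$recoil_px[2])
          mk_daughter <- function(idx, tip_is_last) {
            cp <- tubes[[ti]]$cp[idx, , , drop = FALSE]
            cp <- array(cp, c(length(idx), 2L, TT))
            hw <- tubes[[ti]]$hw[idx, , drop = FALSE]
            hw[] <- config$tube_halfwidth
            nI <- length(idx)
            tip <- if (tip_is_last) nI else 1L
            nb <- if (tip_is_last) nI - 1L else 2L
            act <- rep(FALSE, TT)
            act[(f1 + 2L):TT] <- TRUE
            for (fi in (f1 + 2L):TT) {
              # retract the scission tip 2 px along the tube axis, then recoil
              axis <- cp[nb, , fi] - cp[tip, , fi]
              axis <- axis / max(sqrt(sum(axis^2)), 1e-9)
              cp[tip, , fi] <- cp[tip, , fi] + axis * 2
              rec <- recoil_total * min(1, (fi - f1 - 1L) / post_div)
              cp[, 1L, fi] <- cp[, 1L, fi] + axis[1] * rec
              cp[, 2L, fi] <- cp[, 2L, fi] + axis[2] * rec
              hw[tip, fi] <- config$tube_halfwidth * 0.7
            }
            list(cp = cp, hw = hw, active = act)
          }
          d1 <- mk_daughter(1L:mid, tip_is_last = TRUE)
          d2 <- mk_daughter(mid:K, tip_is_last = FALSE)
          id1 <- next_tube_id + 1L; id2 <- next_tube_id + 2L
          next_tube_id <- next_tube_id + 2L
          tubes[[id1]] <- c(d1, list(id = id1, parent = ti))
          tubes[[id2]] <- c(d2, list(id = id2, parent = ti))
          div_info[[length(div_info) + 1L]] <- list(
            event_id = ev$event_id, tube = ti, daughters = c(id1, id2),
            t_scission = f1, site = site,
            d_tip = c(mid, 1L))                    # tip row index in each daughter
        }
      }
    }
    # --- keep free spheres off the tubes -----------------------------------
    # Unscheduled tube-sphere tangencies would be real contact events the
    # ground truth does not label; push free spheres out to a standoff
    # distance (control-point approximation of the tube boundary).
    standoff <- 3
    for (si in seq_along(spheres)) {
      pos <- spheres[[si]]$center                    # 2 x TT
      free <- !sphere_busy[si, ]
      for (tb in tubes) {
        act <- tb$active & free
        if (!any(act)) next
        K2 <- dim(tb$cp)[1]
        d2 <- matrix(Inf, K2, TT)
        for (k in seq_len(K2)) {
          d2[k, act] <- (tb$cp[k, 1L, act] - pos[1L, act])^2 +
            (tb$cp[k, 2L, act] - pos[2L, act])^2
        }
        nearest <- max.col(-t(d2))                   # nearest control point
        dmin <- sqrt(d2[cbind(nearest, seq_len(TT))])
        hw_near <- tb$hw[cbind(nearest, seq_len(TT))]
        clearance <- hw_near + spheres[[si]]$radius + standoff
        viol <- which(act & dmin < clearance)
        for (fi in viol) {
          dir <- pos[, fi] - tb$cp[nearest[fi], , fi]
          nrm <- sqrt(sum(dir^2))
          dir <- if (nrm < 1e-6) c(1, 0) else dir / nrm
          pos[, fi] <- pos[, fi] + dir * (clearance[fi] - dmin[fi])
        }
      }
      pos[1L, ] <- clamp(pos[1L, ], 2, W - 3)
      pos[2L, ] <- clamp(pos[2L, ], 2, H - 3)
      spheres[[si]]$center[, free] <- pos[, free]
    }
    list(tubes = tubes, spheres = spheres, events = events[keep, , drop = FALSE],
         divisions = div_info)
  })
  tubes <- realized$tubes; spheres <- realized$spheres
  events <- realized$events
  if (nrow(events)) {
    events$x <- clamp(events$x, 0, W - 1L)
    events$y <- clamp(events$y, 0, H - 1L)
    events$event_id <- seq_len(nrow(events))
    rownames(events) <- NULL
  }

  # --- negative records: event-free spots plus ruffle bait -----------------
  neg_seed <- substream_seed(config$seed, "negatives")
  events <- with_seed(neg_seed, {
    n_pos <- nrow(events)
    n_neg <- ceiling(0.9 * n_pos)
    if (n_neg > 0 && TT > 12L) {
      neg <- empty_events()
      busy <- rep(FALSE, TT)
      for (e in seq_len(n_pos)) {
        busy[max(1L, events$t_start[e] - 4L):(events$t_end[e] + 1L)] <- TRUE
      }
      free_t <- which(!busy[6:(TT - 1L)]) + 4L      # 0-based, window room
      for (i in seq_len(n_neg)) {
        if (!length(free_t)) break
        t0 <- free_t[sample.int(length(free_t), 1L)]
        if (i %% 2L == 1L && length(traj$ruffles)) {
          rf <- traj$ruffles[[1L + (i %% length(traj$ruffles))]]
          p <- rf$pts[sample.int(nrow(rf$pts), 1L), ]
        } else {
          p <- c(stats::runif(1, min(20, W * 0.25), W - 1 - min(20, W * 0.25)),
                 stats::runif(1, min(20, H * 0.25), H - 1 - min(20, H * 0.25)))
        }
        neg <- rbind(neg, data.frame(
          event_id = NA_integer_, class = "contact", polarity = "negative",
          t_start = max(0L, t0 - 4L), t_end = t0,
          x = clamp(p[1], 0, W - 1), y = clamp(p[2], 0, H - 1),
          tube = NA_integer_, sphere = NA_integer_))
      }
      if (nrow(neg)) {
        events <- rbind(events, neg)
        events$event_id <- seq_len(nrow(events))
        rownames(events) <- NULL
      }
    }
    events
  })

  # --- TMRE flicker schedule: 1-3 s subdomain dropouts ---------------------
  tmre_seed <- substream_seed(config$seed, "tmre")
  dropouts <- with_seed(tmre_seed, {
    out <- list()
    for (tb in tubes) {
      t <- 0
      repeat {
        t <- t + stats::rexp(1, 0.5 / 60)          # ~0.5 flickers/min/tube
        if (t >= config$duration) break
        dur <- stats::runif(1, 1, 3)               # seconds
        f0 <- as.integer(floor(t * config$frame_rate))
        f1 <- as.integer(floor((t + dur) * config$frame_rate))
        if (f1 >= TT) break
        s0 <- stats::runif(1, 0, 0.55)
        out[[length(out) + 1L]] <- data.frame(
          tube = tb$id, f0 = f0, f1 = f1, s0 = s0,
          s1 = s0 + stats::runif(1, 0.3, 0.45), dur_s = dur)
      }
    }
    if (length(out)) do.call(rbind, out) else
      data.frame(tube = integer(0), f0 = integer(0), f1 = integer(0),
                 s0 = numeric(0), s1 = numeric(0), dur_s = numeric(0))
  })

  structure(list(config = config, events = events, tubes = tubes,
                 spheres = spheres, ruffles = traj$ruffles,
                 nucleus = traj$nucleus, divisions = realized$divisions,
                 tmre_dropouts = dropouts, n_frames = TT),
            class = "eda_trajectory")
}

#' @export
print.eda_trajectory <- function(x, ...) {
  cat(sprintf("<eda_trajectory> %d frames, %d tubes (%d post-division), %d spheres, %d ruffles\n",
              x$n_frames, length(x$tubes),
              sum(vapply(x$tubes, function(t) !is.na(t$parent), logical(1))),
              length(x$spheres), length(x$ruffles)))
  cat(sprintf("  events: %d positive (%s), %d negative\n",
              sum(x$events$polarity == "positive"),
              paste(names(table(x$events$class[x$events$polarity == "positive"])),
                    collapse = "/"),
              sum(x$events$polarity == "negative")))
  invisible(x)
}

#' Geometry snapshot of a trajectory at one frame
#'
#' @param traj an [simulate_sample()] trajectory
#' @param t 0-based frame index
#' @return list with active `tubes`, `spheres`, `ruffles`, `nucleus` and `t`
#' @export
state_at <- function(traj, t) {
  stopifnot(inherits(traj, "eda_trajectory"))
  if (t < 0 || t >= traj$n_frames) stop("state_at: frame index out of range")
  fi <- as.integer(t) + 1L
  tubes <- list()
  for (tb in traj$tubes) {
    if (!tb$active[fi]) next
    tubes[[length(tubes) + 1L]] <-
      list(id = tb$id, cp = tb$cp[, , fi], hw = tb$hw[, fi])
  }
  ruffles <- lapply(traj$ruffles, function(rf) {
    ph <- 2 * pi * t / rf$drift_per
    off <- rf$drift_amp * c(sin(ph + rf$drift_ph[1]), cos(ph + rf$drift_ph[2]))
    list(pts = sweep(rf$pts, 2, -off), hw = rf$hw)
  })
  list(t = as.integer(t), tubes = tubes,
       spheres = lapply(traj$spheres, function(s)
         list(id = s$id, center = s$center[, fi], radius = s$radius,
              type = s$type)),
       ruffles = ruffles, nucleus = traj$nucleus)
}

#' Binary organelle mask at one frame
#'
#' @param state a [state_at()] snapshot
#' @param config the trajectory's [sim_config()]
#' @param what "all", "tubes", "spheres", "ruffles", or "tube:<id>"
#' @return logical matrix (TRUE inside organelles)
#' @export
organelle_mask <- function(state, config, what = "all") {
  H <- config$height; W <- config$width
  f <- matrix(Inf, H, W)
  want_tube <- function(id) {
    what %in% c("all", "tubes") ||
      (startsWith(what, "tube:") && id == as.integer(sub("tube:", "", what)))
  }
  for (tb in state$tubes) {
    if (!want_tube(tb$id)) next
    f <- pmin(f, field_polyline(H, W, tb$cp, tb$hw))
  }
  if (what %in% c("all", "spheres")) {
    for (s in state$spheres) f <- pmin(f, field_disk(H, W, s$center, s$radius))
  }
  if (what %in% c("all", "ruffles")) {
    for (r in state$ruffles) f <- pmin(f, field_polyline(H, W, r$pts, r$hw))
  }
  f < 0
}
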