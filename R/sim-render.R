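# Frame rendering: phase-contrast absorption + halo, and channel-specific
# fluorescence. All renderers are pure functions of (state, config) — noise is
# drawn from a per-frame, per-channel sub-stream of the config seed.

frame_noise_seed <- function(config, channel, t)
  substream_seed(config$seed, paste0("noise-", channel, "-", t))

# smooth 0..1 interior indicator from a signed field (1 well inside)
soft_inside <- function(f, edge = 1) clamp(-f / edge, 0, 1)

all_fields <- function(state, config) {
  H <- config$height; W <- config$width
  fields <- list()
  for (tb in state$tubes) {
    fields[[length(fields) + 1L]] <-
      list(f = field_polyline(H, W, tb$cp, tb$hw), kind = "tube", id = tb$id)
  }
  for (s in state$spheres) {
    fields[[length(fields) + 1L]] <-
      list(f = field_disk(H, W, s$center, s$radius), kind = "sphere",
           id = s$id, type = s$type)
  }
  for (r in state$ruffles) {
    fields[[length(fields) + 1L]] <-
      list(f = field_polyline(H, W, r$pts, r$hw), kind = "ruffle")
  }
  fields
}

finish_frame <- function(img, config, channel, t) {
  img <- gaussian_blur(img, config$psf_sigma)
  if (config$noise_sd > 0) {
    img <- img + with_seed(frame_noise_seed(config, channel, t),
                           matrix(stats::rnorm(length(img), 0, config$noise_sd),
                                  nrow(img)))
  }
  pmax(img, 0)
}

#' Render a phase-contrast frame
#'
#' Organelle interiors are darker than the background (absorption), with a
#' bright halo ring of width ~`psf_sigma` at boundaries scaled by `halo_gain`;
#' the image is Gaussian-blurred with `psf_sigma`, Gaussian read noise of sd
#' `noise_sd` is added, and the result is clipped to be non-negative.
#'
#' @param state a [state_at()] snapshot
#' @param config the [sim_config()]
#' @return numeric matrix (height x width)
#' @export
render_phase_frame <- function(state, config) {
  bg <- config$background
  img <- matrix(bg, config$height, config$width)
  for (fd in all_fields(state, config)) {
    bb <- attr(fd$f, "bbox")
    if (is.null(bb) || bb[2] < bb[1]) next
    ri <- (bb[1]:bb[2]) + 1L; ci <- (bb[3]:bb[4]) + 1L
    f <- fd$f[ri, ci, drop = FALSE]
    finite <- is.finite(f)
    if (!any(finite)) next
    amp <- if (fd$kind == "ruffle") 0.85 else 1     # ruffles nearly tube-like
    add <- -amp * config$absorption * bg * soft_inside(f)
    if (config$halo_gain > 0) {
      halo <- exp(-f^2 / (2 * config$psf_sigma^2))
      halo[!finite] <- 0
      halo[f < -config$psf_sigma] <- 0              # ring sits on the boundary
      add <- add + amp * config$halo_gain * bg * 0.5 * halo
    }
    img[ri, ci] <- img[ri, ci] + add
  }
  finish_frame(img, config, "phase", state$t)
}

nucleus_field <- function(nuc, config) {
  H <- config$height; W <- config$width
  xs <- 0:(W - 1); ys <- 0:(H - 1)
  dx2 <- ((xs - nuc$center[1]) / nuc$rx)^2
  dy2 <- ((ys - nuc$center[2]) / nuc$ry)^2
  sqrt(outer(dy2, dx2, "+")) - 1                    # <0 inside the ellipse
}

# Fraction of TMRE signal retained along a tube at frame t (dropout mask per
# densified arclength sample), via the trajectory's flicker schedule.
tmre_retained <- function(traj, tube_id, t) {
  dr <- traj$tmre_dropouts
  dr[dr$tube == tube_id & dr$f0 <= t & dr$f1 >= t, , drop = FALSE]
}

#' Render a fluorescence frame for one channel
#'
#' Channel-specific structure: `mito_fluo` fills tubes; `ld_fluo` /
#' `lyso_fluo` fill the corresponding spheres; `drp1_fluo` renders puncta at
#' division sites that disassemble onto both daughter tips after scission;
#' `tmre` fills tubes with transient (1-3 s) subdomain dropouts; `hoechst`
#' renders the nucleus; `sytox` renders the nucleus only after cell death.
#' Intensities are multiplied by the remaining fluorophore pool (bleaching),
#' then blurred and noised as in phase.
#'
#' @param state a [state_at()] snapshot
#' @param channel fluorescence channel tag
#' @param config the [sim_config()]
#' @param traj the full trajectory (needed for `drp1_fluo` and `tmre`
#'   schedules); optional for the other channels
#' @param fluorophore_pool fraction of fluorophore remaining in this channel
#' @param sample_dead logical; has the cell died (drives `sytox`)
#' @return numeric matrix (height x width)
#' @export
render_fluorescence_frame <- function(state, channel, config, traj = NULL,
                                      fluorophore_pool = 1, sample_dead = FALSE) {
  if (!channel %in% FLUOR_CHANNELS)
    stop("render_fluorescence_frame: unknown fluorescence channel `",
         channel, "`")
  H <- config$height; W <- config$width
  amp <- 120 * fluorophore_pool                     # full-pool peak intensity
  img <- matrix(0, H, W)
  t <- state$t
  if (channel == "mito_fluo" || channel == "tmre") {
    for (tb in state$tubes) {
      f <- field_polyline(H, W, tb$cp, tb$hw)
      add <- amp * soft_inside(f)
      if (channel == "tmre" && !is.null(traj)) {
        dr <- tmre_retained(traj, tb$id, t)
        if (nrow(dr)) {
          # zero out the dropped arclength subdomain(s)
          d <- densify_polyline(tb$cp, tb$hw)
          n <- length(d$x)
          keep <- rep(TRUE, n)
          for (k in seq_len(nrow(dr))) {
            i0 <- max(1L, ceiling(dr$s0[k] * n)); i1 <- min(n, ceiling(dr$s1[k] * n))
            keep[i0:i1] <- FALSE
          }
          if (!all(keep)) {
            fk <- matrix(Inf, H, W)
            # field of the retained portion only
            run <- rle(keep)
            pos <- cumsum(c(1L, run$lengths))
            for (rr in seq_along(run$values)) {
              if (!run$values[rr]) next
              idx <- pos[rr]:(pos[rr + 1L] - 1L)
              if (length(idx) < 2L) next
              fk <- pmin(fk, field_polyline(H, W, cbind(d$x[idx], d$y[idx]),
                                            d$hw[idx]))
            }
            add <- amp * soft_inside(fk) + 0.15 * amp *
              (soft_inside(f) - soft_inside(fk))    # residual signal in dropout
            add <- pmax(add, 0)
          }
        }
      }
      img <- img + add
    }
  } else if (channel %in% c("ld_fluo", "lyso_fluo")) {
    want <- if (channel == "ld_fluo") "ld" else "lyso"
    for (s in state$spheres) {
      if (s$type != want) next
      img <- img + amp * soft_inside(field_disk(H, W, s$center, s$radius))
    }
  } else if (channel == "drp1_fluo") {
    if (is.null(traj))
      stop("render_fluorescence_frame: drp1_fluo requires `traj`")
    punctum <- function(center, intensity, sigma = 1.6) {
      xs <- 0:(W - 1); ys <- 0:(H - 1)
      intensity * exp(-outer((ys - center[2])^2, (xs - center[1])^2, "+") /
                        (2 * sigma^2))
    }
    for (dv in traj$divisions) {
      ev <- traj$events[traj$events$event_id == dv$event_id, ]
      if (!nrow(ev)) ev <- data.frame(t_start = dv$t_scission - 5L)
      if (t >= ev$t_start[1] && t <= dv$t_scission) {
        # assembling punctum at the constriction
        site <- traj$tubes[[dv$tube]]$cp[(dim(traj$tubes[[dv$tube]]$cp)[1] + 1L) %/% 2L, , t + 1L]
        img <- img + punctum(site, amp * 1.4)
      } else if (t > dv$t_scission) {
        # disassembly on both daughter tips (asymmetric split)
        decay <- exp(-(t - dv$t_scission) / 12)
        split <- 0.62                               # brighter-tip fraction
        for (j in 1:2) {
          dtube <- traj$tubes[[dv$daughters[j]]]
          if (!dtube$active[t + 1L]) next
          tip_row <- if (j == 1L) dim(dtube$cp)[1] else 1L
          tip <- dtube$cp[tip_row, , t + 1L]
          frac <- if (j == 1L) split else 1 - split
          img <- img + punctum(tip, amp * 1.4 * 2 * frac * decay)
        }
      }
    }
  } else if (channel == "hoechst") {
    img <- img + amp * soft_inside(nucleus_field(state$nucleus, config), 0.1)
  } else if (channel == "sytox") {
    if (sample_dead)
      img <- img + amp * soft_inside(nucleus_field(state$nucleus, config), 0.1)
  }
  finish_frame(img, config, channel, t)
}
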