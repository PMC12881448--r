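# Downstream quantifications: death scoring, survival fits, duty-cycle
# arithmetic, image quality, DRP1 ratios, TMRE tracking.

synth_nucleus_frame <- function(centers, radii, level, bg = 20, noise = 2,
                                shape = c(128, 128), seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(bg, shape[1], shape[2])
    xs <- 0:(shape[2] - 1); ys <- 0:(shape[1] - 1)
    for (i in seq_along(radii)) {
      d <- sqrt(outer((ys - centers[[i]][2])^2, (xs - centers[[i]][1])^2, "+"))
      m[d < radii[i]] <- bg + level[i]
    }
    m + matrix(stats::rnorm(prod(shape), 0, noise), shape[1])
  })
}

test_that("nucleus death scoring follows the 0.5 ratio cutoff", {
  centers <- list(c(35, 40), c(90, 80))
  hoechst <- synth_nucleus_frame(centers, c(12, 12), c(100, 100), seed = 1)
  # SYTOX present only in nucleus 2
  sytox <- synth_nucleus_frame(centers[2], 12, 100, seed = 2)
  res <- nucleus_death_ratio(sytox, hoechst)
  expect_equal(nrow(res), 2L)
  res <- res[order(res$x), ]
  expect_false(res$dead[1])
  expect_true(res$dead[2])
  expect_lt(res$ratio[1], 0.1)
  expect_gt(res$ratio[2], 0.9)
  # SYTOX identically zero: all ratios 0, all alive
  res0 <- nucleus_death_ratio(matrix(0, 128, 128), hoechst)
  expect_true(all(res0$ratio == 0) && !any(res0$dead))
  # equal channels: ratio ~1, dead
  res1 <- nucleus_death_ratio(hoechst, hoechst)
  expect_true(all(res1$dead) && all(abs(res1$ratio - 1) < 0.05))
  expect_warning(nucleus_death_ratio(matrix(0, 64, 64), matrix(0, 64, 64)),
                 "no nuclei")
})

test_that("death times are recovered within one 250 s sampling interval", {
  # cohort imaged every 250 s; each cell's SYTOX flips at its death time
  centers <- list(c(25, 25), c(75, 25), c(25, 75), c(75, 75))
  death_times <- c(400, 900, 1600, Inf)             # s; last cell survives
  hoechst <- synth_nucleus_frame(centers, rep(10, 4), rep(100, 4), seed = 3)
  grid <- seq(0, 2000, by = 250)
  recovered <- rep(NA_real_, 4)
  for (tt in grid) {
    on_now <- which(death_times <= tt)
    sytox <- synth_nucleus_frame(centers[on_now], rep(10, length(on_now)),
                                 rep(100, length(on_now)), seed = 4 + tt)
    res <- nucleus_death_ratio(sytox, hoechst)
    res <- res[order(res$y, res$x), ]
    ord <- order(vapply(centers, function(ce) ce[2] * 1000 + ce[1], numeric(1)))
    for (k in seq_len(4)) {
      i <- which(abs(res$x - centers[[k]][1]) < 5 & abs(res$y - centers[[k]][2]) < 5)
      if (length(i) == 1 && res$dead[i] && is.na(recovered[k])) recovered[k] <- tt
    }
  }
  expect_true(all(abs(recovered[1:3] - death_times[1:3]) <= 250))
  expect_true(is.na(recovered[4]))
})

test_that("survival curves and exponential fits", {
  tab <- data.frame(cell_id = 1:6, condition = "x",
                    death_time = c(10, 20, 30, 100, 100, 100),
                    censored = c(rep(FALSE, 3), rep(TRUE, 3)),
                    replicate = 1L)
  cur <- survival_curve(tab, c(0, 15, 25, 99))
  expect_equal(cur$mean, c(1, 5/6, 4/6, 3/6))
  expect_true(all(cur$sd == 0))                    # single replicate
  expect_true(all(diff(cur$mean) <= 0))            # non-increasing
  # no deaths -> flat 1
  tabn <- transform(tab, censored = TRUE, death_time = 100)
  expect_true(all(survival_curve(tabn, c(0, 50, 99))$mean == 1))
  # noiseless exponential: half-life = ln2 x 100 to high precision
  tgrid <- seq(0, 400, by = 5)
  fit <- fit_decay(data.frame(time = tgrid, mean = exp(-tgrid / 100)))
  expect_equal(fit$half_life, log(2) * 100, tolerance = 1e-6)
  expect_equal(fit$k, 0.01, tolerance = 1e-6)
  # identical fits give excess mortality 1
  expect_equal(excess_mortality(fit, fit, 100), 1)
  # non-decaying curve is clipped and flagged
  flat <- fit_decay(data.frame(time = tgrid, mean = rep(1, length(tgrid))))
  expect_true(flat$clipped)
  expect_gt(flat$half_life, 1e6)
})

test_that("duty-cycle arithmetic reproduces the reference frame counts", {
  m31 <- duty_cycle_model(3.1, 20, 1)
  m32 <- duty_cycle_model(3.2, 20, 1)
  expect_identical(continuous_frames_per_event(m31), 186L)
  expect_identical(continuous_frames_per_event(m32), 192L)
  expect_equal(fold_reduction(m31, 20), 9.3)
  expect_equal(round(fold_reduction(m31, 20)), 9)
  expect_equal(round(fold_reduction(m32, 20)), 10)
  expect_error(fold_reduction(m31, 0), "zero")
  # invariant to frame rate when triggered frames scale with it
  for (fr in c(0.5, 1, 2, 5)) {
    m <- duty_cycle_model(3.1, 20, fr)
    expect_equal(fold_reduction(m, 20 * fr), 9.3, tolerance = 1e-9)
  }
})

test_that("image quality metrics", {
  expect_equal(image_quality(rep(50, 10), c(4, 6, 5, 5, 4, 6))$snr,
               50 / sd(c(4, 6, 5, 5, 4, 6)))
  q <- image_quality(c(10, 10), c(10, 11, 9, 10))
  expect_equal(q$contrast, 0, tolerance = 0.01)
  expect_error(image_quality(1:3, rep(5, 4)), "zero-variance")
  # snr halves when noise sd doubles (rendered frames)
  st <- state_at(contact_traj(), 0)
  mask <- organelle_mask(st, contact_traj()$config, "tubes")
  # background region far from any structure (outside blur/halo tails)
  allmask <- organelle_mask(st, contact_traj()$config)
  bgm <- edascope:::gaussian_blur(allmask * 1, 4) < 1e-4
  snr_at <- function(nsd) {
    cfg <- tiny_sim_config(duration = 120, contact_rate = 1.2, seed = 11L,
                           noise_sd = nsd)
    f <- render_fluorescence_frame(st, "mito_fluo", cfg, contact_traj())
    image_quality(f[mask], f[bgm])$snr
  }
  r <- snr_at(2) / snr_at(4)
  expect_lt(abs(r - 2), 0.2)
})

test_that("drp1 tip ratios", {
  fr <- matrix(100, 64, 64)
  fr[21:23, 21:23] <- 120   # +20 x 9 px = 180 above offset
  fr[41:43, 41:43] <- 110   # 90 above offset
  r <- drp1_tip_ratio(fr, list(c(21, 21), c(41, 41)), camera_offset = 100)
  expect_equal(r$ratio, 2)
  # invariant under swapping tips; always >= 1
  r2 <- drp1_tip_ratio(fr, list(c(41, 41), c(21, 21)), camera_offset = 100)
  expect_equal(r2$ratio, r$ratio)
  expect_equal(drp1_tip_ratio(fr, list(c(21, 21), c(21 + 8, 21)),
                              camera_offset = 100)$ratio >= 1, TRUE)
  # equal tips -> 1
  expect_equal(drp1_tip_ratio(fr, list(c(21, 21), c(22 + 12, 21)),
                              camera_offset = 100)$intensities[1], 180)
  # zero lower intensity -> Inf, flagged
  rz <- drp1_tip_ratio(fr, list(c(21, 21), c(50, 50)), camera_offset = 100)
  expect_true(is.infinite(rz$ratio) && rz$flagged)
  expect_error(drp1_tip_ratio(fr, list(c(21, 21), c(22, 21)), 100), "overlap")
  expect_error(drp1_tip_ratio(fr, list(c(0, 0), c(30, 30)), 100), "outside")
})

test_that("simulated symmetric division keeps DRP1 on both tips (ratio band)", {
  traj <- division_traj()
  cfg <- traj$config
  dv <- traj$divisions[[1]]
  t <- dv$t_scission + 2L
  fl <- render_fluorescence_frame(state_at(traj, t), "drp1_fluo", cfg, traj)
  tips <- lapply(1:2, function(j) {
    dtube <- traj$tubes[[dv$daughters[j]]]
    tip_row <- if (j == 1L) dim(dtube$cp)[1] else 1L
    dtube$cp[tip_row, , t + 1L]
  })
  r <- drp1_tip_ratio(fl, tips, camera_offset = 0)
  expect_gte(r$ratio, 1)
  expect_lte(r$ratio, 2.5)   # both-tip retention, not single-sided
})

test_that("tmre tracker: identity stability, classification, flicker", {
  set.seed(12)
  TT <- 50
  mov <- lapply(1:TT, function(t) {
    m <- matrix(5, 64, 64) + matrix(rnorm(64 * 64, 0, 0.3), 64)
    m[10:14, (8 + t %/% 5):(18 + t %/% 5)] <- 50     # slowly moving bar
    # flicker dips but stays above the segmentation threshold (an overlap
    # tracker cannot bridge frames where the object vanishes entirely)
    m[40:44, 40:50] <- ifelse(t %in% 25:27, 30, 50)
    m
  })
  tc <- tmre_track_classify(mov, event_center = c(45, 42), event_t = 5,
                            radius_um = 1.5, pixel_size = 0.1)
  expect_equal(nrow(tc), 2L)                 # track count = object count
  expect_equal(sum(tc$contact_positive), 1L)
  expect_true(tc$contact_positive[tc$dist_px < 15])
  ii <- attr(tc, "intensity")
  expect_equal(nrow(ii), 2L)                 # identities stable over 50 frames
  expect_true(all(!is.na(ii)))
  # flicker dip recovered within one frame
  flick_track <- which(tc$contact_positive)
  d <- detect_flicker(ii[tc$track_id[flick_track], ], n_sd = 3, window = 20)
  expect_equal(nrow(d), 1L)
  expect_lte(abs(d$f0 - 24), 1)
  expect_lte(abs(d$duration - 3), 1)
  # a track 3 um away at 0.1 um/px is negative
  expect_false(tc$contact_positive[tc$dist_px > 15])
})

test_that("simulated tmre flicker is recovered from rendered movies", {
  cfg <- tiny_sim_config(duration = 200, n_mito = 2L, n_spheres = 0L,
                         n_ruffles = 0L, seed = 61L, noise_sd = 1)
  traj <- simulate_sample(cfg)
  dr <- traj$tmre_dropouts
  expect_gt(nrow(dr), 0)                  # deterministic at this config/seed
  dr <- dr[1, ]
  # mean intensity of the affected tube (its own per-frame mask) dips
  # during the dropout
  series <- vapply(0:(traj$n_frames - 1L), function(t) {
    st <- state_at(traj, t)
    f <- render_fluorescence_frame(st, "tmre", cfg, traj)
    mean(f[organelle_mask(st, cfg, paste0("tube:", dr$tube))])
  }, numeric(1))
  inside <- mean(series[(dr$f0:dr$f1) + 1L])
  outside <- mean(series[-((dr$f0:dr$f1) + 1L)])
  expect_lt(inside, 0.85 * outside)
})
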