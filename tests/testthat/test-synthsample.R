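# Simulator: event scheduling, trajectory realization, rendering, exposure.

test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(frame_rate = 0), "positive")
  expect_error(sim_config(contact_duration = 0.2, frame_rate = 1), ">= 1 frame")
  expect_error(sim_config(n_mito = -1), "non-negative")
  expect_error(sim_config(height = 48, width = 48, n_mito = 40L),
               "exceed what fits")
})

test_that("schedule_events draws Poisson contact/division schedules", {
  cfg <- sim_config(duration = 3600, seed = 1)
  # zero rate -> no events of that class
  ev0 <- schedule_events(sim_config(duration = 600, contact_rate = 0,
                                    division_rate = 0, seed = 1))
  expect_equal(nrow(ev0), 0L)
  # determinism
  expect_identical(schedule_events(cfg, seed = 42), schedule_events(cfg, seed = 42))
  expect_false(identical(schedule_events(cfg, seed = 42),
                         schedule_events(cfg, seed = 43)))
  # frames-in-span invariant and spans
  ev <- schedule_events(cfg)
  expect_true(all(ev$t_start <= ev$t_end))
  expect_true(all(ev$t_end < n_frames(cfg)))
  keep <- ev$class == "contact" & ev$polarity == "positive"
  spans <- ev$t_end[keep] - ev$t_start[keep] + 1L
  expect_true(all(spans == 20L))
  # Poisson mean: rate 2/min over 60 min across 40 seeds -> mean near 120
  cfg2 <- sim_config(duration = 3600, contact_rate = 2, near_miss_rate = 0,
                     division_rate = 0)
  counts <- vapply(1:40, function(s) nrow(schedule_events(cfg2, seed = s)),
                   numeric(1))
  se <- sqrt(120 / 40)
  expect_lt(abs(mean(counts) - 120), 3 * se + 2)  # +2 for boundary-clipped events
  # inter-event intervals at the reference contact rate ~ 186 s
  cfgr <- sim_config(duration = 40000, contact_rate = 1 / 3.1, division_rate = 0)
  iv <- unlist(lapply(1:6, function(s) {
    sch <- schedule_events(cfgr, seed = s)
    diff(sch$t_start[sch$polarity == "positive"])
  }))
  expect_lt(abs(mean(iv) - 186), 3 * 186 / sqrt(length(iv)) + 5)
})

test_that("simulate_sample realizes contacts with zero boundary distance", {
  traj <- contact_traj()
  ev <- traj$events[traj$events$polarity == "positive", ]
  expect_gt(nrow(ev), 0)
  e <- ev[1, ]
  tb <- traj$tubes[[e$tube]]; sp <- traj$spheres[[e$sphere]]
  dists <- vapply(e$t_start:e$t_end, function(t) {
    fi <- t + 1L
    edascope:::min_boundary_distance(tb$cp[, , fi], tb$hw[, fi],
                                     sp$center[, fi], sp$radius)
  }, numeric(1))
  # no visible separation for the whole event span (>= 3 frames)
  expect_gte(length(dists), 3L)
  expect_true(all(abs(dists) < 0.15))
})

test_that("divisions split the affected tube into two components", {
  traj <- division_traj()
  expect_gt(length(traj$divisions), 0)
  dv <- traj$divisions[[1]]
  cfg <- traj$config
  before <- organelle_mask(state_at(traj, dv$t_scission), cfg,
                           paste0("tube:", dv$tube))
  expect_equal(edascope:::count_components(before), 1L)
  st <- state_at(traj, dv$t_scission + 1L)
  after <- organelle_mask(st, cfg, paste0("tube:", dv$daughters[1])) |
    organelle_mask(st, cfg, paste0("tube:", dv$daughters[2]))
  expect_equal(edascope:::count_components(after), 2L)
  # parent inactive after scission
  expect_false(any(vapply(st$tubes, function(t) t$id == dv$tube, logical(1))))
})

test_that("trajectories are a pure function of (config, seed)", {
  cfg <- tiny_sim_config(contact_rate = 1, seed = 21L)
  t1 <- simulate_sample(cfg)
  t2 <- simulate_sample(cfg)
  expect_identical(t1$events, t2$events)
  expect_identical(t1$tubes[[1]]$cp, t2$tubes[[1]]$cp)
  t3 <- simulate_sample(tiny_sim_config(contact_rate = 1, seed = 22L))
  expect_false(identical(t1$tubes[[1]]$cp, t3$tubes[[1]]$cp))
  # frames identical too
  f1 <- render_phase_frame(state_at(t1, 3), cfg)
  f2 <- render_phase_frame(state_at(t2, 3), cfg)
  expect_identical(f1, f2)
})

test_that("phase rendering: absorption, halo, noise contracts", {
  cfg <- tiny_sim_config(noise_sd = 0, halo_gain = 0, seed = 2L)
  traj <- simulate_sample(cfg)
  st <- state_at(traj, 0)
  fr <- render_phase_frame(st, cfg)
  # pure blurred absorption: nothing exceeds the background constant
  expect_lte(max(fr), cfg$background + 1e-9)
  expect_lt(min(fr), cfg$background)
  expect_true(all(fr >= 0))
  # determinism without noise
  expect_identical(fr, render_phase_frame(st, cfg))
  # organelle/background contrast grows monotonically with absorption
  mask <- organelle_mask(st, cfg, "tubes")
  bgm <- !organelle_mask(st, cfg)
  contrast <- vapply(c(0.1, 0.2, 0.3, 0.45, 0.6), function(a) {
    cfa <- tiny_sim_config(noise_sd = 0, halo_gain = 0, absorption = a, seed = 2L)
    f <- render_phase_frame(st, cfa)
    abs(mean(f[mask]) - mean(f[bgm])) / mean(f[bgm])
  }, numeric(1))
  expect_true(all(diff(contrast) > 0))
})

test_that("fluorescence rendering follows channel structure", {
  traj <- contact_traj()
  cfg <- traj$config
  st <- state_at(traj, 2)
  # bleached-out pool leaves only the noise floor
  f0 <- render_fluorescence_frame(st, "mito_fluo", cfg, traj,
                                  fluorophore_pool = 0)
  expect_lt(max(f0), 6 * cfg$noise_sd)
  # mito channel bright inside tubes, dark elsewhere
  f1 <- render_fluorescence_frame(st, "mito_fluo", cfg, traj)
  mask <- organelle_mask(st, cfg, "tubes")
  expect_gt(mean(f1[mask]), 10 * mean(f1[!mask]))
  expect_error(render_fluorescence_frame(st, "nope", cfg), "unknown")
  # sytox renders the nucleus only after death
  fs_alive <- render_fluorescence_frame(st, "sytox", cfg, traj)
  fs_dead <- render_fluorescence_frame(st, "sytox", cfg, traj, sample_dead = TRUE)
  expect_lt(max(fs_alive), 10)
  expect_gt(max(fs_dead), 50)
})

test_that("drp1 puncta disassemble onto both daughter tips", {
  traj <- division_traj()
  cfg <- traj$config
  dv <- traj$divisions[[1]]
  ev <- traj$events[traj$events$event_id == dv$event_id, ]
  t <- dv$t_scission + 3L
  fl <- render_fluorescence_frame(state_at(traj, t), "drp1_fluo", cfg, traj)
  pk <- extract_peaks(fl / (max(fl) + 1e-9) * 0.99, 0.2, min_distance = 3, t = t)
  near <- pk[sqrt((pk$x - ev$x)^2 + (pk$y - ev$y)^2) <= 10, ]
  expect_equal(nrow(near), 2L)
})

test_that("tmre dropout durations live in the 1-3 s band", {
  cfg <- sim_config(duration = 3000, n_mito = 6, seed = 31L)
  traj <- simulate_sample(cfg)
  dr <- traj$tmre_dropouts
  expect_gt(nrow(dr), 5)
  expect_true(all(dr$dur_s >= 1 & dr$dur_s <= 3))
  durations_frames <- dr$f1 - dr$f0
  expect_true(all(durations_frames >= 1 & durations_frames <= 3))
})

test_that("apply_exposure: dose, bleaching, and death bookkeeping", {
  cfg <- tiny_sim_config(seed = 3L)
  spec <- exposure_spec("correlative", c("phase", "mito_fluo", "ld_fluo"))
  s <- new_cell_sample(cfg)
  s2 <- apply_exposure(s, spec, time = 0)
  inc_expected <- (2 + cfg$phase_dose_factor) * 35 * 100
  expect_equal(s2$accumulated_dose, inc_expected)
  expect_equal(s2$fluorophore_pool[["mito_fluo"]], 1 - cfg$bleach_rate)
  expect_equal(s2$fluorophore_pool[["tmre"]], 1)   # unexposed channel untouched
  # hazard 0 -> immortal
  cfg0 <- tiny_sim_config(hazard_coeff = 0, seed = 3L)
  s0 <- new_cell_sample(cfg0)
  for (i in 1:200) s0 <- apply_exposure(s0, spec, time = i)
  expect_true(s0$alive)
  # dose ledger replay equals accumulated dose; alive never reverts
  expect_equal(sum(s2$dose_ledger), s2$accumulated_dose)
  expect_error(apply_exposure(s, exposure_spec("surveillance", "phase",
                                               exposure_time = -1)),
               "non-negative")
})

test_that("Monte-Carlo survival matches the closed form", {
  # constant fluorescence hazard h per frame: S(t) ~ exp(-h t)
  cfg <- sim_config(duration = 600, hazard_coeff = 2e-6, seed = 17L)
  spec <- exposure_spec("correlative", c("phase", "mito_fluo"))
  h <- cfg$hazard_coeff * (1 + cfg$phase_dose_factor) * 35 * 100
  tab <- simulate_death_cohort(cfg, spec, n_cells = 500, n_frames_total = 600)
  tt <- c(50, 100, 200, 400)
  emp <- vapply(tt, function(t0) mean(tab$censored | tab$death_time > t0),
                numeric(1))
  expected <- exp(-h * tt)
  se <- sqrt(expected * (1 - expected) / 500)
  expect_true(all(abs(emp - expected) < 3 * se + 0.01))
})

test_that("phase cohort mortality is <= 1/100 of fluorescence mortality", {
  cfg <- sim_config(duration = 600, seed = 19L)
  fl <- simulate_death_cohort(cfg, exposure_spec("correlative",
                                                 c("phase", "mito_fluo")),
                              n_cells = 400, n_frames_total = 600)
  ph <- simulate_death_cohort(cfg, exposure_spec("surveillance", "phase"),
                              n_cells = 400, n_frames_total = 600)
  mort_fl <- mean(!fl$censored); mort_ph <- mean(!ph$censored)
  expect_gt(mort_fl, 0.5)
  expect_lte(mort_ph, mort_fl / 100)
})

test_that("virtual microscope acquisition contracts", {
  traj <- contact_traj()
  vm <- virtual_microscope(traj)
  a1 <- vm_acquire(vm, 0, exposure_spec("surveillance", "phase"))
  expect_named(a1$frames, "phase")
  a2 <- vm_acquire(vm, 1, exposure_spec("correlative",
                                        c("phase", "mito_fluo", "ld_fluo")))
  expect_length(a2$frames, 3L)
  expect_equal(a2$sample$accumulated_dose - a1$sample$accumulated_dose,
               (2 + traj$config$phase_dose_factor) * 35 * 100)
  # phase does not bleach fluorophores
  vm2 <- virtual_microscope(traj)
  for (t in 0:59) invisible(vm_acquire(vm2, t, exposure_spec("surveillance", "phase"),
                                       render = FALSE))
  expect_true(all(vm2$sample$fluorophore_pool == 1))
  expect_error(vm_acquire(vm, traj$n_frames, exposure_spec("surveillance", "phase")),
               class = "eda_end_of_acquisition")
})
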