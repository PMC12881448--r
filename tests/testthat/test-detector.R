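# Heatmap labels, soft focal loss, both detector architectures, training.

test_that("render_labels places unit-peak Gaussians on the last five frames", {
  ev <- mk_events(10, 20, 32, 32)
  shape <- c(64, 64)
  expect_equal(render_labels(ev, 5, shape, 4), matrix(0, 64, 64))
  m <- render_labels(ev, 20, shape, 4)
  expect_equal(m[33, 33], 1.0)
  # value at 3 sigma distance: exp(-4.5)
  expect_equal(m[33, 33 + 12], exp(-4.5), tolerance = 1e-12)
  # sixth-from-last frame not labeled
  expect_equal(max(render_labels(ev, 15, shape, 4)), 0)
  expect_equal(max(render_labels(ev, 16, shape, 4)), 1)
  # negative events never labeled
  evn <- mk_events(10, 20, 32, 32, polarity = "negative")
  expect_equal(max(render_labels(evn, 20, shape, 4)), 0)
  # overlap combines by max and stays in [0,1]; order-invariant
  ev2 <- mk_events(c(10, 12), c(20, 20), c(32, 35), c(32, 32))
  m2 <- render_labels(ev2, 20, shape, 4)
  expect_lte(max(m2), 1)
  expect_identical(m2, render_labels(ev2[2:1, ], 20, shape, 4))
  expect_error(render_labels(mk_events(1, 2, 200, 10), 2, shape, 4), "outside")
})

test_that("soft focal loss: closed forms and the BCE limit", {
  # pred == target in {0,1} -> loss 0
  tg <- matrix(c(0, 1, 0, 1), 2)
  expect_equal(soft_focal_loss(tg, tg, 2), 0, tolerance = 1e-6)
  # worked value: pred 0.5, target 0, gamma 2 -> 0.25 ln 2 per pixel
  p <- matrix(0.5, 8, 8); z <- matrix(0, 8, 8)
  expect_equal(soft_focal_loss(p, z, 2), 0.25 * log(2), tolerance = 1e-12)
  # gamma 0 == BCE to 1e-12 on random soft inputs
  set.seed(3)
  for (i in 1:20) {
    pr <- matrix(runif(64, 0.01, 0.99), 8)
    tgt <- matrix(runif(64), 8)
    bce <- mean(-tgt * log(pr) - (1 - tgt) * log(1 - pr))
    expect_equal(soft_focal_loss(pr, tgt, 0), bce, tolerance = 1e-12)
    expect_gte(soft_focal_loss(pr, tgt, 2), 0)
  }
  # exact 0/1 predictions are clamped, never NaN
  expect_true(is.finite(soft_focal_loss(matrix(c(0, 1), 1), matrix(c(1, 0), 1), 2)))
})

test_that("build_detector: shape/range contracts and config validation", {
  expect_error(detector_config(stateful = TRUE, n_time_points = 1), "stateful")
  cfg <- detector_config(n_time_points = 5, initial_filters = 4, seed = 3)
  det <- build_detector(cfg)
  w <- array(runif(64 * 64 * 5), c(64, 64, 5))
  m <- infer(det, w)
  expect_equal(dim(m), c(64, 64))
  expect_true(all(m >= 0 & m <= 1))
  expect_error(infer(det, w[, , 1:3]), "n_time_points")
  # fixed seed -> identical untrained outputs across builds
  det2 <- build_detector(cfg)
  expect_identical(m, infer(det2, w))
  # different seed -> different weights
  det3 <- build_detector(detector_config(n_time_points = 5,
                                         initial_filters = 4, seed = 4))
  expect_false(identical(m, infer(det3, w)))
})

test_that("compiled patch kernels agree with the pure-R reference", {
  set.seed(8)
  for (d in list(c(6, 8, 2, 3), c(12, 12, 1, 1), c(8, 6, 3, 5))) {
    x <- array(rnorm(prod(d)), d)
    expect_equal(edascope:::im2col3(x), edascope:::im2col3_ref(x))
    dxp <- matrix(rnorm(d[1] * d[2] * d[3] * 9 * d[4]),
                  d[1] * d[2] * d[3], 9 * d[4])
    expect_equal(edascope:::col2im3(dxp, d[1], d[2], d[3], d[4]),
                 edascope:::col2im3_ref(dxp, d[1], d[2], d[3], d[4]))
  }
})

test_that("backprop matches finite differences (both architectures)", {
  set.seed(42)
  for (stateful in c(FALSE, TRUE)) {
    cfg <- detector_config(n_time_points = 3, stateful = stateful,
                           initial_filters = 2, seed = 7)
    det <- build_detector(cfg)
    x <- array(runif(8 * 8 * 2 * 3), c(8, 8, 2, 3))
    tg <- array(runif(8 * 8 * 2), c(8, 8, 2, 1))
    fwd <- function(p) if (stateful) edascope:::stateful_fwd(p, x, 2)
                       else edascope:::unet_fwd(p, x, 2)
    fw <- fwd(det$params)
    dz <- edascope:::soft_focal_grad_z(fw$y, tg, 0)
    gr <- if (stateful) edascope:::stateful_bwd(det$params, fw, dz, 2)
          else edascope:::unet_bwd(det$params, fw, dz, 2)
    nbad <- 0L
    for (nm in names(det$params)) {
      v <- det$params[[nm]]$W
      for (k in sample(length(v), min(4, length(v)))) {
        eps <- 1e-5
        p1 <- det$params; p1[[nm]]$W[k] <- v[k] + eps
        p2 <- det$params; p2[[nm]]$W[k] <- v[k] - eps
        num <- (soft_focal_loss(fwd(p1)$y, tg, 0) -
                  soft_focal_loss(fwd(p2)$y, tg, 0)) / (2 * eps)
        rel <- abs(num - gr[[nm]]$W[k]) /
          max(1e-8, abs(num) + abs(gr[[nm]]$W[k]))
        if (rel > 1e-4) nbad <- nbad + 1L
      }
    }
    # allow at most one ReLU-kink artifact among the sampled weights
    expect_lte(nbad, 1L)
  }
})

test_that("non-stateful detector is translation-covariant", {
  cfg <- detector_config(n_time_points = 1, initial_filters = 8, seed = 12)
  det <- build_detector(cfg)
  set.seed(5)
  base <- matrix(0.1, 64, 64)
  base[28:36, 28:36] <- 1
  m1 <- infer(det, base)
  shifted <- matrix(0.1, 64, 64)
  shifted[36:44, 28:36] <- 1                 # shift by +8 rows
  m2 <- infer(det, shifted)
  # compare away from borders
  p1 <- which(m1[15:50, 15:50] == max(m1[15:50, 15:50]), arr.ind = TRUE)[1, ]
  p2 <- which(m2[15:50, 15:50] == max(m2[15:50, 15:50]), arr.ind = TRUE)[1, ]
  expect_lte(abs((p2[1] - p1[1]) - 8), 1)
  expect_lte(abs(p2[2] - p1[2]), 1)
})

test_that("stateful detector: memory, reset, and temporal sensitivity", {
  cfg <- detector_config(n_time_points = 3, stateful = TRUE,
                         initial_filters = 4, seed = 9)
  det <- build_detector(cfg)
  set.seed(6)
  w <- array(runif(32 * 32 * 3), c(32, 32, 3))
  det <- reset_state(det)
  m1 <- infer(det, w)
  # without reset the hidden state carries over: same window, new answer
  m2 <- infer(det, w)
  expect_false(identical(m1, m2))
  # reset restores the initial state exactly
  det <- reset_state(det)
  expect_identical(infer(det, w), m1)
  # frame order matters for a dynamic window ...
  det <- reset_state(det)
  mp <- infer(det, w[, , c(2, 3, 1)])
  expect_false(identical(m1, mp))
  # ... but not for a constant-in-time window
  wc <- array(rep(w[, , 1], 3), c(32, 32, 3))
  det <- reset_state(det)
  mc1 <- infer(det, wc)
  det <- reset_state(det)
  expect_identical(mc1, infer(det, wc[, , c(3, 1, 2)]))
})

test_that("infer_sequence: padding, reset reproducibility, streaming equivalence", {
  cfg <- detector_config(n_time_points = 3, initial_filters = 4, seed = 2)
  det <- build_detector(cfg)
  set.seed(10)
  movie <- array(runif(32 * 32 * 6) * 50, c(32, 32, 6))
  maps <- infer_sequence(det, movie)
  expect_length(maps, 6L)
  # streaming through analyzer_step equals infer_sequence (same padding)
  st <- acquisition_state(controller_config(buffer_length = 3L))
  for (t in 0:5) {
    an <- analyzer_step(st, movie[, , t + 1], det, t)
    st <- an$state
    expect_equal(an$score_map, maps[[t + 1]], tolerance = 1e-12)
  }
  # stateful: reset -> run -> reset -> run is reproducible
  dets <- build_detector(detector_config(n_time_points = 3, stateful = TRUE,
                                         initial_filters = 4, seed = 2))
  s1 <- infer_sequence(dets, movie)
  s2 <- infer_sequence(dets, movie)
  expect_identical(s1, s2)
})

test_that("training reduces the loss and is seed-deterministic", {
  movies <- make_event_movies("contact", n_events = 4L, seed = 77L,
                              size = 40L, duration = 40)
  ts <- make_crop_dataset(movies, n_time_points = 3)
  expect_true(all(table(ts$event_id, ts$split)[, 1] == 0 |
                    table(ts$event_id, ts$split)[, 2] == 0))  # split by event
  cfg <- detector_config(n_time_points = 3, initial_filters = 8,
                         epochs = 3, seed = 5)
  det <- train_detector(build_detector(cfg), ts)
  expect_lt(utils::tail(det$loss_history, 1), det$loss_history[1])
  det2 <- train_detector(build_detector(cfg), ts)
  expect_identical(det$loss_history, det2$loss_history)
  expect_identical(det$params, det2$params)
  expect_error(train_detector(build_detector(cfg),
                              structure(list(x = ts$x, y = ts$y,
                                             event_id = ts$event_id,
                                             split = rep("validation", length(ts$split)),
                                             t_end = ts$t_end),
                                        class = "training_set")),
               "empty training split")
})

test_that("consistency filter retains events by mean peak score", {
  expect_true(consistency_retain(c(0.9, 0.8, 0.7, 0.9, 0.8), 0.36))
  expect_equal(mean(c(0.9, 0.8, 0.7, 0.9, 0.8)), 0.82)
  expect_false(consistency_retain(rep(0, 5), 0.36))
  expect_true(consistency_retain(c(0.1, 0.0, 0.1), 0))      # any positive score
  expect_false(consistency_retain(c(0.5, 0.2), 0.36, statistic = "min"))
  expect_true(consistency_retain(c(0.5, 0.4), 0.36, statistic = "min"))
})

test_that("refine_labels scores labeled frames through a detector", {
  # an oracle-scored movie: use labels as a perfectly consistent detector by
  # training a tiny net is overkill here — instead check the plumbing with a
  # constant-output untrained detector (scores ~0.5 everywhere)
  cfg <- detector_config(n_time_points = 1, initial_filters = 2, seed = 1)
  det <- build_detector(cfg)
  movie <- array(runif(32 * 32 * 12), c(32, 32, 12))
  ev <- mk_events(c(2, 6), c(6, 10), c(10, 20), c(10, 20))
  out <- refine_labels(ev, det, movie, consistency_threshold = 0.01)
  expect_equal(nrow(out), 2L)            # untrained scores ~0.5 > 0.01
  out2 <- refine_labels(ev, det, movie, consistency_threshold = 0.99)
  expect_equal(nrow(out2), 0L)
  expect_true(all(out$consistency_score > 0.01))
  expect_error(refine_labels(mk_events(20, 30, 5, 5), det, movie), "labeled frames")
})
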