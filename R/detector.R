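# Heatmap event detectors: channel-stacked U-Net and stateful U-Net with a
# convolutional LSTM memory bottleneck. Implemented directly on the
# primitives in nn-ops.R; all randomness is seeded.

#' Detector configuration
#'
#' @param n_time_points frames per input window (1, 3, or 5 typical). For the
#'   non-stateful detector the frames are stacked as input channels; for the
#'   stateful detector this is the backpropagation-through-time window.
#' @param stateful use the recurrent ConvLSTM bottleneck (requires
#'   `n_time_points >= 2`)
#' @param depth U-Net depth (levels of pooling; default 2)
#' @param initial_filters filters at the first level, doubling per level
#'   (default 16)
#' @param loss "soft_focal" or "bce"
#' @param gamma focusing exponent of the soft focal loss
#' @param alpha positive-pixel balancing weight used during training (the
#'   per-pixel loss is scaled by `1 + alpha x target`); 0 disables
#' @param learning_rate,epochs,batch_size optimizer settings (adaptive moment
#'   estimation)
#' @param sigma_label Gaussian label sd in pixels
#' @param seed seed for weight init and batch shuffling
#' @return object of class `detector_config`
#' @export
detector_config <- function(n_time_points = 3L, stateful = FALSE,
                            depth = 2L, initial_filters = 16L,
                            loss = c("soft_focal", "bce"), gamma = 2,
                            alpha = 8, learning_rate = 1e-3, epochs = 30L,
                            batch_size = 8L, sigma_label = 4, seed = 1L) {
  loss <- match.arg(loss)
  stopifnot(n_time_points >= 1, depth >= 1, initial_filters >= 1,
            gamma >= 0, alpha >= 0, learning_rate > 0, epochs >= 1,
            batch_size >= 1)
  if (stateful && n_time_points < 2)
    stop("detector_config: stateful requires n_time_points >= 2")
  structure(list(n_time_points = as.integer(n_time_points),
                 stateful = isTRUE(stateful), depth = as.integer(depth),
                 initial_filters = as.integer(initial_filters),
                 loss = loss, gamma = gamma, alpha = alpha,
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 sigma_label = sigma_label, seed = as.integer(seed)),
            class = "detector_config")
}

#' Build an (untrained) detector
#'
#' Non-stateful: encoder-decoder with skip connections, `depth` levels,
#' `initial_filters` doubling per level, the `n_time_points` input frames
#' stacked as channels, and a sigmoidal single-channel score head. Stateful:
#' the same encoder applied identically to each frame (time-distributed), a
#' convolutional LSTM consuming the encoder sequence at the bottleneck, and a
#' decoder with skip connections from the last frame's encoder features.
#'
#' @param config a [detector_config()]
#' @return object of class `c("unet_detector", "eda_detector")`
#' @export
build_detector <- function(config) {
  stopifnot(inherits(config, "detector_config"))
  F0 <- config$initial_filters; d <- config$depth
  cin <- if (config$stateful) 1L else config$n_time_points
  params <- with_seed(substream_seed(config$seed, "init"), {
    p <- list()
    ch <- cin
    for (i in seq_len(d)) {
      co <- F0 * 2^(i - 1L)
      p[[paste0("enc", i)]] <- init_conv(9L * ch, co)
      ch <- co
    }
    if (config$stateful) {
      # memory bottleneck: hidden width = its input width (desk-scale choice)
      cb <- F0 * 2^(d - 1L)
      p$lstm <- init_conv(9L * (ch + cb), 4L * cb, gain = 1)
      p$lstm$b[cb + seq_len(cb)] <- 1          # forget-gate bias
    } else {
      cb <- F0 * 2^d
      p$bott <- init_conv(9L * ch, cb)
    }
    ch <- cb
    for (i in rev(seq_len(d))) {
      skip <- F0 * 2^(i - 1L)
      p[[paste0("dec", i)]] <- init_conv(9L * (ch + skip), skip)
      ch <- skip
    }
    p$out <- init_conv(ch, 1L, gain = 1)
    p
  })
  st <- new.env(parent = emptyenv())
  st$h <- NULL; st$c <- NULL
  structure(list(config = config, params = params, state = st,
                 needs_pixels = TRUE, trained = FALSE,
                 loss_history = numeric(0)),
            class = c("unet_detector", "eda_detector"))
}

#' @export
print.unet_detector <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<unet_detector> %s, %d time point(s), depth %d, %d initial filters, %s loss%s\n",
              if (cfg$stateful) "stateful (ConvLSTM bottleneck)" else "channel-stacked",
              cfg$n_time_points, cfg$depth, cfg$initial_filters, cfg$loss,
              if (x$trained) sprintf(", trained (%d epochs)",
                                     length(x$loss_history)) else ", untrained"))
  invisible(x)
}

# ---- forward / backward -----------------------------------------------------

# Shared encoder: x [H,W,B,Cin] -> pooled bottleneck input + per-level caches.
encoder_fwd <- function(params, x, depth) {
  caches <- list()
  cur <- x
  for (i in seq_len(depth)) {
    cv <- conv3_fwd(cur, params[[paste0("enc", i)]])
    rl <- relu_fwd(cv$y)
    pl <- maxpool_fwd(rl$y)
    caches[[i]] <- list(cv = cv, rl = rl, pl = pl, e = rl$y)
    cur <- pl$y
  }
  list(out = cur, caches = caches)
}

encoder_bwd <- function(params, caches, dout, depth, grads,
                        dskips = NULL) {
  dcur <- dout
  for (i in rev(seq_len(depth))) {
    dcur <- maxpool_bwd(dcur, caches[[i]]$pl)
    if (!is.null(dskips) && !is.null(dskips[[i]])) dcur <- dcur + dskips[[i]]
    dcur <- relu_bwd(dcur, caches[[i]]$rl)
    bw <- conv3_bwd(dcur, caches[[i]]$cv, params[[paste0("enc", i)]])
    nm <- paste0("enc", i)
    grads[[nm]]$W <- grads[[nm]]$W + bw$dW
    grads[[nm]]$b <- grads[[nm]]$b + bw$db
    dcur <- bw$dx
  }
  list(grads = grads, dx = dcur)
}

decoder_fwd <- function(params, bott, enc_caches, depth) {
  caches <- list()
  cur <- bott
  for (i in rev(seq_len(depth))) {
    up <- upsample_fwd(cur)
    cc <- concat_c(up, enc_caches[[i]]$e)
    cv <- conv3_fwd(cc, params[[paste0("dec", i)]])
    rl <- relu_fwd(cv$y)
    caches[[i]] <- list(cv = cv, rl = rl, c_up = dim(up)[4])
    cur <- rl$y
  }
  hd <- conv1_fwd(cur, params$out)
  y <- sigmoid(hd$y)
  list(y = y, caches = caches, head = hd)
}

decoder_bwd <- function(params, caches, head, dz, depth, grads) {
  # dz is the gradient wrt the sigmoid PRE-activation of the head
  bw <- conv1_bwd(dz, head, params$out)
  grads$out$W <- grads$out$W + bw$dW
  grads$out$b <- grads$out$b + bw$db
  dcur <- bw$dx
  dskips <- vector("list", depth)
  for (i in seq_len(depth)) {
    dcur <- relu_bwd(dcur, caches[[i]]$rl)
    bw <- conv3_bwd(dcur, caches[[i]]$cv, params[[paste0("dec", i)]])
    nm <- paste0("dec", i)
    grads[[nm]]$W <- grads[[nm]]$W + bw$dW
    grads[[nm]]$b <- grads[[nm]]$b + bw$db
    sp <- split_c(bw$dx, caches[[i]]$c_up)
    dskips[[i]] <- sp[[2]]
    dcur <- upsample_bwd(sp[[1]])
  }
  list(grads = grads, dbott = dcur, dskips = dskips)
}

# Non-stateful forward. x [H,W,B,Cin]; returns score [H,W,B,1] + caches.
unet_fwd <- function(params, x, depth) {
  en <- encoder_fwd(params, x, depth)
  bt_cv <- conv3_fwd(en$out, params$bott)
  bt_rl <- relu_fwd(bt_cv$y)
  de <- decoder_fwd(params, bt_rl$y, en$caches, depth)
  list(y = de$y, en = en, bt = list(cv = bt_cv, rl = bt_rl), de = de)
}

unet_bwd <- function(params, fw, dz, depth) {
  grads <- zero_grads(params)
  db <- decoder_bwd(params, fw$de$caches, fw$de$head, dz, depth, grads)
  grads <- db$grads
  dbt <- relu_bwd(db$dbott, fw$bt$rl)
  bw <- conv3_bwd(dbt, fw$bt$cv, params$bott)
  grads$bott$W <- grads$bott$W + bw$dW
  grads$bott$b <- grads$bott$b + bw$db
  eb <- encoder_bwd(params, fw$en$caches, bw$dx, depth, grads,
                    dskips = db$dskips)
  eb$grads
}

convlstm_step <- function(params, x, h, c) {
  cb <- length(params$lstm$b) %/% 4L
  cv <- conv3_fwd(concat_c(x, h), params$lstm)
  z <- cv$y
  i <- sigmoid(z[, , , seq_len(cb), drop = FALSE])
  f <- sigmoid(z[, , , cb + seq_len(cb), drop = FALSE])
  o <- sigmoid(z[, , , 2L * cb + seq_len(cb), drop = FALSE])
  g <- tanh(z[, , , 3L * cb + seq_len(cb), drop = FALSE])
  cn <- f * c + i * g
  tc <- tanh(cn)
  hn <- o * tc
  list(h = hn, c = cn, cache = list(cv = cv, i = i, f = f, o = o, g = g,
                                    c_prev = c, tc = tc, cx = dim(x)[4]))
}

convlstm_step_bwd <- function(params, cache, dh, dc, grads) {
  i <- cache$i; f <- cache$f; o <- cache$o; g <- cache$g; tc <- cache$tc
  do <- dh * tc
  dc <- dc + dh * o * (1 - tc^2)
  di <- dc * g
  dg <- dc * i
  df <- dc * cache$c_prev
  dc_prev <- dc * f
  dz_parts <- list(di * i * (1 - i), df * f * (1 - f),
                   do * o * (1 - o), dg * (1 - g^2))
  d1 <- dim(i)
  dz <- array(0, c(d1[1], d1[2], d1[3], 4L * d1[4]))
  for (q in 1:4) dz[, , , (q - 1L) * d1[4] + seq_len(d1[4])] <- dz_parts[[q]]
  bw <- conv3_bwd(dz, cache$cv, params$lstm)
  grads$lstm$W <- grads$lstm$W + bw$dW
  grads$lstm$b <- grads$lstm$b + bw$db
  sp <- split_c(bw$dx, cache$cx)
  list(dx = sp[[1]], dh_prev = sp[[2]], dc_prev = dc_prev, grads = grads)
}

# Stateful forward over a window. x [H,W,B,T] (single-channel frames along T);
# h0/c0 NULL means zeros. Returns last-frame score + all caches for BPTT.
stateful_fwd <- function(params, x, depth, h0 = NULL, c0 = NULL) {
  d <- dim(x); TT <- d[4]
  cb <- length(params$lstm$b) %/% 4L
  hw <- c(d[1] %/% 2^depth, d[2] %/% 2^depth)
  if (is.null(h0)) h0 <- array(0, c(hw[1], hw[2], d[3], cb))
  if (is.null(c0)) c0 <- array(0, c(hw[1], hw[2], d[3], cb))
  h <- h0; c <- c0
  enc <- vector("list", TT); lstm <- vector("list", TT)
  for (t in seq_len(TT)) {
    xt <- x[, , , t, drop = FALSE]
    en <- encoder_fwd(params, xt, depth)
    st <- convlstm_step(params, en$out, h, c)
    h <- st$h; c <- st$c
    enc[[t]] <- en; lstm[[t]] <- st$cache
  }
  de <- decoder_fwd(params, h, enc[[TT]]$caches, depth)
  list(y = de$y, enc = enc, lstm = lstm, de = de, h = h, c = c, TT = TT)
}

stateful_bwd <- function(params, fw, dz, depth) {
  grads <- zero_grads(params)
  db <- decoder_bwd(params, fw$de$caches, fw$de$head, dz, depth, grads)
  grads <- db$grads
  dh <- db$dbott
  dc <- dh * 0
  for (t in rev(seq_len(fw$TT))) {
    sb <- convlstm_step_bwd(params, fw$lstm[[t]], dh, dc, grads)
    grads <- sb$grads
    eb <- encoder_bwd(params, fw$enc[[t]]$caches, sb$dx, depth, grads,
                      dskips = if (t == fw$TT) db$dskips else NULL)
    grads <- eb$grads
    dh <- sb$dh_prev; dc <- sb$dc_prev
  }
  grads
}

# ---- inference --------------------------------------------------------------

as_window_array <- function(window) {
  if (is.matrix(window)) window <- array(window, c(dim(window), 1L))
  stopifnot(length(dim(window)) == 3L)
  window
}

#' Run a detector on one input window
#'
#' The non-stateful detector requires exactly `n_time_points` frames and is a
#' pure function of the window. The stateful detector steps its hidden state
#' through every frame of the window (starting from the current state) and
#' returns the score map of the last frame; use [reset_state()] between
#' movies.
#'
#' @param detector a built [build_detector()] object
#' @param window \[H, W, T\] array (or a matrix for T = 1) of normalized
#'   frames, oldest first
#' @return score matrix in \[0,1\]
#' @export
infer <- function(detector, window) {
  stopifnot(inherits(detector, "unet_detector"))
  window <- as_window_array(window)
  cfg <- detector$config
  d <- dim(window)
  if (d[3] != cfg$n_time_points && !cfg$stateful)
    stop("infer: window length ", d[3], " != n_time_points ", cfg$n_time_points)
  if (d[1] %% 2^cfg$depth != 0 || d[2] %% 2^cfg$depth != 0)
    stop("infer: frame size must be divisible by 2^depth")
  if (cfg$stateful) {
    h <- detector$state$h; c <- detector$state$c
    x <- array(window, c(d[1], d[2], 1L, d[3]))
    fw <- stateful_fwd(detector$params, x, cfg$depth, h, c)
    detector$state$h <- fw$h; detector$state$c <- fw$c
    matrix(fw$y, d[1], d[2])
  } else {
    x <- array(window, c(d[1], d[2], 1L, d[3]))
    fw <- unet_fwd(detector$params, x, cfg$depth)
    matrix(fw$y, d[1], d[2])
  }
}

#' @export
reset_state.unet_detector <- function(detector) {
  detector$state$h <- NULL
  detector$state$c <- NULL
  detector
}

#' @export
eda_infer.unet_detector <- function(detector, window, t = NULL) {
  window <- as_window_array(window)
  if (detector$config$stateful) {
    # streaming semantics: the analyzer feeds overlapping windows, so only
    # the newest frame advances the recurrent state
    d <- dim(window)
    infer(detector, window[, , d[3], drop = FALSE])
  } else {
    infer(detector, window)
  }
}

#' Run a detector over a whole movie
#'
#' One score map per frame. The non-stateful detector sees rolling windows,
#' left-padded by repeating the first frame; the stateful detector is reset
#' and then carries its state frame to frame.
#'
#' @param detector a detector
#' @param movie \[H, W, T\] array or list of frame matrices
#' @param normalize percentile-normalize frames before inference
#' @return list of score matrices, one per frame
#' @export
infer_sequence <- function(detector, movie, normalize = TRUE) {
  if (is.list(movie)) movie <- array(unlist(movie),
                                     c(dim(movie[[1]]), length(movie)))
  d <- dim(movie)
  if (normalize)
    for (t in seq_len(d[3])) movie[, , t] <- normalize_frame(movie[, , t])
  cfg <- detector$config
  out <- vector("list", d[3])
  if (cfg$stateful) {
    detector <- reset_state(detector)
    for (t in seq_len(d[3]))
      out[[t]] <- infer(detector, movie[, , t, drop = FALSE])
  } else {
    np <- cfg$n_time_points
    for (t in seq_len(d[3])) {
      idx <- pmax(1L, (t - np + 1L):t)
      out[[t]] <- infer(detector, movie[, , idx, drop = FALSE])
    }
  }
  out
}
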