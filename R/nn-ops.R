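# Minimal CNN primitives on [H, W, B, C] arrays (batch-third layout so the
# im2col patch matrix rows enumerate (H, W, B) and a single BLAS gemm does the
# convolution for the whole batch). All backward passes are hand-derived.

# -- 3x3 "same" convolution ---------------------------------------------------

# x [H,W,B,Cin] -> patch matrix [(H*W*B) x (9*Cin)], zero-padded borders.
# Column order: offset k (1..9, (di, dj) column-major) fastest, channel slow.
# Compiled kernel; im2col3_ref is the pure-R reference used in tests.
im2col3 <- function(x) {
  d <- dim(x)
  im2col3_cpp(x, d[1], d[2], d[3], d[4])
}

im2col3_ref <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; B <- d[3]; C <- d[4]
  xp <- array(0, c(H, W, B, 9L, C))
  k <- 0L
  for (dj in -1:1) for (di in -1:1) {
    k <- k + 1L
    ti <- max(1L, 1L - di):min(H, H - di)
    tj <- max(1L, 1L - dj):min(W, W - dj)
    xp[ti, tj, , k, ] <- x[ti + di, tj + dj, , , drop = FALSE]
  }
  dim(xp) <- c(H * W * B, 9L * C)
  xp
}

col2im3 <- function(dxp, H, W, B, C) {
  dx <- col2im3_cpp(dxp, H, W, B, C)
  dim(dx) <- c(H, W, B, C)
  dx
}

col2im3_ref <- function(dxp, H, W, B, C) {
  dim(dxp) <- c(H, W, B, 9L, C)
  dx <- array(0, c(H, W, B, C))
  k <- 0L
  for (dj in -1:1) for (di in -1:1) {
    k <- k + 1L
    ti <- max(1L, 1L - di):min(H, H - di)
    tj <- max(1L, 1L - dj):min(W, W - dj)
    add <- dxp[ti, tj, , k, , drop = FALSE]
    dim(add) <- dim(add)[-4L]
    dx[ti + di, tj + dj, , ] <- dx[ti + di, tj + dj, , , drop = FALSE] + add
  }
  dx
}

conv3_fwd <- function(x, p) {
  d <- dim(x)
  out <- conv3_fwd_cpp(x, d[1], d[2], d[3], d[4], p$W, p$b)
  y <- out$y
  dim(y) <- c(d[1], d[2], d[3], ncol(p$W))
  list(y = y, xp = out$xp, xdim = d)
}

conv3_bwd <- function(dy, cache, p) {
  d <- cache$xdim
  dim(dy) <- c(d[1] * d[2] * d[3], length(p$b))
  out <- conv3_bwd_cpp(dy, cache$xp, p$W, d[1], d[2], d[3], d[4])
  dx <- out$dx
  dim(dx) <- d
  list(dx = dx, dW = out$dW, db = out$db)
}

# pure-R reference path (cross-checked in tests)
conv3_fwd_ref <- function(x, p) {
  d <- dim(x)
  xp <- im2col3_ref(x)
  y <- xp %*% p$W
  y <- sweep(y, 2, p$b, "+")
  dim(y) <- c(d[1], d[2], d[3], ncol(p$W))
  list(y = y, xp = xp, xdim = d)
}

conv3_bwd_ref <- function(dy, cache, p) {
  d <- cache$xdim
  dim(dy) <- c(d[1] * d[2] * d[3], length(p$b))
  dW <- crossprod(cache$xp, dy)
  db <- colSums(dy)
  dxp <- tcrossprod(dy, p$W)
  dx <- col2im3_ref(dxp, d[1], d[2], d[3], d[4])
  list(dx = dx, dW = dW, db = db)
}

# -- 1x1 convolution ----------------------------------------------------------

conv1_fwd <- function(x, p) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2] * d[3], d[4])
  y <- sweep(xm %*% p$W, 2, p$b, "+")
  dim(y) <- c(d[1], d[2], d[3], ncol(p$W))
  list(y = y, xm = xm, xdim = d)
}

conv1_bwd <- function(dy, cache, p) {
  d <- cache$xdim
  dim(dy) <- c(d[1] * d[2] * d[3], length(p$b))
  dx <- tcrossprod(dy, p$W)
  dim(dx) <- d
  list(dx = dx, dW = crossprod(cache$xm, dy), db = colSums(dy))
}

# -- activations --------------------------------------------------------------

relu_fwd <- function(x) { m <- x > 0; list(y = x * m, mask = m) }
relu_bwd <- function(dy, cache) dy * cache$mask
sigmoid <- function(x) 1 / (1 + exp(-x))

# -- 2x2 max pooling ----------------------------------------------------------

maxpool_fwd <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  io <- seq(1L, H, 2L); jo <- seq(1L, W, 2L)
  a <- list(x[io, jo, , , drop = FALSE], x[io + 1L, jo, , , drop = FALSE],
            x[io, jo + 1L, , , drop = FALSE], x[io + 1L, jo + 1L, , , drop = FALSE])
  y <- pmax(a[[1]], a[[2]], a[[3]], a[[4]])
  w <- array(1L, dim(y))
  w[a[[2]] > a[[1]]] <- 2L
  m <- pmax(a[[1]], a[[2]])
  w[a[[3]] > m] <- 3L
  m <- pmax(m, a[[3]])
  w[a[[4]] > m] <- 4L
  list(y = y, which = w, xdim = d)
}

maxpool_bwd <- function(dy, cache) {
  d <- cache$xdim; H <- d[1]; W <- d[2]
  io <- seq(1L, H, 2L); jo <- seq(1L, W, 2L)
  dx <- array(0, d)
  w <- cache$which
  dx[io, jo, , ]           <- dy * (w == 1L)
  dx[io + 1L, jo, , ]      <- dy * (w == 2L)
  dx[io, jo + 1L, , ]      <- dy * (w == 3L)
  dx[io + 1L, jo + 1L, , ] <- dy * (w == 4L)
  dx
}

# -- 2x nearest-neighbor upsampling ------------------------------------------

upsample_fwd <- function(x) {
  d <- dim(x)
  y <- array(0, c(2L * d[1], 2L * d[2], d[3], d[4]))
  io <- seq(1L, 2L * d[1], 2L); jo <- seq(1L, 2L * d[2], 2L)
  y[io, jo, , ] <- x; y[io + 1L, jo, , ] <- x
  y[io, jo + 1L, , ] <- x; y[io + 1L, jo + 1L, , ] <- x
  y
}

upsample_bwd <- function(dy) {
  d <- dim(dy)
  io <- seq(1L, d[1], 2L); jo <- seq(1L, d[2], 2L)
  dy[io, jo, , , drop = FALSE] + dy[io + 1L, jo, , , drop = FALSE] +
    dy[io, jo + 1L, , , drop = FALSE] + dy[io + 1L, jo + 1L, , , drop = FALSE]
}

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, c(da[1], da[2], da[3], da[4] + db[4]))
  y[, , , seq_len(da[4])] <- a
  y[, , , da[4] + seq_len(db[4])] <- b
  y
}

split_c <- function(dy, ca) {
  list(dy[, , , seq_len(ca), drop = FALSE],
       dy[, , , -seq_len(ca), drop = FALSE])
}

# -- parameter initialization and Adam ---------------------------------------

init_conv <- function(k2cin, cout, gain = 2) {
  list(W = matrix(stats::rnorm(k2cin * cout, 0, sqrt(gain / k2cin)), k2cin, cout),
       b = rep(0, cout))
}

adam_init <- function(params) {
  st <- list(t = 0)
  st$m <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
  st$v <- st$m
  st
}

adam_step <- function(params, grads, st, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1
  b1c <- 1 - beta1^st$t; b2c <- 1 - beta2^st$t
  for (nm in names(params)) {
    for (f in c("W", "b")) {
      g <- grads[[nm]][[f]]
      st$m[[nm]][[f]] <- beta1 * st$m[[nm]][[f]] + (1 - beta1) * g
      st$v[[nm]][[f]] <- beta2 * st$v[[nm]][[f]] + (1 - beta2) * g^2
      params[[nm]][[f]] <- params[[nm]][[f]] -
        lr * (st$m[[nm]][[f]] / b1c) / (sqrt(st$v[[nm]][[f]] / b2c) + eps)
    }
  }
  list(params = params, state = st)
}

zero_grads <- function(params)
  lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))

acc_grads <- function(g, add) {
  for (nm in names(add)) {
    g[[nm]]$W <- g[[nm]]$W + add[[nm]]$dW
    g[[nm]]$b <- g[[nm]]$b + add[[nm]]$db
  }
  g
}
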