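# Shared numeric / image utilities.

#' Derive a reproducible sub-stream seed from a master seed
#'
#' Separate concerns (geometry, events, noise, death, weight init, ...) draw
#' from independent streams so that e.g. toggling noise does not perturb the
#' event schedule. The derived seed stays below 2^31.
#'
#' @param seed master seed (integer)
#' @param stream character tag naming the concern
#' @return an integer seed
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) * 48271 + h + 1) %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur of a 2D matrix, replicate-padded at borders.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) / 2L
  blur_axis <- function(m, k, r) {
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(k)) {
      off <- i - r - 1L
      idx <- clamp(seq_len(n) + off, 1L, n)
      out <- out + k[i] * m[idx, , drop = FALSE]
    }
    out
  }
  img <- blur_axis(img, k, r)
  t(blur_axis(t(img), k, r))
}

# Percentile normalization used before detector inference: maps the 1st
# percentile to 0 and the 99th to 1, clipped to [0, 1].
#' Normalize a frame for detector input
#'
#' @param frame 2D numeric matrix
#' @param probs lower/upper percentiles mapped to 0 and 1
#' @return matrix with values in \[0, 1\]
#' @export
normalize_frame <- function(frame, probs = c(0.01, 0.99)) {
  q <- stats::quantile(frame, probs, names = FALSE)
  if (q[2] - q[1] < .Machine$double.eps) return(frame * 0)
  clamp((frame - q[1]) / (q[2] - q[1]), 0, 1)
}

# Otsu threshold on a numeric matrix (256-bin histogram).
otsu_threshold <- function(img, n_bins = 256L) {
  rng <- range(img)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(findInterval(img, seq(rng[1], rng[2], length.out = n_bins + 1L),
                             rightmost.closed = TRUE, all.inside = TRUE), n_bins)
  p <- h / sum(h)
  mids <- seq(rng[1], rng[2], length.out = n_bins + 1L)[-1] - diff(rng) / (2 * n_bins)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

# Minimum cross-entropy (Li) threshold, brute-force over histogram bins.
li_threshold <- function(img, n_bins = 256L) {
  x <- as.numeric(img)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  mids <- edges[-1] - diff(rng) / (2 * n_bins)
  h <- tabulate(findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE), n_bins)
  g <- pmax(mids - rng[1], .Machine$double.eps)  # shift so intensities > 0
  m <- h * g
  c1 <- cumsum(m); c2 <- sum(m) - c1
  n1 <- cumsum(h); n2 <- sum(h) - n1
  mu1 <- c1 / pmax(n1, 1); mu2 <- c2 / pmax(n2, 1)
  eta <- -c1 * log(pmax(mu1, .Machine$double.eps)) -
          c2 * log(pmax(mu2, .Machine$double.eps))
  eta[n1 == 0 | n2 == 0] <- Inf
  mids[which.min(eta)]
}

# Connected-component labeling of a logical matrix (8-connectivity), by
# iterative label propagation (vectorized pmin over shifted copies).
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  lab[mask] <- seq_len(sum(mask))
  big <- sum(mask) + 1L
  labn <- matrix(big, H, W)
  repeat {
    labn[mask] <- lab[mask]
    m <- labn
    # 8-neighbor min propagation
    m[-1, ]  <- pmin(m[-1, ],  labn[-H, ])
    m[-H, ]  <- pmin(m[-H, ],  labn[-1, ])
    m[, -1]  <- pmin(m[, -1],  labn[, -W])
    m[, -W]  <- pmin(m[, -W],  labn[, -1])
    m[-1, -1] <- pmin(m[-1, -1], labn[-H, -W])
    m[-H, -W] <- pmin(m[-H, -W], labn[-1, -1])
    m[-1, -W] <- pmin(m[-1, -W], labn[-H, -1])
    m[-H, -1] <- pmin(m[-H, -1], labn[-1, -W])
    m[!mask] <- 0L
    if (identical(m[mask], lab[mask])) break
    lab[mask] <- m[mask]
  }
  ids <- sort(unique(lab[mask]))
  lab[mask] <- match(lab[mask], ids)
  lab
}

# Count of 8-connected components in a logical matrix.
count_components <- function(mask) {
  if (!any(mask)) return(0L)
  max(label_components(mask))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
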