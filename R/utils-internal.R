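# internal numerics shared across modules

# run code under a seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), force(code))
}

# separable 1-D Gaussian kernel; sigma in pixels
.gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# convolve a 3-D array along one margin with a 1-D kernel, replicate edges;
# EBImage::gblur assumes periodic (FFT) edges and isotropic sigma, neither of
# which is wanted for small anisotropic PSFs, hence this direct version
.conv_along <- function(a, k, margin) {
  if (length(k) == 1L) return(a)
  r <- (length(k) - 1L) / 2L
  d <- dim(a)
  n <- d[margin]
  idx <- function(i) pmin(pmax(i, 1L), n)  # replicate edge
  out <- array(0, d)
  for (j in seq_along(k)) {
    off <- j - r - 1L
    src <- idx(seq_len(n) + off)
    out <- out + k[j] * switch(margin,
      a[src, , , drop = FALSE],
      a[, src, , drop = FALSE],
      a[, , src, drop = FALSE])
  }
  out
}

# anisotropic Gaussian blur of a (x, y, z) volume; sigmas in pixels/planes
.gauss_blur3 <- function(vol, sigma_xy_px, sigma_z_pl) {
  kxy <- .gauss_kernel(sigma_xy_px)
  kz <- .gauss_kernel(sigma_z_pl)
  vol <- .conv_along(vol, kxy, 1L)
  vol <- .conv_along(vol, kxy, 2L)
  if (dim(vol)[3] > 1L) vol <- .conv_along(vol, kz, 3L)
  vol
}

# Poisson shot noise + Gaussian read noise, clamped at zero
.apply_noise <- function(vol, poisson = TRUE, read_sd = 2) {
  v <- as.numeric(vol)
  if (poisson) v <- rpois(length(v), pmax(v, 0))
  if (read_sd > 0) v <- v + rnorm(length(v), sd = read_sd)
  array(pmax(v, 0), dim(vol))
}

# global Otsu threshold over an arbitrary array (EBImage::otsu is per-frame)
.otsu_threshold <- function(x, levels = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) <= 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = levels)
  mids <- (breaks[-1] + breaks[-(levels + 1L)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  n <- w[levels]; mt <- m[levels]
  w0 <- w[-levels]; m0 <- m[-levels]
  w1 <- n - w0
  ok <- w0 > 0 & w1 > 0
  between <- rep(-Inf, levels - 1L)
  between[ok] <- (mt * w0[ok] / n - m0[ok])^2 / (w0[ok] / n * w1[ok] / n) # scaled between-class variance
  mids[which.max(between)]
}

# bilinear interpolation of matrix `m` at fractional (1-based) indices
.bilinear <- function(m, xi, yi) {
  nx <- nrow(m); ny <- ncol(m)
  x0 <- pmin(pmax(floor(xi), 1L), nx - 1L)
  y0 <- pmin(pmax(floor(yi), 1L), ny - 1L)
  fx <- pmin(pmax(xi - x0, 0), 1)
  fy <- pmin(pmax(yi - y0, 0), 1)
  m[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
    m[cbind(x0 + 1L, y0)] * fx * (1 - fy) +
    m[cbind(x0, y0 + 1L)] * (1 - fx) * fy +
    m[cbind(x0 + 1L, y0 + 1L)] * fx * fy
}

# circular moving-average smoothing of a periodic profile
.circ_smooth <- function(v, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  n <- length(v)
  r <- (width - 1L) / 2L
  out <- numeric(n)
  for (off in -r:r) out <- out + v[((seq_len(n) - 1L + off) %% n) + 1L]
  out / width
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
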