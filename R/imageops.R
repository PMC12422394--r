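# 2D/3D image primitives used by the boundary and vessel stages: intensity
# normalization, Otsu thresholding, CLAHE, sliding-window statistics, binary
# morphology and separable Gaussian smoothing. Kept internal; the heavy 3D
# kernels (median filter, labelling, EDT, thinning) live in src/.

# Affine rescale to [0, 1]; returns NULL when the dynamic range is degenerate,
# which callers treat as "no candidate band".
normalize01 <- function(img) {
  rng <- range(img)
  if (!all(is.finite(rng)) || diff(rng) < 1e-10) return(NULL)
  (img - rng[1]) / diff(rng)
}

# Otsu's threshold on values in [0, 1].
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  h <- tabulate(pmin(pmax(floor(x * nbins) + 1L, 1L), nbins), nbins)
  p <- h / sum(h)
  mids <- (seq_len(nbins) - 0.5) / nbins
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

# Contrast-limited adaptive histogram equalization on a [0,1] image.
# `tiles` = c(rows, cols) tile grid; `clip` = clip limit as a multiple of the
# uniform bin height. Tile mappings are bilinearly interpolated.
clahe <- function(img, tiles = c(8L, 8L), clip = 2, nbins = 64L) {
  nr <- nrow(img); nc <- ncol(img)
  tr <- max(1L, min(tiles[1], nr)); tc <- max(1L, min(tiles[2], nc))
  # tile index and center per row/col
  rb <- round(seq(0, nr, length.out = tr + 1))
  cb <- round(seq(0, nc, length.out = tc + 1))
  rcent <- (rb[-1] + rb[-(tr + 1)] + 1) / 2
  ccent <- (cb[-1] + cb[-(tc + 1)] + 1) / 2
  bin <- pmin(pmax(floor(img * nbins) + 1L, 1L), nbins)
  # per-tile clipped CDF lookup tables
  luts <- array(0, dim = c(nbins, tr, tc))
  for (ti in seq_len(tr)) for (tj in seq_len(tc)) {
    sub <- bin[(rb[ti] + 1):rb[ti + 1], (cb[tj] + 1):cb[tj + 1]]
    h <- tabulate(sub, nbins)
    n <- sum(h)
    lim <- clip * n / nbins
    excess <- sum(pmax(h - lim, 0))
    h <- pmin(h, lim) + excess / nbins
    luts[, ti, tj] <- cumsum(h) / n
  }
  # bilinear interpolation of tile mappings
  ri <- findInterval(seq_len(nr), rcent, all.inside = FALSE)
  ci <- findInterval(seq_len(nc), ccent, all.inside = FALSE)
  r0 <- clamp(ri, 1L, tr); r1 <- clamp(ri + 1L, 1L, tr)
  c0 <- clamp(ci, 1L, tc); c1 <- clamp(ci + 1L, 1L, tc)
  wr <- ifelse(r1 == r0, 0, (seq_len(nr) - rcent[r0]) / (rcent[r1] - rcent[r0]))
  wc <- ifelse(c1 == c0, 0, (seq_len(nc) - ccent[c0]) / (ccent[c1] - ccent[c0]))
  wr <- clamp(wr, 0, 1); wc <- clamp(wc, 0, 1)
  out <- matrix(0, nr, nc)
  for (j in seq_len(nc)) {
    b <- bin[, j]
    v00 <- luts[cbind(b, r0, rep(c0[j], nr))]
    v10 <- luts[cbind(b, r1, rep(c0[j], nr))]
    v01 <- luts[cbind(b, r0, rep(c1[j], nr))]
    v11 <- luts[cbind(b, r1, rep(c1[j], nr))]
    out[, j] <- (1 - wc[j]) * ((1 - wr) * v00 + wr * v10) +
      wc[j] * ((1 - wr) * v01 + wr * v11)
  }
  out
}

# Sliding-window mean and (population) standard deviation with edge
# replication, via padded integral images. `window` is the square side; for
# even sizes the window covers floor((w-1)/2) pixels before and ceil((w-1)/2)
# after the center pixel in each axis.
local_mean_sd <- function(img, window) {
  nr <- nrow(img); nc <- ncol(img)
  if (window > nr || window > nc) stopf("window (%d) larger than image (%dx%d)", window, nr, nc)
  lo <- floor((window - 1) / 2); hi <- ceiling((window - 1) / 2)
  pad <- img[clamp(seq(1 - lo, nr + hi), 1L, nr), clamp(seq(1 - lo, nc + hi), 1L, nc), drop = FALSE]
  ii <- function(m) {
    m <- apply(m, 2, cumsum)
    m <- t(apply(m, 1, cumsum))
    rbind(0, cbind(0, m))  # zero-padded integral image
  }
  s1 <- ii(pad); s2 <- ii(pad^2)
  r0 <- seq_len(nr); c0 <- seq_len(nc)
  boxsum <- function(s) {
    s[r0 + window, c0 + window, drop = FALSE] - s[r0, c0 + window, drop = FALSE] -
      s[r0 + window, c0, drop = FALSE] + s[r0, c0, drop = FALSE]
  }
  n <- window * window
  m <- boxsum(s1) / n
  v <- pmax(boxsum(s2) / n - m^2, 0)
  list(mean = m, sd = sqrt(v))
}

# --- binary morphology ------------------------------------------------------

shift2 <- function(m, di, dj, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ri <- seq_len(nr) - di; ci <- seq_len(nc) - dj
  ok_r <- ri >= 1 & ri <= nr; ok_c <- ci >= 1 & ci <= nc
  out[ok_r, ok_c] <- m[ri[ok_r], ci[ok_c]]
  out
}

erode2 <- function(m, iter = 1) {
  for (it in seq_len(iter)) {
    out <- m
    for (di in -1:1) for (dj in -1:1)
      if (di != 0 || dj != 0) out <- out & shift2(m, di, dj, fill = FALSE)
    m <- out
  }
  m
}

dilate2 <- function(m, iter = 1) {
  for (it in seq_len(iter)) {
    out <- m
    for (di in -1:1) for (dj in -1:1)
      if (di != 0 || dj != 0) out <- out | shift2(m, di, dj, fill = FALSE)
    m <- out
  }
  m
}

open2 <- function(m, iter = 1) if (iter < 1) m else dilate2(erode2(m, iter), iter)
close2 <- function(m, iter = 1) if (iter < 1) m else erode2(dilate2(m, iter), iter)

# 3x3x1 in-plane structuring element on (axial, ascan, bscan) arrays: each
# B-scan slab is treated independently.
erode3_inplane <- function(arr, iter = 1) {
  for (b in seq_len(dim(arr)[3])) arr[, , b] <- erode2(arr[, , b, drop = TRUE], iter)
  arr
}

dilate3_inplane <- function(arr, iter = 1) {
  for (b in seq_len(dim(arr)[3])) arr[, , b] <- dilate2(arr[, , b, drop = TRUE], iter)
  arr
}

open3_inplane <- function(arr, iter = 1) {
  if (iter < 1) return(arr)
  dilate3_inplane(erode3_inplane(arr, iter), iter)
}

# Separable Gaussian smoothing of a matrix with edge replication (used to
# correlate the phantom surface fields).
gauss_kernel1 <- function(sigma) {
  h <- max(1L, ceiling(3 * sigma))
  kern <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  kern / sum(kern)
}

gaussian_blur2 <- function(m, sigma_r, sigma_c) {
  smooth1 <- function(x, sigma) {
    if (sigma <= 0) return(x)
    kern <- gauss_kernel1(sigma)
    h <- (length(kern) - 1L) / 2L
    n <- length(x)
    xp <- x[clamp(seq(1 - h, n + h), 1L, n)]
    as.numeric(stats::filter(xp, kern, sides = 2))[(h + 1):(h + n)]
  }
  m <- apply(m, 2, smooth1, sigma = sigma_r)
  t(apply(m, 1, smooth1, sigma = sigma_c))
}
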