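# Independent oracles: brute-force re-implementations kept deliberately naive
# and separate from the package code paths they check.

# Per-pixel Phansalkar threshold via explicit window loops (edge replication
# by index clamping, population SD), marking pixels strictly below T.
phansalkar_oracle <- function(img, window = 16L, k = 0.25, R = 0.5, p = 2, q = 10) {
  nr <- nrow(img); nc <- ncol(img)
  lo <- floor((window - 1) / 2); hi <- ceiling((window - 1) / 2)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ri <- pmin(pmax((i - lo):(i + hi), 1), nr)
    ci <- pmin(pmax((j - lo):(j + hi), 1), nc)
    vals <- img[ri, ci]
    m <- mean(vals)
    s <- sqrt(mean((vals - m)^2))
    thr <- m * (1 + p * exp(-q * m) + k * (s / R - 1))
    out[i, j] <- img[i, j] < thr
  }
  out
}

# Voxel-by-voxel point-in-capsule rasterization of one straight tube on the
# (axial, ascan, bscan) grid, in micrometre coordinates.
rasterize_tube_oracle <- function(n_axial, n_ascans, n_bscans, spacing, p0, p1, radius) {
  out <- array(FALSE, dim = c(n_axial, n_ascans, n_bscans))
  seg <- p1 - p0
  L2 <- sum(seg^2)
  for (k in seq_len(n_bscans)) for (j in seq_len(n_ascans)) for (i in seq_len(n_axial)) {
    pnt <- c((j - 1) * spacing[2], (k - 1) * spacing[1], (i - 1) * spacing[3])
    tt <- if (L2 == 0) 0 else max(0, min(1, sum((pnt - p0) * seg) / L2))
    cl <- p0 + tt * seg
    out[i, j, k] <- sum((pnt - cl)^2) <= radius^2
  }
  out
}

# ICC(A,1) from the two-way ANOVA table produced by stats::aov.
icc_a1_oracle <- function(g1, g2) {
  n <- length(g1)
  df <- data.frame(y = c(g1, g2),
                   row = factor(rep(seq_len(n), 2)),
                   col = factor(rep(1:2, each = n)))
  tab <- summary(stats::aov(y ~ row + col, data = df))[[1]]
  msr <- tab["row", "Mean Sq"]; msc <- tab["col", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

# Exhaustive Fisher p for a 2 x c table: enumerate first-row fillings with
# fixed margins; p = total probability of tables no more probable than the
# observed one.
fisher_oracle_2xc <- function(tab) {
  stopifnot(nrow(tab) == 2)
  cs <- colSums(tab); r1 <- sum(tab[1, ]); N <- sum(tab)
  logp_row <- function(x) sum(lchoose(cs, x)) - lchoose(N, r1)
  cells <- lapply(cs, function(m) 0:m)
  grid <- expand.grid(cells)
  grid <- grid[rowSums(grid) == r1, , drop = FALSE]
  lp <- apply(grid, 1, logp_row)
  lobs <- logp_row(tab[1, ])
  sum(exp(lp[lp <= lobs + 1e-7]))
}

# Two-sided 2 x 2 Fisher p from the hypergeometric closed form.
fisher_oracle_2x2 <- function(tab) {
  m <- sum(tab[, 1]); n <- sum(tab[, 2]); k <- sum(tab[1, ])
  supp <- max(0, k - n):min(k, m)
  d <- stats::dhyper(supp, m, n, k)
  sum(d[d <= stats::dhyper(tab[1, 1], m, n, k) * (1 + 1e-7)])
}

# 26-neighbourhood binary dilation of a 3D array (used for monotonicity
# properties), independent of the package morphology helpers.
dilate26_oracle <- function(arr) {
  d <- dim(arr)
  out <- arr
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    src_i <- pmin(pmax(seq_len(d[1]) - di, 1), d[1])
    src_j <- pmin(pmax(seq_len(d[2]) - dj, 1), d[2])
    src_k <- pmin(pmax(seq_len(d[3]) - dk, 1), d[3])
    out <- out | arr[src_i, src_j, src_k]
  }
  out
}
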