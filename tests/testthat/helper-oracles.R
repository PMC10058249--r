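# Independent brute-force reference implementations used as oracles.
# Deliberately written as plain loops, sharing no code with the package paths
# they check.

# true 2D convolution (kernel flipped) with mirror-reflect padding,
# pixel-by-pixel loops
brute_conv2_reflect <- function(img, k) {
  nr <- nrow(img); nc <- ncol(img)
  kr <- nrow(k); kc <- ncol(k)
  cr <- (kr + 1) %/% 2; cc <- (kc + 1) %/% 2
  reflect <- function(i, n) {
    # mirror across the edge without duplicating it: 0 -> 2, -1 -> 3, n+1 -> n-1
    while (i < 1 || i > n) {
      if (i < 1) i <- 2 - i
      if (i > n) i <- 2 * n - i
    }
    i
  }
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    for (cl in seq_len(nc)) {
      acc <- 0
      for (i in seq_len(kr)) {
        for (j in seq_len(kc)) {
          ri <- reflect(r - (i - cr), nr)
          ci <- reflect(cl - (j - cc), nc)
          acc <- acc + k[i, j] * img[ri, ci]
        }
      }
      out[r, cl] <- acc
    }
  }
  out
}

# per-pixel half-angle orientation reference: recompute the angle from the
# smoothed derivative rasters one pixel at a time
brute_orientation_angle <- function(sIxx, sIyy, sIxy) {
  nr <- nrow(sIxx); nc <- ncol(sIxx)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (cl in seq_len(nc)) {
      a <- 0.5 * atan2(-2 * sIxy[r, cl], sIxx[r, cl] - sIyy[r, cl]) * 180 / pi
      if (a >= 90) a <- a - 180
      out[r, cl] <- a
    }
  }
  out
}

# brute-force band column mean: explicit row loop
brute_band_mean <- function(m, rows) {
  out <- numeric(ncol(m))
  for (cl in seq_len(ncol(m))) {
    s <- 0
    for (r in rows) s <- s + m[r, cl]
    out[cl] <- s / length(rows)
  }
  out
}

# smallest signed difference between two orientations (degrees, period 180)
angle_diff <- function(a, b) {
  d <- (a - b + 90) %% 180 - 90
  d
}

# small noise-free microtissue spec for fast tests
quick_tissue_spec <- function(...) {
  microtissue_spec(noise_sd = 0, ...)
}
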