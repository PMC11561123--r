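# Independent brute-force oracles and small fixture builders.

# average ranks computed from first principles (no rank())
brute_avg_ranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    less <- sum(x < x[i])
    ties <- sum(x == x[i])
    r[i] <- less + (ties + 1) / 2   # mean of occupied rank positions
  }
  r
}

# Spearman rho as rank-then-Pearson via explicit sums
brute_spearman <- function(x, y) {
  rx <- brute_avg_ranks(x)
  ry <- brute_avg_ranks(y)
  n <- length(x)
  sxy <- sum((rx - mean(rx)) * (ry - mean(ry)))
  sxx <- sum((rx - mean(rx))^2)
  syy <- sum((ry - mean(ry))^2)
  sxy / sqrt(sxx * syy)
}

# triple-loop support-mask count
brute_support_mask <- function(arrays, threshold, min_n) {
  d <- dim(arrays[[1]])
  out <- array(0, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    cnt <- 0
    for (a in arrays) if (a[i, j, k] > threshold) cnt <- cnt + 1
    if (cnt >= min_n) out[i, j, k] <- 1
  }
  out
}

# independent trilinear interpolation at one 0-based voxel-space point
brute_trilinear <- function(arr, p) {
  d <- dim(arr)
  if (any(p < 0) || any(p > d - 1)) return(0)
  f <- pmin(floor(p), d - 2); f <- pmax(f, 0)
  t <- p - f
  acc <- 0
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di) t[1] else 1 - t[1]) *
         (if (dj) t[2] else 1 - t[2]) *
         (if (dk) t[3] else 1 - t[3])
    acc <- acc + w * arr[f[1] + di + 1, f[2] + dj + 1, f[3] + dk + 1]
  }
  acc
}

# small random volume on an identity-spacing grid
random_volume <- function(dim = c(10, 10, 10), voxel = 1, origin = c(0, 0, 0)) {
  v <- make_grid(dim, voxel, origin)
  v$data <- array(stats::runif(prod(dim)), dim)
  v
}

# brute-force weighted fiber score from raw definitions
brute_weighted_fiber <- function(efield, trk, threshold) {
  num <- 0; den <- 0; n_int <- 0
  for (s in seq_along(trk$streamlines)) {
    vals <- vapply(seq_len(nrow(trk$streamlines[[s]])), function(i)
      stimmap::interp_volume(efield, trk$streamlines[[s]][i, ]),
      numeric(1))
    if (max(vals) > threshold) {
      n_int <- n_int + 1
      m <- mean(vals)
      num <- num + m * trk$fiber_r[s]
      den <- den + m
    }
  }
  if (n_int == 0) return(list(wmean = NA_real_, n = 0))
  list(wmean = num / den, n = n_int)
}

# tiny deterministic cohort of constant-valued E-fields on a shared grid
constant_fields <- function(values, dim = c(4, 4, 4)) {
  lapply(values, function(v) {
    g <- make_grid(dim, 1)
    g$data[] <- v
    g
  })
}
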