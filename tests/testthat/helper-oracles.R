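# Independent reference implementations, written as straight-line loops from
# the operative definitions. They deliberately share no code with the package
# internals so they can serve as oracles.

ref_pad1 <- function(m) {
  ri <- c(1, seq_len(nrow(m)), nrow(m))
  ci <- c(1, seq_len(ncol(m)), ncol(m))
  m[ri, ci, drop = FALSE]
}

# full reference Canny chain: Gaussian smoothing (replicate padding), Sobel
# sums evaluated pixel by pixel, strict-greater NMS over quantized sectors,
# nearest-rank quantile thresholds, flood-fill hysteresis from strong pixels.
ref_canny <- function(m, delta = 1, radius = ceiling(3 * delta),
                      q_high = 0.9, low_ratio = 0.4, connectivity = 8) {
  nr <- nrow(m); nc <- ncol(m)
  # smoothing
  off <- -radius:radius
  k <- matrix(0, 2 * radius + 1, 2 * radius + 1)
  for (i in seq_along(off)) for (j in seq_along(off))
    k[i, j] <- exp(-(off[i]^2 + off[j]^2) / (2 * delta^2))
  k <- k / sum(k)
  get_px <- function(mm, r, c) mm[min(max(r, 1), nr), min(max(c, 1), nc)]
  sm <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    acc <- 0
    for (i in seq_along(off)) for (j in seq_along(off))
      acc <- acc + k[i, j] * get_px(m, r + off[i], c + off[j])
    sm[r, c] <- acc
  }
  # Sobel
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    gx[r, c] <- (get_px(sm, r - 1, c + 1) + 2 * get_px(sm, r, c + 1) +
                 get_px(sm, r + 1, c + 1)) -
                (get_px(sm, r - 1, c - 1) + 2 * get_px(sm, r, c - 1) +
                 get_px(sm, r + 1, c - 1))
    gy[r, c] <- (get_px(sm, r - 1, c - 1) + 2 * get_px(sm, r - 1, c) +
                 get_px(sm, r - 1, c + 1)) -
                (get_px(sm, r + 1, c - 1) + 2 * get_px(sm, r + 1, c) +
                 get_px(sm, r + 1, c + 1))
  }
  mag <- sqrt(gx^2 + gy^2)
  # NMS: compare along the raster-space gradient line (drow, dcol) = (-gy, gx)
  sup <- matrix(0, nr, nc)
  magat <- function(r, c) if (r < 1 || r > nr || c < 1 || c > nc) 0 else mag[r, c]
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    a <- atan2(-gy[r, c], gx[r, c]) %% pi
    d <- if (a < pi / 8 || a >= 7 * pi / 8) c(0, 1)
         else if (a < 3 * pi / 8) c(1, 1)
         else if (a < 5 * pi / 8) c(1, 0)
         else c(1, -1)
    if (mag[r, c] > magat(r + d[1], c + d[2]) &&
        mag[r, c] > magat(r - d[1], c - d[2])) sup[r, c] <- mag[r, c]
  }
  # thresholds: nearest-rank quantile of nonzero magnitudes
  v <- sort(sup[sup > 0])
  if (length(v) == 0) {
    t_high <- 0; t_low <- 0
  } else {
    t_high <- v[ceiling(q_high * length(v))]
    t_low <- low_ratio * t_high
  }
  ref_hysteresis(sup, t_low, t_high, connectivity)
}

# flood-fill hysteresis oracle: strong pixels seed a search through weak ones
ref_hysteresis <- function(sup, t_low, t_high, connectivity = 8) {
  nr <- nrow(sup); nc <- ncol(sup)
  strong <- sup >= t_high & sup > 0
  weak <- sup >= t_low & sup < t_high & sup > 0
  edges <- strong
  offs <- if (connectivity == 4) list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
          else list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
                    c(1, -1), c(1, 0), c(1, 1))
  queue <- which(strong, arr.ind = TRUE)
  while (nrow(queue) > 0) {
    px <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
    for (d in offs) {
      r <- px[1] + d[1]; c <- px[2] + d[2]
      if (r >= 1 && r <= nr && c >= 1 && c <= nc && weak[r, c] &&
          !edges[r, c]) {
        edges[r, c] <- TRUE
        queue <- rbind(queue, c(r, c))
      }
    }
  }
  edges
}

# brute-force per-window SSIM (uniform window, n-1 statistics)
ref_ssim <- function(M, N, H = 8, k1 = 0.01, k2 = 0.03, L = 255) {
  C1 <- (k1 * L)^2; C2 <- (k2 * L)^2; C3 <- C2 / 2
  vals <- c()
  for (i in seq_len(nrow(M) - H + 1)) for (j in seq_len(ncol(M) - H + 1)) {
    Mw <- M[i:(i + H - 1), j:(j + H - 1)]
    Nw <- N[i:(i + H - 1), j:(j + H - 1)]
    n <- H * H
    muM <- mean(Mw); muN <- mean(Nw)
    vM <- sum((Mw - muM)^2) / (n - 1); vN <- sum((Nw - muN)^2) / (n - 1)
    cMN <- sum((Mw - muM) * (Nw - muN)) / (n - 1)
    l <- (2 * muM * muN + C1) / (muM^2 + muN^2 + C1)
    cc <- (2 * sqrt(vM) * sqrt(vN) + C2) / (vM + vN + C2)
    s <- (cMN + C3) / (sqrt(vM) * sqrt(vN) + C3)
    vals <- c(vals, l * cc * s)
  }
  mean(vals)
}

# Student t density from the closed form, for quadrature p-value oracles
ref_t_density <- function(x, df) {
  exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
    (1 + x^2 / df)^(-(df + 1) / 2)
}

# small random test raster with piecewise structure plus noise
random_raster <- function(n = 16, seed = 1) {
  set.seed(seed)
  base <- matrix(0, n, n)
  # a few random rectangles to create real edges
  for (k in 1:3) {
    r <- sort(sample(n, 2)); c <- sort(sample(n, 2))
    base[r[1]:r[2], c[1]:c[2]] <- runif(1, 50, 255)
  }
  pmin(pmax(base + matrix(rnorm(n * n, 0, 10), n, n), 0), 255)
}
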