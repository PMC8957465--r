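#' Mean squared error between two rasters
#'
#' `(1 / (m * n)) * sum((I - J)^2)`: symmetric, nonnegative, zero exactly
#' when the rasters are identical.
#'
#' @param I,J rasters or matrices of identical dimensions.
#' @return nonnegative scalar.
#' @export
mse <- function(I, J) {
  I <- as.matrix(I); J <- as.matrix(J)
  if (!all(dim(I) == dim(J)))
    stopf("dimension mismatch: %dx%d vs %dx%d", nrow(I), ncol(I),
          nrow(J), ncol(J))
  mean((I - J)^2)
}

#' Peak signal-to-noise ratio in decibels
#'
#' `10 * log10(MAX^2 / MSE)` with `MAX = 2^bit_depth - 1`. Larger is better.
#' Identical inputs have zero MSE; the function then returns `+Inf` and
#' signals a classed warning (`hamri_infinite_psnr`) so callers can treat the
#' degenerate case distinctly.
#'
#' @inheritParams mse
#' @param bit_depth bit depth defining the peak value (default: taken from
#'   `I` when it is an `image_raster`, else 8).
#' @return PSNR in dB, or `+Inf` for identical images.
#' @examples
#' a <- matrix(0, 4, 4); b <- a + 16
#' psnr(a, b)   # 10 * log10(255^2 / 256) = 24.048 dB
#' @export
psnr <- function(I, J, bit_depth = NULL) {
  if (is.null(bit_depth)) {
    bit_depth <- if (inherits(I, "image_raster")) attr(I, "bit_depth") else 8L
  }
  e <- mse(I, J)
  if (e == 0) {
    warning(structure(class = c("hamri_infinite_psnr", "warning", "condition"),
                      list(message = "identical images: PSNR is infinite",
                           call = NULL)))
    return(Inf)
  }
  mx <- 2^bit_depth - 1
  10 * log10(mx^2 / e)
}

#' SSIM parameter set
#'
#' @param window side of the square sliding window in pixels (default 8).
#' @param k1,k2 stabilizing constants (defaults 0.01 and 0.03).
#' @param L dynamic range of the pixel values (default 255 for 8-bit).
#' @return list of class `ssim_params` with derived constants
#'   `C1 = (k1 * L)^2`, `C2 = (k2 * L)^2`, `C3 = C2 / 2`.
#' @export
ssim_params <- function(window = 8L, k1 = 0.01, k2 = 0.03, L = 255) {
  window <- as.integer(window)
  if (window < 2L) stopf("window must be >= 2")
  if (L <= 0) stopf("L must be positive")
  structure(list(window = window, k1 = k1, k2 = k2, L = L,
                 C1 = (k1 * L)^2, C2 = (k2 * L)^2, C3 = (k2 * L)^2 / 2),
            class = "ssim_params")
}

#' Window statistics for SSIM
#'
#' Means, sample variances (denominator `H*W - 1`) and sample covariance of
#' two equal-size windows.
#'
#' @param M,N numeric matrices of identical dimensions with at least 2
#'   entries.
#' @return named numeric vector `(mu_M, mu_N, var_M, var_N, cov_MN)`.
#' @export
window_stats <- function(M, N) {
  M <- as.matrix(M); N <- as.matrix(N)
  if (!all(dim(M) == dim(N))) stopf("window dimension mismatch")
  n <- length(M)
  if (n < 2L) stopf("windows need at least 2 pixels")
  mu_M <- mean(M); mu_N <- mean(N)
  c(mu_M = mu_M, mu_N = mu_N,
    var_M = sum((M - mu_M)^2) / (n - 1),
    var_N = sum((N - mu_N)^2) / (n - 1),
    cov_MN = sum((M - mu_M) * (N - mu_N)) / (n - 1))
}

#' Luminance, contrast and structure components of SSIM
#'
#' `l = (2 mu_M mu_N + C1) / (mu_M^2 + mu_N^2 + C1)`,
#' `c = (2 s_M s_N + C2) / (var_M + var_N + C2)`,
#' `s = (cov_MN + C3) / (s_M s_N + C3)`; the additive constants keep every
#' component finite.
#'
#' @inheritParams window_stats
#' @param params an [ssim_params()] object.
#' @return named numeric vector `(l, c, s)`.
#' @export
ssim_components <- function(M, N, params = ssim_params()) {
  st <- window_stats(M, N)
  sd_M <- sqrt(st[["var_M"]]); sd_N <- sqrt(st[["var_N"]])
  c(l = (2 * st[["mu_M"]] * st[["mu_N"]] + params$C1) /
        (st[["mu_M"]]^2 + st[["mu_N"]]^2 + params$C1),
    c = (2 * sd_M * sd_N + params$C2) / (st[["var_M"]] + st[["var_N"]] + params$C2),
    s = (st[["cov_MN"]] + params$C3) / (sd_M * sd_N + params$C3))
}

# Sliding-window sums of a matrix over all HxH windows fully inside it,
# via a 2-D integral image. Returns a (nr-H+1) x (nc-H+1) matrix.
box_sums <- function(m, H) {
  S <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
  cs <- apply(m, 2L, cumsum)                      # cumulative down rows
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = nrow(m))
  cs2 <- t(apply(cs, 1L, cumsum))                 # then across columns
  if (nrow(m) == 1L) cs2 <- matrix(cs2, nrow = 1L)
  S[-1L, -1L] <- cs2
  nr <- nrow(m) - H + 1L; nc <- ncol(m) - H + 1L
  S[(1L + H):(nrow(m) + 1L), (1L + H):(ncol(m) + 1L), drop = FALSE] -
    S[(1L + H):(nrow(m) + 1L), 1L:nc, drop = FALSE] -
    S[1L:nr, (1L + H):(ncol(m) + 1L), drop = FALSE] +
    S[1L:nr, 1L:nc, drop = FALSE]
}

#' Structural similarity between two rasters
#'
#' Sliding-window SSIM: an `H x H` uniform (unweighted) window moves with
#' stride 1 over every position fully inside the rasters; per window the
#' product `l * c * s` is computed from the window statistics, and the
#' overall value is the arithmetic mean over windows. Windows are uniform by
#' design (no Gaussian weighting).
#'
#' @param M,N rasters or matrices of identical dimensions, each at least
#'   `window` in both dimensions.
#' @param params an [ssim_params()] object.
#' @return object of class `ssim_result`: list with `value` (mean SSIM),
#'   `map` (per-window SSIM matrix, entry `[i, j]` for the window whose
#'   top-left pixel is `(i, j)`), and `components` (list of `l`, `c`, `s`
#'   matrices).
#' @export
ssim <- function(M, N, params = ssim_params()) {
  M <- as.matrix(M); N <- as.matrix(N)
  if (!all(dim(M) == dim(N))) stopf("dimension mismatch")
  H <- params$window
  if (nrow(M) < H || ncol(M) < H)
    stopf("raster (%dx%d) smaller than the %dx%d window", nrow(M), ncol(M),
          H, H)
  n <- H * H
  sM <- box_sums(M, H);  sN <- box_sums(N, H)
  sMM <- box_sums(M * M, H); sNN <- box_sums(N * N, H)
  sMN <- box_sums(M * N, H)
  mu_M <- sM / n; mu_N <- sN / n
  var_M <- pmax((sMM - n * mu_M^2) / (n - 1), 0)
  var_N <- pmax((sNN - n * mu_N^2) / (n - 1), 0)
  cov_MN <- (sMN - n * mu_M * mu_N) / (n - 1)
  sd_M <- sqrt(var_M); sd_N <- sqrt(var_N)
  l <- (2 * mu_M * mu_N + params$C1) / (mu_M^2 + mu_N^2 + params$C1)
  cc <- (2 * sd_M * sd_N + params$C2) / (var_M + var_N + params$C2)
  s <- (cov_MN + params$C3) / (sd_M * sd_N + params$C3)
  map <- l * cc * s
  structure(list(value = mean(map), map = map,
                 components = list(l = l, c = cc, s = s), params = params),
            class = "ssim_result")
}

#' @export
print.ssim_result <- function(x, ...) {
  cat(sprintf("<ssim_result> mean SSIM %.4f over %d windows (%dx%d, H = %d)\n",
              x$value, length(x$map), nrow(x$map), ncol(x$map),
              x$params$window))
  invisible(x)
}
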