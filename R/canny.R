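#' Normalized 2-D Gaussian smoothing kernel
#'
#' Builds the `(2*radius+1) x (2*radius+1)` discrete Gaussian
#' `exp(-(x^2 + y^2) / (2 * delta^2))`, normalized to sum exactly 1 so that
#' constant images are fixed points of smoothing.
#'
#' @param delta Gaussian standard deviation in pixels (> 0).
#' @param radius kernel half-width in pixels; the default `ceiling(3 * delta)`
#'   covers at least 99.7% of the continuous mass.
#' @return numeric matrix of kernel weights summing to 1.
#' @examples
#' k <- gaussian_kernel(1, 1)
#' sum(k)          # 1
#' k[2, 2]         # ~0.2042
#' @export
gaussian_kernel <- function(delta, radius = ceiling(3 * delta)) {
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0)
    stopf("delta must be a positive scalar")
  radius <- as.integer(radius)
  if (radius < 1L) stopf("radius must be >= 1")
  off <- -radius:radius
  k <- exp(-outer(off^2, off^2, `+`) / (2 * delta^2))
  k / sum(k)
}

# Discrete 2-D convolution with replicate border padding, via summed shifts of
# the padded matrix (O(kernel area) vectorized adds).
conv2_replicate <- function(m, kernel) {
  r <- (nrow(kernel) - 1L) %/% 2L
  p <- pad_replicate(m, r)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(kernel))) {
    for (j in seq_len(ncol(kernel))) {
      w <- kernel[i, j]
      if (w == 0) next
      # kernel offset (i - r - 1, j - r - 1); convolution flips the kernel,
      # but all kernels used here are symmetric or handled explicitly
      out <- out + w * p[(i - 1L) + seq_len(nrow(m)),
                         (j - 1L) + seq_len(ncol(m)), drop = FALSE]
    }
  }
  out
}

#' Gaussian smoothing of a raster
#'
#' The first Canny stage: `I' = I * G` with a normalized Gaussian kernel and
#' replicate padding at the borders.
#'
#' @param image an `image_raster` (or plain matrix, taken as 8-bit).
#' @inheritParams gaussian_kernel
#' @return an `image_raster` of the same dimensions and depth.
#' @export
smooth_raster <- function(image, delta = 1, radius = ceiling(3 * delta)) {
  image <- as_image(image)
  k <- gaussian_kernel(delta, radius)
  image_raster(conv2_replicate(as_raster_matrix(image), k), bit_depth(image))
}

as_image <- function(x) {
  if (inherits(x, "image_raster")) x else image_raster(as.matrix(x))
}

#' Sobel gradient field
#'
#' First-order difference templates approximating the partial derivatives:
#' the horizontal derivative at `(x, y)` is the 1-2-1-weighted column at
#' `x + 1` minus the 1-2-1-weighted column at `x - 1`, and the vertical
#' derivative is the weighted row at `y - 1` minus the weighted row at
#' `y + 1` (y increases downward). Magnitude is `sqrt(gx^2 + gy^2)`;
#' direction is the four-quadrant angle `atan2(gy, gx)` in radians, defined
#' as 0 where both components vanish.
#'
#' With `literal_direction = TRUE` the direction is instead computed as
#' `atan(gx / gy)` (axes swapped, two-quadrant), a compatibility mode; only
#' the non-maximum-suppression sector assignment consumes the direction, and
#' that is derived from `(gx, gy)` directly, so the flag does not change edge
#' output.
#'
#' @param image an `image_raster`, at least 3x3; borders use replicate
#'   padding.
#' @param literal_direction logical; see Details.
#' @return an object of class `gradient_field`: list with matrices `gx`,
#'   `gy`, `magnitude`, `direction`.
#' @export
sobel_gradients <- function(image, literal_direction = FALSE) {
  image <- as_image(image)
  m <- as_raster_matrix(image)
  if (nrow(m) < 3L || ncol(m) < 3L)
    stopf("gradient computation needs at least a 3x3 image (got %dx%d)",
          nrow(m), ncol(m))
  p <- pad_replicate(m, 1L)
  nr <- nrow(m); nc <- ncol(m)
  sh <- function(dr, dc) p[dr + 1L + seq_len(nr), dc + 1L + seq_len(nc),
                           drop = FALSE]
  # columns x+1 minus x-1, rows weighted 1,2,1
  gx <- (sh(-1L, 1L) + 2 * sh(0L, 1L) + sh(1L, 1L)) -
        (sh(-1L, -1L) + 2 * sh(0L, -1L) + sh(1L, -1L))
  # rows y-1 minus y+1, columns weighted 1,2,1
  gy <- (sh(-1L, -1L) + 2 * sh(-1L, 0L) + sh(-1L, 1L)) -
        (sh(1L, -1L) + 2 * sh(1L, 0L) + sh(1L, 1L))
  mag <- sqrt(gx^2 + gy^2)
  dir <- if (literal_direction) {
    d <- atan(gx / gy)
    d[gx == 0 & gy == 0] <- 0
    d
  } else {
    atan2(gy, gx)  # atan2 returns 0 at (0, 0)
  }
  structure(list(gx = gx, gy = gy, magnitude = mag, direction = dir),
            class = "gradient_field")
}

#' @export
print.gradient_field <- function(x, ...) {
  cat(sprintf("<gradient_field> %d x %d, max magnitude %.4g\n",
              nrow(x$magnitude), ncol(x$magnitude), max(x$magnitude)))
  invisible(x)
}

# Sector of the gradient line through a pixel, in raster (row, col)
# coordinates. gy is "row above minus row below", so the raster-space gradient
# is (drow, dcol) = (-gy, gx); only the undirected line matters for NMS.
# Sectors: 1 = horizontal neighbors (0 deg), 2 = down-right/up-left diagonal
# (45 deg), 3 = vertical neighbors (90 deg), 4 = down-left/up-right (135 deg).
nms_sector <- function(gx, gy) {
  a <- atan2(-gy, gx) %% pi
  s <- integer(length(a))
  s[a < pi / 8 | a >= 7 * pi / 8] <- 1L
  s[a >= pi / 8 & a < 3 * pi / 8] <- 2L
  s[a >= 3 * pi / 8 & a < 5 * pi / 8] <- 3L
  s[a >= 5 * pi / 8 & a < 7 * pi / 8] <- 4L
  dim(s) <- dim(gx)
  s
}

#' Non-maximum suppression
#'
#' Thins the gradient magnitude: the direction is quantized to four sectors
#' (0, 45, 90, 135 degrees) and each pixel keeps its magnitude only if it is
#' strictly greater than both neighbors along its sector; otherwise it is set
#' to 0. Out-of-bounds neighbors count as 0, so a lone maximum at the border
#' survives; constant plateaus are suppressed entirely by the strict rule.
#'
#' @param field a `gradient_field` from [sobel_gradients()].
#' @return numeric matrix of suppressed magnitudes (same dimensions).
#' @export
nonmax_suppress <- function(field) {
  if (!inherits(field, "gradient_field")) stopf("not a gradient_field")
  mag <- field$magnitude
  nr <- nrow(mag); nc <- ncol(mag)
  sec <- nms_sector(field$gx, field$gy)
  pm <- matrix(0, nr + 2L, nc + 2L)        # zero padding: OOB neighbors are 0
  pm[1L + seq_len(nr), 1L + seq_len(nc)] <- mag
  nb <- function(dr, dc) pm[dr + 1L + seq_len(nr), dc + 1L + seq_len(nc),
                            drop = FALSE]
  off <- list(`1` = c(0L, 1L), `2` = c(1L, 1L), `3` = c(1L, 0L),
              `4` = c(1L, -1L))
  keep <- matrix(FALSE, nr, nc)
  for (s in 1:4) {
    d <- off[[s]]
    ok <- mag > nb(d[1L], d[2L]) & mag > nb(-d[1L], -d[2L])
    keep <- keep | (sec == s & ok)
  }
  out <- matrix(0, nr, nc)
  out[keep] <- mag[keep]
  out
}

#' Quantile-derived hysteresis thresholds
#'
#' The double-threshold stage needs two magnitude cut-offs; when none are
#' given they are derived per image: `t_high` is the `q_high` nearest-rank
#' quantile of the nonzero suppressed magnitudes and `t_low = low_ratio *
#' t_high`.
#'
#' @param suppressed matrix of suppressed magnitudes from
#'   [nonmax_suppress()].
#' @param q_high upper-threshold quantile in (0, 1); default 0.90.
#' @param low_ratio `t_low / t_high` in (0, 1]; default 0.4.
#' @return named numeric vector `c(t_low, t_high)`; `(0, 0)` with a warning
#'   when the raster has no nonzero magnitudes.
#' @export
auto_thresholds <- function(suppressed, q_high = 0.90, low_ratio = 0.4) {
  if (!(q_high > 0 && q_high < 1)) stopf("q_high must be in (0, 1)")
  if (!(low_ratio > 0 && low_ratio <= 1)) stopf("low_ratio must be in (0, 1]")
  v <- suppressed[suppressed > 0]
  if (length(v) == 0L) {
    warning("no nonzero gradient magnitudes; thresholds set to (0, 0)",
            call. = FALSE)
    return(c(t_low = 0, t_high = 0))
  }
  v <- sort(v)
  t_high <- v[ceiling(q_high * length(v))]   # nearest-rank quantile
  c(t_low = low_ratio * t_high, t_high = t_high)
}

# Binary dilation restricted to a mask, iterated to the fixpoint: the set of
# `weak` pixels transitively connected to `seed` under 4- or 8-connectivity.
propagate <- function(seed, weak, connectivity = 8L) {
  nr <- nrow(seed); nc <- ncol(seed)
  offs <- if (connectivity == 4L) {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  } else {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
         c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  }
  cur <- seed
  repeat {
    p <- matrix(FALSE, nr + 2L, nc + 2L)
    p[1L + seq_len(nr), 1L + seq_len(nc)] <- cur
    grown <- cur
    for (d in offs) {
      grown <- grown | p[d[1L] + 1L + seq_len(nr), d[2L] + 1L + seq_len(nc),
                         drop = FALSE]
    }
    nxt <- cur | (grown & weak)
    if (all(nxt == cur)) return(cur)
    cur <- nxt
  }
}

#' Double-threshold hysteresis edge linking
#'
#' Pixels with suppressed magnitude at or above `t_high` are strong edges;
#' pixels in `[t_low, t_high)` are weak candidates; a weak pixel becomes an
#' edge exactly when it is connected - transitively, through weak pixels,
#' under the chosen connectivity - to some strong pixel. Pixels with zero
#' magnitude are never edges (so a blank raster yields an empty edge map even
#' at `t_high = 0`).
#'
#' @inheritParams auto_thresholds
#' @param t_low,t_high magnitude thresholds, `0 <= t_low <= t_high`.
#' @param connectivity 4 or 8 (default 8).
#' @return an object of class `edge_map`: list with logical matrix `edges`
#'   and character matrix `provenance` with per-pixel labels `"none"`,
#'   `"weak-suppressed"`, `"strong"`, `"weak-linked"`.
#' @export
hysteresis_link <- function(suppressed, t_low, t_high, connectivity = 8L) {
  if (t_low > t_high) stopf("t_low (%g) must not exceed t_high (%g)",
                            t_low, t_high)
  if (t_low < 0) stopf("thresholds must be nonnegative")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stopf("connectivity must be 4 or 8")
  m <- as.matrix(suppressed)
  strong <- m >= t_high & m > 0
  weak <- m >= t_low & m < t_high & m > 0
  linked <- propagate(strong, weak, connectivity) & weak
  prov <- matrix("none", nrow(m), ncol(m))
  prov[weak] <- "weak-suppressed"
  prov[linked] <- "weak-linked"
  prov[strong] <- "strong"
  structure(list(edges = strong | linked, provenance = prov),
            class = "edge_map")
}

#' @export
print.edge_map <- function(x, ...) {
  cat(sprintf("<edge_map> %d x %d, %d edge pixels (%d strong, %d weak-linked)\n",
              nrow(x$edges), ncol(x$edges), sum(x$edges),
              sum(x$provenance == "strong"), sum(x$provenance == "weak-linked")))
  invisible(x)
}

#' @export
plot.edge_map <- function(x, ...) {
  m <- x$edges * 1
  graphics::image(t(m[nrow(m):1, , drop = FALSE]),
                  col = c("black", "white"), axes = FALSE,
                  asp = nrow(m) / ncol(m), ...)
  invisible(x)
}

#' Canny parameter set
#'
#' @param delta Gaussian smoothing standard deviation in pixels.
#' @param kernel_radius smoothing kernel half-width (default
#'   `ceiling(3 * delta)`).
#' @param t_low,t_high absolute magnitude thresholds; leave `NULL` to derive
#'   them per image with [auto_thresholds()].
#' @param q_high,low_ratio quantile parameters used when absolute thresholds
#'   are unset.
#' @param connectivity 4 or 8.
#' @return a list of class `canny_params`.
#' @export
canny_params <- function(delta = 1, kernel_radius = ceiling(3 * delta),
                         t_low = NULL, t_high = NULL,
                         q_high = 0.90, low_ratio = 0.4, connectivity = 8L) {
  if (delta <= 0) stopf("delta must be positive")
  if (!is.null(t_low) != !is.null(t_high))
    stopf("set both t_low and t_high, or neither")
  if (!is.null(t_low) && (t_low < 0 || t_low > t_high))
    stopf("need 0 <= t_low <= t_high")
  structure(list(delta = delta, kernel_radius = as.integer(kernel_radius),
                 t_low = t_low, t_high = t_high, q_high = q_high,
                 low_ratio = low_ratio, connectivity = as.integer(connectivity)),
            class = "canny_params")
}

#' Canny edge detection
#'
#' The full chain: Gaussian smoothing, Sobel gradients, non-maximum
#' suppression, (automatic) double thresholds, hysteresis linking. All stage
#' intermediates are attached to the result for inspection.
#'
#' @param image an `image_raster` or numeric matrix.
#' @param params a [canny_params()] object.
#' @return an `edge_map` with attribute `stages`: list with `smoothed`,
#'   `gradients`, `suppressed`, `thresholds`.
#' @examples
#' ph <- make_phantom(phantom_spec(noise_model = "none"))
#' em <- canny(ph$clean, canny_params(delta = 1))
#' @export
canny <- function(image, params = canny_params()) {
  if (!inherits(params, "canny_params")) stopf("params must be canny_params()")
  image <- as_image(image)
  sm <- smooth_raster(image, params$delta, params$kernel_radius)
  gf <- sobel_gradients(sm)
  sup <- nonmax_suppress(gf)
  thr <- if (is.null(params$t_high)) {
    if (any(sup > 0)) {
      auto_thresholds(sup, params$q_high, params$low_ratio)
    } else {
      c(t_low = 0, t_high = 0)   # blank image: nothing to threshold
    }
  } else {
    c(t_low = params$t_low, t_high = params$t_high)
  }
  em <- hysteresis_link(sup, thr[["t_low"]], thr[["t_high"]],
                        params$connectivity)
  attr(em, "stages") <- list(smoothed = sm, gradients = gf, suppressed = sup,
                             thresholds = thr)
  em
}

#' L2 approximation degree between two rasters
#'
#' Discrete L2 distance `sqrt(sum((f - g)^2))` over all pixels, the degree to
#' which one raster approximates another (0 means identical).
#'
#' @param f,g rasters or matrices of identical dimensions.
#' @return nonnegative scalar.
#' @export
approximation_degree <- function(f, g) {
  f <- as.matrix(f); g <- as.matrix(g)
  if (!all(dim(f) == dim(g)))
    stopf("dimension mismatch: %dx%d vs %dx%d", nrow(f), ncol(f),
          nrow(g), ncol(g))
  sqrt(sum((f - g)^2))
}

# Label 8- (or 4-) connected components of a logical matrix by breadth-first
# search. Returns an integer matrix, 0 = background; components are numbered
# in raster scan order of their first pixel.
label_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 4L) {
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  } else {
    cbind(rep(-1L:1L, 3L), rep(-1L:1L, each = 3L))[-5L, , drop = FALSE]
  }
  nxt <- 0L
  # scan column-major so "first pixel" = lexicographically smallest (row, col)
  # within each column order; components re-sorted by min pixel below
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    nxt <- nxt + 1L
    stack <- matrix(c(r0, c0), 1L)
    lab[r0, c0] <- nxt
    while (nrow(stack) > 0L) {
      cur <- stack[nrow(stack), ]
      stack <- stack[-nrow(stack), , drop = FALSE]
      for (k in seq_len(nrow(offs))) {
        r <- cur[1L] + offs[k, 1L]; c <- cur[2L] + offs[k, 2L]
        if (r >= 1L && r <= nr && c >= 1L && c <= nc &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          stack <- rbind(stack, c(r, c))
        }
      }
    }
  }
  lab
}

#' Extract the candidate synovial contour from an edge map
#'
#' Returns the largest connected component of the edge set as the candidate
#' synovial contour, with a flag stating whether it encloses a nonempty
#' interior (pixels unreachable by a flood fill of the non-contour area
#' started from the raster border). Ties on component size are broken toward
#' the component whose minimal `(row, col)` pixel is lexicographically
#' smallest.
#'
#' @param edge_map an `edge_map`.
#' @param connectivity connectivity for the component search (default 8).
#' @return list with logical matrix `contour` and logical `closed`.
#' @export
extract_synovial_contour <- function(edge_map, connectivity = 8L) {
  if (!inherits(edge_map, "edge_map")) stopf("not an edge_map")
  e <- edge_map$edges
  if (!any(e)) {
    return(list(contour = matrix(FALSE, nrow(e), ncol(e)), closed = FALSE))
  }
  lab <- label_components(e, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  best_ids <- which(sizes == max(sizes))
  if (length(best_ids) > 1L) {
    # lexicographically smallest (row, col) first pixel wins
    first_px <- t(vapply(best_ids, function(id) {
      w <- which(lab == id, arr.ind = TRUE)
      w[order(w[, 1L], w[, 2L])[1L], ]
    }, integer(2L)))
    o <- order(first_px[, 1L], first_px[, 2L])
    best <- best_ids[o[1L]]
  } else {
    best <- best_ids
  }
  contour <- lab == best
  # flood the complement from the border (4-connected background so that an
  # 8-connected one-pixel ring is watertight)
  free <- !contour
  seed <- matrix(FALSE, nrow(e), ncol(e))
  seed[1L, ] <- free[1L, ]; seed[nrow(e), ] <- free[nrow(e), ]
  seed[, 1L] <- free[, 1L]; seed[, ncol(e)] <- free[, ncol(e)]
  outside <- propagate(seed, free, 4L)
  closed <- any(free & !outside)
  list(contour = contour, closed = closed)
}
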