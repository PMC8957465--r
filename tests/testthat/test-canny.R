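test_that("gaussian kernel is normalized with the analytic center weight", {
  for (delta in c(0.5, 1, 2.3)) {
    k <- gaussian_kernel(delta, 3)
    expect_equal(sum(k), 1)
  }
  # delta 1, radius 1: center = 1 / (1 + 4 e^-1/2 + 4 e^-1)
  k <- gaussian_kernel(1, 1)
  expect_equal(k[2, 2], 1 / (1 + 4 * exp(-0.5) + 4 * exp(-1)),
               tolerance = 1e-12)
  # near-identity limit
  k0 <- gaussian_kernel(1e-3, 1)
  expect_gte(k0[2, 2], 1 - 1e-6)
  expect_error(gaussian_kernel(0), "delta")
})

test_that("smoothing fixes constants, reproduces the kernel on an impulse, and is linear", {
  const <- image_raster(matrix(100, 9, 9))
  expect_equal(as.matrix(smooth_raster(const, 1.7)),
               matrix(100, 9, 9), ignore_attr = TRUE)

  imp <- matrix(0, 7, 7); imp[4, 4] <- 1
  sm <- as.matrix(smooth_raster(image_raster(imp), 1, radius = 1))
  expect_equal(sm[3:5, 3:5], gaussian_kernel(1, 1), ignore_attr = TRUE,
               tolerance = 1e-12)

  set.seed(42)
  for (rep in 1:5) {
    I <- matrix(runif(64, 0, 255), 8, 8)
    J <- matrix(runif(64, 0, 255), 8, 8)
    a <- runif(1, -2, 2); b <- runif(1, -2, 2)
    lhs <- as.matrix(smooth_raster(image_raster(a * I + b * J), 1.2))
    rhs <- a * as.matrix(smooth_raster(image_raster(I), 1.2)) +
           b * as.matrix(smooth_raster(image_raster(J), 1.2))
    expect_equal(lhs, rhs, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("Sobel gradients match hand evaluation and the magnitude identity", {
  expect_error(sobel_gradients(image_raster(matrix(1, 2, 2))), "3x3")

  gf <- sobel_gradients(image_raster(matrix(7, 6, 6)))
  expect_true(all(gf$gx == 0) && all(gf$gy == 0) && all(gf$magnitude == 0))
  expect_true(all(gf$direction == 0))

  # vertical step: columns 1:4 zero, 5:8 one; at column 4 the left neighbors
  # are 0 and right neighbors are 1, so gx = 1 + 2 + 1 = 4, gy = 0
  step <- matrix(rep(c(0, 0, 0, 0, 1, 1, 1, 1), each = 8), 8, 8)
  gf <- sobel_gradients(image_raster(step))
  expect_equal(gf$gx[4, 4], 4)
  expect_equal(gf$gy[4, 4], 0)
  expect_equal(gf$magnitude[4, 4], 4)

  # Eq-consistency and 90-degree rotation equivariance on random rasters
  set.seed(7)
  for (rep in 1:5) {
    m <- matrix(runif(64, 0, 255), 8, 8)
    gf <- sobel_gradients(image_raster(m))
    expect_equal(gf$magnitude^2, gf$gx^2 + gf$gy^2, tolerance = 1e-9)
    # rotate 90 deg counterclockwise in raster terms
    rot <- t(m)[ncol(m):1, ]
    gr <- sobel_gradients(image_raster(rot))
    expect_equal(gr$magnitude, t(gf$magnitude)[ncol(m):1, ], tolerance = 1e-9)
  }
})

test_that("literal two-quadrant direction mode leaves the edge output unchanged", {
  m <- random_raster(12, seed = 31)
  a <- sobel_gradients(image_raster(m))
  b <- sobel_gradients(image_raster(m), literal_direction = TRUE)
  expect_equal(a$gx, b$gx)
  expect_false(isTRUE(all.equal(a$direction, b$direction)))
  # NMS consumes (gx, gy), not the stored angle
  expect_equal(nonmax_suppress(a), nonmax_suppress(b))
})

test_that("non-maximum suppression keeps lone maxima, kills plateaus, preserves ridges", {
  # single nonzero pixel survives (neighbors are 0, strict inequality holds)
  gf <- structure(list(gx = matrix(0, 5, 5), gy = matrix(0, 5, 5),
                       magnitude = matrix(0, 5, 5),
                       direction = matrix(0, 5, 5)), class = "gradient_field")
  gf$gx[3, 3] <- 3; gf$gy[3, 3] <- 4
  gf$magnitude[3, 3] <- 5
  out <- nonmax_suppress(gf)
  expect_equal(out[3, 3], 5)
  expect_equal(sum(out), 5)

  # flat plateau of constant magnitude with horizontal gradient: all interior
  # suppressed under the strict-greater rule
  gf2 <- structure(list(gx = matrix(1, 5, 5), gy = matrix(0, 5, 5),
                        magnitude = matrix(1, 5, 5),
                        direction = matrix(0, 5, 5)), class = "gradient_field")
  expect_true(all(nonmax_suppress(gf2) == 0))

  # one-pixel-wide vertical ridge with horizontal gradients survives intact
  mag <- matrix(0, 7, 7); mag[, 4] <- 4
  gx <- matrix(0, 7, 7); gx[, 4] <- 4
  gf3 <- structure(list(gx = gx, gy = matrix(0, 7, 7), magnitude = mag,
                        direction = matrix(0, 7, 7)), class = "gradient_field")
  out3 <- nonmax_suppress(gf3)
  expect_equal(out3[, 4], rep(4, 7))
  expect_equal(sum(out3 != 0), 7)

  # never increases magnitudes, never creates nonzeros
  set.seed(11)
  for (rep in 1:10) {
    m <- random_raster(10, seed = rep)
    f <- sobel_gradients(image_raster(m))
    s <- nonmax_suppress(f)
    expect_true(all(s <= f$magnitude + 1e-12))
    expect_true(all(s[f$magnitude == 0] == 0))
  }
})

test_that("auto thresholds use nearest-rank quantiles of nonzero magnitudes", {
  sup <- matrix(0, 10, 10)
  sup[1:100] <- 1:100
  th <- auto_thresholds(sup, 0.90, 0.4)
  expect_equal(th[["t_high"]], 90)
  expect_equal(th[["t_low"]], 36)
  th1 <- auto_thresholds(sup, 0.90, 1)
  expect_equal(th1[["t_low"]], th1[["t_high"]])
  expect_warning(z <- auto_thresholds(matrix(0, 4, 4)), "no nonzero")
  expect_equal(unname(z), c(0, 0))
})

test_that("hysteresis links weak pixels through weak chains to strong seeds", {
  sup <- matrix(0, 5, 5)
  sup[3, 3] <- 10
  em <- hysteresis_link(sup, 2, 5)
  expect_true(em$edges[3, 3])
  expect_equal(em$provenance[3, 3], "strong")

  sup2 <- matrix(0, 5, 5); sup2[3, 3] <- 4   # isolated weak pixel
  em2 <- hysteresis_link(sup2, 2, 5)
  expect_false(any(em2$edges))
  expect_equal(em2$provenance[3, 3], "weak-suppressed")

  # weak-weak-strong diagonal chain is fully linked under 8-connectivity
  sup3 <- matrix(0, 5, 5)
  sup3[1, 1] <- 3; sup3[2, 2] <- 3; sup3[3, 3] <- 10
  em3 <- hysteresis_link(sup3, 2, 5, connectivity = 8)
  expect_true(all(em3$edges[cbind(1:3, 1:3)]))
  expect_equal(em3$provenance[1, 1], "weak-linked")
  # but not under 4-connectivity (diagonal steps are not adjacent)
  em4 <- hysteresis_link(sup3, 2, 5, connectivity = 4)
  expect_equal(sum(em4$edges), 1)

  expect_error(hysteresis_link(sup, 6, 5), "t_low")
})

test_that("hysteresis equals the flood-fill oracle on random rasters", {
  for (seed in 1:20) {
    set.seed(seed)
    sup <- matrix(rexp(64, 1 / 20), 8, 8)
    sup[sample(64, 30)] <- 0
    th <- sort(runif(2, 0, 40))
    for (conn in c(4L, 8L)) {
      em <- hysteresis_link(sup, th[1], th[2], conn)
      expect_equal(em$edges, ref_hysteresis(sup, th[1], th[2], conn))
    }
  }
})

test_that("hysteresis is monotone in both thresholds", {
  set.seed(5)
  sup <- matrix(rexp(100, 1 / 10), 10, 10)
  base <- hysteresis_link(sup, 4, 12)$edges
  lower_tlow <- hysteresis_link(sup, 2, 12)$edges
  expect_true(all(base <= lower_tlow))      # lowering t_low never removes
  higher_thigh <- hysteresis_link(sup, 4, 18)$edges
  expect_true(all(higher_thigh <= base))    # raising t_high never adds
})

test_that("the full chain matches an independent reference implementation", {
  for (seed in 1:30) {
    m <- random_raster(16, seed = seed)
    em <- canny(image_raster(m), canny_params(delta = 1))
    expect_equal(em$edges, ref_canny(m, delta = 1),
                 info = paste("seed", seed))
  }
})

test_that("a blank image yields an empty edge map", {
  em <- canny(image_raster(matrix(50, 32, 32)))
  expect_false(any(em$edges))
})

test_that("a filled disk yields one closed ring within 1.5 px of the circle", {
  n <- 64; R <- 20
  img <- matrix(30, n, n)
  rr <- matrix(seq_len(n), n, n); cc <- t(rr)
  img[(rr - 32)^2 + (cc - 32)^2 <= R^2] <- 200
  em <- canny(image_raster(img), canny_params(delta = 1))
  expect_true(any(em$edges))
  w <- which(em$edges, arr.ind = TRUE)
  dist <- abs(sqrt((w[, 1] - 32)^2 + (w[, 2] - 32)^2) - R)
  expect_lt(max(dist), 1.5)
  ct <- extract_synovial_contour(em)
  expect_true(ct$closed)
  expect_equal(sum(ct$contour), sum(em$edges))  # single 8-connected ring
})

test_that("approximation degree is the discrete L2 distance and a metric", {
  f <- matrix(0, 2, 2); g <- matrix(3, 2, 2)
  expect_equal(approximation_degree(f, f), 0)
  expect_equal(approximation_degree(f, g), 6)
  expect_error(approximation_degree(f, matrix(0, 3, 3)), "mismatch")
  set.seed(3)
  for (rep in 1:10) {
    a <- matrix(runif(16), 4, 4); b <- matrix(runif(16), 4, 4)
    h <- matrix(runif(16), 4, 4)
    expect_lte(approximation_degree(a, h),
               approximation_degree(a, b) + approximation_degree(b, h) + 1e-12)
  }
})

test_that("contour extraction picks the largest component with the documented tie-break", {
  e <- matrix(FALSE, 10, 20)
  e[2, 2:9] <- TRUE            # size 8
  e[7:8, c(2, 3)] <- TRUE      # size 4
  em <- structure(list(edges = e, provenance = NULL), class = "edge_map")
  ct <- extract_synovial_contour(em)
  expect_equal(sum(ct$contour), 8)
  expect_true(all(which(ct$contour, arr.ind = TRUE)[, 1] == 2))
  expect_false(ct$closed)      # open segment encloses nothing

  # equal sizes: the component whose minimal (row, col) pixel is smallest wins
  e2 <- matrix(FALSE, 6, 6)
  e2[5, 1:3] <- TRUE
  e2[2, 4:6] <- TRUE
  em2 <- structure(list(edges = e2, provenance = NULL), class = "edge_map")
  ct2 <- extract_synovial_contour(em2)
  expect_true(all(which(ct2$contour, arr.ind = TRUE)[, 1] == 2))

  empty <- structure(list(edges = matrix(FALSE, 4, 4), provenance = NULL),
                     class = "edge_map")
  ct3 <- extract_synovial_contour(empty)
  expect_false(any(ct3$contour))
  expect_false(ct3$closed)
})
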