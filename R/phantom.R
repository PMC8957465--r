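#' Synthetic joint-phantom specification
#'
#' Describes a 2-D joint phantom: two (or more) elliptical bone cross
#' sections, a synovial ring (annulus) whose filled outer disk defines the
#' joint region, an effusion blob occupying a prescribed fraction of the
#' joint region, and near-zero-intensity hemosiderin foci (hemosiderin is
#' markedly hypointense on MRI). The concentric geometry gives a closed
#' synovial contour with analytically known areas, so edge detection and
#' scoring can be validated against ground truth.
#'
#' Coordinates are `(row, col)`, 1-based, row increasing downward.
#'
#' @param height,width raster size in pixels.
#' @param bit_depth bits per pixel (default 8).
#' @param bone_geometry list of ellipses, each
#'   `list(center = c(row, col), axes = c(semi_row, semi_col), intensity)`;
#'   `NULL` for none.
#' @param synovium_ring `list(center, inner_radius, thickness, intensity)` in
#'   pixels, or `NULL`; the joint region is the filled disk of radius
#'   `inner_radius + thickness` (the whole raster if no ring is given).
#' @param effusion_fraction target effusion area as a fraction of the
#'   joint-region area, in `[0, 1)`; 0 disables the blob.
#' @param effusion_intensity rendered intensity of the effusion blob.
#' @param hemosiderin_foci `list(count, radius, intensity)`; foci are placed
#'   deterministically just inside the synovial ring. `count = 0` disables.
#' @param noise_model `"none"`, `"gaussian"` or `"rician"` (the default:
#'   MRI magnitude statistics).
#' @param noise_sigma noise scale in intensity units (>= 0).
#' @param background,intensity_synovium,intensity_bone rendering intensities.
#' @param seed integer seed for the noise draw.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 128L, width = 128L, bit_depth = 8L,
                         bone_geometry = list(
                           list(center = c(20, 64), axes = c(12, 28),
                                intensity = 200),
                           list(center = c(108, 64), axes = c(12, 28),
                                intensity = 200)),
                         synovium_ring = list(center = c(64, 64),
                                              inner_radius = 28, thickness = 8,
                                              intensity = 120),
                         effusion_fraction = 0.10,
                         effusion_intensity = 170,
                         hemosiderin_foci = list(count = 2L, radius = 4,
                                                 intensity = 2),
                         noise_model = c("rician", "gaussian", "none"),
                         noise_sigma = 20, background = 30,
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  spec <- structure(list(height = as.integer(height), width = as.integer(width),
                         bit_depth = as.integer(bit_depth),
                         bone_geometry = bone_geometry,
                         synovium_ring = synovium_ring,
                         effusion_fraction = effusion_fraction,
                         effusion_intensity = effusion_intensity,
                         hemosiderin_foci = hemosiderin_foci,
                         noise_model = noise_model, noise_sigma = noise_sigma,
                         background = background, seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  h <- spec$height; w <- spec$width
  if (h < 8L || w < 8L) stopf("phantom raster must be at least 8x8")
  if (!(spec$effusion_fraction >= 0 && spec$effusion_fraction < 1))
    stopf("effusion_fraction must lie in [0, 1)")
  if (spec$noise_sigma < 0) stopf("noise_sigma must be >= 0")
  inside <- function(r, c) r >= 1 && r <= h && c >= 1 && c <= w
  for (i in seq_along(spec$bone_geometry)) {
    b <- spec$bone_geometry[[i]]
    if (!inside(b$center[1] - b$axes[1], b$center[2] - b$axes[2]) ||
        !inside(b$center[1] + b$axes[1], b$center[2] + b$axes[2]))
      stopf("bone ellipse %d extends outside the %dx%d raster", i, h, w)
  }
  ring <- spec$synovium_ring
  if (!is.null(ring)) {
    r_out <- ring$inner_radius + ring$thickness
    if (ring$thickness <= 0 || ring$inner_radius <= 0)
      stopf("synovium_ring radii must be positive")
    if (!inside(ring$center[1] - r_out, ring$center[2] - r_out) ||
        !inside(ring$center[1] + r_out, ring$center[2] + r_out))
      stopf("synovium_ring extends outside the %dx%d raster", h, w)
  }
  hf <- spec$hemosiderin_foci
  if (!is.null(hf) && hf$count > 0 && is.null(ring))
    stopf("hemosiderin foci need a synovium_ring to be placed in")
  invisible(spec)
}

disk_mask <- function(h, w, center, radius) {
  r <- matrix(seq_len(h), h, w)
  c <- matrix(seq_len(w), h, w, byrow = TRUE)
  (r - center[1])^2 + (c - center[2])^2 <= radius^2
}

ellipse_mask <- function(h, w, center, axes) {
  r <- matrix(seq_len(h), h, w)
  c <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((r - center[1]) / axes[1])^2 + ((c - center[2]) / axes[2])^2 <= 1
}

#' Add seeded noise to a raster
#'
#' Gaussian noise adds zero-mean normal deviates; Rician noise (the magnitude
#' statistics of complex MRI data) replaces each pixel `v` by
#' `sqrt((v + n1)^2 + n2^2)` with independent zero-mean normal `n1`, `n2` of
#' standard deviation `sigma`. Either way the result is clipped to
#' `[0, 2^bit_depth - 1]`. The draw is seeded and reproducible; the caller's
#' RNG state is untouched.
#'
#' @param image an `image_raster`.
#' @param model `"gaussian"`, `"rician"` or `"none"`.
#' @param sigma noise standard deviation in intensity units (>= 0).
#' @param seed integer seed.
#' @return an `image_raster` of the same dimensions and depth.
#' @export
add_noise <- function(image, model = c("rician", "gaussian", "none"),
                      sigma = 10, seed = 1L) {
  model <- match.arg(model)
  if (sigma < 0) stopf("sigma must be >= 0")
  image <- as_image(image)
  m <- as_raster_matrix(image)
  if (model == "none" || sigma == 0) return(image)
  out <- with_seed(seed, {
    if (model == "gaussian") {
      m + matrix(stats::rnorm(length(m), 0, sigma), nrow(m), ncol(m))
    } else {
      n1 <- matrix(stats::rnorm(length(m), 0, sigma), nrow(m), ncol(m))
      n2 <- matrix(stats::rnorm(length(m), 0, sigma), nrow(m), ncol(m))
      sqrt((m + n1)^2 + n2^2)
    }
  })
  mx <- raster_max(image)
  image_raster(pmin(pmax(out, 0), mx), bit_depth(image))
}

#' Render a joint phantom
#'
#' Renders the phantom described by a [phantom_spec()]: background, then bone
#' ellipses, synovial ring, effusion blob and hemosiderin foci, in that order
#' (later layers overwrite earlier ones; each class's mask holds the pixels
#' where that class is topmost). The effusion blob is a disk whose radius is
#' chosen so its area is `effusion_fraction` of the rendered joint-region
#' area, placed inside the ring. Ground-truth IPSG grades are computed from
#' the rendered masks with [score_from_masks()], so mask/grade consistency
#' holds by construction.
#'
#' @param spec a [phantom_spec()].
#' @param thresholds [grade_thresholds()] used for the ground-truth grades.
#' @return list of class `phantom_image`: `clean` and `noisy` rasters, the
#'   `masks` list (`joint_region`, `bone`, `bones`, `synovium`, `effusion`,
#'   `hemosiderin`), `true_grades` (an [ipsg_card()]) and the `spec`.
#' @examples
#' ph <- make_phantom(phantom_spec(seed = 7))
#' ph$true_grades$effusion   # grade 2 at the default 10% effusion fraction
#' @export
make_phantom <- function(spec = phantom_spec(),
                         thresholds = grade_thresholds()) {
  validate_phantom_spec(spec)
  h <- spec$height; w <- spec$width
  img <- matrix(spec$background, h, w)
  empty <- matrix(FALSE, h, w)
  bones <- list()
  for (b in spec$bone_geometry) {
    bm <- ellipse_mask(h, w, b$center, b$axes)
    img[bm] <- b$intensity
    bones[[length(bones) + 1L]] <- bm
  }
  ring <- spec$synovium_ring
  if (!is.null(ring)) {
    outer_disk <- disk_mask(h, w, ring$center,
                            ring$inner_radius + ring$thickness)
    inner_disk <- disk_mask(h, w, ring$center, ring$inner_radius)
    syn <- outer_disk & !inner_disk
    img[syn] <- ring$intensity
    joint_region <- outer_disk
  } else {
    syn <- empty
    joint_region <- !empty
  }
  eff <- empty
  if (spec$effusion_fraction > 0) {
    if (is.null(ring))
      stopf("an effusion blob needs a synovium_ring joint region")
    target <- spec$effusion_fraction * sum(joint_region)
    r_eff <- sqrt(target / pi)
    room <- ring$inner_radius - r_eff - 1
    if (room < 0)
      stopf("effusion blob (radius %.1f px) does not fit inside the ring",
            r_eff)
    off <- 0.45 * room
    ec <- ring$center + c(off, -off) / sqrt(2)
    eff <- disk_mask(h, w, ec, r_eff) & joint_region
    img[eff] <- spec$effusion_intensity
  }
  hem <- empty
  hf <- spec$hemosiderin_foci
  if (!is.null(hf) && hf$count > 0) {
    rad_pos <- ring$inner_radius - hf$radius - 1
    if (rad_pos <= 0) stopf("hemosiderin focus radius too large for the ring")
    for (k in seq_len(hf$count)) {
      ang <- 2 * pi * (k - 1) / hf$count + pi / 6
      fc <- ring$center + rad_pos * c(sin(ang), cos(ang))
      fm <- disk_mask(h, w, fc, hf$radius)
      img[fm] <- hf$intensity
      hem <- hem | fm
    }
  }
  # masks reflect the final layering: later layers overwrite earlier ones
  bones_top <- lapply(bones, function(bm) bm & !syn & !eff & !hem)
  bone_top <- Reduce(`|`, bones_top, empty)
  syn_top <- syn & !eff & !hem
  eff_top <- eff & !hem
  masks <- list(joint_region = joint_region, bone = bone_top,
                bones = bones_top, synovium = syn_top, effusion = eff_top,
                hemosiderin = hem)
  clean <- image_raster(img, spec$bit_depth)
  noisy <- add_noise(clean, spec$noise_model, spec$noise_sigma, spec$seed)
  grade_masks <- masks
  if (is.null(ring)) {
    # no joint structure: grade against an all-true region (empty lesions
    # still give an all-zero card)
    grade_masks$joint_region <- !empty
  }
  true_grades <- score_from_masks(grade_masks, thresholds)
  structure(list(clean = clean, noisy = noisy, masks = masks,
                 true_grades = true_grades, spec = spec),
            class = "phantom_image")
}

#' @export
print.phantom_image <- function(x, ...) {
  ts <- total_score(x$true_grades)
  cat(sprintf("<phantom_image> %dx%d %d-bit, %s noise (sigma %g), true IPSG total %d\n",
              x$spec$height, x$spec$width, x$spec$bit_depth,
              x$spec$noise_model, x$spec$noise_sigma, ts[["total"]]))
  invisible(x)
}

#' @export
plot.phantom_image <- function(x, which = c("clean", "noisy"), ...) {
  which <- match.arg(which)
  plot(x[[which]], main = paste("phantom:", which), ...)
  invisible(x)
}

#' Write a phantom's rasters and masks to a directory
#'
#' `clean` and `noisy` go out as PNG (8-bit) or NIfTI (any depth); each mask
#' as a 0/1 PNG.
#'
#' @param phantom a `phantom_image`.
#' @param dir output directory (created if missing).
#' @param format `"png"` or `"nii"`.
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir, format = c("png", "nii")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- format
  write_raster(phantom$clean, file.path(dir, paste0("clean.", ext)))
  write_raster(phantom$noisy, file.path(dir, paste0("noisy.", ext)))
  for (nm in c("joint_region", "bone", "synovium", "effusion", "hemosiderin")) {
    m <- phantom$masks[[nm]]
    png::writePNG(m * 1, file.path(dir, paste0("mask_", nm, ".png")))
  }
  invisible(dir)
}
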