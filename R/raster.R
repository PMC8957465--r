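#' Grayscale image rasters
#'
#' `image_raster()` wraps a numeric matrix as the pipeline's universal pixel
#' container. Pixels are kept real-valued internally (intermediate stages such
#' as Gaussian smoothing are not quantized); values are clipped and rounded to
#' the integer range `[0, 2^bit_depth - 1]` only when a raster is written to
#' disk.
#'
#' Indexing convention used throughout the package: `x` is the column index,
#' `y` is the row index, with `y` increasing downward (the usual raster
#' convention), both 1-based as is natural in R.
#'
#' @param pixels numeric matrix of intensities (rows = y, columns = x).
#' @param bit_depth integer bit depth; the representable maximum is
#'   `2^bit_depth - 1` (255 for the 8-bit default).
#' @return An object of class `image_raster`: the pixel matrix with a
#'   `bit_depth` attribute.
#' @examples
#' r <- image_raster(matrix(0, 32, 32))
#' raster_max(r)
#' @export
image_raster <- function(pixels, bit_depth = 8L) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stopf("pixels must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stopf("raster must be at least 1x1")
  bit_depth <- as.integer(bit_depth)
  if (is.na(bit_depth) || bit_depth < 1L || bit_depth > 31L)
    stopf("bit_depth must be an integer in [1, 31]")
  structure(pixels, bit_depth = bit_depth, class = c("image_raster", "matrix"))
}

#' @rdname image_raster
#' @param x an `image_raster`.
#' @export
raster_max <- function(x) 2^attr(x, "bit_depth") - 1

#' @rdname image_raster
#' @export
bit_depth <- function(x) attr(x, "bit_depth") %||% 8L

`%||%` <- function(a, b) if (is.null(a)) b else a

as_raster_matrix <- function(x) {
  m <- unclass(x)
  attr(m, "bit_depth") <- NULL
  m
}

#' @export
print.image_raster <- function(x, ...) {
  cat(sprintf("<image_raster> %d x %d, %d-bit, range [%.3g, %.3g]\n",
              nrow(x), ncol(x), bit_depth(x), min(x), max(x)))
  invisible(x)
}

#' @export
plot.image_raster <- function(x, ..., main = NULL) {
  m <- as_raster_matrix(x)
  # image() draws column-major bottom-up; transpose and flip for raster order
  graphics::image(t(m[nrow(m):1, , drop = FALSE]),
                  col = grDevices::gray.colors(256, 0, 1),
                  axes = FALSE, asp = nrow(m) / ncol(m), main = main, ...)
  invisible(x)
}

# Clip to the representable range and round to integers (write-time contract).
quantize <- function(x) {
  mx <- raster_max(x)
  m <- pmin(pmax(round(as_raster_matrix(x)), 0), mx)
  image_raster(m, bit_depth(x))
}

#' Read and write rasters
#'
#' PNG (8-bit grayscale) and NIfTI (arbitrary depth) round-trips. The format
#' is inferred from the file extension. PNG files are written quantized to
#' 8 bits; NIfTI stores the integer-quantized values at the declared depth.
#'
#' @param path file path ending in `.png`, `.nii` or `.nii.gz`.
#' @param raster an `image_raster`.
#' @param bit_depth depth to assume when reading NIfTI (taken from the file's
#'   data range otherwise); PNG is always read as 8-bit.
#' @return `read_raster()` returns an `image_raster`; `write_raster()` returns
#'   `path` invisibly.
#' @export
read_raster <- function(path, bit_depth = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (tolower(tools::file_ext(path)) == "png") {
    arr <- tryCatch(png::readPNG(path),
                    error = function(e) stopf("failed to read PNG %s: %s",
                                              path, conditionMessage(e)))
    if (length(dim(arr)) == 3L) arr <- arr[, , 1L]  # first channel of RGB(A)
    image_raster(round(arr * 255), 8L)
  } else if (ext == "nii") {
    arr <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stopf("failed to read NIfTI %s: %s",
                                              path, conditionMessage(e)))
    m <- as.matrix(arr[, ])
    bd <- if (is.null(bit_depth)) {
      mx <- max(m, 0)
      max(8L, as.integer(ceiling(log2(mx + 1))))
    } else as.integer(bit_depth)
    image_raster(m, bd)
  } else {
    stopf("unsupported raster format '%s' (supported: png, nii, nii.gz)", ext)
  }
}

#' @rdname read_raster
#' @export
write_raster <- function(raster, path) {
  if (!inherits(raster, "image_raster")) stopf("not an image_raster")
  q <- quantize(raster)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (tolower(tools::file_ext(path)) == "png") {
    if (bit_depth(raster) != 8L)
      stopf("PNG output supports 8-bit rasters only (got %d-bit); use NIfTI",
            bit_depth(raster))
    png::writePNG(as_raster_matrix(q) / 255, path)
  } else if (ext == "nii") {
    dtype <- if (bit_depth(raster) <= 8L) "uint8" else "int32"
    RNifti::writeNifti(RNifti::asNifti(as_raster_matrix(q), datatype = dtype),
                       path)
  } else {
    stopf("unsupported raster format '%s' (supported: png, nii, nii.gz)", ext)
  }
  invisible(path)
}
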