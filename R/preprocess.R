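#' Binary specimen image
#'
#' Container for a binarized specimen raster: a logical mask (`TRUE` =
#' specimen foreground), an optional pixel-to-physical-unit scale, and a
#' provenance record of how the mask was produced (threshold level actually
#' used, polarity, morphology radii), so that a semi-automated analysis
#' remains reproducible.
#'
#' @param mask logical matrix, `TRUE` on the specimen.
#' @param pixel_scale optional positive number: physical length per pixel.
#' @param provenance named list of processing settings.
#' @return An object of class `binary_image`.
#' @export
binary_image <- function(mask, pixel_scale = NULL, provenance = list()) {
  stopifnot(is.matrix(mask))
  mask <- mask & TRUE  # coerce numeric 0/1 to logical, keep dims
  if (!is.null(pixel_scale)) {
    stopifnot(is.numeric(pixel_scale), length(pixel_scale) == 1L, pixel_scale > 0)
  }
  structure(list(mask = mask, pixel_scale = pixel_scale,
                 provenance = provenance),
            class = "binary_image")
}

#' @export
print.binary_image <- function(x, ...) {
  cat(sprintf("<binary_image> %d x %d px, %d foreground px (%.1f%%)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              100 * mean(x$mask)))
  if (!is.null(x$pixel_scale))
    cat(sprintf("  pixel scale: %g units/px\n", x$pixel_scale))
  if (length(x$provenance))
    cat("  provenance:", paste(names(x$provenance),
                               vapply(x$provenance, format, ""),
                               sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Convert a raster to 8-bit grayscale
#'
#' Multi-channel input is combined with the ITU-R BT.601 luminance weights
#' (0.299 R + 0.587 G + 0.114 B); an alpha channel, if present, is ignored.
#' Single-channel input passes through unchanged. Output intensities are on
#' the 0--255 scale.
#'
#' @param img numeric matrix (already gray, any range) or 3D array with 1,
#'   3 or 4 channels in the third dimension, values in `[0,1]` or `[0,255]`.
#' @return numeric matrix of intensities in `[0, 255]`.
#' @export
to_grayscale <- function(img) {
  if (is.matrix(img)) {
    g <- img
  } else if (is.array(img) && length(dim(img)) == 3L) {
    nc <- dim(img)[3L]
    if (nc == 1L) {
      g <- img[, , 1L]
    } else if (nc %in% c(3L, 4L)) {
      g <- 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
    } else {
      stop("unsupported channel count: ", nc, " (expected 1, 3 or 4)")
    }
    dim(g) <- dim(img)[1:2]
  } else {
    stop("expected a matrix or a 3D array raster")
  }
  if (max(g, na.rm = TRUE) <= 1 + 1e-9) g <- g * 255
  g
}

#' Otsu's threshold
#'
#' Exhaustively evaluates all 256 candidate 8-bit levels and returns the one
#' maximizing the between-class variance of the two-class split of the
#' intensity histogram. Pixels with intensity `<= level` fall in the lower
#' class. When several consecutive levels achieve the maximum (empty
#' histogram gaps), the midpoint of the maximizing plateau is returned, so
#' the level sits between the two modes of a clean bimodal image.
#'
#' @param gray numeric matrix of intensities in `[0, 255]`.
#' @return integer threshold level in `0..254`.
#' @export
otsu_threshold <- function(gray) {
  v <- as.integer(round(as.vector(gray)))
  stopifnot(all(v >= 0), all(v <= 255))
  if (length(unique(v)) < 2L)
    stop("degenerate histogram: image has a single intensity value")
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)                      # P(class0) for level t = 0..255
  mu <- cumsum(p * (0:255))               # partial mean
  mu_t <- mu[256L]
  # between-class variance for thresholds t = 0..254 (split at <= t)
  w0 <- omega[1:255]
  sigma_b <- (mu_t * w0 - mu[1:255])^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  best <- which(sigma_b >= max(sigma_b) - 1e-12)
  as.integer(round(mean(range(best)))) - 1L
}

#' Threshold a grayscale image into a binary specimen mask
#'
#' @param gray numeric matrix of intensities in `[0, 255]`.
#' @param level threshold level in `[0, 255]`, or `NULL` to use
#'   [otsu_threshold()]. Recorded in the result's provenance either way.
#' @param polarity `"bright"` if the specimen is lighter than the
#'   background (foreground = intensity > level), `"dark"` otherwise.
#' @param pixel_scale optional physical length per pixel.
#' @return A [binary_image()].
#' @export
binarize <- function(gray, level = NULL, polarity = c("bright", "dark"),
                     pixel_scale = NULL) {
  polarity <- match.arg(polarity)
  auto <- is.null(level)
  if (auto) level <- otsu_threshold(gray)
  stopifnot(level >= 0, level <= 255)
  mask <- if (polarity == "bright") gray > level else gray <= level
  binary_image(mask, pixel_scale = pixel_scale,
               provenance = list(threshold_level = level,
                                 threshold_auto = auto,
                                 polarity = polarity))
}

#' Morphological cleanup of a binary mask
#'
#' Opening (removes stray foreground specks) followed by closing (fills
#' small holes), both with disc-shaped structuring elements. A radius of 0
#' skips that operation; `clean(x, 0, 0)` is the identity.
#'
#' @param binary a [binary_image()].
#' @param open_radius,close_radius nonnegative disc radii in pixels.
#' @return A [binary_image()] with updated provenance.
#' @export
clean <- function(binary, open_radius = 1, close_radius = 1) {
  stopifnot(inherits(binary, "binary_image"),
            open_radius >= 0, close_radius >= 0)
  m <- binary$mask * 1
  disc <- function(r) EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "disc")
  if (open_radius > 0) m <- EBImage::opening(m, disc(open_radius))
  if (close_radius > 0) m <- EBImage::closing(m, disc(close_radius))
  prov <- binary$provenance
  prov$open_radius <- open_radius
  prov$close_radius <- close_radius
  binary_image(matrix(as.logical(m > 0.5), nrow(binary$mask)),
               pixel_scale = binary$pixel_scale, provenance = prov)
}

#' Read a PNG or TIFF raster
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return numeric matrix (gray) or 3D array (color), values in `[0, 1]`.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (expected PNG or TIFF)"))
  img
}

#' Write a binary mask as a single-channel PNG (0/255)
#'
#' @param binary a [binary_image()] or logical matrix.
#' @param path output file path.
#' @export
write_mask_png <- function(binary, path) {
  m <- if (inherits(binary, "binary_image")) binary$mask else binary
  png::writePNG(m * 1, path)
  invisible(path)
}

#' Full pre-processing step: raster file or array to clean binary mask
#'
#' Grayscale conversion, (Otsu or manual) thresholding and morphological
#' cleanup in one call, mirroring the usual treatment of microscope images
#' of specimens on a contrasting background.
#'
#' @param img path to a PNG/TIFF file, or a raster array/matrix.
#' @param level,polarity,pixel_scale passed to [binarize()].
#' @param open_radius,close_radius passed to [clean()].
#' @return A [binary_image()].
#' @export
preprocess_image <- function(img, level = NULL, polarity = "bright",
                             open_radius = 1, close_radius = 1,
                             pixel_scale = NULL) {
  if (is.character(img)) img <- read_raster(img)
  g <- to_grayscale(img)
  b <- binarize(g, level = level, polarity = polarity,
                pixel_scale = pixel_scale)
  clean(b, open_radius = open_radius, close_radius = close_radius)
}
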