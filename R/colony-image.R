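#' Colony image container
#'
#' A `colony_image` holds one single-channel 2D intensity grid with pixel
#' calibration. Intensities are dimensionless, normalized to `[0, 1]` (integer
#' samples are scaled by `1/(2^bitdepth - 1)` at load time). All pixel
#' coordinates in this package are 1-based `(row, col)` pairs at pixel centers,
#' origin at the top-left, rows increasing downward.
#'
#' @param pixels Numeric matrix of intensities in `[0, 1]`.
#' @param pixel_size_um Physical pixel size in micrometres per pixel (> 0).
#' @param source_path Provenance string (file the image came from, or
#'   `"synthetic"`).
#' @param channel_label Free-text channel description, e.g. `"GFP"`.
#'
#' @return An object of class `colony_image` with fields `pixels`, `height`,
#'   `width`, `pixel_size_um`, `source_path`, `channel_label`.
#' @export
colony_image <- function(pixels, pixel_size_um = 1, source_path = "<memory>",
                         channel_label = "") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have height >= 1 and width >= 1", call. = FALSE)
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop("all intensity values must be finite", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("intensity values must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number", call. = FALSE)
  structure(
    list(pixels = unname(pixels),
         height = nrow(pixels), width = ncol(pixels),
         pixel_size_um = pixel_size_um,
         source_path = source_path, channel_label = channel_label),
    class = "colony_image")
}

#' @export
print.colony_image <- function(x, ...) {
  cat(sprintf("<colony_image> %d x %d px, %.3g um/px, range [%.3f, %.3f], %s\n",
              x$height, x$width, x$pixel_size_um,
              min(x$pixels), max(x$pixels),
              if (nzchar(x$channel_label)) x$channel_label else "unlabelled"))
  invisible(x)
}

#' Load a microscopy image as a normalized colony image
#'
#' Reads a PNG or TIFF image and returns a [colony_image] with intensities in
#' `[0, 1]`. Integer samples are scaled by `1/(2^bitdepth - 1)` (255 for 8-bit,
#' 65535 for 16-bit). Multi-channel images are reduced either to the requested
#' `channel` or, when `channel` is `NULL`, to luminance via [to_grayscale()].
#' ND2 (Nikon) input is not supported by this build; such files raise an error
#' naming the format so callers can convert to TIFF upstream.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff` file.
#' @param channel Optional 1-based channel index for multi-channel images.
#' @param pixel_size_um Micrometres per pixel for this image (> 0).
#' @param channel_label Free-text channel description stored on the result.
#'
#' @return A [colony_image].
#' @export
load_image <- function(path, channel = NULL, pixel_size_um = 1,
                       channel_label = "") {
  if (!file.exists(path))
    stop(sprintf("cannot read image: file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    nd2 = stop(sprintf(
      "ND2 input is not supported at runtime by this build: %s (convert to TIFF)",
      path), call. = FALSE),
    stop(sprintf("unsupported image format '.%s': %s", ext, path), call. = FALSE))
  if (is.list(arr)) arr <- arr[[1]]  # multi-directory TIFF: first plane
  if (length(dim(arr)) == 3L) {
    if (!is.null(channel)) {
      if (channel < 1L || channel > dim(arr)[3L])
        stop(sprintf("channel index %d out of range (image has %d channels)",
                     channel, dim(arr)[3L]), call. = FALSE)
      arr <- arr[, , channel]
    } else {
      return(to_grayscale(arr, pixel_size_um = pixel_size_um,
                          source_path = path, channel_label = channel_label))
    }
  } else if (!is.null(channel) && channel != 1L) {
    stop(sprintf("channel index %d out of range (image has 1 channel)",
                 channel), call. = FALSE)
  }
  colony_image(as.matrix(arr), pixel_size_um = pixel_size_um,
               source_path = path, channel_label = channel_label)
}

#' Convert a multi-channel image to grayscale
#'
#' Uses the standard luminance weights (0.299, 0.587, 0.114) for RGB input.
#' Two-channel (gray + alpha) input keeps the first channel; an alpha channel
#' in RGBA input is dropped. Single-channel input is returned unchanged.
#'
#' @param x A `colony_image`, a numeric matrix, or an H x W x C numeric array.
#' @param pixel_size_um,source_path,channel_label Metadata for the result when
#'   `x` is a bare array.
#'
#' @return A [colony_image].
#' @export
to_grayscale <- function(x, pixel_size_um = 1, source_path = "<memory>",
                         channel_label = "") {
  if (inherits(x, "colony_image")) return(x)
  if (is.matrix(x))
    return(colony_image(x, pixel_size_um, source_path, channel_label))
  d <- dim(x)
  if (length(d) != 3L)
    stop("expected a matrix or an H x W x C array", call. = FALSE)
  nc <- d[3L]
  g <- if (nc == 1L) x[, , 1L]
  else if (nc == 2L) x[, , 1L]                      # gray + alpha
  else 0.299 * x[, , 1L] + 0.587 * x[, , 2L] + 0.114 * x[, , 3L]  # RGB(A)
  colony_image(g, pixel_size_um, source_path, channel_label)
}

#' Grayscale luminance weights used by [to_grayscale()]
#' @return Named numeric vector of RGB weights.
#' @export
grayscale_weights <- function() c(r = 0.299, g = 0.587, b = 0.114)

#' Write a colony image or binary mask as an 8-bit PNG
#'
#' @param x A [colony_image] or a logical/numeric matrix in `[0, 1]`.
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  m <- if (inherits(x, "colony_image")) x$pixels else x
  if (is.logical(m)) m <- m * 1
  png::writePNG(pmin(pmax(m, 0), 1), path)
  invisible(path)
}
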