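#' Grayscale morphological erosion
#'
#' Each pixel is replaced by the minimum over a square window (flat
#' structuring element). The image border is handled by edge replication, so
#' a constant image is unchanged and `kernel = 1` is the identity. Applied
#' before thresholding, erosion suppresses bright speckle noise smaller than
#' the kernel.
#'
#' @param image A [colony_image] or numeric matrix.
#' @param kernel Odd window size in pixels (default 5, i.e. a 5 x 5 window).
#' @return Same type as the input, eroded.
#' @export
erode_gray <- function(image, kernel = 5L) {
  if (kernel < 1L || kernel %% 2L == 0L)
    stop("`kernel` must be a positive odd integer", call. = FALSE)
  m <- if (inherits(image, "colony_image")) image$pixels else image
  out <- window_extreme(m, kernel, pmin)
  if (inherits(image, "colony_image")) {
    image$pixels <- out
    image
  } else out
}

# windowed min/max by shifting with edge replication
window_extreme <- function(m, kernel, combine) {
  if (kernel == 1L) return(m)
  r <- (kernel - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (di in -r:r) {
    ri <- pmin(pmax(seq_len(nr) + di, 1L), nr)
    for (dj in -r:r) {
      if (di == 0L && dj == 0L) next
      ci <- pmin(pmax(seq_len(nc) + dj, 1L), nc)
      out <- combine(out, m[ri, ci, drop = FALSE])
    }
  }
  out
}

# binary dilation with the same flat square element
dilate_binary <- function(mask, kernel = 5L) {
  window_extreme(mask & TRUE, kernel, function(a, b) a | b)
}

#' Otsu threshold of an intensity image
#'
#' Histogram-based threshold maximizing the between-class variance over a
#' 256-bin histogram of the intensities in `[0, 1]` (256 bins regardless of
#' input bit depth). The returned value is the upper edge of the chosen bin,
#' so thresholding with `intensity > threshold` separates the two classes.
#' Ties in the between-class variance resolve to the lowest threshold.
#'
#' @param image A [colony_image] or numeric matrix with values in `[0, 1]`.
#' @param n_bins Number of histogram bins (default 256).
#' @return Threshold value in `[0, 1]`.
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  m <- if (inherits(image, "colony_image")) image$pixels else image
  v <- as.vector(m)
  if (length(unique(v)) < 2L)
    stop("Otsu threshold undefined: image is constant", call. = FALSE)
  bin <- pmin(pmax(floor(v * n_bins), 0), n_bins - 1L)  # bin k covers [k/n, (k+1)/n)
  counts <- tabulate(bin + 1L, nbins = n_bins)
  p <- counts / length(v)
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  omega <- cumsum(p)               # P(class 0) for threshold after bin k
  mu <- cumsum(p * mids)           # first moment of class 0
  mu_t <- mu[n_bins]
  valid <- omega > 0 & omega < 1
  sigma_b <- rep(-Inf, n_bins)
  sigma_b[valid] <- (mu_t * omega[valid] - mu[valid])^2 /
    (omega[valid] * (1 - omega[valid]))
  k <- which.max(sigma_b)          # first maximum -> lowest threshold
  k / n_bins                       # upper edge of bin k-1 (0-based k-1)
}

#' Binarize an image at a threshold
#'
#' A pixel is foreground iff its intensity is strictly greater than the
#' threshold.
#'
#' @param image A [colony_image] or numeric matrix.
#' @param threshold Value in `[0, 1]`.
#' @return Logical matrix.
#' @export
binarize <- function(image, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  m <- if (inherits(image, "colony_image")) image$pixels else image
  m > threshold
}

#' Segment a macrocolony into periphery and core contours
#'
#' Runs the segmentation chain: grayscale erosion (square kernel), Otsu
#' thresholding, binarization, and border-following contour extraction with
#' hole boundaries retained. The largest contour by enclosed area is the
#' colony periphery; the second largest is the colony core, accepted only if
#' it passes the configurable gates (a representative point inside the
#' periphery polygon, and area between `core_min_frac` and `core_max_frac`
#' of the periphery area) that keep dust or plate edges from being mislabeled
#' as the core.
#'
#' With `compensate = TRUE` (default) the binary mask is dilated with the
#' same structuring element after thresholding. Grayscale erosion shifts
#' every bright-to-dark boundary inward by half the kernel; the dilation
#' cancels that shift on clean edges (the pair acts as a morphological
#' opening) so enclosed areas are unbiased while speckle suppression is kept.
#'
#' @param image A [colony_image].
#' @param kernel Odd erosion kernel size (default 5).
#' @param compensate Dilate the binary mask by the same kernel (default TRUE).
#' @param core_min_frac,core_max_frac Core area gates as fractions of the
#'   periphery area (defaults 0.01 and 0.9).
#' @return A list with elements `periphery` ([colony_contour]), `core`
#'   ([colony_contour] or `NULL`), `threshold`, `mask` (the binary mask the
#'   contours were traced from), and `contours` (the full ranked list).
#' @export
segment_colony <- function(image, kernel = 5L, compensate = TRUE,
                           core_min_frac = 0.01, core_max_frac = 0.9) {
  stopifnot(inherits(image, "colony_image"))
  eroded <- erode_gray(image$pixels, kernel)
  thr <- tryCatch(otsu_threshold(eroded),
                  error = function(e) stop(sprintf(
                    "segmentation failed for %s: %s", image$source_path,
                    conditionMessage(e)), call. = FALSE))
  mask <- binarize(eroded, thr)
  if (compensate) mask <- dilate_binary(mask, kernel)
  contours <- find_contours(mask)
  if (!length(contours))
    stop(sprintf("segmentation failed for %s: no contour found",
                 image$source_path), call. = FALSE)
  periphery <- contours[[1L]]
  periphery$role <- "periphery"
  core <- NULL
  if (length(contours) >= 2L) {
    cand <- contours[[2L]]
    frac <- cand$enclosed_area_px / periphery$enclosed_area_px
    rep_pt <- round(colMeans(cand$vertices))
    per_mask <- rasterize_polygon(periphery$vertices,
                                  dim = c(image$height, image$width))
    inside <- rep_pt[1L] >= 1 && rep_pt[1L] <= image$height &&
      rep_pt[2L] >= 1 && rep_pt[2L] <= image$width &&
      per_mask[rep_pt[1L], rep_pt[2L]]
    if (inside && frac >= core_min_frac && frac <= core_max_frac) {
      core <- cand
      core$role <- "core"
    }
  }
  list(periphery = periphery, core = core, threshold = thr, mask = mask,
       contours = contours)
}

#' Physical coverage area of a contour
#'
#' @param contour A [colony_contour].
#' @param pixel_size_um Micrometres per pixel.
#' @return Enclosed area in square micrometres.
#' @export
coverage_area <- function(contour, pixel_size_um) {
  stopifnot(inherits(contour, "colony_contour"), pixel_size_um > 0)
  contour$enclosed_area_px * pixel_size_um^2
}
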