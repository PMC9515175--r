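#' Exposed/unexposed region masks for intensity analysis
#'
#' Rasterizes the periphery and core contours and builds the four analysis
#' regions: the periphery *annulus* (periphery minus core) and the core,
#' each split into exposed and unexposed sides by the separating line. When
#' the core is absent only the two periphery masks are returned, with a
#' warning.
#'
#' @param periphery A [colony_contour].
#' @param core A [colony_contour] or `NULL`.
#' @param line A [separating_line].
#' @param dim Image `(height, width)`.
#' @return Named list of logical masks: `periphery_exposed`,
#'   `periphery_unexposed` and (when the core exists) `core_exposed`,
#'   `core_unexposed`.
#' @export
region_masks <- function(periphery, core, line, dim) {
  stopifnot(inherits(periphery, "colony_contour"),
            inherits(line, "separating_line"))
  per <- rasterize_polygon(periphery$vertices, dim = dim)
  s <- matrix(signed_distance(pixel_grid(dim), line), dim[1L], dim[2L])
  if (!any(per & s > 0) || !any(per & s < 0))
    stop("separating line does not intersect the colony", call. = FALSE)
  out <- list()
  if (is.null(core)) {
    warning("core contour absent: returning periphery-only masks",
            call. = FALSE)
    out$periphery_exposed <- per & s > 0
    out$periphery_unexposed <- per & s < 0
  } else {
    co <- rasterize_polygon(core$vertices, dim = dim)
    if (any(co & !per))
      co <- co & per  # clip numerically protruding core pixels
    ann <- per & !co
    out$periphery_exposed <- ann & s > 0
    out$periphery_unexposed <- ann & s < 0
    out$core_exposed <- co & s > 0
    out$core_unexposed <- co & s < 0
  }
  out
}

# (row, col) coordinates of every pixel center in a grid, column-major
pixel_grid <- function(dim) {
  cbind(rep(seq_len(dim[1L]), times = dim[2L]),
        rep(seq_len(dim[2L]), each = dim[1L]))
}

#' Exposed-to-unexposed mean-intensity ratio of a region
#'
#' @param image A [colony_image].
#' @param masks Named mask list from [region_masks()].
#' @param region `"periphery"` or `"core"`.
#' @return A list of class `intensity_result`: `region`, `mean_exposed`,
#'   `mean_unexposed`, `ratio` (exposed / unexposed).
#' @export
intensity_ratio <- function(image, masks, region = "periphery") {
  region <- match.arg(region, c("periphery", "core"))
  me <- masks[[paste0(region, "_exposed")]]
  mu <- masks[[paste0(region, "_unexposed")]]
  if (is.null(me) || is.null(mu) || !any(me) || !any(mu))
    stop(sprintf("degenerate region: empty %s half-mask", region),
         call. = FALSE)
  mean_e <- mean(image$pixels[me])
  mean_u <- mean(image$pixels[mu])
  structure(list(region = region, mean_exposed = mean_e,
                 mean_unexposed = mean_u, ratio = mean_e / mean_u),
            class = "intensity_result")
}

#' @export
print.intensity_result <- function(x, ...) {
  cat(sprintf("<intensity_result: %s> exposed %.4f / unexposed %.4f = %.4f\n",
              x$region, x$mean_exposed, x$mean_unexposed, x$ratio))
  invisible(x)
}

#' Augmented intensity ratio for control colonies
#'
#' Control plates have no source, so no preferred axis: the half-vs-half
#' mean-intensity ratio is computed under three partitions of the region
#' about the colony center — left vs right halves, top vs bottom halves, and
#' the diagonal pairing of upper-left + bottom-right quadrants vs upper-right
#' + bottom-left quadrants — and their arithmetic mean is returned.
#'
#' @param image A [colony_image].
#' @param region_mask Logical mask of the region (e.g. periphery annulus).
#' @param center `(row, col)` colony center.
#' @return A list of class `intensity_result` with `ratio` the mean of the
#'   three partition ratios and `partition_ratios` the individual values
#'   (`left_right`, `top_bottom`, `diagonal`).
#' @export
control_augmented_ratio <- function(image, region_mask, center) {
  stopifnot(inherits(image, "colony_image"), is.matrix(region_mask))
  g <- pixel_grid(dim(region_mask))
  drow <- matrix(g[, 1L] - center[1L], nrow(region_mask))
  dcol <- matrix(g[, 2L] - center[2L], nrow(region_mask))
  px <- image$pixels
  ratio_of <- function(ma, mb, what) {
    a <- region_mask & ma; b <- region_mask & mb
    if (!any(a) || !any(b))
      stop(sprintf("degenerate region: empty %s partition cell", what),
           call. = FALSE)
    mean(px[a]) / mean(px[b])
  }
  r_lr <- ratio_of(dcol < 0, dcol > 0, "left/right")
  r_tb <- ratio_of(drow < 0, drow > 0, "top/bottom")
  r_dg <- ratio_of(drow * dcol > 0, drow * dcol < 0, "diagonal")  # UL+BR vs UR+BL
  structure(list(region = "augmented",
                 mean_exposed = NA_real_, mean_unexposed = NA_real_,
                 ratio = mean(c(r_lr, r_tb, r_dg)),
                 partition_ratios = c(left_right = r_lr, top_bottom = r_tb,
                                      diagonal = r_dg)),
            class = "intensity_result")
}

#' Euclidean pixel distances to a source point
#'
#' @param coords n x 2 `(row, col)` matrix.
#' @param source `(row, col)` of the source.
#' @return Numeric vector of distances in pixels.
#' @export
pixel_distances <- function(coords, source) {
  coords <- matrix(as.numeric(coords), ncol = 2L)
  sqrt((coords[, 1L] - source[1L])^2 + (coords[, 2L] - source[2L])^2)
}

#' Leading-edge band mask on the exposed side
#'
#' The leading edge is the outermost band of the colony periphery: pixels
#' inside the periphery whose Euclidean distance (distance transform) to the
#' outside is at most `width`, intersected with the exposed half. The
#' periphery polygon is filled before the transform, so interior holes (the
#' core) do not cut into the band.
#'
#' Because the band measures the periphery, core pixels are excluded when a
#' core contour is supplied: a colony whose core sits within `width` of the
#' rim would otherwise leak core intensities into the leading-edge
#' regression.
#'
#' @param periphery A [colony_contour].
#' @param line A [separating_line].
#' @param width Band width in pixels (default 20).
#' @param dim Image `(height, width)`.
#' @param exclude Optional [colony_contour] (the core) whose rasterization
#'   is removed from the band.
#' @return Logical mask; empty (with a warning) if the colony is thinner
#'   than the band everywhere on the exposed side.
#' @export
leading_edge_band <- function(periphery, line, width = 20, dim,
                              exclude = NULL) {
  stopifnot(width >= 1)
  per <- rasterize_polygon(periphery$vertices, dim = dim)
  dm <- EBImage::distmap(per * 1L)
  dmat <- if (is.matrix(dm)) dm else EBImage::imageData(dm)
  s <- matrix(signed_distance(pixel_grid(dim), line), dim[1L], dim[2L])
  band <- per & dmat <= width & s > 0
  if (!is.null(exclude))
    band <- band & !rasterize_polygon(exclude$vertices, dim = dim)
  if (!any(band))
    warning("leading-edge band is empty (colony thinner than band width)",
            call. = FALSE)
  band
}

#' Leading-edge intensity vs distance regression
#'
#' Ordinary least-squares fit of pixel intensity on Euclidean distance from
#' the source, over the pixels of the leading-edge band. A negative slope
#' close to the source means intensity drops toward the source.
#'
#' @param image A [colony_image].
#' @param band Logical mask from [leading_edge_band()].
#' @param source `(row, col)` of the source.
#' @return A list of class `edge_regression`: `slope` (intensity per pixel),
#'   `intercept`, `r_squared`, `n_pixels`.
#' @export
edge_regression <- function(image, band, source) {
  stopifnot(inherits(image, "colony_image"), is.matrix(band))
  idx <- which(band)
  if (length(idx) < 2L)
    stop("leading-edge regression needs at least 2 band pixels", call. = FALSE)
  nr <- nrow(band)
  coords <- cbind((idx - 1L) %% nr + 1L, (idx - 1L) %/% nr + 1L)
  d <- pixel_distances(coords, source)
  y <- image$pixels[idx]
  if (max(d) - min(d) < .Machine$double.eps^0.5)
    stop("leading-edge regression is rank deficient: all distances equal",
         call. = FALSE)
  if (stats::var(y) == 0) {
    res <- list(slope = 0, intercept = y[1L], r_squared = 0,
                n_pixels = length(idx))
  } else {
    fit <- stats::lm(y ~ d)
    res <- list(slope = unname(stats::coef(fit)[2L]),
                intercept = unname(stats::coef(fit)[1L]),
                r_squared = suppressWarnings(summary(fit)$r.squared),
                n_pixels = length(idx))
  }
  class(res) <- "edge_regression"
  res
}

#' @export
print.edge_regression <- function(x, ...) {
  cat(sprintf(
    "<edge_regression> slope %.3e / px, intercept %.4f, R^2 %.3f, n = %d\n",
    x$slope, x$intercept, x$r_squared, x$n_pixels))
  invisible(x)
}
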