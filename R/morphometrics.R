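#' Separating line between exposed and unexposed halves
#'
#' The line passes through the colony seeding point, perpendicular to the
#' direction from the seeding point toward the antimicrobial source, so the
#' "exposed" half is the one facing the source. For control layouts (no
#' source) the line defaults to the image-vertical line through the center
#' and "exposed" is, by convention, the right half.
#'
#' @param layout An [experiment_layout].
#' @return An object of class `separating_line` with fields `point` (the
#'   colony center), `normal` (unit `(row, col)` vector pointing into the
#'   exposed half) and `tangent` (unit vector along the line). Signed
#'   distance of a point `p` to the line is `dot(p - point, normal)`;
#'   positive values are exposed.
#' @export
separating_line <- function(layout) {
  stopifnot(inherits(layout, "experiment_layout"))
  ctr <- layout$colony_center
  if (is.null(layout$source_center)) {
    normal <- c(0, 1)  # control: vertical line, exposed = right by convention
  } else {
    d <- layout$source_center - ctr
    len <- sqrt(sum(d^2))
    if (len < .Machine$double.eps^0.5)
      stop(sprintf("layout '%s': source coincides with colony center",
                   layout$image_id), call. = FALSE)
    normal <- d / len
  }
  structure(list(point = ctr, normal = normal,
                 tangent = c(-normal[2L], normal[1L])),
            class = "separating_line")
}

#' Signed distance of points to a separating line
#' @param pts n x 2 `(row, col)` matrix.
#' @param line A [separating_line].
#' @return Numeric vector; positive on the exposed side.
#' @export
signed_distance <- function(pts, line) {
  pts <- matrix(as.numeric(pts), ncol = 2L)
  (pts[, 1L] - line$point[1L]) * line$normal[1L] +
    (pts[, 2L] - line$point[2L]) * line$normal[2L]
}

#' Reflect points across a separating line
#' @inheritParams signed_distance
#' @return n x 2 matrix of reflected points.
#' @export
reflect_points <- function(pts, line) {
  pts <- matrix(as.numeric(pts), ncol = 2L)
  s <- signed_distance(pts, line)
  pts - 2 * cbind(s * line$normal[1L], s * line$normal[2L])
}

#' Split a closed contour into unexposed and exposed half-polylines
#'
#' Contour vertices are partitioned by the sign of their distance to the
#' line; at every sign change the line-intersection point is interpolated
#' and added to both sides, so each half is an open polyline whose endpoints
#' lie on the line.
#'
#' @param contour A [colony_contour].
#' @param line A [separating_line].
#' @return List with `unexposed` and `exposed`, each an n x 2 vertex matrix.
#' @export
split_halves <- function(contour, line) {
  stopifnot(inherits(contour, "colony_contour"),
            inherits(line, "separating_line"))
  v <- contour$vertices
  s <- signed_distance(v, line)
  if (all(s >= 0) || all(s <= 0))
    stop("contour does not cross the separating line", call. = FALSE)
  n <- nrow(v)
  take_side <- function(positive) {
    on_side <- if (positive) s > 0 else s < 0
    # rotate so the cyclic sequence starts just after an off-side vertex
    start <- which(!on_side & on_side[c(2:n, 1L)])[1L]
    ord <- ((start:(start + n - 1L)) - 1L) %% n + 1L
    vv <- v[ord, , drop = FALSE]
    ss <- s[ord]
    keep <- if (positive) ss > 0 else ss < 0
    out <- list()
    i <- 1L
    while (i <= n) {
      if (keep[i]) {
        j <- i
        while (j < n && keep[j + 1L]) j <- j + 1L
        # entry crossing between i-1 and i (i > 1 by rotation)
        pa <- vv[i - 1L, ]; pb <- vv[i, ]
        t0 <- ss[i - 1L] / (ss[i - 1L] - ss[i])
        entry <- pa + t0 * (pb - pa)
        jn <- if (j == n) 1L else j + 1L
        pc <- vv[j, ]; pd <- vv[if (j == n) 1L else j + 1L, ]
        sd_next <- if (j == n) s[ord[1L]] else ss[j + 1L]
        t1 <- ss[j] / (ss[j] - sd_next)
        exit <- pc + t1 * (pd - pc)
        out[[length(out) + 1L]] <- rbind(entry, vv[i:j, , drop = FALSE], exit)
        i <- j + 1L
      } else i <- i + 1L
    }
    do.call(rbind, out)
  }
  list(unexposed = unname(take_side(FALSE)), exposed = unname(take_side(TRUE)))
}

#' Mirror a half-polyline about the separating line into a closed contour
#'
#' Every vertex is reflected across the line and the reflected vertices are
#' appended in reverse order, producing a closed contour symmetric about the
#' line. Endpoints (which lie on the line) are not duplicated.
#'
#' @param half n x 2 open polyline whose endpoints lie on the line.
#' @param line A [separating_line].
#' @return A [colony_contour] with role `"mirrored"`.
#' @export
mirror_half <- function(half, line) {
  half <- matrix(as.numeric(half), ncol = 2L)
  n <- nrow(half)
  if (n < 3L) stop("half-polyline needs at least 3 vertices", call. = FALSE)
  refl <- reflect_points(half, line)
  closed <- rbind(half, refl[(n - 1L):2L, , drop = FALSE])
  colony_contour(closed, role = "mirrored")
}

#' Direct least-squares ellipse fit
#'
#' Fits the algebraic conic `A x^2 + B xy + C y^2 + D x + E y + F = 0`
#' constrained to an ellipse (`4AC - B^2 = 1`) by the numerically stable
#' partitioned generalized-eigenvalue formulation, then converts to geometric
#' parameters. Coordinates are centered and scaled internally for
#' conditioning.
#'
#' @param contour A [colony_contour] or an n x 2 `(row, col)` matrix with at
#'   least 5 distinct points.
#' @return An object of class `fitted_ellipse`: `center` `(row, col)`,
#'   `semi_major`, `semi_minor` (pixels, `semi_major >= semi_minor > 0`),
#'   `angle` (radians in `[0, pi)`, major axis from the image horizontal) and
#'   `major_axis` (unit `(row, col)` direction of the major axis).
#' @export
fit_ellipse <- function(contour) {
  pts <- if (inherits(contour, "colony_contour")) contour$vertices else
    as.matrix(contour)
  pts <- unique(round(pts, 10))
  if (nrow(pts) < 5L)
    stop("ellipse fit needs at least 5 distinct points", call. = FALSE)
  # work in (x, y) = (col, row)
  x <- pts[, 2L]; y <- pts[, 1L]
  mx <- mean(x); my <- mean(y)
  sc <- max(stats::sd(x), stats::sd(y))
  if (!is.finite(sc) || sc == 0)
    stop("ellipse fit failed: degenerate (collinear or coincident) points",
         call. = FALSE)
  xs <- (x - mx) / sc; ys <- (y - my) / sc
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T1 <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("ellipse fit failed: degenerate point configuration", call. = FALSE))
  M <- S1 + S2 %*% T1
  M <- rbind(M[3L, ] / 2, -M[2L, ], M[1L, ] / 2)  # inv(C1) %*% M
  ev <- eigen(M)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1L, ] * evec[3L, ] - evec[2L, ]^2
  k <- which(cond > 0)
  if (!length(k))
    stop("ellipse fit failed: no elliptical solution (degenerate input)",
         call. = FALSE)
  a1 <- evec[, k[1L]]
  coef_s <- c(a1, as.vector(T1 %*% a1))  # A B C D E F in scaled coords
  # unscale: x = (X - mx)/sc, y = (Y - my)/sc
  A <- coef_s[1L] / sc^2
  B <- coef_s[2L] / sc^2
  C <- coef_s[3L] / sc^2
  D <- -2 * coef_s[1L] * mx / sc^2 - coef_s[2L] * my / sc^2 + coef_s[4L] / sc
  E <- -coef_s[2L] * mx / sc^2 - 2 * coef_s[3L] * my / sc^2 + coef_s[5L] / sc
  F <- coef_s[1L] * mx^2 / sc^2 + coef_s[2L] * mx * my / sc^2 +
    coef_s[3L] * my^2 / sc^2 - coef_s[4L] * mx / sc - coef_s[5L] * my / sc +
    coef_s[6L]
  conic_to_ellipse(A, B, C, D, E, F)
}

conic_to_ellipse <- function(A, B, C, D, E, F) {
  den <- 4 * A * C - B^2
  if (den <= 0) stop("conic is not an ellipse", call. = FALSE)
  x0 <- (B * E - 2 * C * D) / den
  y0 <- (B * D - 2 * A * E) / den
  mu <- A * x0^2 + B * x0 * y0 + C * y0^2 + D * x0 + E * y0 + F
  Q <- matrix(c(A, B / 2, B / 2, C), 2L)
  eq <- eigen(Q, symmetric = TRUE)
  ax2 <- -mu / eq$values            # squared semi-axes, one per eigenvector
  if (any(ax2 <= 0)) stop("conic is not a real ellipse", call. = FALSE)
  i_major <- which.max(ax2)
  vmaj <- eq$vectors[, i_major]     # (x, y) direction of major axis
  theta <- atan2(vmaj[2L], vmaj[1L]) %% pi
  structure(
    list(center = c(y0, x0),
         semi_major = sqrt(max(ax2)), semi_minor = sqrt(min(ax2)),
         angle = theta,
         major_axis = c(vmaj[2L], vmaj[1L]) / sqrt(sum(vmaj^2))),
    class = "fitted_ellipse")
}

#' @export
print.fitted_ellipse <- function(x, ...) {
  cat(sprintf(
    "<fitted_ellipse> center (%.1f, %.1f), a = %.2f, b = %.2f, angle = %.1f deg\n",
    x$center[1L], x$center[2L], x$semi_major, x$semi_minor,
    x$angle * 180 / pi))
  invisible(x)
}

#' Half-extent of a fitted ellipse along a direction
#'
#' Returns `sqrt(a^2 cos^2(alpha) + b^2 sin^2(alpha))` where `alpha` is the
#' angle between the requested direction and the major axis — the ellipse's
#' half-width along that direction (the maximum projection of boundary points
#' onto it).
#'
#' @param e A `fitted_ellipse`.
#' @param direction Unit `(row, col)` vector.
#' @return Half-extent in pixels.
#' @export
ellipse_extent <- function(e, direction) {
  stopifnot(inherits(e, "fitted_ellipse"), length(direction) == 2L)
  len <- sqrt(sum(direction^2))
  if (abs(len - 1) > 1e-6)
    stop("`direction` must be a unit vector", call. = FALSE)
  ca <- sum(direction * e$major_axis)
  sqrt(e$semi_major^2 * ca^2 + e$semi_minor^2 * (1 - ca^2))
}

#' One-sided deformation ratios of a colony region
#'
#' Splits the contour into exposed/unexposed halves about the separating
#' line, mirrors each half into a closed line-symmetric contour, fits both
#' to ellipses, and reports the unexposed/exposed ratio of ellipse extents
#' along the center-to-source axis (`horiz_ratio`) and its perpendicular
#' (`vert_ratio`). Values above 1 indicate inhibition (a smaller footprint)
#' on the exposed side; a line-symmetric contour gives ratios of 1.
#'
#' @param contour A [colony_contour] (periphery or core).
#' @param layout An [experiment_layout].
#' @param region `"periphery"` or `"core"`.
#' @return A list of class `deformation_result`: `region`, `horiz_ratio`,
#'   `vert_ratio`, plus the two fitted ellipses (`fit_unexposed`,
#'   `fit_exposed`).
#' @export
deformation_ratios <- function(contour, layout, region = "periphery") {
  region <- match.arg(region, c("periphery", "core"))
  line <- separating_line(layout)
  halves <- split_halves(contour, line)
  fit_u <- fit_ellipse(mirror_half(halves$unexposed, line))
  fit_e <- fit_ellipse(mirror_half(halves$exposed, line))
  horiz <- line$normal
  vert <- line$tangent
  res <- list(region = region,
              horiz_ratio = ellipse_extent(fit_u, horiz) /
                ellipse_extent(fit_e, horiz),
              vert_ratio = ellipse_extent(fit_u, vert) /
                ellipse_extent(fit_e, vert),
              fit_unexposed = fit_u, fit_exposed = fit_e)
  class(res) <- "deformation_result"
  res
}

#' @export
print.deformation_result <- function(x, ...) {
  cat(sprintf("<deformation_result: %s> horiz %.3f, vert %.3f\n",
              x$region, x$horiz_ratio, x$vert_ratio))
  invisible(x)
}
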