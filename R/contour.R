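#' Closed pixel-coordinate contour
#'
#' A closed polygon of 1-based `(row, col)` pixel-center coordinates together
#' with the pixel area it encloses. Contours come out of [find_contours()]
#' (boundaries of binary-mask regions, traced with a Moore border-following
#' walk) or out of [mirror_half()] (reflected half-contours). The polygon is
#' stored open (first vertex not repeated); closure is implicit.
#'
#' `enclosed_area_px` is the rasterized pixel count of the filled polygon
#' (holes filled). For traced contours it is the exact filled-component pixel
#' count; for constructed polygons it is computed by scanline rasterization.
#'
#' @param vertices n x 2 numeric matrix of `(row, col)` vertices, n >= 3.
#' @param enclosed_area_px Optional precomputed enclosed area; computed by
#'   rasterization when missing.
#' @param role Optional label: `"periphery"`, `"core"`, `"mirrored"`, ...
#' @return An object of class `colony_contour`.
#' @export
colony_contour <- function(vertices, enclosed_area_px = NULL, role = "") {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop("a contour needs an n x 2 vertex matrix with n >= 3", call. = FALSE)
  colnames(vertices) <- c("row", "col")
  if (is.null(enclosed_area_px)) {
    # shift into positive coordinates so off-grid polygons are not clipped
    off <- floor(apply(vertices, 2L, min)) - 1L
    shifted <- sweep(vertices, 2L, off)
    enclosed_area_px <- sum(rasterize_polygon(shifted))
  }
  structure(list(vertices = vertices,
                 enclosed_area_px = as.numeric(enclosed_area_px),
                 role = role),
            class = "colony_contour")
}

#' @export
print.colony_contour <- function(x, ...) {
  cat(sprintf("<colony_contour%s> %d vertices, enclosed area %.0f px\n",
              if (nzchar(x$role)) paste0(": ", x$role) else "",
              nrow(x$vertices), x$enclosed_area_px))
  invisible(x)
}

# Moore-neighbour border following (clockwise in (row, col) screen
# coordinates), Jacob's stopping criterion. `mask` is a logical matrix holding
# one 8-connected component; returns the boundary pixel centers in tracing
# order, starting from the top-most then left-most pixel.
trace_boundary <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(NULL)
  nr <- nrow(mask)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  ord <- order(rows, cols)
  start <- c(rows[ord[1L]], cols[ord[1L]])
  # clockwise Moore neighbourhood starting west
  moves <- matrix(c(0L, -1L, -1L, -1L, -1L, 0L, -1L, 1L,
                    0L, 1L, 1L, 1L, 1L, 0L, 1L, -1L),
                  ncol = 2L, byrow = TRUE)
  inside <- function(p) p[1L] >= 1L && p[1L] <= nr &&
    p[2L] >= 1L && p[2L] <= ncol(mask)
  at <- function(p) inside(p) && mask[p[1L], p[2L]]
  out <- matrix(0L, nrow = 4L * length(idx) + 8L, ncol = 2L)
  out[1L, ] <- start
  n_out <- 1L
  # backtrack direction: came from the west (scan order guarantees west empty)
  prev_dir <- 1L
  cur <- start
  first_next <- NULL
  repeat {
    found <- FALSE
    for (k in 0L:7L) {
      d <- (prev_dir - 1L + k) %% 8L + 1L
      cand <- cur + moves[d, ]
      if (at(cand)) {
        # Jacob's criterion: stop when re-entering start with same next pixel
        if (n_out > 1L && all(cur == start)) {
          if (!is.null(first_next) && all(cand == first_next)) {
            return(out[seq_len(n_out - 1L), , drop = FALSE])
          }
        }
        if (is.null(first_next)) first_next <- cand
        n_out <- n_out + 1L
        if (n_out > nrow(out))
          out <- rbind(out, matrix(0L, nrow = nrow(out), ncol = 2L))
        out[n_out, ] <- cand
        # new backtrack: direction from cand toward cur, rotated one step cw
        back <- ((d + 4L - 1L) %% 8L)  # opposite direction, 0-based
        prev_dir <- (back + 1L) %% 8L + 1L
        cur <- cand
        found <- TRUE
        break
      }
    }
    if (!found) return(out[1L, , drop = FALSE])  # isolated pixel
    if (n_out > 4L * length(idx) + 4L)
      return(out[seq_len(n_out), , drop = FALSE])
  }
}

#' Rasterize a closed polygon onto a pixel grid
#'
#' Even-odd scanline fill over pixel centers at integer `(row, col)`
#' positions, inclusive of pixels whose centers lie on the polygon boundary
#' (boundary pixels are unioned in). Used to turn contours into region masks.
#'
#' @param vertices n x 2 `(row, col)` polygon (closed implicitly).
#' @param dim Optional `(height, width)` of the target grid; defaults to the
#'   polygon's bounding box extent.
#' @return A logical matrix of dimension `dim`.
#' @export
rasterize_polygon <- function(vertices, dim = NULL) {
  v <- as.matrix(vertices)
  if (is.null(dim))
    dim <- c(ceiling(max(v[, 1L])) + 1L, ceiling(max(v[, 2L])) + 1L)
  h <- dim[1L]; w <- dim[2L]
  mask <- matrix(FALSE, h, w)
  n <- nrow(v)
  y1 <- v[, 1L]; x1 <- v[, 2L]
  y2 <- v[c(2:n, 1L), 1L]; x2 <- v[c(2:n, 1L), 2L]
  keep <- y1 != y2
  y1k <- y1[keep]; x1k <- x1[keep]; y2k <- y2[keep]; x2k <- x2[keep]
  lo <- pmin(y1k, y2k); hi <- pmax(y1k, y2k)
  # half-open rule in y: edge crosses scanline r iff lo <= r < hi
  r_from <- pmax(1L, ceiling(lo))
  r_to <- pmin(h, ceiling(hi) - 1L)
  counts <- pmax(0L, r_to - r_from + 1L)
  if (sum(counts)) {
    e <- rep.int(seq_along(y1k), counts)
    r <- unlist(lapply(seq_along(counts), function(i)
      if (counts[i] > 0L) seq.int(r_from[i], r_to[i]) else integer(0)))
    xc <- x1k[e] + (r - y1k[e]) / (y2k[e] - y1k[e]) * (x2k[e] - x1k[e])
    ordr <- order(r, xc)
    r <- r[ordr]; xc <- xc[ordr]
    # fill between alternating crossing pairs
    starts <- seq.int(1L, length(xc), by = 2L)
    for (s in starts) {
      if (s + 1L > length(xc)) break
      if (r[s] != r[s + 1L]) next  # defensive; parity should pair within rows
      c0 <- max(1L, ceiling(xc[s] - 1e-9))
      c1 <- min(w, floor(xc[s + 1L] + 1e-9))
      if (c0 <= c1) mask[r[s], c0:c1] <- TRUE
    }
  }
  # union boundary pixels (rounded vertices) so thin/edge-on pixels count
  br <- round(v[, 1L]); bc <- round(v[, 2L])
  ok <- br >= 1L & br <= h & bc >= 1L & bc <= w
  mask[cbind(br[ok], bc[ok])] <- TRUE
  mask
}

#' Extract region boundaries from a binary mask
#'
#' Border-following contour extraction. Outer boundaries of all 8-connected
#' foreground components are reported, and so are hole boundaries (boundaries
#' of background components fully enclosed by foreground) — an interior
#' intensity transition such as a colony core shows up as a hole in the
#' thresholded mask, and retaining its boundary is what lets the area ranking
#' find it. Contours are sorted by strictly descending enclosed area; ties
#' break by top-most, then left-most first vertex. Components whose boundary
#' has fewer than 3 pixels are dropped (sub-resolution specks).
#'
#' The enclosed area of an outer boundary is the filled pixel count of its
#' component (holes included); the enclosed area of a hole boundary is the
#' hole's pixel count.
#'
#' @param mask Logical matrix.
#' @return List of [colony_contour] objects (empty for an empty mask).
#' @export
find_contours <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- mask & TRUE  # coerce to logical
  out <- list()
  if (any(mask)) {
    lab <- EBImage::bwlabel(mask)
    lab_m <- if (is.matrix(lab)) lab else EBImage::imageData(lab)
    for (id in seq_len(max(lab_m))) {
      comp <- lab_m == id
      b <- trace_boundary(comp)
      if (is.null(b) || nrow(b) < 3L) next
      filled <- EBImage::fillHull(comp * 1L)
      filled_m <- if (is.matrix(filled)) filled else EBImage::imageData(filled)
      out[[length(out) + 1L]] <-
        colony_contour(b, enclosed_area_px = sum(filled_m > 0))
    }
    # holes: background components not touching the image border
    bg <- !mask
    labh <- EBImage::bwlabel(bg)
    labh_m <- if (is.matrix(labh)) labh else EBImage::imageData(labh)
    border_ids <- unique(c(labh_m[1L, ], labh_m[nrow(mask), ],
                           labh_m[, 1L], labh_m[, ncol(mask)]))
    for (id in setdiff(seq_len(max(labh_m)), border_ids)) {
      hole <- labh_m == id
      b <- trace_boundary(hole)
      if (is.null(b) || nrow(b) < 3L) next
      filledh <- EBImage::fillHull(hole * 1L)
      filledh_m <- if (is.matrix(filledh)) filledh else EBImage::imageData(filledh)
      out[[length(out) + 1L]] <-
        colony_contour(b, enclosed_area_px = sum(filledh_m > 0))
    }
  }
  if (!length(out)) return(list())
  areas <- vapply(out, function(ct) ct$enclosed_area_px, numeric(1))
  r1 <- vapply(out, function(ct) ct$vertices[1L, 1L], numeric(1))
  c1 <- vapply(out, function(ct) ct$vertices[1L, 2L], numeric(1))
  out[order(-areas, r1, c1)]
}
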