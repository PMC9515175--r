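layout_with_source <- function(center, source, id = "t") {
  experiment_layout(id, center, source, distance_cm = 1, day = 1,
                    group_label = "1cm")
}

test_that("separating line is perpendicular to the center-source axis", {
  l <- separating_line(layout_with_source(c(100, 100), c(100, 300)))
  expect_equal(l$normal, c(0, 1))               # source east -> exposed right
  expect_gt(signed_distance(c(100, 150), l), 0)  # right of center: exposed
  expect_lt(signed_distance(c(100, 50), l), 0)

  l2 <- separating_line(layout_with_source(c(100, 100), c(300, 100)))
  expect_equal(l2$normal, c(1, 0))              # source south -> exposed below
  expect_gt(signed_distance(c(150, 100), l2), 0)

  ctrl <- experiment_layout("c", c(50, 50), day = 1, group_label = "control")
  expect_equal(separating_line(ctrl)$normal, c(0, 1))  # default vertical line

  expect_error(separating_line(layout_with_source(c(10, 10), c(10, 10))),
               "coincides")
})

test_that("split_halves partitions a contour at the line", {
  circ <- colony_contour(ellipse_points(200, c(100, 100), 50, 50))
  line <- separating_line(layout_with_source(c(100, 100), c(100, 400)))
  halves <- split_halves(circ, line)
  expect_equal(nrow(halves$unexposed), nrow(halves$exposed), tolerance = 0.05)
  # endpoints lie on the line
  for (h in halves) {
    expect_lt(abs(signed_distance(h[1L, , drop = FALSE], line)), 1e-9)
    expect_lt(abs(signed_distance(h[nrow(h), , drop = FALSE], line)), 1e-9)
  }

  # square straddling the line at 1/3 of its width: rasterized 1:2 halves
  sq <- colony_contour(rbind(c(10, 10), c(10, 70), c(70, 70), c(70, 10)))
  line3 <- separating_line(layout_with_source(c(40, 30), c(40, 200)))
  hs <- split_halves(sq, line3)
  a_un <- mirror_half(hs$unexposed, line3)$enclosed_area_px / 2
  a_ex <- mirror_half(hs$exposed, line3)$enclosed_area_px / 2
  expect_equal(a_un / a_ex, 1 / 2, tolerance = 0.05)

  # contour entirely on one side of the line
  far <- separating_line(layout_with_source(c(40, 200), c(40, 400)))
  expect_error(split_halves(sq, far), "does not cross")
})

test_that("mirroring reflects across the line and closes the contour", {
  line <- separating_line(layout_with_source(c(0, 5), c(0, 50)))
  pts <- rbind(c(-3, 5), c(0, 2), c(3, 5))   # endpoints on the line col = 5
  m <- mirror_half(pts, line)
  refl <- reflect_points(c(0, 2), line)
  expect_equal(abs(refl[1, 2] - 5), 3)        # distance d maps to d

  # involution: reflecting twice restores the original points
  twice <- reflect_points(reflect_points(pts, line), line)
  expect_equal(twice, pts, tolerance = 1e-12)

  # mirrored half-circle recovers the full circle's area (pixel-count oracle)
  dims <- c(121, 121)
  disk <- disk_mask(dims, c(61, 61), 40)
  circ <- find_contours(disk)[[1L]]
  vline <- separating_line(layout_with_source(c(61, 61), c(61, 200)))
  hs <- split_halves(circ, vline)
  area_m <- mirror_half(hs$unexposed, vline)$enclosed_area_px
  expect_equal(area_m / sum(disk), 1, tolerance = 0.02)
  expect_equal(area_m / (pi * 40^2), 1, tolerance = 0.02)

  # mirroring either half of a symmetric contour gives equal areas
  area_e <- mirror_half(hs$exposed, vline)$enclosed_area_px
  expect_equal(area_m / area_e, 1, tolerance = 0.01)
})

test_that("direct ellipse fit recovers circles and ellipses", {
  circ <- fit_ellipse(ellipse_points(100, c(50, 50), 10, 10))
  expect_equal(circ$semi_major, 10, tolerance = 1e-3)
  expect_equal(circ$semi_minor, 10, tolerance = 1e-3)

  ell <- fit_ellipse(ellipse_points(100, c(80, 120), 20, 10))
  expect_equal(ell$semi_major, 20, tolerance = 0.01)
  expect_equal(ell$semi_minor, 10, tolerance = 0.01)
  expect_equal(ell$center, c(80, 120), tolerance = 1e-6)
  expect_true(ell$angle < 1e-6 || pi - ell$angle < 1e-6)  # horizontal axis

  rot <- fit_ellipse(ellipse_points(200, c(0, 0), 20, 10, theta = pi / 6))
  expect_equal(rot$semi_major, 20, tolerance = 0.01)
  expect_equal(min(abs(rot$angle - pi / 6), abs(rot$angle - pi / 6 - pi)),
               0, tolerance = 1e-6)

  expect_error(fit_ellipse(rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))),
               "at least 5")
  collinear <- cbind(1:10, 2 * (1:10))
  expect_error(fit_ellipse(collinear), "degenerate|not an ellipse")
})

test_that("ellipse extent along a direction matches the projection oracle", {
  e <- fit_ellipse(ellipse_points(200, c(0, 0), 20, 10))
  expect_equal(ellipse_extent(e, c(0, 1)), 20, tolerance = 1e-3)  # horizontal
  expect_equal(ellipse_extent(e, c(1, 0)), 10, tolerance = 1e-3)  # vertical

  circ <- fit_ellipse(ellipse_points(100, c(0, 0), 7, 7))
  d <- c(1, 1) / sqrt(2)
  expect_equal(ellipse_extent(circ, d), 7, tolerance = 1e-3)

  # rotated ellipse: extent equals the max projection of boundary points
  er <- fit_ellipse(ellipse_points(500, c(0, 0), 20, 10, theta = pi / 6))
  bd <- ellipse_points(1e5, c(0, 0), 20, 10, theta = pi / 6)
  oracle <- max(bd[, 2L])        # projection onto the horizontal direction
  expect_equal(ellipse_extent(er, c(0, 1)), oracle, tolerance = 1e-3)

  expect_error(ellipse_extent(er, c(1, 1)), "unit")
})

test_that("deformation ratios recover generation parameters", {
  # two-half-ellipse colony: unexposed 100, exposed 70, vertical 90
  sp <- synthetic_spec(size = c(260, 300), center = c(130, 140),
                       r_unexposed = 100, r_exposed = 70, r_vertical = 90,
                       source = c(130, 290), distance_cm = 1,
                       group_label = "1cm", seed = 21L)
  g <- generate_colony(sp)
  seg <- segment_colony(g$image)
  d <- deformation_ratios(seg$periphery, g$layout, "periphery")
  expect_equal(d$horiz_ratio, 100 / 70, tolerance = 0.05)
  expect_equal(d$vert_ratio, 1, tolerance = 0.05)

  # line-symmetric colony: both ratios 1
  gs <- generate_colony(synthetic_spec(seed = 9L))
  segs <- segment_colony(gs$image)
  ds <- deformation_ratios(segs$periphery, gs$layout, "periphery")
  expect_equal(ds$horiz_ratio, 1, tolerance = 0.02)
  expect_equal(ds$vert_ratio, 1, tolerance = 0.02)
})

test_that("deformation ratios are invariant under whole-scene rotation", {
  sp <- treated_spec(0.7, seed = 31L)
  g <- generate_colony(sp)
  seg <- segment_colony(g$image)
  base <- deformation_ratios(seg$periphery, g$layout, "periphery")

  rotate_scene <- function(px, center, source, k) {
    # k quarter-turns counterclockwise of the pixel matrix and coordinates
    h <- nrow(px); w <- ncol(px)
    rot_pt <- function(p, h, w) c(w - p[2L] + 1, p[1L])  # 90 deg ccw
    for (i in seq_len(k)) {
      px <- t(px)[ncol(px):1L, , drop = FALSE]
      center <- rot_pt(center, h, w)
      source <- rot_pt(source, h, w)
      tmp <- h; h <- nrow(px); w <- ncol(px)
    }
    list(px = px, center = center, source = source)
  }
  for (k in 1:3) {
    rs <- rotate_scene(g$image$pixels, g$layout$colony_center,
                       g$layout$source_center, k)
    img_r <- colony_image(rs$px, pixel_size_um = g$image$pixel_size_um)
    lay_r <- experiment_layout("rot", rs$center, rs$source, 1, 1, "1cm")
    seg_r <- segment_colony(img_r)
    dr <- deformation_ratios(seg_r$periphery, lay_r, "periphery")
    expect_equal(dr$horiz_ratio / base$horiz_ratio, 1, tolerance = 0.02)
    expect_equal(dr$vert_ratio / base$vert_ratio, 1, tolerance = 0.02)
  }
})
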