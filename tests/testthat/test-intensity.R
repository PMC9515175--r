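test_that("region masks carve half-annulus and half-core regions", {
  sc <- make_disk_scene()
  masks <- region_masks(sc$per, sc$core, sc$line, sc$dims)
  expect_setequal(names(masks), c("periphery_exposed", "periphery_unexposed",
                                  "core_exposed", "core_unexposed"))
  half_ann <- pi * (100^2 - 40^2) / 2
  half_core <- pi * 40^2 / 2
  expect_equal(sum(masks$periphery_exposed) / half_ann, 1, tolerance = 0.02)
  expect_equal(sum(masks$periphery_unexposed) / half_ann, 1, tolerance = 0.02)
  expect_equal(sum(masks$core_exposed) / half_core, 1, tolerance = 0.02)
  expect_equal(sum(masks$core_unexposed) / half_core, 1, tolerance = 0.02)
  # disjoint regions; annulus excludes the core
  expect_false(any(masks$periphery_exposed & masks$core_exposed))

  expect_warning(m2 <- region_masks(sc$per, NULL, sc$line, sc$dims),
                 "core contour absent")
  expect_setequal(names(m2), c("periphery_exposed", "periphery_unexposed"))

  off_line <- separating_line(
    experiment_layout("o", c(5, 5), c(5, 100), 1, 1, "1cm"))
  expect_error(region_masks(sc$per, sc$core, off_line, sc$dims),
               "does not intersect")
})

test_that("intensity ratio divides exposed by unexposed region means", {
  sc <- make_disk_scene()
  masks <- region_masks(sc$per, sc$core, sc$line, sc$dims)

  uni <- colony_image(matrix(0.6, sc$dims[1L], sc$dims[2L]))
  r <- intensity_ratio(uni, masks, "periphery")
  expect_identical(r$ratio, 1)

  px <- matrix(0.8, sc$dims[1L], sc$dims[2L])
  px[, sc$center[2L]:sc$dims[2L]] <- 0.4  # exposed (right) half dimmer
  img <- colony_image(px)
  expect_equal(intensity_ratio(img, masks, "periphery")$ratio, 0.5)
  expect_equal(intensity_ratio(img, masks, "core")$ratio, 0.5)

  # oracle: direct per-pixel summation on a smooth gradient image
  grad <- colony_image(matrix(seq(0, 1, length.out = sc$dims[1L] * sc$dims[2L]),
                              sc$dims[1L], sc$dims[2L]))
  r2 <- intensity_ratio(grad, masks, "periphery")
  oracle <- sum(grad$pixels[masks$periphery_exposed]) /
    sum(masks$periphery_exposed) /
    (sum(grad$pixels[masks$periphery_unexposed]) /
       sum(masks$periphery_unexposed))
  expect_equal(r2$ratio, oracle, tolerance = 1e-9)

  empty <- masks
  empty$periphery_exposed[] <- FALSE
  expect_error(intensity_ratio(uni, empty, "periphery"), "degenerate")
})

test_that("control augmentation averages the three stated partitions", {
  dims <- c(10, 10)
  center <- c(5.5, 5.5)
  region <- matrix(TRUE, dims[1L], dims[2L])

  uni <- colony_image(matrix(0.25, dims[1L], dims[2L]))
  expect_identical(control_augmented_ratio(uni, region, center)$ratio, 1)

  px <- matrix(0.5, dims[1L], dims[2L])
  px[, 1:5] <- 1.0                       # left half bright
  res <- control_augmented_ratio(colony_image(px), region, center)
  expect_equal(unname(res$partition_ratios["left_right"]), 2.0)
  expect_equal(unname(res$partition_ratios["top_bottom"]), 1.0)
  expect_equal(unname(res$partition_ratios["diagonal"]), 1.0)
  expect_equal(res$ratio, 4 / 3)

  # mirror-symmetric image: the reflection swaps the two diagonal cells,
  # so the diagonal partition ratio is exactly 1 (and so is left/right)
  set.seed(8)
  half <- matrix(runif(50), 10, 5)
  sym <- cbind(half, half[, 5:1])        # symmetric about the center column
  res2 <- control_augmented_ratio(colony_image(sym), region, center)
  expect_equal(unname(res2$partition_ratios["diagonal"]), 1.0)
  expect_equal(unname(res2$partition_ratios["left_right"]), 1.0)
})

test_that("pixel distances are Euclidean", {
  expect_identical(pixel_distances(c(0, 0), c(3, 4)), 5)
  expect_identical(pixel_distances(c(7, 2), c(7, 2)), 0)
  set.seed(4)
  pts <- matrix(runif(2000, 0, 500), ncol = 2L)
  src <- c(250, 100)
  naive <- apply(pts, 1L, function(p) sqrt(sum((p - src)^2)))
  expect_equal(pixel_distances(pts, src), naive, tolerance = 1e-12)
})

test_that("leading-edge band is the outer rim of the exposed half", {
  dims <- c(121, 121)
  center <- c(61, 61)
  per <- find_contours(disk_mask(dims, center, 50))[[1L]]
  line <- separating_line(experiment_layout("b", center, c(61, 400), 1, 1,
                                            "1cm"))
  band <- leading_edge_band(per, line, width = 20, dim = dims)
  expect_equal(sum(band) / (pi * (50^2 - 30^2) / 2), 1, tolerance = 0.03)
  expect_true(all(band[, 1:60] == FALSE))   # exposed side only

  wide <- leading_edge_band(per, line, width = 100, dim = dims)
  half <- disk_mask(dims, center, 50)
  half[, 1:61] <- FALSE
  expect_equal(sum(wide) / sum(half), 1, tolerance = 0.02)  # saturates to the exposed half

  thin <- leading_edge_band(per, line, width = 1, dim = dims)
  expect_lt(sum(thin), 200)                 # one-pixel rim
  expect_gt(sum(thin), 50)
})

test_that("edge regression matches exact and noisy linear intensities", {
  dims <- c(60, 60)
  band <- matrix(TRUE, dims[1L], dims[2L])
  src <- c(-40, -40)
  coords <- cbind(rep(seq_len(dims[1L]), times = dims[2L]),
                  rep(seq_len(dims[2L]), each = dims[1L]))
  d <- pixel_distances(coords, src)

  exact <- colony_image(matrix(0.5 - 0.001 * d, dims[1L], dims[2L]))
  fit <- edge_regression(exact, band, src)
  expect_equal(fit$slope, -0.001, tolerance = 1e-9)
  expect_equal(fit$intercept, 0.5, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$n_pixels, prod(dims))

  flat <- colony_image(matrix(0.4, dims[1L], dims[2L]))
  ffit <- edge_regression(flat, band, src)
  expect_identical(ffit$slope, 0)
  expect_identical(ffit$r_squared, 0)

  one_dist <- matrix(FALSE, dims[1L], dims[2L])
  one_dist[10, c(10, 50)] <- TRUE            # equidistant from (10, 30)
  expect_error(edge_regression(flat, one_dist, c(10, 30)), "rank deficient")

  # normal-equations oracle on noisy data
  set.seed(12)
  y <- pmin(pmax(0.5 + 2e-3 * d + rnorm(length(d), 0, 0.02), 0), 1)
  noisy <- colony_image(matrix(y, dims[1L], dims[2L]))
  nfit <- edge_regression(noisy, band, src)
  sxx <- sum((d - mean(d))^2)
  slope_o <- sum((d - mean(d)) * (y - mean(y))) / sxx
  int_o <- mean(y) - slope_o * mean(d)
  r2_o <- slope_o^2 * sxx / sum((y - mean(y))^2)
  expect_equal(nfit$slope, slope_o, tolerance = 1e-9)
  expect_equal(nfit$intercept, int_o, tolerance = 1e-9)
  expect_equal(nfit$r_squared, r2_o, tolerance = 1e-9)
})

test_that("mirroring the scene inverts the intensity ratio", {
  sp <- synthetic_spec(size = c(320, 320), center = c(160.5, 160.5),
                       source = c(160.5, 660), distance_cm = 1,
                       gradient = 3e-4, group_label = "1cm", seed = 17L)
  g <- generate_colony(sp)
  seg <- segment_colony(g$image)
  line <- separating_line(g$layout)
  dims <- c(g$image$height, g$image$width)
  masks <- region_masks(seg$periphery, seg$core, line, dims)
  r1 <- intensity_ratio(g$image, masks, "periphery")$ratio

  flip <- function(m) m[, ncol(m):1L, drop = FALSE]
  img_f <- colony_image(flip(g$image$pixels))
  masks_f <- lapply(masks, flip)
  # flipping swaps the exposed and unexposed halves
  names(masks_f) <- c("periphery_unexposed", "periphery_exposed",
                      "core_unexposed", "core_exposed")
  r2 <- intensity_ratio(img_f, masks_f, "periphery")$ratio
  expect_equal(r2, 1 / r1, tolerance = 1e-6)
})
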