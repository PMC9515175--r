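#' Specification of a synthetic macrocolony image
#'
#' Forward model used to benchmark every pipeline stage against known ground
#' truth. The colony footprint is the union of two half-ellipses sharing the
#' vertical (perpendicular-to-source) axis: semi-axis `r_unexposed` on the
#' side away from the source, `r_exposed` on the side facing it, and common
#' vertical semi-axis `r_vertical`. The core is a scaled copy (factor
#' `core_scale`, optionally with its own exposed-side asymmetry). Intensity
#' is a per-region base level (background / periphery lawn / core) plus, on
#' colony pixels, a gradient `gradient` per pixel of Euclidean distance from
#' the virtual source (centered on the footprint's mean source distance so
#' the levels keep their meaning), plus Gaussian noise, clipped to `[0, 1]`.
#'
#' The core's base level is *below* the periphery lawn: in the thresholded
#' mask the core then shows up as an interior hole, whose boundary is the
#' second-largest contour — the configuration the segmentation stage is
#' built around.
#'
#' Defaults describe a mature (day 3) colony: 320 x 320 px frame at
#' 20 um/px (6.4 mm field), colony semi-axes 110 px (2.2 mm radius), core at
#' 45% of the colony, source 1 cm to the right of the seeding point.
#'
#' @param size `(height, width)` in pixels.
#' @param center `(row, col)` seeding point.
#' @param r_unexposed,r_exposed,r_vertical Footprint semi-axes in pixels.
#' @param core_scale Core semi-axes as a fraction of the colony's (0, 1).
#' @param core_asymmetry Exposed-side factor for the core's horizontal
#'   semi-axis (default 1 = symmetric core).
#' @param level_background,level_periphery,level_core Base intensities.
#' @param gradient Intensity per pixel of distance from the source.
#' @param source `(row, col)` of the virtual source (may be outside the
#'   frame), or `NULL` for a control colony.
#' @param distance_cm Nominal source distance (metadata only).
#' @param noise_sd Gaussian noise standard deviation.
#' @param pixel_size_um Micrometres per pixel.
#' @param day Imaging day index.
#' @param group_label Group name for the layout.
#' @param seed Integer seed making the noise field reproducible.
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(size = c(320L, 320L), center = c(160, 160),
                           r_unexposed = 110, r_exposed = 110,
                           r_vertical = 110,
                           core_scale = 0.45, core_asymmetry = 1,
                           level_background = 0.05, level_periphery = 0.72,
                           level_core = 0.18,
                           gradient = 0, source = NULL, distance_cm = NULL,
                           noise_sd = 0.02, pixel_size_um = 20,
                           day = 3L, group_label = if (is.null(source))
                             "control" else "treated",
                           seed = 1L) {
  spec <- list(size = as.integer(size), center = as.numeric(center),
               r_unexposed = r_unexposed, r_exposed = r_exposed,
               r_vertical = r_vertical, core_scale = core_scale,
               core_asymmetry = core_asymmetry,
               level_background = level_background,
               level_periphery = level_periphery, level_core = level_core,
               gradient = gradient,
               source = if (is.null(source)) NULL else as.numeric(source),
               distance_cm = distance_cm, noise_sd = noise_sd,
               pixel_size_um = pixel_size_um, day = as.integer(day),
               group_label = group_label, seed = as.integer(seed))
  if (any(c(spec$r_unexposed, spec$r_exposed, spec$r_vertical) <= 0))
    stop("all semi-axes must be > 0", call. = FALSE)
  if (spec$core_scale <= 0 || spec$core_scale >= 1)
    stop("`core_scale` must lie in (0, 1)", call. = FALSE)
  if (spec$noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  levels <- c(spec$level_background, spec$level_periphery, spec$level_core)
  if (any(levels < 0 | levels > 1))
    stop("base intensity levels must lie in [0, 1]", call. = FALSE)
  if (is.null(spec$source) && spec$gradient != 0)
    stop("a gradient needs a source position", call. = FALSE)
  class(spec) <- "synthetic_spec"
  spec
}

#' Generate one synthetic macrocolony image with ground truth
#'
#' Deterministic given `spec$seed`; the ground truth records the exact
#' generation parameters and rasterized region pixel counts, so recovery by
#' the pipeline can be tested quantitatively.
#'
#' @param spec A [synthetic_spec()].
#' @param image_id Identifier used in the layout.
#' @return List with `image` ([colony_image]), `layout`
#'   ([experiment_layout]) and `truth` (list: semi-axes, expected
#'   `horiz_ratio = r_unexposed / r_exposed`, footprint/core pixel areas and
#'   masks, gradient, noise sd).
#' @export
generate_colony <- function(spec, image_id = "synthetic") {
  stopifnot(inherits(spec, "synthetic_spec"))
  h <- spec$size[1L]; w <- spec$size[2L]
  rr <- matrix(seq_len(h), h, w) - spec$center[1L]
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - spec$center[2L]
  half_ellipse <- function(ru, re, rv) {
    rx <- ifelse(cc <= 0, ru, re)
    (cc / rx)^2 + (rr / rv)^2 <= 1
  }
  footprint <- half_ellipse(spec$r_unexposed, spec$r_exposed, spec$r_vertical)
  core <- half_ellipse(spec$core_scale * spec$r_unexposed,
                       spec$core_asymmetry * spec$core_scale * spec$r_unexposed,
                       spec$core_scale * spec$r_vertical)
  img <- matrix(spec$level_background, h, w)
  img[footprint] <- spec$level_periphery
  img[core] <- spec$level_core
  if (!is.null(spec$source) && spec$gradient != 0) {
    d <- sqrt((rr + spec$center[1L] - spec$source[1L])^2 +
              (cc + spec$center[2L] - spec$source[2L])^2)
    img[footprint] <- img[footprint] +
      spec$gradient * (d[footprint] - mean(d[footprint]))
  }
  if (spec$noise_sd > 0) {
    old <- seed_guard(spec$seed)
    on.exit(old(), add = TRUE)
    img <- img + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
  }
  img <- pmin(pmax(img, 0), 1)
  image <- colony_image(img, pixel_size_um = spec$pixel_size_um,
                        source_path = "synthetic",
                        channel_label = "synthetic-GFP")
  layout <- experiment_layout(
    image_id = image_id, colony_center = spec$center,
    source_center = spec$source, distance_cm = spec$distance_cm,
    day = spec$day, group_label = spec$group_label, image_dim = c(h, w))
  truth <- list(
    r_unexposed = spec$r_unexposed, r_exposed = spec$r_exposed,
    r_vertical = spec$r_vertical,
    core_r_unexposed = spec$core_scale * spec$r_unexposed,
    core_r_exposed = spec$core_asymmetry * spec$core_scale * spec$r_unexposed,
    core_r_vertical = spec$core_scale * spec$r_vertical,
    horiz_ratio = spec$r_unexposed / spec$r_exposed,
    core_horiz_ratio = 1 / spec$core_asymmetry,
    footprint_area_px = sum(footprint), core_area_px = sum(core),
    footprint_mask = footprint, core_mask = core,
    gradient = spec$gradient, noise_sd = spec$noise_sd)
  list(image = image, layout = layout, truth = truth)
}

# set the RNG reproducibly and return a restorer for the caller's state
seed_guard <- function(seed) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (has_seed) assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

# deterministic per-colony seed derived from a master seed (stays < 2^31)
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + index * 16807) %% 2147483647)
}

#' Generate a cohort of synthetic colonies across treatment groups
#'
#' Emulates a one-day imaging cohort: for each group a base [synthetic_spec()]
#' is jittered per colony (multiplicative log-normal jitter with standard
#' deviation `jitter_sd` on the footprint semi-axes, independent per axis)
#' and rendered with a per-colony seed derived from the master seed, so the
#' whole cohort is reproducible yet colonies are independent. Groups with
#' `n = 0` are omitted with a warning.
#'
#' @param n_per_group Named integer vector of colony counts per group.
#' @param specs Named list of base [synthetic_spec()]s, names matching
#'   `n_per_group`.
#' @param master_seed Integer master seed.
#' @param jitter_sd Log-scale jitter sd on semi-axes (default 0.03).
#' @param out_dir Optional directory; when given, PNG images plus
#'   `layout.csv` and `truth.csv` are written there.
#' @return List with `colonies` (list of [generate_colony()] results),
#'   `layouts`, and `truth` (data frame of ground-truth scalars per colony).
#' @export
generate_cohort <- function(n_per_group, specs, master_seed = 1L,
                            jitter_sd = 0.03, out_dir = NULL) {
  stopifnot(length(n_per_group) >= 1L,
            all(names(n_per_group) %in% names(specs)))
  colonies <- list()
  truth_rows <- list()
  idx <- 0L
  for (g in names(n_per_group)) {
    n <- n_per_group[[g]]
    if (n == 0L) {
      warning(sprintf("group '%s' has n = 0 and is omitted", g),
              call. = FALSE)
      next
    }
    base <- specs[[g]]
    for (i in seq_len(n)) {
      idx <- idx + 1L
      seed_i <- derive_seed(master_seed, idx)
      restore <- seed_guard(derive_seed(master_seed, idx + 100000L))
      jit <- exp(stats::rnorm(3L, 0, jitter_sd))
      restore()
      sp <- base
      sp$r_unexposed <- base$r_unexposed * jit[1L]
      sp$r_exposed <- base$r_exposed * jit[2L]
      sp$r_vertical <- base$r_vertical * jit[3L]
      sp$seed <- seed_i
      id <- sprintf("%s_%02d", gsub("[^A-Za-z0-9.]+", "-", g), i)
      colonies[[id]] <- generate_colony(sp, image_id = id)
      tr <- colonies[[id]]$truth
      truth_rows[[id]] <- data.frame(
        image_id = id, group = g, day = sp$day,
        r_unexposed = tr$r_unexposed, r_exposed = tr$r_exposed,
        r_vertical = tr$r_vertical, horiz_ratio = tr$horiz_ratio,
        core_horiz_ratio = tr$core_horiz_ratio,
        footprint_area_px = tr$footprint_area_px,
        core_area_px = tr$core_area_px,
        gradient = tr$gradient, noise_sd = tr$noise_sd, seed = sp$seed,
        stringsAsFactors = FALSE)
    }
  }
  layouts <- lapply(colonies, `[[`, "layout")
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(colonies))
      write_image(colonies[[id]]$image, file.path(out_dir,
                                                  paste0(id, ".png")))
    write_layout(layouts, file.path(out_dir, "layout.csv"))
    utils::write.csv(truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
  }
  list(colonies = colonies, layouts = layouts, truth = truth)
}

#' Study-condition cohort specs (control and 1 / 1.5 / 2 cm groups)
#'
#' Base specifications for the four-group demo cohort matching the study's
#' group sizes (12, 11, 9 plates at 1, 1.5 and 2 cm, 12 control plates).
#' Exposure effects scale with proximity: the exposed-side semi-axis factor
#' is 0.60, 0.75, 0.90 at 1, 1.5, 2 cm (control 1.0), and the intensity
#' gradient is 3e-4, 1e-4, 3e-5 per pixel (control 0). At 20 um/px, 1 cm is
#' 500 px; sources sit east (right) of the seeding point at the nominal
#' distance.
#'
#' @param scale Resolution scale factor applied to all lengths (default 1).
#' @param noise_sd Noise level passed to every spec (default 0.02).
#' @param day Imaging day (default 3).
#' @return List with `n_per_group` and `specs`, ready for
#'   [generate_cohort()].
#' @export
study_cohort_specs <- function(scale = 1, noise_sd = 0.02, day = 3L) {
  px_per_cm <- 500 * scale                 # 20 um/px at scale 1
  sz <- round(c(320, 320) * scale)
  ctr <- (sz + 1) / 2
  base <- function(f, dist_cm, grad, group) {
    synthetic_spec(
      size = sz, center = ctr,
      r_unexposed = 110 * scale, r_exposed = 110 * scale * f,
      r_vertical = 110 * scale,
      gradient = if (is.null(dist_cm)) 0 else grad / scale,
      source = if (is.null(dist_cm)) NULL else
        c(ctr[1L], ctr[2L] + dist_cm * px_per_cm),
      distance_cm = dist_cm, noise_sd = noise_sd,
      pixel_size_um = 20 / scale, day = day, group_label = group)
  }
  list(
    n_per_group = c(`1cm` = 12L, `1.5cm` = 11L, `2cm` = 9L, control = 12L),
    specs = list(
      `1cm` = base(0.60, 1.0, 3e-4, "1cm"),
      `1.5cm` = base(0.75, 1.5, 1e-4, "1.5cm"),
      `2cm` = base(0.90, 2.0, 3e-5, "2cm"),
      control = base(1.0, NULL, 0, "control")))
}
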