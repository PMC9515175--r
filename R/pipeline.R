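#' Measure one colony image end to end
#'
#' Runs segmentation, deformation morphometrics (periphery and core),
#' intensity ratios and — for non-control layouts — the leading-edge
#' regression, returning one measurement-record row per metric.
#'
#' @param image A [colony_image].
#' @param layout The image's [experiment_layout].
#' @param kernel Erosion kernel (default 5).
#' @param band_width Leading-edge band width in pixels (default 20).
#' @param core_min_frac,core_max_frac Core acceptance gates
#'   (see [segment_colony()]).
#' @return A records data frame (see [measurement_records()]).
#' @export
measure_colony <- function(image, layout, kernel = 5L, band_width = 20,
                           core_min_frac = 0.01, core_max_frac = 0.9) {
  seg <- segment_colony(image, kernel = kernel,
                        core_min_frac = core_min_frac,
                        core_max_frac = core_max_frac)
  line <- separating_line(layout)
  dims <- c(image$height, image$width)
  rec <- function(metric, value)
    measurement_records(layout$image_id, layout$group_label, layout$day,
                        metric, value)
  rows <- list(rec("coverage_area_um2",
                   coverage_area(seg$periphery, image$pixel_size_um)))
  dp <- deformation_ratios(seg$periphery, layout, "periphery")
  rows <- c(rows, list(rec("horiz_ratio_periphery", dp$horiz_ratio),
                       rec("vert_ratio_periphery", dp$vert_ratio)))
  masks <- suppressWarnings(
    region_masks(seg$periphery, seg$core, line, dims))
  if (!is.null(seg$core)) {
    dc <- deformation_ratios(seg$core, layout, "core")
    rows <- c(rows, list(rec("horiz_ratio_core", dc$horiz_ratio),
                         rec("vert_ratio_core", dc$vert_ratio)))
  }
  is_control <- is.null(layout$source_center)
  if (is_control) {
    per_mask <- masks$periphery_exposed | masks$periphery_unexposed
    rows <- c(rows, list(rec(
      "intensity_ratio_periphery",
      control_augmented_ratio(image, per_mask, layout$colony_center)$ratio)))
    if (!is.null(seg$core)) {
      core_mask <- masks$core_exposed | masks$core_unexposed
      rows <- c(rows, list(rec(
        "intensity_ratio_core",
        control_augmented_ratio(image, core_mask,
                                layout$colony_center)$ratio)))
    }
  } else {
    rows <- c(rows, list(rec("intensity_ratio_periphery",
                             intensity_ratio(image, masks, "periphery")$ratio)))
    if (!is.null(seg$core))
      rows <- c(rows, list(rec("intensity_ratio_core",
                               intensity_ratio(image, masks, "core")$ratio)))
    band <- leading_edge_band(seg$periphery, line, width = band_width,
                              dim = dims, exclude = seg$core)
    if (any(band)) {
      er <- edge_regression(image, band, layout$source_center)
      rows <- c(rows, list(rec("edge_slope", er$slope),
                           rec("edge_intercept", er$intercept),
                           rec("edge_r2", er$r_squared)))
    }
  }
  do.call(rbind, rows)
}

#' Run the full analysis pipeline over an image set
#'
#' For every layout row: load the image (or take it from `images`), measure
#' all metrics, and finally compare every treatment group to control per
#' metric and day. Analysis is deterministic — rerunning on the same inputs
#' reproduces the output CSVs byte-identically.
#'
#' @param layouts List of [experiment_layout]s, or a path to a layout CSV.
#' @param images Either a directory containing `<image_id>.png` files, or a
#'   named list of [colony_image]s keyed by image id.
#' @param out_dir Output directory; `records.csv`, `comparisons.csv` and
#'   `run_log.json` are written there (created if needed).
#' @param pixel_size_um Calibration applied to images loaded from disk.
#' @param kernel,band_width,core_min_frac,core_max_frac See
#'   [measure_colony()].
#' @param control_label Control group label (default `"control"`).
#' @param welch Use Welch's t-test in the comparisons (default FALSE).
#' @return Invisibly, a list with `records` and `comparisons` data frames.
#' @export
run_pipeline <- function(layouts, images, out_dir,
                         pixel_size_um = 20, kernel = 5L, band_width = 20,
                         core_min_frac = 0.01, core_max_frac = 0.9,
                         control_label = "control", welch = FALSE) {
  if (is.character(layouts) && length(layouts) == 1L)
    layouts <- read_layout(layouts)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  all_records <- list()
  for (l in layouts) {
    img <- if (is.character(images)) {
      path <- file.path(images, paste0(l$image_id, ".png"))
      tryCatch(load_image(path, pixel_size_um = pixel_size_um),
               error = function(e) stop(sprintf(
                 "pipeline failed at stage 'load' for image '%s': %s",
                 l$image_id, conditionMessage(e)), call. = FALSE))
    } else images[[l$image_id]]
    if (is.null(img))
      stop(sprintf("pipeline failed at stage 'load': no image for id '%s'",
                   l$image_id), call. = FALSE)
    all_records[[l$image_id]] <- tryCatch(
      measure_colony(img, l, kernel = kernel, band_width = band_width,
                     core_min_frac = core_min_frac,
                     core_max_frac = core_max_frac),
      error = function(e) stop(sprintf(
        "pipeline failed at stage 'measure' for image '%s': %s",
        l$image_id, conditionMessage(e)), call. = FALSE))
  }
  records <- do.call(rbind, all_records)
  rownames(records) <- NULL
  write_records(records, file.path(out_dir, "records.csv"))
  comparisons <- if (control_label %in% records$group)
    compare_to_control(records, control_label = control_label, welch = welch)
  else {
    warning(sprintf("no '%s' group present; skipping group comparisons",
                    control_label), call. = FALSE)
    NULL
  }
  if (!is.null(comparisons))
    utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
  log <- list(package = "colonymorph",
              version = as.character(utils::packageVersion("colonymorph")),
              n_images = length(layouts),
              parameters = list(pixel_size_um = pixel_size_um,
                                kernel = kernel, band_width = band_width,
                                core_min_frac = core_min_frac,
                                core_max_frac = core_max_frac,
                                control_label = control_label,
                                welch = welch))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(records = records, comparisons = comparisons))
}
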