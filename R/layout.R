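#' Experiment layout for one colony image
#'
#' Describes the exposure geometry of a single macrocolony plate: where the
#' colony was seeded, where the antimicrobial droplet sits (absent for
#' controls), the nominal seeding-point-to-source distance, and the imaging
#' day. Coordinates are 1-based `(row, col)` pixel positions; the source may
#' lie outside the image frame.
#'
#' @param image_id Identifier linking the layout to an image file.
#' @param colony_center Numeric `(row, col)` of the seeding point, inside the
#'   image when image dimensions are known.
#' @param source_center Numeric `(row, col)` of the antimicrobial source, or
#'   `NULL` for control plates.
#' @param distance_cm Nominal source distance in centimetres (> 0), or `NULL`.
#' @param day Imaging day index (integer >= 1).
#' @param group_label Group name, e.g. `"control"`, `"1cm"`, `"1.5cm"`, `"2cm"`.
#' @param image_dim Optional `(height, width)` used to validate the center.
#'
#' @return An object of class `experiment_layout`.
#' @export
experiment_layout <- function(image_id, colony_center, source_center = NULL,
                              distance_cm = NULL, day = 1L,
                              group_label = "control", image_dim = NULL) {
  stopifnot(length(colony_center) == 2L, is.numeric(colony_center))
  is_control <- is.null(source_center)
  if (!is_control && (length(source_center) != 2L || anyNA(source_center)))
    stop("`source_center` must be (row, col) or NULL", call. = FALSE)
  if (is_control != identical(tolower(group_label), "control"))
    stop(sprintf(
      "layout '%s': source coordinates are absent if and only if the group is 'control' (got group '%s')",
      image_id, group_label), call. = FALSE)
  if (!is.null(distance_cm)) {
    if (!is.finite(distance_cm) || distance_cm <= 0)
      stop(sprintf("layout '%s': nominal distance must be > 0 when present",
                   image_id), call. = FALSE)
  }
  if (!is.null(image_dim)) {
    if (colony_center[1L] < 1 || colony_center[1L] > image_dim[1L] ||
        colony_center[2L] < 1 || colony_center[2L] > image_dim[2L])
      stop(sprintf("layout '%s': colony center (%g, %g) outside image bounds %d x %d",
                   image_id, colony_center[1L], colony_center[2L],
                   image_dim[1L], image_dim[2L]), call. = FALSE)
  }
  day <- as.integer(day)
  if (is.na(day) || day < 1L)
    stop(sprintf("layout '%s': day must be an integer >= 1", image_id),
         call. = FALSE)
  structure(
    list(image_id = as.character(image_id),
         colony_center = as.numeric(colony_center),
         source_center = if (is_control) NULL else as.numeric(source_center),
         distance_cm = if (is.null(distance_cm)) NULL else as.numeric(distance_cm),
         day = day, group_label = as.character(group_label)),
    class = "experiment_layout")
}

#' @export
print.experiment_layout <- function(x, ...) {
  src <- if (is.null(x$source_center)) "control (no source)" else
    sprintf("source (%g, %g), %g cm", x$source_center[1L], x$source_center[2L],
            if (is.null(x$distance_cm)) NA_real_ else x$distance_cm)
  cat(sprintf("<experiment_layout> %s: center (%g, %g), %s, day %d, group '%s'\n",
              x$image_id, x$colony_center[1L], x$colony_center[2L], src,
              x$day, x$group_label))
  invisible(x)
}

layout_columns <- c("image_id", "center_row", "center_col", "source_row",
                    "source_col", "distance_cm", "day", "group")

#' Read an experiment layout table
#'
#' The layout CSV has one row per image with columns `image_id, center_row,
#' center_col, source_row, source_col, distance_cm, day, group`. Empty
#' `source_row`/`source_col`/`distance_cm` fields denote control plates.
#'
#' @param path Path to the layout CSV.
#' @return A list of [experiment_layout] objects, one per row.
#' @export
read_layout <- function(path) {
  if (!file.exists(path))
    stop(sprintf("layout file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(layout_columns, names(df))
  if (length(missing_cols))
    stop(sprintf("layout %s: missing columns: %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    parse_err <- function(msg)
      stop(sprintf("layout %s row %d: %s", path, i, msg), call. = FALSE)
    center <- suppressWarnings(as.numeric(c(row$center_row, row$center_col)))
    if (anyNA(center)) parse_err("colony center is not numeric")
    src <- suppressWarnings(as.numeric(c(row$source_row, row$source_col)))
    has_src <- !all(is.na(src))
    if (has_src && anyNA(src)) parse_err("source coordinates half-specified")
    dist <- suppressWarnings(as.numeric(row$distance_cm))
    tryCatch(
      experiment_layout(
        image_id = row$image_id, colony_center = center,
        source_center = if (has_src) src else NULL,
        distance_cm = if (is.na(dist)) NULL else dist,
        day = row$day, group_label = row$group),
      error = function(e) parse_err(conditionMessage(e)))
  })
}

#' Write an experiment layout table
#'
#' Inverse of [read_layout()]; round-trips all fields.
#'
#' @param layouts List of [experiment_layout] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layouts, path) {
  df <- do.call(rbind, lapply(layouts, function(l) {
    data.frame(
      image_id = l$image_id,
      center_row = l$colony_center[1L], center_col = l$colony_center[2L],
      source_row = if (is.null(l$source_center)) NA_real_ else l$source_center[1L],
      source_col = if (is.null(l$source_center)) NA_real_ else l$source_center[2L],
      distance_cm = if (is.null(l$distance_cm)) NA_real_ else l$distance_cm,
      day = l$day, group = l$group_label,
      stringsAsFactors = FALSE)
  }))
  if (is.null(df)) df <- as.data.frame(
    stats::setNames(rep(list(character(0)), length(layout_columns)),
                    layout_columns))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

metric_vocabulary <- c(
  "coverage_area_um2",
  "horiz_ratio_periphery", "vert_ratio_periphery",
  "horiz_ratio_core", "vert_ratio_core",
  "intensity_ratio_periphery", "intensity_ratio_core",
  "edge_slope", "edge_intercept", "edge_r2")

#' Build a table of per-colony measurement records
#'
#' The row type shared by every pipeline stage: one scalar metric for one
#' colony image. `metric` must come from the fixed vocabulary
#' `r paste(metric_vocabulary, collapse = ", ")`.
#'
#' @param image_id,group,day,metric,value Vectors (recycled to equal length).
#' @return A `data.frame` with columns `image_id, group, day, metric, value`.
#' @export
measurement_records <- function(image_id, group, day, metric, value) {
  df <- data.frame(image_id = as.character(image_id),
                   group = as.character(group),
                   day = as.integer(day),
                   metric = as.character(metric),
                   value = as.numeric(value),
                   stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$metric), metric_vocabulary)
  if (length(bad))
    stop(sprintf("unknown metric name(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  if (nrow(df) && any(!is.finite(df$value)))
    stop("measurement values must be finite", call. = FALSE)
  df
}

records_columns <- c("image_id", "group", "day", "metric", "value")

#' Write measurement records to CSV
#'
#' Fixed header `image_id, group, day, metric, value`; an empty record set
#' writes a header-only file. Round-trips losslessly with [read_records()].
#'
#' @param records Data frame from [measurement_records()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  stopifnot(all(records_columns %in% names(records)))
  utils::write.csv(records[, records_columns, drop = FALSE], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read measurement records written by [write_records()]
#' @param path CSV path.
#' @return A records data frame (possibly zero rows).
#' @export
read_records <- function(path) {
  if (!file.exists(path))
    stop(sprintf("records file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(image_id = "character",
                                       group = "character", day = "integer",
                                       metric = "character", value = "numeric"))
  missing_cols <- setdiff(records_columns, names(df))
  if (length(missing_cols))
    stop(sprintf("records %s: missing columns: %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  df
}
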