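#' Read and write MOT-Challenge box files
#'
#' The interchange format is the MOT-Challenge CSV layout: one box per row,
#' comma-separated fields `frame, id, bb_left, bb_top, bb_width, bb_height,
#' conf, x, y, z`, no header. Raw detections carry `id = -1`; the world
#' coordinates `x, y, z` are unused placeholders written as `-1`.
#'
#' `read_detections()` returns the rows sorted stably by frame (ties keep
#' file order) with the `id` column dropped. `read_tracks()` keeps the ids.
#' Numeric fields are written with six decimals, so a write/read round trip
#' is lossless at that precision.
#'
#' @param path File path.
#' @return `read_detections()`: a tibble `frame, left, top, width, height,
#'   conf`. `read_tracks()`: a tibble `frame, id, left, top, width,
#'   height, conf`.
#' @name mot_io
NULL

read_mot <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  cols <- c("frame", "id", "left", "top", "width", "height", "conf", "x", "y", "z")
  if (file.size(path) == 0) {
    out <- lapply(cols, function(x) numeric(0))
    names(out) <- cols
    return(tibble::as_tibble(out))
  }
  raw <- tryCatch(
    utils::read.csv(path, header = FALSE, col.names = cols,
                    colClasses = "numeric"),
    error = function(e) abort(paste0("malformed MOT file ", path, ": ",
                                     conditionMessage(e))))
  bad <- which(!is.finite(raw$frame) | raw$frame < 1 |
                 raw$width <= 0 | raw$height <= 0)
  if (length(bad) > 0) {
    abort(sprintf("malformed MOT row at line %d of %s", bad[1], path))
  }
  tibble::as_tibble(raw[order(raw$frame), , drop = FALSE])
}

#' @rdname mot_io
#' @export
read_detections <- function(path) {
  out <- read_mot(path)
  out$frame <- as.integer(out$frame)
  out[, c("frame", "left", "top", "width", "height", "conf")]
}

#' @rdname mot_io
#' @export
read_tracks <- function(path) {
  out <- read_mot(path)
  out$frame <- as.integer(out$frame)
  out$id <- as.integer(out$id)
  out[, c("frame", "id", "left", "top", "width", "height", "conf")]
}

mot_lines <- function(frame, id, left, top, width, height, conf) {
  sprintf("%d,%d,%.6f,%.6f,%.6f,%.6f,%.6f,-1,-1,-1",
          as.integer(frame), as.integer(id), left, top, width, height, conf)
}

#' @rdname mot_io
#' @param dets A detection table (`frame`, box columns, `conf`); written
#'   with `id = -1`.
#' @export
write_detections <- function(dets, path) {
  writeLines(mot_lines(dets$frame, rep(-1L, nrow(dets)), dets$left, dets$top,
                       dets$width, dets$height, dets$conf), path)
  invisible(path)
}

#' @rdname mot_io
#' @param tracks A track table (`frame`, `id`, box columns); written with
#'   `conf = 1`.
#' @export
write_tracks <- function(tracks, path) {
  conf <- if ("conf" %in% names(tracks)) tracks$conf else rep(1, nrow(tracks))
  writeLines(mot_lines(tracks$frame, tracks$id, tracks$left, tracks$top,
                       tracks$width, tracks$height, conf), path)
  invisible(path)
}

#' Read and write appearance feature sidecars
#'
#' Features are stored as a headered CSV with columns `frame`, `det`
#' (1-based detection index within the frame, in detection-file row order)
#' and `f1 ... fD`.
#'
#' @param path File path.
#' @param features A feature tibble as produced by [simulate_scene()].
#' @name feature_io
#' @export
read_features <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  out <- tibble::as_tibble(utils::read.csv(path))
  need <- c("frame", "det")
  if (!all(need %in% names(out))) {
    abort(paste0("malformed feature file ", path, ": need frame and det columns"))
  }
  out
}

#' @rdname feature_io
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' Read and write pipeline configuration
#'
#' A single YAML file can hold up to three sections: `scene` (arguments of
#' [scene_config()]), `tracker` (arguments of [tracker_config()]) and
#' `line` (`x1, y1, x2, y2, band, direction`, see [counting_line()]). A
#' dump/load round trip reproduces the configuration exactly.
#'
#' @param path YAML file path.
#' @return `read_config()`: a list with any of `scene`, `tracker`, `line`
#'   populated as package objects.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(raw$scene)) out$scene <- do.call(scene_config, raw$scene)
  if (!is.null(raw$tracker)) out$tracker <- do.call(tracker_config, raw$tracker)
  if (!is.null(raw$line)) {
    ln <- raw$line
    out$line <- counting_line(ln$x1, ln$y1, ln$x2, ln$y2,
                              band = ln$band %||% 5,
                              direction = ln$direction %||% "both")
  }
  out
}

#' @rdname read_config
#' @param config A list with any of `scene` (a `scene_config`), `tracker`
#'   (a `tracker_config`), `line` (a `counting_line`).
#' @export
write_config <- function(config, path) {
  flat_line <- function(l) list(x1 = l$p1[1], y1 = l$p1[2], x2 = l$p2[1],
                                y2 = l$p2[2], band = l$band,
                                direction = l$direction)
  raw <- list()
  if (!is.null(config$scene)) {
    raw$scene <- unclass(config$scene)
    if (!is.null(raw$scene$line)) raw$scene$line <- flat_line(raw$scene$line)
    if (!is.null(raw$scene$crossing_schedule)) {
      raw$scene$crossing_schedule <-
        lapply(as.list(raw$scene$crossing_schedule), as.vector)
    }
  }
  if (!is.null(config$tracker)) raw$tracker <- unclass(config$tracker)
  if (!is.null(config$line)) raw$line <- flat_line(config$line)
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' Write an evaluation report
#'
#' Emits the same metrics twice: a machine-readable JSON file and a flat
#' `key value` text file next to it (same path with extension `.txt`).
#'
#' @param metrics A named list of scalar metrics.
#' @param path Path of the JSON report.
#' @export
write_report <- function(metrics, path) {
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA)
  txt <- sub("\\.json$", ".txt", path)
  if (identical(txt, path)) txt <- paste0(path, ".txt")
  writeLines(paste(names(metrics), vapply(metrics, format, character(1))), txt)
  invisible(path)
}
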