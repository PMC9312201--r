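#' Define a counting line
#'
#' The counting line is a virtual segment in the detection coordinate frame.
#' "Touching" the line is modelled as the target-box centre entering a band
#' of half-width `band` around the segment; a sign flip of the centre's side
#' between consecutive frames also registers a touch, so fast targets that
#' jump the band in one frame are still caught. The two sides of the line
#' are named after the directed segment `p1 -> p2`: the side with positive
#' cross product `(p2 - p1) x (p - p1)` is `"left"`, the other `"right"`
#' (note that with image y pointing down, "left" appears to the right on
#' screen).
#'
#' @param x1,y1,x2,y2 Endpoints in pixels; must differ.
#' @param band Band half-width in pixels, `>= 0`. Default 5.
#' @param direction Which crossings count: `"both"`, `"left_to_right"`
#'   (entered on the left side, detached on the right), or
#'   `"right_to_left"`.
#' @return An object of class `counting_line`.
#' @export
counting_line <- function(x1, y1, x2, y2, band = 5, direction = "both") {
  if (x1 == x2 && y1 == y2) abort("counting_line: endpoints must differ")
  if (band < 0) abort("counting_line: band must be >= 0")
  direction <- match.arg(direction, c("both", "left_to_right", "right_to_left"))
  structure(list(p1 = c(x1, y1), p2 = c(x2, y2), band = band,
                 direction = direction),
            class = "counting_line")
}

#' Which side of the counting line a point is on
#'
#' @param x,y Point coordinates (vectorised).
#' @param line A [counting_line()].
#' @return An integer vector: `+1` (left of `p1 -> p2`), `-1` (right), or
#'   `0` when the point lies on the band (perpendicular distance at most
#'   `band` and its projection within the segment extended by `band`).
#' @export
line_side <- function(x, y, line) {
  d <- line$p2 - line$p1
  len <- sqrt(sum(d^2))
  rx <- x - line$p1[1]; ry <- y - line$p1[2]
  cross <- d[1] * ry - d[2] * rx
  perp <- abs(cross) / len
  tproj <- (d[1] * rx + d[2] * ry) / len     # signed distance along segment
  on_band <- perp <= line$band & tproj >= -line$band & tproj <= len + line$band
  ifelse(on_band, 0L, ifelse(cross > 0, 1L, -1L))
}

new_counter_state <- function() {
  list(A = integer(0),            # ids that have touched the line
       B = integer(0),            # ids that touched and then detached across
       entry_side = integer(0),   # per id in A: side held before touching
       last_side = integer(0),    # per live id: side at the previous frame
       touch_frame = integer(0),  # frame of first touch, per id in A
       cross_frame = integer(0))  # frame added to B, per id in B
}

countable <- function(entry, exit, direction) {
  if (direction == "both") return(TRUE)
  want_entry <- if (direction == "left_to_right") 1L else -1L
  # unknown entry side (id first seen on the band) counts either way
  (entry == 0L || entry == want_entry) && exit == -want_entry
}

# advance the two-set counter by one frame of confirmed track centres
counter_update <- function(state, ids, sides, frame) {
  for (k in seq_along(ids)) {
    id <- ids[k]; s <- sides[k]
    key <- as.character(id)
    prev <- state$last_side[key]
    prev <- if (is.na(prev)) NA_integer_ else prev
    in_A <- id %in% state$A
    touched <- s == 0L || (!is.na(prev) && prev != 0L && s == -prev)
    if (!in_A && touched) {
      state$A <- c(state$A, id)
      entry <- if (!is.na(prev) && prev != 0L) prev else 0L
      state$entry_side[key] <- entry
      state$touch_frame[key] <- frame
      in_A <- TRUE
    }
    if (in_A && !(id %in% state$B) && s != 0L) {
      entry <- state$entry_side[key]
      if (s != entry) {   # detached on the far side (or entry unknown)
        if (countable(entry, s, state$direction %||% "both")) {
          state$B <- c(state$B, id)
          state$cross_frame[key] <- frame
        }
      }
    }
    state$last_side[key] <- s
  }
  state
}

#' Count line crossings in a track table
#'
#' Replays the two-set single-line counter over a track table. Set `A`
#' accumulates every track id whose box centre has touched the line; set
#' `B` accumulates the ids that, being in `A`, were later observed off the
#' band on the side opposite the one they arrived from. The count is `|B|`.
#' Because `B` is a set of ids, a target dithering on the band — touching
#' and retreating to its entry side — is never counted, and a target can be
#' counted at most once.
#'
#' @param tracks A track table `(frame, id, left, top, width, height)` as
#'   returned by [track_detections()].
#' @param line A [counting_line()].
#' @param roi Optional region-of-interest polygon (two-column matrix of
#'   vertices); tracks whose centre falls outside it are ignored. The
#'   polygon only restricts which tracks reach the counter; it carries no
#'   counting semantics.
#' @return An object of class `line_count`: a list with `count` (`|B|`),
#'   `A` and `B` (tibbles of ids with touch/cross frames and entry sides),
#'   and `per_frame` (tibble of the cumulative count after each frame).
#' @examples
#' tr <- tibble::tibble(frame = 1:5, id = 1L,
#'                      left = seq(80, 120, 10), top = 50,
#'                      width = 10, height = 10)
#' count_crossings(tr, counting_line(100, 0, 100, 100, band = 2))$count
#' @export
count_crossings <- function(tracks, line, roi = NULL) {
  state <- new_counter_state()
  state$direction <- line$direction
  frames <- if (nrow(tracks) > 0) seq_len(max(tracks$frame)) else integer(0)
  per_frame <- integer(length(frames))
  cx <- tracks$left + tracks$width / 2
  cy <- tracks$top + tracks$height / 2
  keep <- rep(TRUE, nrow(tracks))
  if (!is.null(roi)) keep <- point_in_polygon(cx, cy, roi)
  sides_all <- line_side(cx, cy, line)
  for (f in frames) {
    rows <- which(tracks$frame == f & keep)
    state <- counter_update(state, tracks$id[rows], sides_all[rows], f)
    per_frame[f] <- length(state$B)
  }
  structure(list(
    count = length(state$B),
    A = tibble::tibble(id = state$A,
                       touch_frame = unname(state$touch_frame[as.character(state$A)]),
                       entry_side = unname(state$entry_side[as.character(state$A)])),
    B = tibble::tibble(id = state$B,
                       cross_frame = unname(state$cross_frame[as.character(state$B)])),
    per_frame = tibble::tibble(frame = frames, count = per_frame),
    line = line),
    class = "line_count")
}

# even-odd ray-casting point-in-polygon test
point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
    hit <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, hit)
    j <- i
  }
  inside
}

#' Cumulative counts per time interval
#'
#' Replays the counter and reports the cumulative count at the end of each
#' consecutive block of `interval_frames` frames (the reporting protocol of
#' interval-based counting experiments, e.g. 15-second blocks of a
#' fixed-rate video).
#'
#' @inheritParams count_crossings
#' @param interval_frames Frames per interval, `>= 1`.
#' @param n_frames Total frames; defaults to the last track frame.
#' @return A tibble `(interval, frame_end, cumulative_count)`.
#' @export
interval_counts <- function(tracks, line, interval_frames, n_frames = NULL,
                            roi = NULL) {
  if (interval_frames < 1) abort("interval_frames must be >= 1")
  lc <- count_crossings(tracks, line, roi)
  if (is.null(n_frames)) n_frames <- max(tracks$frame, 0L)
  if (n_frames < interval_frames) {
    return(tibble::tibble(interval = 1L, frame_end = as.integer(n_frames),
                          cumulative_count = lc$count))
  }
  ends <- seq(interval_frames, n_frames, by = interval_frames)
  if (length(ends) == 0 || ends[length(ends)] < n_frames) {
    ends <- c(ends, n_frames)
  }
  cum <- vapply(ends, function(e) {
    pf <- lc$per_frame
    rows <- pf$frame <= e
    if (any(rows)) max(pf$count[rows]) else 0L
  }, integer(1))
  tibble::tibble(interval = seq_along(ends), frame_end = as.integer(ends),
                 cumulative_count = cum)
}

#' @export
print.line_count <- function(x, ...) {
  cat("<line_count>", x$count, "crossing(s);",
      nrow(x$A), "id(s) touched the line\n")
  invisible(x)
}

#' @export
print.counting_line <- function(x, ...) {
  cat(sprintf("<counting_line> (%g, %g) -> (%g, %g), band %g px, %s\n",
              x$p1[1], x$p1[2], x$p2[1], x$p2[2], x$band, x$direction))
  invisible(x)
}
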