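#' Construct a bounding-box table
#'
#' Boxes live in continuous image coordinates with the origin at the top-left
#' corner, x rightward and y downward, and are stored as
#' `(left, top, width, height)` to match the MOT-Challenge interchange format.
#'
#' @param left,top Coordinates of the top-left corner, in pixels.
#' @param width,height Box extent in pixels; must be strictly positive.
#' @return A tibble with columns `left`, `top`, `width`, `height`.
#' @examples
#' bbox(0, 0, 10, 20)
#' @export
bbox <- function(left, top, width, height) {
  b <- tibble::tibble(left = as.numeric(left), top = as.numeric(top),
                      width = as.numeric(width), height = as.numeric(height))
  check_boxes(b)
  b
}

check_boxes <- function(b, what = "box") {
  need <- c("left", "top", "width", "height")
  missing <- setdiff(need, names(b))
  if (length(missing) > 0) {
    abort(paste0("invalid ", what, " table: missing column(s) ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(b) > 0 && (any(b$width <= 0) || any(b$height <= 0))) {
    abort(paste0("invalid ", what, ": width and height must be positive"))
  }
  invisible(b)
}

#' Intersection over union of paired boxes
#'
#' Computes the overlap rate (IoU) between corresponding rows of two box
#' tables: the area of the intersection divided by the area of the union.
#' Disjoint boxes score 0, identical boxes score 1. Length-1 inputs are
#' recycled against the other table.
#'
#' @param a,b Box tables (columns `left`, `top`, `width`, `height`).
#' @return A numeric vector of IoU values in `[0, 1]`.
#' @examples
#' iou(bbox(0, 0, 10, 10), bbox(5, 0, 10, 10)) # 1/3
#' @export
iou <- function(a, b) {
  check_boxes(a); check_boxes(b)
  if (nrow(a) == 1 && nrow(b) > 1) a <- a[rep(1, nrow(b)), ]
  if (nrow(b) == 1 && nrow(a) > 1) b <- b[rep(1, nrow(a)), ]
  if (nrow(a) != nrow(b)) abort("iou: box tables must have matching lengths")
  ix <- pmax(0, pmin(a$left + a$width, b$left + b$width) - pmax(a$left, b$left))
  iy <- pmax(0, pmin(a$top + a$height, b$top + b$height) - pmax(a$top, b$top))
  inter <- ix * iy
  union <- a$width * a$height + b$width * b$height - inter
  inter / union
}

#' Pairwise IoU matrix
#'
#' @param a,b Box tables with n and m rows.
#' @return An n x m matrix of IoU values.
#' @export
iou_matrix <- function(a, b) {
  check_boxes(a); check_boxes(b)
  n <- nrow(a); m <- nrow(b)
  out <- matrix(0, n, m)
  if (n == 0 || m == 0) return(out)
  ax2 <- a$left + a$width; ay2 <- a$top + a$height
  bx2 <- b$left + b$width; by2 <- b$top + b$height
  for (j in seq_len(m)) {
    ix <- pmax(0, pmin(ax2, bx2[j]) - pmax(a$left, b$left[j]))
    iy <- pmax(0, pmin(ay2, by2[j]) - pmax(a$top, b$top[j]))
    inter <- ix * iy
    out[, j] <- inter / (a$width * a$height + b$width[j] * b$height[j] - inter)
  }
  out
}

#' Convert boxes to measurement coordinates
#'
#' The tracker's observation space is `(u, v, gamma, h)`: box centre x and y,
#' aspect ratio width/height, and height. This is the parameterisation in
#' which the Kalman filter observes detections.
#'
#' @param b A box table.
#' @return A tibble with columns `u`, `v`, `gamma`, `h`.
#' @examples
#' box_to_measurement(bbox(0, 0, 10, 20)) # u = 5, v = 10, gamma = 0.5, h = 20
#' @export
box_to_measurement <- function(b) {
  check_boxes(b)
  quick_tbl(list(u = b$left + b$width / 2, v = b$top + b$height / 2,
                 gamma = b$width / b$height, h = b$height))
}

#' Convert measurement coordinates back to boxes
#'
#' Exact inverse of [box_to_measurement()].
#'
#' @param m A data frame with columns `u`, `v`, `gamma`, `h` (all `gamma`,
#'   `h` strictly positive).
#' @return A box table.
#' @export
measurement_to_box <- function(m) {
  need <- c("u", "v", "gamma", "h")
  if (!all(need %in% names(m))) {
    abort("invalid measurement: need columns u, v, gamma, h")
  }
  if (nrow(m) > 0 && (any(m$gamma <= 0) || any(m$h <= 0))) {
    abort("invalid measurement: gamma and h must be positive")
  }
  w <- m$gamma * m$h
  quick_tbl(list(left = m$u - w / 2, top = m$v - m$h / 2,
                 width = w, height = m$h))
}

#' Drop low-confidence detections
#'
#' Keeps exactly the detections whose confidence is at least `tau`,
#' preserving the original row order.
#'
#' @param dets A detection table with a `conf` column.
#' @param tau Confidence threshold in `[0, 1]`. Default 0.5; the value is a
#'   convention of this toolkit, not a published threshold.
#' @return The filtered detection table.
#' @export
filter_confidence <- function(dets, tau = 0.5) {
  if (!is.numeric(tau) || length(tau) != 1 || tau < 0 || tau > 1) {
    abort("tau must be a single value in [0, 1]")
  }
  dets[dets$conf >= tau, , drop = FALSE]
}

# cheap tibble constructor for hot paths (columns already validated)
quick_tbl <- function(cols) {
  structure(cols, class = c("tbl_df", "tbl", "data.frame"),
            row.names = c(NA_integer_, -length(cols[[1]])))
}

#' Greedy non-maximum suppression
#'
#' Standard detector post-processing: visit boxes in decreasing confidence
#' order, keep the current box, and suppress any remaining box whose IoU with
#' a kept box exceeds `iou_thresh`. Ties on confidence are broken by original
#' row order (earlier row wins) so the result is deterministic.
#'
#' @param dets A detection table (box columns plus `conf`).
#' @param iou_thresh Suppression threshold in `(0, 1]`. Default 0.5.
#' @return The surviving rows of `dets`, in original order.
#' @export
nms <- function(dets, iou_thresh = 0.5) {
  if (!is.numeric(iou_thresh) || length(iou_thresh) != 1 ||
      iou_thresh <= 0 || iou_thresh > 1) {
    abort("iou_thresh must be a single value in (0, 1]")
  }
  check_boxes(dets, "detection")
  n <- nrow(dets)
  if (n <= 1) return(dets)
  l <- dets$left; tp <- dets$top
  r <- l + dets$width; b <- tp + dets$height
  area <- dets$width * dets$height
  ord <- order(-dets$conf, seq_len(n))
  keep <- logical(n)
  alive <- rep(TRUE, n)
  for (i in ord) {
    if (!alive[i]) next
    keep[i] <- TRUE
    inter <- pmax(0, pmin(r, r[i]) - pmax(l, l[i])) *
      pmax(0, pmin(b, b[i]) - pmax(tp, tp[i]))
    ious <- inter / (area + area[i] - inter)
    alive <- alive & !(ious > iou_thresh)
    alive[i] <- FALSE
  }
  dets[keep, , drop = FALSE]
}
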