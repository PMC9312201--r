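#' Appearance cost matrix between track galleries and detection features
#'
#' Each track keeps a bounded gallery of appearance embeddings from its past
#' matches. The cost of pairing track i with detection j is the smallest
#' cosine distance `1 - g . f` over the gallery vectors `g` of track i, so a
#' detection resembling any recent appearance of the track is cheap. All
#' vectors must be unit-norm. A track with an empty gallery gets an all-`Inf`
#' row (no appearance evidence, pair forbidden at this stage).
#'
#' @param galleries A list, one element per track, each a list of unit-norm
#'   numeric vectors (possibly empty).
#' @param feats A numeric matrix of detection features, one row per
#'   detection, or a list of unit-norm vectors.
#' @return A tracks x detections numeric matrix of costs in `[0, 2]`, with
#'   `Inf` for empty-gallery rows.
#' @export
appearance_cost <- function(galleries, feats) {
  if (is.list(feats)) feats <- do.call(rbind, feats)
  n <- length(galleries)
  m <- if (is.null(feats)) 0 else nrow(feats)
  out <- matrix(Inf, n, m)
  if (m == 0) return(out)
  for (i in seq_len(n)) {
    g <- galleries[[i]]
    if (length(g) == 0) next
    G <- do.call(rbind, g)
    # 1 - max cosine similarity over the gallery, clipped at 0 for rounding
    out[i, ] <- pmax(0, 1 - apply(G %*% t(feats), 2, max))
  }
  out
}

#' Apply a Mahalanobis motion gate to a cost matrix
#'
#' Pairs whose squared Mahalanobis distance in measurement space exceeds the
#' gate threshold are marked infeasible (`Inf`); the rest keep their cost.
#' The default threshold is the 0.95 chi-square quantile with 4 degrees of
#' freedom, matching the dimensionality of the `(u, v, gamma, h)` observation.
#'
#' @param costs A numeric cost matrix.
#' @param gating A matrix of squared Mahalanobis distances, same shape.
#' @param threshold Gate value; default `qchisq(0.95, 4)` (about 9.488).
#' @return The gated cost matrix.
#' @export
gate_cost <- function(costs, gating, threshold = qchisq(0.95, df = 4)) {
  if (!all(dim(costs) == dim(gating))) abort("gate_cost: shape mismatch")
  costs[gating > threshold] <- Inf
  costs
}

# Build the gated association cost between a set of tracks and detections.
# With features present: appearance cost gated by motion. Without features
# the tracker still runs in a degraded, motion-only mode: the cost is the
# gated Mahalanobis distance itself and max_cost becomes the gate threshold.
association_cost <- function(tracks, meas, feats, cfg) {
  nt <- length(tracks); nd <- nrow(meas)
  gating <- matrix(Inf, nt, nd)
  for (i in seq_len(nt)) {
    gating[i, ] <- kf_gating_distance(tracks[[i]]$kstate, meas,
                                      cfg$std_weight_pos)
  }
  if (!is.null(feats)) {
    costs <- appearance_cost(lapply(tracks, function(t) t$gallery), feats)
    list(costs = gate_cost(costs, gating, cfg$gate_threshold),
         max_cost = cfg$max_cost)
  } else {
    costs <- gating
    costs[gating > cfg$gate_threshold] <- Inf
    list(costs = costs, max_cost = cfg$gate_threshold)
  }
}

#' Cascade matching over track staleness
#'
#' Associates detections to tracks age group by age group: tracks matched in
#' the most recent frame (smallest frames-since-update `a_k`) are offered
#' the detections first, and only the leftovers reach staler tracks. This
#' priority protects the identities of recently seen targets while still
#' letting a track occluded for up to `A_max` frames reclaim its detection
#' when it reappears. Within each age group a Mahalanobis-gated appearance
#' assignment is solved; without features a motion-only cost is used.
#'
#' @param tracks A list of track objects (each with `kstate`, `gallery`,
#'   `a_k`).
#' @param dets A detection table for the current frame.
#' @param feats Detection feature matrix (rows aligned with `dets`) or
#'   `NULL`.
#' @param cfg A [tracker_config()].
#' @return A list with `matches` (matrix of track index, detection index),
#'   `unmatched_tracks`, `unmatched_dets`.
#' @export
matching_cascade <- function(tracks, dets, feats, cfg) {
  nd <- nrow(dets)
  matches <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("track", "det")))
  if (length(tracks) == 0 || nd == 0) {
    return(list(matches = matches, unmatched_tracks = seq_along(tracks),
                unmatched_dets = seq_len(nd)))
  }
  meas <- as.matrix(box_to_measurement(dets))
  det_left <- seq_len(nd)
  unmatched_tracks <- integer(0)
  ages <- sort(unique(vapply(tracks, function(t) t$a_k, integer(1))))
  for (age in ages[ages <= cfg$A_max]) {
    idx <- which(vapply(tracks, function(t) t$a_k, integer(1)) == age)
    if (length(det_left) == 0) { unmatched_tracks <- c(unmatched_tracks, idx); next }
    cc <- association_cost(tracks[idx], meas[det_left, , drop = FALSE],
                           if (is.null(feats)) NULL
                           else feats[det_left, , drop = FALSE], cfg)
    sol <- solve_assignment(cc$costs, cc$max_cost)
    if (nrow(sol$matches) > 0) {
      matches <- rbind(matches, cbind(idx[sol$matches[, 1]],
                                      det_left[sol$matches[, 2]]))
    }
    unmatched_tracks <- c(unmatched_tracks, idx[sol$unmatched_rows])
    det_left <- det_left[sol$unmatched_cols]
  }
  stale <- which(vapply(tracks, function(t) t$a_k, integer(1)) > cfg$A_max)
  list(matches = matches,
       unmatched_tracks = sort(c(unmatched_tracks, stale)),
       unmatched_dets = det_left)
}

#' IoU fallback matching
#'
#' Second association stage: minimum-cost assignment on `1 - IoU` between
#' predicted track boxes and leftover detections. Pairs with IoU below
#' `iou_floor` are infeasible. This stage catches tracks the appearance
#' cascade missed (and newborn tracks with no gallery yet), using spatial
#' overlap alone.
#'
#' @param track_boxes Predicted box table, one row per candidate track.
#' @param det_boxes Box table of still-unmatched detections.
#' @param iou_floor Minimum IoU for a feasible pair; default 0.3.
#' @return A list with `matches` (track row, detection row),
#'   `unmatched_tracks`, `unmatched_dets` (row indices).
#' @export
iou_match <- function(track_boxes, det_boxes, iou_floor = 0.3) {
  costs <- pmax(1 - iou_matrix(track_boxes, det_boxes), 0)  # clip rounding
  costs[costs > 1 - iou_floor] <- Inf
  sol <- solve_assignment(costs, max_cost = 1 - iou_floor)
  list(matches = `colnames<-`(sol$matches, c("track", "det")),
       unmatched_tracks = sol$unmatched_rows,
       unmatched_dets = sol$unmatched_cols)
}
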