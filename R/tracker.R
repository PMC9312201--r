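#' Tracker configuration
#'
#' Collects every tunable of the tracking pipeline in one validated list.
#'
#' @param A_max Maximum number of consecutive frames a track may go
#'   unmatched before it is deleted (staleness limit). Default 30.
#' @param n_init Number of consecutive matched frames (counting the frame
#'   the track was born on) before a tentative track is confirmed.
#'   Default 3.
#' @param tau Detection confidence threshold, see [filter_confidence()].
#' @param nms_thresh IoU threshold for [nms()].
#' @param gate_threshold Mahalanobis gate, see [gate_cost()].
#' @param max_cost Maximum admissible appearance (cosine) cost for a
#'   cascade match. Default 0.2.
#' @param iou_floor Minimum IoU for the fallback stage, see [iou_match()].
#' @param gallery_size Appearance vectors retained per track (most recent
#'   kept). Default 100.
#' @param std_weight_pos,std_weight_vel Kalman noise weights, see
#'   [kf_initiate()].
#' @return A list of class `tracker_config`.
#' @export
tracker_config <- function(A_max = 30L, n_init = 3L, tau = 0.5,
                           nms_thresh = 0.5,
                           gate_threshold = qchisq(0.95, df = 4),
                           max_cost = 0.2, iou_floor = 0.3,
                           gallery_size = 100L,
                           std_weight_pos = 1 / 20,
                           std_weight_vel = 1 / 160) {
  cfg <- list(A_max = as.integer(A_max), n_init = as.integer(n_init),
              tau = tau, nms_thresh = nms_thresh,
              gate_threshold = gate_threshold, max_cost = max_cost,
              iou_floor = iou_floor, gallery_size = as.integer(gallery_size),
              std_weight_pos = std_weight_pos, std_weight_vel = std_weight_vel)
  stopifnot(cfg$A_max >= 1, cfg$n_init >= 1, cfg$gallery_size >= 1,
            cfg$tau >= 0, cfg$tau <= 1, cfg$max_cost > 0, cfg$iou_floor >= 0)
  structure(cfg, class = "tracker_config")
}

#' Create a tracker
#'
#' Returns a mutable tracker object (an environment) holding the track set
#' and frame counter. Most users call [track_detections()] instead; the
#' stepwise interface exists for online use and for inspecting lifecycle
#' state mid-sequence.
#'
#' @param config A [tracker_config()].
#' @return An object of class `pen_tracker`.
#' @export
new_tracker <- function(config = tracker_config()) {
  trk <- new.env(parent = emptyenv())
  trk$config <- config
  trk$tracks <- list()        # live tracks
  trk$next_id <- 1L
  trk$last_frame <- 0L
  class(trk) <- "pen_tracker"
  trk
}

new_track <- function(id, meas_row, feature, cfg) {
  list(id = id, status = "tentative",
       kstate = kf_initiate(meas_row, cfg$std_weight_pos, cfg$std_weight_vel),
       hits = 1L, a_k = 0L,
       gallery = if (is.null(feature)) list() else list(feature))
}

# predicted (left, top, width, height) of one track, as a plain vector
predicted_box_vec <- function(track) {
  m <- track$kstate$mean
  g <- max(m[3], 1e-6); h <- max(m[4], 1e-6)
  w <- g * h
  c(m[1] - w / 2, m[2] - h / 2, w, h)
}

track_predicted_box <- function(track) {
  b <- predicted_box_vec(track)
  quick_tbl(list(left = b[1], top = b[2], width = b[3], height = b[4]))
}

boxes_tbl <- function(tracks) {
  B <- vapply(tracks, predicted_box_vec, numeric(4))
  quick_tbl(list(left = B[1, ], top = B[2, ], width = B[3, ], height = B[4, ]))
}

#' Advance the tracker by one frame
#'
#' Runs the full per-frame pipeline: (1) Kalman-predict every live track,
#' (2) preprocess the detections (confidence filter then NMS), (3) attach
#' appearance features, (4) associate — cascade matching over the confirmed
#' tracks, then IoU matching over tentative and just-missed tracks,
#' (5) update matched tracks (resetting their staleness counter to zero),
#' age and prune unmatched ones, spawn tentative tracks from unmatched
#' detections and confirm tentative tracks after `n_init` consecutive
#' matched frames, (6) emit the confirmed, currently matched tracks.
#'
#' A tentative track that misses a single frame before confirmation is
#' discarded; a confirmed track survives up to `A_max` consecutive misses.
#'
#' @param trk A [new_tracker()] object (modified in place).
#' @param dets Detection table for one frame: columns `left`, `top`,
#'   `width`, `height`, `conf`, optionally a `feature` list-column of
#'   unit-norm vectors. All rows must share the frame index, one greater
#'   than the previous call's.
#' @param frame The frame index (1-based). Defaults to the `frame` column
#'   of `dets`, or the next frame when `dets` is empty.
#' @return A tibble `(frame, id, left, top, width, height)` of confirmed,
#'   currently matched tracks.
#' @export
tracker_step <- function(trk, dets, frame = NULL) {
  cfg <- trk$config
  if (is.null(frame)) {
    frame <- if (!is.null(dets$frame) && nrow(dets) > 0) unique(dets$frame)
             else trk$last_frame + 1L
  }
  if (length(frame) != 1) abort("tracker_step: detections span several frames")
  frame <- as.integer(frame)
  if (frame != trk$last_frame + 1L) {
    abort(sprintf("tracker_step: expected frame %d, got %d",
                  trk$last_frame + 1L, frame))
  }
  trk$last_frame <- frame

  # (1) predict + age
  trk$tracks <- lapply(trk$tracks, function(t) {
    t$kstate <- kf_predict(t$kstate, cfg$std_weight_pos, cfg$std_weight_vel)
    t$a_k <- t$a_k + 1L
    t
  })

  # (2) preprocess
  if (nrow(dets) > 0) {
    dets <- filter_confidence(dets, cfg$tau)
    dets <- nms(dets, cfg$nms_thresh)
  }
  nd <- nrow(dets)

  # (3) features; detections missing a feature get a zero vector (never
  # matched by appearance, still reachable through the IoU stage)
  feats <- NULL
  if (nd > 0 && "feature" %in% names(dets)) {
    have <- !vapply(dets$feature, is.null, logical(1))
    if (any(have)) {
      d <- length(dets$feature[[which(have)[1]]])
      feats <- matrix(0, nd, d)
      feats[have, ] <- do.call(rbind, dets$feature[have])
    }
  }
  statuses <- vapply(trk$tracks, function(t) t$status, character(1))
  confirmed <- which(statuses == "confirmed")
  tentative <- which(statuses == "tentative")

  # (4a) cascade over confirmed tracks
  casc <- matching_cascade(trk$tracks[confirmed], dets, feats, cfg)
  matches <- cbind(confirmed[casc$matches[, 1]], casc$matches[, 2])

  # (4b) IoU fallback: tentative tracks plus confirmed tracks that missed
  # the cascade but were matched only one frame ago
  casc_un <- confirmed[casc$unmatched_tracks]
  iou_cand <- c(tentative,
                casc_un[vapply(trk$tracks[casc_un], function(t) t$a_k,
                               integer(1)) == 1L])
  det_left <- setdiff(seq_len(nd), matches[, 2])
  if (length(iou_cand) > 0 && length(det_left) > 0) {
    tb <- boxes_tbl(trk$tracks[iou_cand])
    im <- iou_match(tb, dets[det_left, , drop = FALSE], cfg$iou_floor)
    if (nrow(im$matches) > 0) {
      matches <- rbind(matches, cbind(iou_cand[im$matches[, 1]],
                                      det_left[im$matches[, 2]]))
    }
  }

  # (5) update matched, prune unmatched, spawn new
  matched_tracks <- matches[, 1]
  meas <- if (nd > 0) as.matrix(box_to_measurement(dets)) else NULL
  for (k in seq_len(nrow(matches))) {
    i <- matches[k, 1]; j <- matches[k, 2]
    t <- trk$tracks[[i]]
    t$kstate <- kf_update(t$kstate, meas[j, ], cfg$std_weight_pos)
    t$hits <- t$hits + 1L
    t$a_k <- 0L
    if (!is.null(feats)) {
      t$gallery <- c(t$gallery, list(feats[j, ]))
      if (length(t$gallery) > cfg$gallery_size) {
        t$gallery <- tail(t$gallery, cfg$gallery_size)
      }
    }
    if (t$status == "tentative" && t$hits >= cfg$n_init) t$status <- "confirmed"
    trk$tracks[[i]] <- t
  }
  deleted <- vapply(seq_along(trk$tracks), function(i) {
    t <- trk$tracks[[i]]
    if (i %in% matched_tracks) return(FALSE)
    t$status == "tentative" || t$a_k > cfg$A_max
  }, logical(1))
  trk$tracks <- trk$tracks[!deleted]

  for (j in setdiff(seq_len(nd), matches[, 2])) {
    f <- if (!is.null(feats)) feats[j, ] else NULL
    trk$tracks <- c(trk$tracks,
                    list(new_track(trk$next_id, meas[j, ], f, cfg)))
    trk$next_id <- trk$next_id + 1L
  }

  # (6) emit confirmed, currently matched tracks
  emit <- which(vapply(trk$tracks, function(t) {
    t$status == "confirmed" && t$a_k == 0L
  }, logical(1)))
  if (length(emit) == 0) {
    return(quick_tbl(list(frame = integer(), id = integer(), left = numeric(),
                          top = numeric(), width = numeric(),
                          height = numeric())))
  }
  ids <- vapply(trk$tracks[emit], function(t) t$id, integer(1))
  ord <- order(ids)
  B <- vapply(trk$tracks[emit], predicted_box_vec, numeric(4))[, ord, drop = FALSE]
  quick_tbl(list(frame = rep(frame, length(emit)), id = ids[ord],
                 left = B[1, ], top = B[2, ], width = B[3, ], height = B[4, ]))
}

#' Track a detection table
#'
#' Batch driver over [tracker_step()]: feeds the detections frame by frame
#' (missing frame indices are processed as empty frames) and concatenates
#' the per-frame confirmed-track output. Deterministic given the inputs and
#' configuration.
#'
#' @param dets A detection table with columns `frame`, `left`, `top`,
#'   `width`, `height`, `conf`, optionally a `feature` list-column (or use
#'   `features` below).
#' @param features Optional feature sidecar table as produced by
#'   [simulate_scene()] or [read_features()]: columns `frame`, `det`
#'   (1-based detection index within the frame) and `f1 ... fD`. Attached
#'   to `dets` by `(frame, row-within-frame)`.
#' @param config A [tracker_config()].
#' @param n_frames Number of frames to process; defaults to `max(dets$frame)`.
#' @return A track tibble `(frame, id, left, top, width, height)`.
#' @examples
#' scene <- simulate_scene(scene_config(n_targets = 3, frames = 30, seed = 7))
#' tracks <- track_detections(scene$detections, scene$features)
#' dplyr::n_distinct(tracks$id)
#' @export
track_detections <- function(dets, features = NULL, config = tracker_config(),
                             n_frames = NULL) {
  if (nrow(dets) > 0 && !is.null(features) && nrow(features) > 0) {
    dets <- attach_features(dets, features)
  }
  if (is.null(n_frames)) {
    n_frames <- if (nrow(dets) > 0) max(dets$frame) else 0L
  }
  trk <- new_tracker(config)
  by_frame <- split(seq_len(nrow(dets)), factor(dets$frame, seq_len(n_frames)))
  out <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    frame_dets <- dets[by_frame[[f]], , drop = FALSE]
    out[[f]] <- tracker_step(trk, frame_dets, frame = f)
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(frame = integer(), id = integer(), left = numeric(),
                          top = numeric(), width = numeric(), height = numeric())
  }
  res
}

# join a (frame, det, f1..fD) sidecar onto the detection rows as a
# `feature` list-column; rows without a sidecar entry get NULL
attach_features <- function(dets, features) {
  fcols <- grep("^f[0-9]+$", names(features), value = TRUE)
  dets <- dplyr::group_by(dets, .data$frame)
  dets <- dplyr::mutate(dets, .det = dplyr::row_number())
  dets <- dplyr::ungroup(dets)
  key <- paste(features$frame, features$det)
  idx <- match(paste(dets$frame, dets$.det), key)
  fm <- as.matrix(features[, fcols, drop = FALSE])
  dets$feature <- lapply(seq_len(nrow(dets)), function(i) {
    if (is.na(idx[i])) NULL else unname(fm[idx[i], ])
  })
  dets$.det <- NULL
  dets
}

#' @export
print.pen_tracker <- function(x, ...) {
  st <- table(factor(vapply(x$tracks, function(t) t$status, character(1)),
                     levels = c("tentative", "confirmed")))
  cat("<pen_tracker> frame", x$last_frame, "|",
      st[["confirmed"]], "confirmed,", st[["tentative"]], "tentative tracks\n")
  invisible(x)
}
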