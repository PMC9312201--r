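#' Configure a synthetic pen scene
#'
#' The simulator emulates a fixed camera looking into an animal pen: 10-30
#' targets (head boxes) wander with noisy constant-velocity motion, an
#' external detector reports their boxes with centre/size jitter, misses
#' targets at a base rate (and much more often when another box occludes
#' them), and hallucinates occasional false positives; each identity emits
#' a fixed appearance embedding observed with noise. Defaults describe a
#' typical pen recording: 20 targets in a 1280 x 720 px view, ~60 px head
#' boxes moving ~3 px/frame, 1 px detector jitter, 5% base miss rate rising
#' to 50% under occlusion, and 0.5 false positives per frame.
#'
#' @param n_targets Number of targets (1-50). Default 20.
#' @param arena_w,arena_h Scene extent in pixels. Default 1280 x 720.
#' @param frames Number of frames. Default 150.
#' @param speed_mean,speed_std Per-target speed draw, pixels/frame.
#' @param turn_std Per-frame heading perturbation, radians.
#' @param box_size_mean,box_size_std Per-target box edge draw, pixels.
#' @param jitter_sigma Detection centre jitter, pixels (size jitter uses
#'   half this value).
#' @param p_miss_base,p_miss_occluded Miss probability for visible /
#'   occluded targets.
#' @param occlusion_iou Ground-truth IoU above which the farther (higher
#'   bottom edge) box counts as occluded.
#' @param fp_rate Expected false positives per frame (Poisson).
#' @param feature_dim,feature_noise Appearance embedding dimension and
#'   observation noise scale; `feature_dim = 0` disables features.
#' @param crossing_schedule Optional tibble/data frame `(id, frame)` of
#'   scripted line crossings; requires `line`. Scheduled targets follow
#'   straight paths crossing `line` at their scheduled frame; the remaining
#'   targets hold still on the near side.
#' @param line A [counting_line()], required with `crossing_schedule`.
#' @param seed Integer seed; every stream the simulator uses derives from
#'   it.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(n_targets = 20L, arena_w = 1280, arena_h = 720,
                         frames = 150L, speed_mean = 3, speed_std = 1,
                         turn_std = 0.15, box_size_mean = 60,
                         box_size_std = 10, jitter_sigma = 1,
                         p_miss_base = 0.05, p_miss_occluded = 0.5,
                         occlusion_iou = 0.3, fp_rate = 0.5,
                         feature_dim = 32L, feature_noise = 0.1,
                         crossing_schedule = NULL, line = NULL, seed = 1L) {
  cfg <- as.list(environment())
  if (!is.null(line) && !inherits(line, "counting_line")) {
    # accept the flat serialised form (x1, y1, x2, y2, band, direction)
    cfg$line <- counting_line(line$x1, line$y1, line$x2, line$y2,
                              band = line$band %||% 5,
                              direction = line$direction %||% "both")
  }
  probs <- c(p_miss_base, p_miss_occluded)
  if (any(probs < 0 | probs > 1)) abort("miss probabilities must be in [0, 1]")
  if (n_targets < 1 || n_targets > 50) abort("n_targets must be in 1..50")
  if (box_size_mean + 4 * box_size_std >= min(arena_w, arena_h)) {
    abort("infeasible scene: boxes larger than the arena")
  }
  if (!is.null(crossing_schedule)) {
    cfg$crossing_schedule <- crossing_schedule <-
      tibble::as_tibble(crossing_schedule)
    if (is.null(line)) abort("crossing_schedule requires a counting line")
    if (anyDuplicated(crossing_schedule$id)) {
      abort("crossing_schedule: one scheduled crossing per id")
    }
    if (any(crossing_schedule$id > n_targets) ||
        any(crossing_schedule$frame < 2) ||
        any(crossing_schedule$frame > frames)) {
      abort("crossing_schedule: ids must exist and frames lie in 2..frames")
    }
  }
  structure(cfg, class = "scene_config")
}

# independent substreams (motion / dropout / false positives / features)
# derived from the scene seed, so toggling one corruption leaves the
# others' draws untouched
scene_streams <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 4)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  setNames(as.list(s), c("motion", "dropout", "fp", "features"))
}

#' Simulate a pen scene
#'
#' Generates ground-truth trajectories and degraded detections from a
#' [scene_config()]. Ground-truth boxes never leave the arena and every
#' target is present in every frame. Fully reproducible from the seed.
#'
#' @param cfg A [scene_config()].
#' @return A list of class `pen_scene` with `gt` (tibble `frame, id, left,
#'   top, width, height`), `detections` (tibble `frame, left, top, width,
#'   height, conf`), `features` (tibble `frame, det, f1...fD`, or `NULL`),
#'   and `config`.
#' @examples
#' scene <- simulate_scene(scene_config(n_targets = 5, frames = 40, seed = 2))
#' head(scene$detections)
#' @export
simulate_scene <- function(cfg) {
  if (!inherits(cfg, "scene_config")) abort("cfg must be a scene_config")
  streams <- scene_streams(cfg$seed)
  gt <- simulate_gt(cfg, streams$motion)
  corrupt_scene(gt, cfg, streams)
}

simulate_gt <- function(cfg, motion_seed) {
  set.seed(motion_seed)
  n <- cfg$n_targets
  w <- pmax(8, rnorm(n, cfg$box_size_mean, cfg$box_size_std))
  h <- pmax(8, rnorm(n, cfg$box_size_mean, cfg$box_size_std))
  scheduled <- integer(0)
  if (!is.null(cfg$crossing_schedule)) scheduled <- cfg$crossing_schedule$id

  cx <- matrix(NA_real_, cfg$frames, n)
  cy <- matrix(NA_real_, cfg$frames, n)

  free <- setdiff(seq_len(n), scheduled)
  if (length(free) > 0) {
    x <- runif(length(free), w[free] / 2, cfg$arena_w - w[free] / 2)
    y <- runif(length(free), h[free] / 2, cfg$arena_h - h[free] / 2)
    if (!is.null(cfg$crossing_schedule)) {
      # scripted scene: unscheduled targets hold still well away from the
      # line on its right-hand side
      anchor <- stationary_positions(length(free), cfg)
      x <- anchor[, 1]; y <- anchor[, 2]
      for (f in seq_len(cfg$frames)) { cx[f, free] <- x; cy[f, free] <- y }
    } else {
      speed <- pmax(0.2, rnorm(length(free), cfg$speed_mean, cfg$speed_std))
      heading <- runif(length(free), 0, 2 * pi)
      for (f in seq_len(cfg$frames)) {
        cx[f, free] <- x; cy[f, free] <- y
        heading <- heading + rnorm(length(free), 0, cfg$turn_std)
        x <- x + speed * cos(heading)
        y <- y + speed * sin(heading)
        # reflect at the walls so boxes stay inside the arena
        for (k in seq_along(free)) {
          i <- free[k]
          lo <- w[i] / 2; hi <- cfg$arena_w - w[i] / 2
          if (x[k] < lo) { x[k] <- 2 * lo - x[k]; heading[k] <- pi - heading[k] }
          if (x[k] > hi) { x[k] <- 2 * hi - x[k]; heading[k] <- pi - heading[k] }
          lo <- h[i] / 2; hi <- cfg$arena_h - h[i] / 2
          if (y[k] < lo) { y[k] <- 2 * lo - y[k]; heading[k] <- -heading[k] }
          if (y[k] > hi) { y[k] <- 2 * hi - y[k]; heading[k] <- -heading[k] }
        }
      }
    }
  }

  if (length(scheduled) > 0) {
    paths <- crossing_paths(cfg)
    for (k in seq_along(scheduled)) {
      cx[, scheduled[k]] <- paths$x[, k]
      cy[, scheduled[k]] <- paths$y[, k]
    }
  }

  tidyr::crossing(frame = seq_len(cfg$frames), id = seq_len(n)) |>
    dplyr::mutate(left = cx[cbind(.data$frame, .data$id)] - w[.data$id] / 2,
                  top = cy[cbind(.data$frame, .data$id)] - h[.data$id] / 2,
                  width = w[.data$id], height = h[.data$id])
}

# unit tangent / normal frame of the counting line
line_frame <- function(line) {
  d <- line$p2 - line$p1
  len <- sqrt(sum(d^2))
  tangent <- d / len
  list(tangent = tangent, normal = c(-tangent[2], tangent[1]), len = len)
}

# straight constant-velocity paths that put each scheduled target's centre
# exactly on the line at its scheduled frame, approaching from the right
# (negative-cross) side; targets hold still before the approach and after
# the exit so the whole path stays near the line
crossing_paths <- function(cfg, approach = 18L) {
  lf <- line_frame(cfg$line)
  sched <- cfg$crossing_schedule
  k <- nrow(sched)
  offsets <- lf$len * (seq_len(k)) / (k + 1)     # spread along the segment
  speed <- max(cfg$speed_mean, 1)
  x <- matrix(NA_real_, cfg$frames, k)
  y <- matrix(NA_real_, cfg$frames, k)
  for (j in seq_len(k)) {
    q <- cfg$line$p1 + offsets[j] * lf$tangent
    prog <- pmin(pmax(seq_len(cfg$frames) - sched$frame[j], -approach), approach)
    x[, j] <- q[1] - lf$normal[1] * speed * (-prog)
    y[, j] <- q[2] - lf$normal[2] * speed * (-prog)
  }
  list(x = x, y = y)
}

stationary_positions <- function(n, cfg, approach = 18L) {
  lf <- line_frame(cfg$line)
  speed <- max(cfg$speed_mean, 1)
  clearance <- speed * approach + 2 * cfg$box_size_mean
  offsets <- lf$len * (seq_len(n)) / (n + 1)
  base <- t(vapply(offsets, function(o) cfg$line$p1 + o * lf$tangent,
                   numeric(2)))
  cbind(base[, 1] - lf$normal[1] * clearance,
        base[, 2] - lf$normal[2] * clearance)
}

# detector emulation: jitter, occlusion-aware dropout, false positives,
# appearance embeddings
corrupt_scene <- function(gt, cfg, streams) {
  set.seed(streams$dropout)
  gt_list <- split(gt, gt$frame)
  kept <- vector("list", cfg$frames)
  for (f in seq_len(cfg$frames)) {
    g <- gt_list[[as.character(f)]]
    occluded <- rep(FALSE, nrow(g))
    if (nrow(g) > 1) {
      M <- iou_matrix(g, g)
      diag(M) <- 0
      bottom <- g$top + g$height
      for (i in seq_len(nrow(g))) {
        over <- which(M[i, ] > cfg$occlusion_iou)
        # the farther box (bottom edge higher in the oblique view) drops
        if (any(bottom[over] > bottom[i])) occluded[i] <- TRUE
      }
    }
    p <- ifelse(occluded, cfg$p_miss_occluded, cfg$p_miss_base)
    kept[[f]] <- g[runif(nrow(g)) >= p, , drop = FALSE]
  }
  det <- dplyr::bind_rows(kept)
  jit <- cfg$jitter_sigma
  det$left <- det$left + rnorm(nrow(det), 0, jit)
  det$top <- det$top + rnorm(nrow(det), 0, jit)
  det$width <- pmax(4, det$width + rnorm(nrow(det), 0, jit / 2))
  det$height <- pmax(4, det$height + rnorm(nrow(det), 0, jit / 2))
  det$conf <- runif(nrow(det), 0.7, 1)

  set.seed(streams$fp)
  n_fp <- rpois(cfg$frames, cfg$fp_rate)
  fp <- NULL
  if (sum(n_fp) > 0) {
    fw <- pmax(8, rnorm(sum(n_fp), cfg$box_size_mean, cfg$box_size_std))
    fh <- pmax(8, rnorm(sum(n_fp), cfg$box_size_mean, cfg$box_size_std))
    fp <- tibble::tibble(
      frame = rep(seq_len(cfg$frames), n_fp), id = NA_integer_,
      left = runif(sum(n_fp), 0, cfg$arena_w - fw),
      top = runif(sum(n_fp), 0, cfg$arena_h - fh),
      width = fw, height = fh, conf = runif(sum(n_fp), 0.5, 0.9))
  }
  det <- dplyr::arrange(dplyr::bind_rows(det, fp), .data$frame)

  features <- NULL
  if (cfg$feature_dim > 0) {
    set.seed(streams$features)
    proto <- matrix(rnorm(cfg$n_targets * cfg$feature_dim),
                    cfg$n_targets, cfg$feature_dim)
    proto <- proto / sqrt(rowSums(proto^2))
    raw <- matrix(rnorm(nrow(det) * cfg$feature_dim, 0, 1),
                  nrow(det), cfg$feature_dim)
    obs <- matrix(NA_real_, nrow(det), cfg$feature_dim)
    true_rows <- !is.na(det$id)
    obs[true_rows, ] <- proto[det$id[true_rows], , drop = FALSE] +
      cfg$feature_noise * raw[true_rows, , drop = FALSE]
    obs[!true_rows, ] <- raw[!true_rows, , drop = FALSE]   # random appearance
    obs <- obs / sqrt(rowSums(obs^2))
    colnames(obs) <- paste0("f", seq_len(cfg$feature_dim))
    features <- det |>
      dplyr::group_by(.data$frame) |>
      dplyr::mutate(det = dplyr::row_number()) |>
      dplyr::ungroup() |>
      dplyr::select("frame", "det") |>
      dplyr::bind_cols(tibble::as_tibble(obs))
  }

  structure(list(gt = gt, detections = dplyr::select(det, -"id"),
                 features = features, config = cfg),
            class = "pen_scene")
}

#' Scripted crossing scene
#'
#' Convenience wrapper around [simulate_scene()]: builds a scene in which
#' exactly `k` targets cross the counting line, one per scheduled frame
#' (evenly spread through the sequence), while the remaining targets hold
#' still on the near side. The ground-truth crossing count is therefore `k`
#' by construction, which makes these scenes the oracle for end-to-end
#' counting checks.
#'
#' @param k Number of crossings, `0 <= k <= n_targets`.
#' @param line A [counting_line()].
#' @param n_targets Total targets; default `k + 3` (at least 4).
#' @param frames Sequence length. Default 100.
#' @param ... Passed to [scene_config()] (noise levels, seed, ...).
#' @return A `pen_scene` (see [simulate_scene()]).
#' @export
scripted_crossing_scene <- function(k, line, n_targets = max(k + 3L, 4L),
                                    frames = 100L, ...) {
  if (k > n_targets) abort("k must not exceed n_targets")
  first <- 25L; last <- frames - 15L
  if (last < first) abort("frames too short for a crossing schedule")
  # an empty schedule still marks the scene as scripted, pinning every
  # unscheduled target to the near side of the line
  schedule <- tibble::tibble(
    id = seq_len(k),
    frame = if (k > 0) as.integer(round(seq(first, last, length.out = k)))
            else integer(0))
  defaults <- list(n_targets = as.integer(n_targets), frames = as.integer(frames),
                   arena_w = 1280, arena_h = 720, speed_mean = 3,
                   box_size_mean = 24, box_size_std = 2,
                   jitter_sigma = 0, p_miss_base = 0, p_miss_occluded = 0,
                   fp_rate = 0, feature_dim = 32L,
                   crossing_schedule = schedule, line = line)
  user <- list(...)
  cfg <- do.call(scene_config, utils::modifyList(defaults, user))
  simulate_scene(cfg)
}

#' Two-target occlusion scene
#'
#' A deliberately ambiguous fixture for studying identity preservation
#' through occlusion. Two targets approach head-on; both vanish from the
#' detections for `occl_len` frames around their meeting point and swap
#' vertical lanes while hidden. On reappearance each target is closer (in
#' Mahalanobis terms) to the other track's constant-velocity prediction
#' than to its own, while both pairings pass the motion gate - so a
#' motion-only tracker tends to swap identities, whereas appearance
#' features resolve the ambiguity.
#'
#' @param seed Scene seed (controls detection jitter and feature noise).
#' @param frames Sequence length. Default 70.
#' @param occl_start First occluded frame. Default 36.
#' @param occl_len Occlusion duration in frames. Default 10.
#' @param feature_dim Embedding dimension (0 disables features). Default 32.
#' @param jitter_sigma Detection jitter. Default 0.5.
#' @return A `pen_scene` whose `gt` has ids 1 (left-entering) and 2.
#' @export
occlusion_scene <- function(seed = 1L, frames = 70L, occl_start = 36L,
                            occl_len = 10L, feature_dim = 32L,
                            jitter_sigma = 0.5) {
  t <- seq_len(frames)
  occl <- seq(occl_start, occl_start + occl_len - 1L)
  swap <- pmin(pmax((t - occl_start + 1) / occl_len, 0), 1) * 20
  gt <- dplyr::bind_rows(
    tibble::tibble(frame = t, id = 1L, cx = 170 + 0.8 * t, cy = 140 + swap),
    tibble::tibble(frame = t, id = 2L, cx = 230 - 0.8 * t, cy = 160 - swap))
  gt <- dplyr::mutate(gt, left = .data$cx - 20, top = .data$cy - 20,
                      width = 40, height = 40)
  gt <- dplyr::select(gt, "frame", "id", "left", "top", "width", "height")
  cfg <- scene_config(n_targets = 2L, arena_w = 400, arena_h = 300,
                      frames = as.integer(frames), jitter_sigma = jitter_sigma,
                      p_miss_base = 0, p_miss_occluded = 0, fp_rate = 0,
                      box_size_mean = 40, box_size_std = 0,
                      feature_dim = as.integer(feature_dim), seed = seed)
  scene <- corrupt_scene(gt, cfg, scene_streams(cfg$seed))
  # hide both targets during the occlusion window; feature rows are
  # row-aligned with detection rows, so filter both and renumber
  occ_rows <- scene$detections$frame %in% occl
  scene$detections <- scene$detections[!occ_rows, , drop = FALSE]
  if (!is.null(scene$features)) {
    scene$features <- scene$features[!occ_rows, , drop = FALSE] |>
      dplyr::group_by(.data$frame) |>
      dplyr::mutate(det = dplyr::row_number()) |>
      dplyr::ungroup()
  }
  scene
}

#' @export
print.pen_scene <- function(x, ...) {
  cat(sprintf("<pen_scene> %d targets, %d frames, %d detections%s\n",
              x$config$n_targets, x$config$frames, nrow(x$detections),
              if (is.null(x$features)) "" else ", with features"))
  invisible(x)
}
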