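test_that("the clean limit reproduces ground truth exactly", {
  cfg <- scene_config(n_targets = 6, frames = 30, jitter_sigma = 0,
                      p_miss_base = 0, p_miss_occluded = 0, fp_rate = 0,
                      seed = 5)
  scene <- simulate_scene(cfg)
  expect_equal(nrow(scene$detections), nrow(scene$gt))
  expect_equal(scene$detections[, c("frame", "left", "top", "width", "height")],
               scene$gt[, c("frame", "left", "top", "width", "height")],
               ignore_attr = TRUE)
})

test_that("simulation is reproducible from the seed", {
  cfg <- scene_config(n_targets = 8, frames = 25, seed = 17)
  s1 <- simulate_scene(cfg)
  s2 <- simulate_scene(cfg)
  expect_identical(s1$gt, s2$gt)
  expect_identical(s1$detections, s2$detections)
  expect_identical(s1$features, s2$features)
  s3 <- simulate_scene(scene_config(n_targets = 8, frames = 25, seed = 18))
  expect_false(identical(s1$detections, s3$detections))
})

test_that("toggling false positives leaves the other streams untouched", {
  base <- scene_config(n_targets = 6, frames = 20, fp_rate = 0, seed = 33)
  with_fp <- scene_config(n_targets = 6, frames = 20, fp_rate = 3, seed = 33)
  s1 <- simulate_scene(base); s2 <- simulate_scene(with_fp)
  expect_identical(s1$gt, s2$gt)
  # true detections are a subset of the fp-augmented detections
  key <- function(d) paste(d$frame, round(d$left, 6), round(d$top, 6))
  expect_true(all(key(s1$detections) %in% key(s2$detections)))
})

test_that("ground truth stays inside the arena with constant target count", {
  cfg <- scene_config(n_targets = 12, frames = 80, seed = 7)
  gt <- simulate_scene(cfg)$gt
  expect_true(all(gt$left >= 0 & gt$top >= 0))
  expect_true(all(gt$left + gt$width <= cfg$arena_w + 1e-9))
  expect_true(all(gt$top + gt$height <= cfg$arena_h + 1e-9))
  expect_true(all(table(gt$frame) == 12))
})

test_that("the empirical miss rate matches p_miss_base", {
  p <- 0.1
  cfg <- scene_config(n_targets = 15, frames = 700, speed_mean = 0.5,
                      box_size_mean = 20, box_size_std = 2,
                      p_miss_base = p, p_miss_occluded = p, fp_rate = 0,
                      feature_dim = 0, seed = 19)
  scene <- simulate_scene(cfg)
  n_tf <- 15 * 700
  miss_rate <- 1 - nrow(scene$detections) / n_tf
  se <- sqrt(p * (1 - p) / n_tf)
  expect_lt(abs(miss_rate - p), 3 * se)
})

test_that("per-frame detection count never exceeds targets plus FPs", {
  cfg <- scene_config(n_targets = 10, frames = 40, fp_rate = 2, seed = 3)
  scene <- simulate_scene(cfg)
  per_frame <- table(factor(scene$detections$frame, 1:40))
  expect_true(all(per_frame <= 10 + 20))  # Poisson(2) tail far below 20
})

test_that("appearance features are unit norm and identity-correlated", {
  cfg <- scene_config(n_targets = 5, frames = 20, p_miss_base = 0,
                      fp_rate = 0, feature_dim = 16, feature_noise = 0.1,
                      seed = 8)
  scene <- simulate_scene(cfg)
  fm <- as.matrix(scene$features[, paste0("f", 1:16)])
  expect_equal(sqrt(rowSums(fm^2)), rep(1, nrow(fm)), tolerance = 1e-6)
  # detections are id-ordered within frames in the clean limit
  ids <- rep(1:5, 20)
  same <- c(); diff_ <- c()
  for (i in seq(1, 50)) for (j in seq(51, 100)) {
    sim <- sum(fm[i, ] * fm[j, ])
    if (ids[i] == ids[j]) same <- c(same, sim) else diff_ <- c(diff_, sim)
  }
  expect_gt(mean(same), 0.85)
  expect_lt(mean(diff_), 0.4)
  expect_gt(mean(same), mean(diff_) + 0.4)
})

test_that("scripted scenes cross exactly k times, on schedule", {
  line <- counting_line(640, 100, 640, 620, band = 6)
  s0 <- scripted_crossing_scene(0, line, seed = 2)
  gt_sides <- function(scene) {
    cx <- scene$gt$left + scene$gt$width / 2
    cy <- scene$gt$top + scene$gt$height / 2
    tibble::tibble(id = scene$gt$id, frame = scene$gt$frame,
                   side = line_side(cx, cy, line))
  }
  crossers <- function(scene) {
    gt_sides(scene) |> dplyr::group_by(id) |>
      dplyr::summarise(crossed = any(side > 0) && any(side < 0)) |>
      dplyr::filter(crossed) |> dplyr::pull(id)
  }
  expect_equal(length(crossers(s0)), 0)
  s7 <- scripted_crossing_scene(7, line, seed = 2)
  expect_equal(sort(crossers(s7)), 1:7)
  # the centre is on the line band at the scheduled frame
  sched <- s7$config$crossing_schedule
  sides <- gt_sides(s7)
  for (r in seq_len(nrow(sched))) {
    at <- sides$side[sides$id == sched$id[r] & sides$frame == sched$frame[r]]
    expect_equal(at, 0L)
  }
  expect_error(scripted_crossing_scene(9, line, n_targets = 5), "exceed")
})

test_that("infeasible configurations are rejected", {
  expect_error(scene_config(arena_w = 50, arena_h = 50, box_size_mean = 60),
               "infeasible")
  expect_error(scene_config(p_miss_base = 1.2), "probabilities")
  expect_error(scene_config(crossing_schedule = data.frame(id = c(1, 1),
                                                           frame = c(5, 9)),
                            line = counting_line(0, 0, 0, 10)),
               "one scheduled crossing")
})

test_that("the occlusion fixture hides both targets for the stated window", {
  sc <- occlusion_scene(seed = 4, occl_start = 36, occl_len = 10)
  expect_equal(sum(sc$detections$frame %in% 36:45), 0)
  expect_equal(sum(sc$detections$frame == 35), 2)
  expect_equal(sum(sc$detections$frame == 46), 2)
  # features stay aligned with detections after the cut
  expect_equal(nrow(sc$features), nrow(sc$detections))
  expect_equal(sc$features$frame, sc$detections$frame)
})
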