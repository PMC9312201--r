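boxes_at <- function(xs, frame = 1L, size = 10) {
  tibble::tibble(frame = frame, left = xs, top = 0, width = size, height = size)
}

test_that("frame matching counts TP/FP/FN correctly", {
  gt <- boxes_at(c(0, 50, 100))
  self <- match_frame(gt, gt)
  expect_equal(self$counts, c(TP = 3, FP = 0, FN = 0))
  none <- match_frame(gt[0, ], gt)
  expect_equal(none$counts, c(TP = 0, FP = 0, FN = 3))
  # crossed overlaps: greedy-by-IoU equals exhaustive best pairing here
  pred <- boxes_at(c(1, 52))
  gt2 <- boxes_at(c(0, 50))
  mf <- match_frame(pred, gt2)
  expect_equal(mf$counts[["TP"]], 2)
  expect_equal(mf$pairs$pred, c(1, 2))
  expect_equal(mf$pairs$gt, c(1, 2))
})

test_that("precision and recall follow their closed forms", {
  expect_equal(precision(c(TP = 7, FP = 3, FN = 0)), 0.7)
  expect_equal(precision(c(TP = 5, FP = 0, FN = 2)), 1)
  expect_equal(recall(c(TP = 9, FP = 0, FN = 1)), 0.9)
  expect_equal(recall(c(TP = 0, FP = 2, FN = 4)), 0)
  set.seed(61)
  for (i in 1:20) {
    c_ <- c(TP = sample(1:50, 1), FP = sample(0:50, 1), FN = sample(0:50, 1))
    expect_equal(precision(c_), c_[["TP"]] / (c_[["TP"]] + c_[["FP"]]))
    expect_equal(recall(c_), c_[["TP"]] / (c_[["TP"]] + c_[["FN"]]))
  }
  expect_warning(precision(c(TP = 0, FP = 0, FN = 1)), "undefined")
  expect_warning(recall(c(TP = 0, FP = 1, FN = 0)), "undefined")
})

test_that("average precision matches hand-traced P-R curves", {
  gt <- boxes_at(c(0, 50, 100))
  perfect <- dplyr::mutate(gt, conf = 1)
  expect_equal(average_precision(perfect, gt), 1)
  allfp <- dplyr::mutate(boxes_at(c(300, 400, 500)), conf = 0.9)
  expect_equal(average_precision(allfp, gt), 0)
  # 5 detections: TP, FP, TP, FP, TP by descending confidence.
  # precision after each: 1, 1/2, 2/3, 1/2, 3/5; recall: 1/3,1/3,2/3,2/3,1.
  # all-point envelope gives (1 + 2/3 + 3/5) / 3.
  dets <- dplyr::bind_rows(
    dplyr::mutate(boxes_at(1), conf = 0.95),
    dplyr::mutate(boxes_at(300), conf = 0.9),
    dplyr::mutate(boxes_at(51), conf = 0.8),
    dplyr::mutate(boxes_at(400), conf = 0.7),
    dplyr::mutate(boxes_at(99), conf = 0.6))
  expect_equal(average_precision(dets, gt), (1 + 2 / 3 + 3 / 5) / 3)
  expect_equal(average_precision(dets, gt, interpolation = "11point"),
               mean(c(rep(1, 4), rep(2 / 3, 3), rep(3 / 5, 4))))
  expect_error(average_precision(dets, gt[0, ]), "no ground truth")
})

test_that("duplicate detections of one object count once", {
  gt <- boxes_at(0)
  dets <- dplyr::bind_rows(dplyr::mutate(boxes_at(0), conf = 0.9),
                           dplyr::mutate(boxes_at(1), conf = 0.8))
  # second detection cannot claim the same gt box: precision drops
  expect_equal(average_precision(dets, gt), 1)  # recall 1 reached first
  dets_rev <- dets[2:1, ] |> dplyr::mutate(conf = c(0.9, 0.8))
  expect_equal(average_precision(dets_rev, gt), 1)
})

test_that("overlap rate is the IoU of predicted and labelled boxes", {
  expect_equal(overlap_rate(bbox(0, 0, 10, 10), bbox(5, 0, 10, 10)), 1 / 3)
  expect_equal(overlap_rate(bbox(0, 0, 8, 8), bbox(0, 0, 8, 8)), 1)
})

test_that("tracking evaluation recovers exact closed forms", {
  gt <- dplyr::bind_rows(lapply(1:10, function(f) {
    boxes_at(c(0, 100), frame = f, size = 30)
  }))
  ev <- tracking_eval(gt, gt)
  expect_equal(ev$AOR, 1)
  expect_equal(ev$ACLE, 0)
  expect_equal(ev$N, 20)
  shifted <- dplyr::mutate(gt, left = left + 3, top = top + 4)
  ev2 <- tracking_eval(shifted, gt)
  expect_equal(unique(ev2$per_pair$CLE), 5)
  expect_equal(ev2$ACLE, 5)
  expect_equal(glance(ev2)$ACLE, 5)
  expect_equal(nrow(tidy(ev2)), 20)
})

test_that("tracking evaluation equals per-pair hand accumulation", {
  set.seed(62)
  gt <- dplyr::bind_rows(lapply(1:10, function(f) {
    boxes_at(c(0, 60, 120) + runif(3, -2, 2), frame = f, size = 20)
  }))
  pred <- dplyr::mutate(gt, left = left + rnorm(30), top = top + rnorm(30))
  ev <- tracking_eval(pred, gt)
  ors <- c(); cles <- c()
  for (f in 1:10) {
    p <- pred[pred$frame == f, ]; g <- gt[gt$frame == f, ]
    for (i in 1:3) {   # same layout: box i matches box i
      ors <- c(ors, iou(p[i, ], g[i, ]))
      cles <- c(cles, sqrt((p$left[i] - g$left[i])^2 + (p$top[i] - g$top[i])^2))
    }
  }
  expect_equal(ev$N, 30)
  expect_equal(ev$AOR, mean(ors))
  expect_equal(ev$ACLE, mean(cles))
})

test_that("centre error grows with detector jitter", {
  acle_at <- function(sig) {
    scene <- simulate_scene(scene_config(n_targets = 10, frames = 40,
                                         jitter_sigma = sig, p_miss_base = 0,
                                         fp_rate = 0, feature_dim = 0,
                                         seed = 63))
    tracking_eval(scene$detections, scene$gt)$ACLE
  }
  errs <- vapply(c(0.5, 2, 4), acle_at, numeric(1))
  expect_true(all(diff(errs) > 0))
})

test_that("counting accuracy is the relative-error complement", {
  expect_equal(counting_accuracy(26, 26), 100)
  expect_equal(counting_accuracy(25, 26), 96.15, tolerance = 1e-4)
  expect_equal(counting_accuracy(0, 7), 0)
  expect_equal(counting_accuracy(40, 10), 0)   # floored at zero
  expect_error(counting_accuracy(5, 0), "undefined")
})
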