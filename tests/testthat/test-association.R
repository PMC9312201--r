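test_that("appearance cost is the smallest cosine distance over the gallery", {
  e1 <- c(1, 0, 0); e2 <- c(0, 1, 0)
  expect_equal(appearance_cost(list(list(e1)), rbind(e1))[1, 1], 0)
  expect_equal(appearance_cost(list(list(e1)), rbind(e2))[1, 1], 1)
  # gallery of two: min of the pairwise distances (brute force)
  set.seed(31)
  g1 <- unit_vec(rnorm(8)); g2 <- unit_vec(rnorm(8)); f <- unit_vec(rnorm(8))
  got <- appearance_cost(list(list(g1, g2)), rbind(f))[1, 1]
  expect_equal(got, min(1 - sum(g1 * f), 1 - sum(g2 * f)))
  # empty gallery row is all infeasible
  expect_true(all(is.infinite(appearance_cost(list(list()), rbind(f)))))
})

test_that("the motion gate masks exactly the out-of-gate entries", {
  costs <- matrix(runif(6), 2, 3)
  gating <- matrix(c(1, 5, 11, 2, 9, 30), 2, 3)
  expect_equal(gate_cost(costs, gating, Inf), costs)
  g0 <- gate_cost(costs, gating, 0)
  expect_true(all(is.infinite(g0)))
  g <- gate_cost(costs, gating, 9.4877)
  expect_identical(is.infinite(g), gating > 9.4877)
  expect_equal(g[is.finite(g)], costs[gating <= 9.4877])
})

test_that("assignment solves small cases exactly", {
  r <- solve_assignment(matrix(c(0, 9, 9, 0), 2, byrow = TRUE))
  expect_equal(r$matches, cbind(row = 1:2, col = 1:2))
  r2 <- solve_assignment(matrix(c(5, 1), 1), max_cost = 2)
  expect_equal(r2$matches, cbind(row = 1L, col = 2L))
  expect_equal(r2$unmatched_cols, 1L)
  r3 <- solve_assignment(matrix(numeric(0), 0, 0))
  expect_equal(nrow(r3$matches), 0)
})

test_that("assignment cost equals exhaustive permutation search", {
  set.seed(32)
  for (i in 1:60) {
    n <- sample(2:4, 1); m <- sample(2:4, 1)
    cost <- matrix(runif(n * m), n, m)
    r <- solve_assignment(cost)
    expect_equal(nrow(r$matches), min(n, m))
    expect_equal(sum(cost[r$matches]), oracle_assignment_cost(cost),
                 tolerance = 1e-12)
  }
})

test_that("assignment respects forbidden pairs and max_cost demotion", {
  cost <- matrix(c(0.1, Inf, Inf, 0.1), 2, byrow = TRUE)
  r <- solve_assignment(cost)
  expect_equal(r$matches, cbind(row = 1:2, col = 1:2))
  # all forbidden: nothing matched
  r2 <- solve_assignment(matrix(Inf, 2, 2))
  expect_equal(nrow(r2$matches), 0)
  expect_equal(r2$unmatched_rows, 1:2)
  # demotion: optimal pair above max_cost is dropped after solving
  r3 <- solve_assignment(matrix(c(0.5, 0.9), 1), max_cost = 0.4)
  expect_equal(nrow(r3$matches), 0)
})

test_that("degenerate cascade equals one gated assignment", {
  set.seed(33)
  cfg <- tracker_config()
  feats <- rbind(unit_vec(c(1, 0, 0, 0)), unit_vec(c(0, 1, 0, 0)))
  tracks <- list(
    make_track(100, 100, gallery = list(feats[1, ])),
    make_track(300, 100, gallery = list(feats[2, ])))
  dets <- tibble::tibble(left = c(290, 90), top = 90, width = 20, height = 20,
                         conf = 0.9)
  res <- matching_cascade(tracks, dets, feats[c(2, 1), ], cfg)
  expect_equal(res$matches[order(res$matches[, 1]), "det"], c(2L, 1L),
               ignore_attr = TRUE)
  # no detections: everything unmatched
  none <- matching_cascade(tracks, dets[0, ], NULL, cfg)
  expect_equal(none$unmatched_tracks, 1:2)
})

test_that("the cascade prefers recently updated tracks over stale ones", {
  cfg <- tracker_config()
  f <- unit_vec(c(1, 1, 0))
  fresh <- make_track(100, 100, a_k = 1L, gallery = list(f))
  stale <- make_track(100, 102, a_k = 5L, gallery = list(f))
  dets <- tibble::tibble(left = 90, top = 91, width = 20, height = 20,
                         conf = 0.9)
  res <- matching_cascade(list(stale, fresh), dets, rbind(f), cfg)
  expect_equal(res$matches, cbind(track = 2L, det = 1L))
  expect_equal(res$unmatched_tracks, 1L)
})

test_that("cascade output partitions tracks and detections", {
  set.seed(34)
  cfg <- tracker_config()
  for (rep in 1:10) {
    nt <- sample(1:6, 1); nd <- sample(0:6, 1)
    feats <- if (nd > 0) {
      t(vapply(seq_len(nd), function(i) unit_vec(rnorm(6)), numeric(6)))
    } else NULL
    tracks <- lapply(seq_len(nt), function(i) {
      make_track(runif(1, 0, 400), runif(1, 0, 400),
                 a_k = sample(1:4, 1),
                 gallery = list(unit_vec(rnorm(6))))
    })
    dets <- tibble::tibble(left = runif(nd, 0, 400), top = runif(nd, 0, 400),
                           width = 20, height = 20, conf = 0.9)
    res <- matching_cascade(tracks, dets, feats, cfg)
    expect_setequal(c(res$matches[, "track"], res$unmatched_tracks), seq_len(nt))
    expect_setequal(c(res$matches[, "det"], res$unmatched_dets), seq_len(nd))
    expect_false(anyDuplicated(res$matches[, "det"]) > 0)
    expect_false(anyDuplicated(res$matches[, "track"]) > 0)
  }
})

test_that("IoU matching assigns by overlap with a floor", {
  tb <- tibble::tibble(left = c(0, 50), top = 0, width = 10, height = 10)
  exact <- iou_match(tb[1, ], tb[1, ])
  expect_equal(exact$matches, cbind(track = 1L, det = 1L))
  disjoint <- iou_match(tb[1, ], tb[2, ], iou_floor = 0.3)
  expect_equal(nrow(disjoint$matches), 0)
  # crossed overlaps resolved to the minimum-total-cost pairing
  tracks <- tibble::tibble(left = c(0, 6), top = 0, width = 10, height = 10)
  dets <- tibble::tibble(left = c(5, 1), top = 0, width = 10, height = 10)
  res <- iou_match(tracks, dets, iou_floor = 0.1)
  cost <- 1 - iou_matrix(tracks, dets)
  expect_equal(sum(cost[res$matches]), oracle_assignment_cost(cost),
               tolerance = 1e-12)
})
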