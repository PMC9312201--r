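# Independent reference implementations used to check the package's fast
# paths. These deliberately use only explicit dense matrix algebra and
# exhaustive search, never the package's own internals.

# textbook Kalman filter with explicit matrices and solve()
oracle_kf <- local({
  F_ <- diag(8); F_[cbind(1:4, 5:8)] <- 1
  H <- cbind(diag(4), matrix(0, 4, 4))
  list(
    predict = function(mean, cov, wp = 1 / 20, wv = 1 / 160) {
      h <- mean[4]
      q <- c(wp * h, wp * h, 1e-2, wp * h, wv * h, wv * h, 1e-5, wv * h)^2
      list(mean = drop(F_ %*% mean), cov = F_ %*% cov %*% t(F_) + diag(q))
    },
    update = function(mean, cov, z, wp = 1 / 20) {
      h <- mean[4]
      r <- c(wp * h, wp * h, 1e-1, wp * h)^2
      S <- H %*% cov %*% t(H) + diag(r)
      K <- cov %*% t(H) %*% solve(S)
      list(mean = drop(mean + K %*% (z - H %*% mean)),
           cov = (diag(8) - K %*% H) %*% cov)
    },
    gating = function(mean, cov, z, wp = 1 / 20) {
      h <- mean[4]
      r <- c(wp * h, wp * h, 1e-1, wp * h)^2
      S <- H %*% cov %*% t(H) + diag(r)
      d <- z - drop(H %*% mean)
      drop(t(d) %*% solve(S) %*% d)
    })
})

# exhaustive minimum-cost assignment by permutation search
oracle_assignment_cost <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }))
  }
  best <- Inf
  if (n <= m) {
    for (p in perms(seq_len(m))) {
      best <- min(best, sum(cost[cbind(seq_len(n), p[seq_len(n)])]))
    }
  } else {
    for (p in perms(seq_len(n))) {
      best <- min(best, sum(cost[cbind(p[seq_len(m)], seq_len(m))]))
    }
  }
  best
}

random_state <- function() {
  m <- c(runif(1, 0, 500), runif(1, 0, 500), runif(1, 0.5, 2), runif(1, 20, 80),
         rnorm(2, 0, 3), rnorm(1, 0, 0.01), rnorm(1, 0, 1))
  A <- matrix(rnorm(64, 0, 0.5), 8, 8)
  list(mean = m, cov = A %*% t(A) + diag(8) * 0.5)
}

random_box <- function() {
  bbox(runif(1, 0, 200), runif(1, 0, 200), runif(1, 5, 60), runif(1, 5, 60))
}

# minimal track object for association-level tests
make_track <- function(u, v, gamma = 1, h = 20, a_k = 1L, gallery = list()) {
  ks <- kf_predict(kf_initiate(c(u, v, gamma, h)))
  list(id = 0L, status = "confirmed", kstate = ks, hits = 3L,
       a_k = as.integer(a_k), gallery = gallery)
}

unit_vec <- function(x) x / sqrt(sum(x^2))

# id of the track box nearest the given ground-truth target at a frame
track_id_at <- function(tracks, gt, target, frame, max_d2 = 400) {
  g <- gt[gt$id == target & gt$frame == frame, ]
  p <- tracks[tracks$frame == frame, ]
  if (nrow(p) == 0 || nrow(g) == 0) return(NA_integer_)
  d2 <- (p$left - g$left)^2 + (p$top - g$top)^2
  if (min(d2) > max_d2) return(NA_integer_)
  p$id[which.min(d2)]
}
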