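#' Minimum-cost bipartite assignment
#'
#' Solves the rectangular assignment problem between tracks (rows) and
#' detections (columns) with the Hungarian algorithm (potentials plus
#' shortest augmenting path, O(n^3)). Entries of `Inf` mark forbidden pairs.
#' The solver first maximises the number of feasible pairs, then minimises
#' total cost among those; afterwards any matched pair whose cost exceeds
#' `max_cost` is demoted to unmatched.
#'
#' @param cost A numeric matrix of non-negative costs, rows = tracks,
#'   columns = detections; `Inf` forbids a pair. May be empty or
#'   non-square.
#' @param max_cost Pairs costlier than this are rejected after solving.
#'   Default `Inf` (accept every feasible pair).
#' @return A list with `matches` (two-column integer matrix of row/column
#'   indices), `unmatched_rows` and `unmatched_cols` (integer vectors).
#' @examples
#' solve_assignment(matrix(c(0, 9, 9, 0), 2, byrow = TRUE))
#' @export
solve_assignment <- function(cost, max_cost = Inf) {
  if (is.null(dim(cost))) cost <- matrix(cost, nrow = NROW(cost))
  n <- nrow(cost); m <- ncol(cost)
  empty <- list(matches = matrix(integer(0), 0, 2,
                                 dimnames = list(NULL, c("row", "col"))),
                unmatched_rows = seq_len(n), unmatched_cols = seq_len(m))
  if (n == 0 || m == 0) return(empty)
  if (any(cost < 0, na.rm = TRUE)) abort("assignment costs must be non-negative")

  # pad to square; forbidden and padding cells get a cost larger than any
  # full real assignment so the solver avoids them whenever possible
  finite <- cost[is.finite(cost)]
  big <- if (length(finite)) sum(finite) + max(finite) + 1 else 1
  N <- max(n, m)
  sq <- matrix(big, N, N)
  sq[seq_len(n), seq_len(m)] <- ifelse(is.finite(cost), cost, big)

  col_row <- hungarian_square(sq)   # for each column, the assigned row

  matched <- matrix(integer(0), 0, 2)
  for (j in seq_len(m)) {
    i <- col_row[j]
    if (i <= n && is.finite(cost[i, j]) && cost[i, j] <= max_cost) {
      matched <- rbind(matched, c(i, j))
    }
  }
  colnames(matched) <- c("row", "col")
  list(matches = matched,
       unmatched_rows = setdiff(seq_len(n), matched[, 1]),
       unmatched_cols = setdiff(seq_len(m), matched[, 2]))
}

# Hungarian algorithm on a square finite cost matrix.
# Returns an integer vector: element j is the row assigned to column j.
# Dual potentials u (rows) and v (columns); p[j+1] holds the row matched to
# column j, with column 0 acting as the virtual root of augmenting paths.
hungarian_square <- function(a) {
  n <- nrow(a)
  u <- numeric(n)          # row potentials
  v <- numeric(n + 1)      # column potentials (index j+1; j = 0 virtual)
  p <- integer(n + 1)      # column -> row assignment (0 = unassigned)
  way <- integer(n + 1)    # predecessor column along the alternating tree
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      cols <- which(!used[-1])          # real columns not yet in the tree
      cur <- a[i0, cols] - u[i0] - v[cols + 1]
      upd <- cur < minv[cols + 1]
      minv[cols[upd] + 1] <- cur[upd]
      way[cols[upd] + 1] <- j0
      jmin <- which.min(minv[cols + 1])
      delta <- minv[cols[jmin] + 1]
      j1 <- cols[jmin]
      used_idx <- which(used)
      u[p[used_idx]] <- u[p[used_idx]] + delta
      v[used_idx] <- v[used_idx] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {                            # augment along the stored path
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  p[-1]
}
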