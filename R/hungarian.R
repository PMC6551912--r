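# Exact solver for the linear assignment problem: given a square cost
# matrix A, find the permutation mu minimising sum_i A[i, mu(i)].
# Jonker-Volgenant style shortest-augmenting-path algorithm with dual
# potentials, O(k^3). Pure R; class sizes here are small (at most a few
# times the chain count) so this is never a bottleneck.

solveAssignment <- function(a) {
  n <- nrow(a)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  u <- numeric(n)          # row potentials
  v <- numeric(n + 1)      # column potentials, col 0 at index 1
  p <- integer(n + 1)      # p[j+1] = row currently matched to column j
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- a[i0, j] - u[i0] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          if (p[j + 1L] > 0L) u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  mu <- integer(n)
  for (j in seq_len(n)) mu[p[j + 1L]] <- j
  mu
}

checkCostMatrix <- function(cost) {
  cost <- as.matrix(cost)
  if (nrow(cost) != ncol(cost)) stop("cost matrix must be square")
  if (!all(is.finite(cost))) stop("cost matrix must be finite")
  cost
}

#' Optimal assignment by the Hungarian algorithm
#'
#' Returns the permutation mu minimising `sum(cost[i, mu[i]])`, computed
#' exactly in O(k^3). Column scanning is in increasing index order, so
#' runs are deterministic and ties resolve towards low indices.
#'
#' @param cost square, finite, numeric cost matrix (Angstrom^2 in the
#'   package's own use).
#' @return integer permutation `mu` with attribute `cost`.
#' @examples
#' hungarianAssign(rbind(c(0, 1), c(0.5, 10)))  # 2, 1 : cost 1.5
#' @export
hungarianAssign <- function(cost) {
  cost <- checkCostMatrix(cost)
  mu <- solveAssignment(cost)
  attr(mu, "cost") <- sum(cost[cbind(seq_len(nrow(cost)), mu)])
  mu
}

#' Greedy assignment (baseline)
#'
#' Repeatedly selects the globally smallest remaining entry among
#' unassigned rows and columns; ties break towards the smallest (row,
#' column) pair. Fast but suboptimal: its cost is always >= the
#' Hungarian cost and can be strictly larger even for 2 x 2 matrices.
#'
#' @inheritParams hungarianAssign
#' @return integer permutation `mu` with attribute `cost`.
#' @examples
#' greedyAssign(rbind(c(0, 1), c(0.5, 10)))  # 1, 2 : cost 10
#' @export
greedyAssign <- function(cost) {
  cost <- checkCostMatrix(cost)
  n <- nrow(cost)
  mu <- integer(n)
  rowFree <- rep(TRUE, n)
  colFree <- rep(TRUE, n)
  for (step in seq_len(n)) {
    sub <- cost[rowFree, colFree, drop = FALSE]
    hit <- which(sub == min(sub), arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
    r <- which(rowFree)[hit[1]]
    cl <- which(colFree)[hit[2]]
    mu[r] <- cl
    rowFree[r] <- FALSE
    colFree[cl] <- FALSE
  }
  attr(mu, "cost") <- sum(cost[cbind(seq_len(n), mu)])
  mu
}
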