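# Minimum-cost bipartite assignment (Hungarian algorithm, potentials /
# shortest augmenting path formulation, O(n^3)). Written here because no
# assignment-problem solver ships with the available package set; verified
# against brute-force permutation enumeration in the tests.
#
# cost: n x m matrix (n <= m is not required; the matrix is padded).
# Returns an integer vector a of length nrow(cost): a[i] = assigned column
# of row i (every row is assigned; pad the matrix to encode "no match").
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0 || m == 0) return(integer(0))
  N <- max(n, m)
  big <- sum(abs(cost[is.finite(cost)])) + 1
  a <- matrix(big * 2, N, N)
  fc <- cost
  fc[!is.finite(fc)] <- big * 4
  a[seq_len(n), seq_len(m)] <- fc
  INF <- .Machine$double.xmax / 4

  u <- numeric(N + 1); v <- numeric(N + 1)
  p <- integer(N + 1)    # p[j+1]: row assigned to column j (0 = none)
  way <- integer(N + 1)
  for (i in seq_len(N)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, N + 1)
    used <- rep(FALSE, N + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- INF; j1 <- 0L
      for (j in seq_len(N)) {
        if (!used[j + 1]) {
          cur <- a[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:N) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(N)
  for (j in seq_len(N)) if (p[j + 1] > 0) ans[p[j + 1]] <- j
  ans[seq_len(n)]
}
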