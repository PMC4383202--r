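# Monte-Carlo oracle for expected normal order statistics, independent of
# the package's quadrature: draw many samples of size n, sort each, average
# each rank.  Rows are sorted with a vectorised odd-even transposition
# network (n passes of pairwise pmin/pmax), so 1e7 replications stay
# feasible in chunks.

row_sort <- function(X) {
  n <- ncol(X)
  for (pass in seq_len(n)) {
    start <- if (pass %% 2 == 1) 1L else 2L
    j <- start
    while (j < n) {
      lo <- pmin(X[, j], X[, j + 1L])
      X[, j + 1L] <- pmax(X[, j], X[, j + 1L])
      X[, j] <- lo
      j <- j + 2L
    }
  }
  X
}

mc_order_stat_means <- function(n, reps, chunk = 2e6, seed = 42) {
  set.seed(seed)
  total <- numeric(n)
  done <- 0
  while (done < reps) {
    k <- min(chunk, reps - done)
    X <- matrix(rnorm(k * n), nrow = k, ncol = n)
    total <- total + colSums(row_sort(X))
    done <- done + k
  }
  total / reps
}
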