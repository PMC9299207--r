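# Independent brute-force DTW oracle: plain-R full DP table, no path logic
# shared with the implementation under test.
oracle_dtw <- function(x, y) {
  n <- length(x)
  m <- length(y)
  D <- matrix(NA_real_, n, m)
  D[1, 1] <- abs(x[1] - y[1])
  if (n > 1) for (i in 2:n) D[i, 1] <- D[i - 1, 1] + abs(x[i] - y[1])
  if (m > 1) for (j in 2:m) D[1, j] <- D[1, j - 1] + abs(x[1] - y[j])
  if (n > 1 && m > 1) {
    for (i in 2:n) {
      for (j in 2:m) {
        D[i, j] <- abs(x[i] - y[j]) +
          min(D[i - 1, j], D[i, j - 1], D[i - 1, j - 1])
      }
    }
  }
  list(distance = D[n, m], lastrow = D[, m], D = D)
}
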