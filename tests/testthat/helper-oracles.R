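# Independent oracles written directly from the definitions; they never call
# the production code paths they validate.

# nearest-bin-mean tuning curves with Euclidean distances, leave-one-out
euclideanTuningOracle <- function(X, ori, nBins = 10L) {
  n <- nrow(X)
  edges <- seq(-90, 90, by = 180 / nBins)
  out <- matrix(NA_real_, n, nBins)
  for (i in seq_len(n)) {
    sims <- numeric(nBins)
    ok <- TRUE
    for (b in seq_len(nBins)) {
      members <- c()
      for (j in seq_len(n)) {
        if (j == i) next
        d <- relativeOrientation(ori[j], ori[i])
        inBin <- if (b < nBins) d >= edges[b] & d < edges[b + 1]
                 else d >= edges[b] & d <= edges[b + 1]
        if (inBin) members <- c(members, j)
      }
      if (!length(members)) { ok <- FALSE; break }
      m <- colMeans(X[members, , drop = FALSE])
      sims[b] <- -sqrt(sum((X[i, ] - m)^2))
    }
    if (ok) out[i, ] <- sims - mean(sims)
  }
  out
}
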