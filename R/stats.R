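# Group-level inference: cluster-based sign-flip permutation tests and
# windowed one-sample t-tests.

# contiguous runs where the t time course exceeds the threshold (either
# tail); returns a data.frame of start/end indices and summed-t masses
.findClusters <- function(tvals, threshold) {
  above <- abs(tvals) > threshold
  if (!any(above)) return(data.frame(start = integer(0), end = integer(0),
                                     mass = numeric(0)))
  # split supra-threshold samples by sign so adjacent positive and negative
  # excursions form separate clusters
  code <- integer(length(tvals))
  code[above & tvals > 0] <- 1L
  code[above & tvals < 0] <- -1L
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  data.frame(start = starts[keep], end = ends[keep],
             mass = mapply(function(s, e) sum(tvals[s:e]),
                           starts[keep], ends[keep]))
}

# zero-variance samples: a nonzero mean is infinitely reliable (clamped to a
# large finite t so cluster masses stay representable); a zero mean carries
# no evidence
.T_CLAMP <- 1e12

.tFromMoments <- function(mu, v, n) {
  tv <- mu / sqrt(v / n)
  degen <- !is.finite(tv)
  tv[degen] <- sign(mu[degen]) * .T_CLAMP
  tv
}

.oneSampleT <- function(X) {
  # X: participants x times; t statistic per column
  n <- nrow(X)
  mu <- colMeans(X)
  v <- (colSums(X^2) - n * mu^2) / (n - 1)
  .tFromMoments(mu, v, n)
}

#' Cluster-based sign-flip permutation test
#'
#' One-sample test of per-participant time courses against zero with
#' family-wise error control over time. Sample-level two-tailed t tests are
#' thresholded at \code{clusterAlpha}; contiguous supra-threshold samples of
#' common sign form clusters with mass equal to their summed t values. The
#' null distribution records, for each random sign flip of whole participant
#' time courses, the maximum absolute cluster mass; each observed cluster's
#' p-value is \code{(1 + #permutations with null mass >= observed) /
#' (1 + nPermutations)}. Paired designs are handled by passing
#' per-participant differences.
#'
#' @param timecourses Numeric matrix, participants x times (no
#'   non-finite values).
#' @param times Sample times in seconds (default: sample indices).
#' @param nPermutations Number of sign-flip permutations (default 100000).
#' @param clusterAlpha Sample-level cluster-forming alpha (two-tailed,
#'   default 0.05).
#' @param seed Integer seed; results are bit-reproducible given the seed.
#' @return A [ClusterResult-class].
#' @export
clusterPermutationTest <- function(timecourses, times = NULL,
                                   nPermutations = 100000L,
                                   clusterAlpha = 0.05, seed = 1L) {
  X <- as.matrix(timecourses)
  if (!all(is.finite(X))) stop("time courses contain non-finite values")
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 participants")
  if (nPermutations < 100L)
    warning("fewer than 100 permutations: p-values will be coarse")
  if (is.null(times)) times <- seq_len(ncol(X))
  threshold <- stats::qt(1 - clusterAlpha / 2, df = n - 1L)
  tobs <- .oneSampleT(X)
  obs <- .findClusters(tobs, threshold)
  css <- colSums(X^2)                  # invariant under sign flips
  maxmass <- .withSeed(seed, {
    vapply(seq_len(nPermutations), function(p) {
      s <- sample(c(-1, 1), n, replace = TRUE)
      mu <- colMeans(X * s)
      v <- (css - n * mu^2) / (n - 1)
      cl <- .findClusters(.tFromMoments(mu, v, n), threshold)
      if (nrow(cl)) max(abs(cl$mass)) else 0
    }, numeric(1))
  })
  p <- vapply(obs$mass, function(m)
    (1 + sum(maxmass >= abs(m))) / (1 + nPermutations), numeric(1))
  clusters <- data.frame(t_start = times[obs$start],
                         t_end = times[obs$end],
                         mass = obs$mass, p = p)
  clusters <- clusters[order(clusters$t_start), , drop = FALSE]
  rownames(clusters) <- NULL
  new("ClusterResult", clusters = clusters,
      nPermutations = as.integer(nPermutations),
      clusterAlpha = clusterAlpha, tail = "two")
}

#' Windowed one-sample t-test
#'
#' Two-tailed one-sample t-test of per-participant values (e.g. window
#' averages of a bias index) against \code{mu}.
#'
#' @param values Numeric vector, one value per participant.
#' @param mu Null value (default 0).
#' @return A list with \code{t}, \code{p} and \code{df}.
#' @export
windowTtest <- function(values, mu = 0) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) stop("need at least 2 values")
  if (stats::sd(values) == 0) {
    # degenerate: all values equal; t is 0/0 when equal to mu
    if (isTRUE(all.equal(values[1], mu)))
      return(list(t = 0, p = 1, df = n - 1L))
    return(list(t = sign(values[1] - mu) * Inf, p = 0, df = n - 1L))
  }
  tt <- stats::t.test(values, mu = mu)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}
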