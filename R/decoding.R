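# Cross-validated Mahalanobis tuning-curve decoding of orientation.

#' Relative-orientation bin edges and centers
#'
#' The \code{nBins} half-open bins \code{[low, high)} partition
#' \code{(-90, 90]}; the boundary value +90 belongs to the top bin. With the
#' default 10 bins the edges are -90, -72, ..., +90 and the centers
#' -81, -63, -45, -27, -9, +9, +27, +45, +63, +81 degrees.
#'
#' @param nBins Even number of bins (default 10).
#' @return \code{orientationBinEdges}: numeric vector of \code{nBins + 1}
#'   edges; \code{orientationBinCenters}: numeric vector of \code{nBins}
#'   centers.
#' @export
orientationBinEdges <- function(nBins = 10L) {
  seq(-90, 90, length.out = nBins + 1L)
}

#' @rdname orientationBinEdges
#' @export
orientationBinCenters <- function(nBins = 10L) {
  e <- orientationBinEdges(nBins)
  (e[-1] + e[-length(e)]) / 2
}

# bin index in 1..nBins for relative orientations in (-90, 90];
# half-open [low, high), except the top bin which also takes +90
.binIndex <- function(delta, nBins = 10L) {
  findInterval(delta, orientationBinEdges(nBins), rightmost.closed = TRUE)
}

#' Sliding-window feature vectors at one time point
#'
#' Concatenates, for every trial, the \code{windowSamples} samples of the
#' trailing window ending at \code{tIndex} across all sensors into one row
#' (sensor-major: each sensor contributes a contiguous block of
#' \code{windowSamples} columns).
#'
#' @param epochs An [OrientationEpochs-class].
#' @param tIndex Sample index (1-based) at which the window ends.
#' @param windowSamples Window length in samples (default 37).
#' @return Numeric matrix, trials x (sensors * windowSamples).
#' @export
buildFeatures <- function(epochs, tIndex, windowSamples = 37L) {
  stopifnot(is(epochs, "OrientationEpochs"))
  if (tIndex > nTimes(epochs))
    stop("tIndex beyond the epoch")
  lo <- tIndex - windowSamples + 1L
  if (lo < 1L)
    stop("window truncated by the epoch edge at tIndex = ", tIndex)
  d <- epochs@data[, , lo:tIndex, drop = FALSE]
  n <- dim(d)[1]
  matrix(aperm(d, c(1, 3, 2)), n, dim(d)[2] * windowSamples)
}

#' Principal-component reduction keeping a target variance fraction
#'
#' Centers the feature matrix and keeps the smallest number of principal
#' components whose cumulative explained-variance ratio reaches
#' \code{variance}. The returned transform is reusable on held-out rows via
#' [projectFeatures()].
#'
#' @param features Numeric matrix (trials x features).
#' @param variance Explained-variance fraction to retain, in (0, 1]
#'   (default 0.90).
#' @return A list of class \code{"pcaTransform"}: \code{center},
#'   \code{rotation} (features x k), \code{k},
#'   \code{explainedVariance} (per component), \code{scores} (trials x k).
#' @export
reduceDimensionality <- function(features, variance = 0.90) {
  if (nrow(features) < 2L)
    stop("need at least 2 rows for PCA")
  ctr <- colMeans(features)
  X <- sweep(features, 2, ctr)
  sv <- svd(X, nu = 0)
  tol <- max(dim(X)) * max(sv$d) * .Machine$double.eps
  pos <- sv$d > tol
  ev <- sv$d^2 / sum(sv$d^2)
  if (variance >= 1) {
    k <- sum(pos)
  } else {
    k <- which(cumsum(ev) >= variance - 1e-12)[1]
    k <- min(k, max(sum(pos), 1L))
  }
  rot <- sv$v[, seq_len(k), drop = FALSE]
  structure(list(center = ctr, rotation = rot, k = k,
                 explainedVariance = ev[seq_len(k)],
                 scores = X %*% rot),
            class = "pcaTransform")
}

#' @rdname reduceDimensionality
#' @param transform A \code{"pcaTransform"} from [reduceDimensionality()].
#' @param newdata Numeric matrix with the same feature columns.
#' @export
projectFeatures <- function(transform, newdata) {
  stopifnot(inherits(transform, "pcaTransform"))
  sweep(newdata, 2, transform$center) %*% transform$rotation
}

#' Mahalanobis distance between two pattern vectors
#'
#' \code{sqrt((x - y)' cov^-1 (x - y))}; with \code{cov = NULL} the identity
#' is used and the distance reduces to Euclidean.
#'
#' @param x,y Numeric vectors of equal length.
#' @param cov Symmetric positive-definite covariance matrix, or \code{NULL}
#'   for the identity.
#' @return Non-negative scalar distance.
#' @examples
#' mahalanobisDistance(c(0, 0), c(3, 4))                    # 5
#' mahalanobisDistance(c(2, 0), c(0, 0), diag(c(4, 1)))     # 1
#' @export
mahalanobisDistance <- function(x, y, cov = NULL) {
  d <- x - y
  if (is.null(cov)) return(sqrt(sum(d^2)))
  R <- tryCatch(chol(cov), error = function(e)
    stop("covariance is singular or not positive definite"))
  sqrt(sum(backsolve(R, d, transpose = TRUE)^2))
}

#' Shrinkage-regularized covariance
#'
#' Sample covariance shrunk toward its diagonal with an analytically chosen
#' intensity (the off-diagonal shrinkage of Schafer & Strimmer 2005),
#' appropriate for the p-close-to-n regimes the decoder works in.
#'
#' @param X Numeric matrix of observations x features (e.g. residual
#'   patterns).
#' @return The regularized covariance matrix, with attribute
#'   \code{"shrinkage"} holding the intensity in [0, 1].
#' @export
shrinkageCovariance <- function(X) {
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 observations")
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / (n - 1)
  W2 <- crossprod(Xc^2)                  # sum_k w_kij^2
  Wm <- crossprod(Xc) / n                # mean_k w_kij
  varS <- n / (n - 1)^3 * (W2 - n * Wm^2)
  off <- row(S) != col(S)
  denom <- sum(S[off]^2)
  lambda <- if (denom > 0) sum(varS[off]) / denom else 1
  lambda <- min(1, max(0, lambda))
  Sigma <- (1 - lambda) * S
  diag(Sigma) <- diag(S)
  # guard against zero-variance features
  eps <- 1e-10 * mean(diag(S))
  if (!is.finite(eps) || eps <= 0) eps <- 1e-12
  diag(Sigma) <- diag(Sigma) + eps
  attr(Sigma, "shrinkage") <- lambda
  Sigma
}

#' Leave-one-trial-out tuning curve for a single held-out trial
#'
#' Training trials are binned by their orientation relative to the held-out
#' trial's orientation into the \code{nBins} half-open bins; the Mahalanobis
#' distance from the held-out pattern to each bin's mean pattern is computed,
#' negated, and mean-centered, yielding the tuning curve. If any bin is
#' empty the curve is undefined (all-\code{NA}) for this trial.
#'
#' @param features Numeric matrix, trials x features (after any PCA).
#' @param orientations Orientations in degrees \code{[0, 180)}, one per row.
#' @param heldOut Index of the held-out (test) trial.
#' @param cov Covariance for the Mahalanobis metric: a matrix, \code{NULL}
#'   (identity), or \code{"shrinkage"} to estimate it from the training
#'   trials' residuals (per-bin means removed) within this fold.
#' @param nBins Number of relative-orientation bins (default 10).
#' @return Numeric vector of \code{nBins} similarities (sum zero), with
#'   attribute \code{"binCenters"}; all \code{NA} if a bin was empty.
#' @export
tuningCurveLoo <- function(features, orientations, heldOut,
                           cov = NULL, nBins = 10L) {
  n <- nrow(features)
  stopifnot(length(orientations) == n, heldOut >= 1L, heldOut <= n)
  train <- setdiff(seq_len(n), heldOut)
  delta <- relativeOrientation(orientations[train],
                               orientations[heldOut])
  bins <- .binIndex(delta, nBins)
  centers <- orientationBinCenters(nBins)
  out <- rep(NA_real_, nBins)
  attr(out, "binCenters") <- centers
  if (length(unique(bins)) < nBins) return(out)
  Xtr <- features[train, , drop = FALSE]
  means <- rowsum(Xtr, bins) / as.vector(table(bins))
  if (identical(cov, "shrinkage")) {
    resid <- Xtr - means[bins, , drop = FALSE]
    cov <- shrinkageCovariance(resid)
  }
  x <- features[heldOut, ]
  d <- vapply(seq_len(nBins), function(b)
    mahalanobisDistance(x, means[b, ], cov), numeric(1))
  sim <- -d
  out[] <- sim - mean(sim)
  out
}

#' Cosine-projected decoding evidence of a tuning curve
#'
#' Each bin's similarity is weighted by the cosine of the doubled bin-center
#' angle (orientation is 180-degree periodic) and averaged. Zero means no
#' recoverable orientation information; higher is stronger coding. Invariant
#' to adding a constant to all similarities.
#'
#' @param curve Numeric vector of bin similarities (a tuning curve), or a
#'   matrix with one curve per row.
#' @param binCenters Bin centers in degrees (default: the 10-bin centers).
#' @return Scalar evidence (or one value per row for a matrix input).
#' @examples
#' ctr <- orientationBinCenters()
#' decodingEvidence(cos(2 * ctr * pi / 180))  # 0.5: perfectly tuned
#' @export
decodingEvidence <- function(curve, binCenters = NULL) {
  if (is.matrix(curve)) {
    if (is.null(binCenters)) binCenters <- orientationBinCenters(ncol(curve))
    w <- cos(2 * binCenters * pi / 180)
    return(as.vector(curve %*% w) / length(w))
  }
  if (is.null(binCenters)) {
    binCenters <- attr(curve, "binCenters")
    if (is.null(binCenters)) binCenters <- orientationBinCenters(length(curve))
  }
  mean(curve * cos(2 * binCenters * pi / 180))
}

# All-trials leave-one-out tuning curves at one time point (vectorized).
# Xw: whitened (or raw, for identity cov) trials x features matrix.
# Returns trials x nBins matrix of mean-centered, sign-reversed distances;
# rows with an empty bin are all-NA.
.tuningCurvesAll <- function(Xw, orientations, nBins = 10L) {
  n <- nrow(Xw)
  Dlt <- relativeOrientation(
    matrix(orientations, n, n, byrow = TRUE),   # train j in columns
    matrix(orientations, n, n))                 # test i in rows
  B <- matrix(.binIndex(as.vector(Dlt), nBins), n, n)
  diag(B) <- 0L                                 # exclude the held-out trial
  xw2 <- rowSums(Xw^2)
  sim <- matrix(NA_real_, n, nBins)
  missing <- rep(FALSE, n)
  for (b in seq_len(nBins)) {
    Ib <- (B == b) * 1
    cnt <- rowSums(Ib)
    empty <- cnt == 0
    missing <- missing | empty
    cnt[empty] <- 1
    Mb <- (Ib %*% Xw) / cnt
    d2 <- rowSums(Mb^2) - 2 * rowSums(Mb * Xw) + xw2
    sim[, b] <- -sqrt(pmax(d2, 0))
  }
  sim[missing, ] <- NA_real_
  sim - rowMeans(sim)
}

# Whitening transform for one time point given the config's cov estimator.
# Residuals are taken about the fitted doubled-angle tuning model so the
# covariance reflects noise, not signal.
.whitenPatterns <- function(X, orientations, covEstimator) {
  if (covEstimator == "identity") return(X)
  ang <- 2 * orientations * pi / 180
  Zm <- cbind(1, cos(ang), sin(ang))
  resid <- qr.resid(qr(Zm), X)
  Sigma <- shrinkageCovariance(resid)
  R <- chol(Sigma)
  t(backsolve(R, t(X), transpose = TRUE))
}

.DECODE_LABELS <- c("target", "previous_target", "sample1", "sample2",
                    "report")

# orientation vector for a decode label, NA where unavailable
.labelOrientations <- function(trials, label) {
  switch(label,
         target = trials$target_orientation,
         previous_target = ifelse(trials$first_in_block, NA_real_,
                                  trials$previous_target_orientation),
         sample1 = trials$sample1_orientation,
         sample2 = trials$sample2_orientation,
         report = trials$report_orientation)
}

#' Leave-one-trial-out decoding across time
#'
#' At every requested time point, sliding-window features are built,
#' reduced by PCA to the configured variance fraction, whitened with the
#' configured covariance estimator, and each trial is decoded with
#' leave-one-trial-out tuning curves; the cosine projection of each curve
#' gives the trial's decoding evidence. The per-participant evidence
#' time course is the across-trial mean of the returned matrix.
#'
#' @param epochs An [OrientationEpochs-class] (one participant).
#' @param trials The participant's trial data.frame; rows are matched to
#'   epochs by \code{trial_id}.
#' @param label Item to decode: \code{"target"}, \code{"previous_target"}
#'   (first-in-block trials drop out), \code{"sample1"}, \code{"sample2"} or
#'   \code{"report"}.
#' @param config An [analysisConfig()].
#' @param timeIndices Sample indices at which to decode; default: every
#'   index where the trailing window fits. Indices where it does not are
#'   skipped with a message.
#' @return A [DecodingResult-class].
#' @export
decodeTimecourse <- function(epochs, trials, label = "target",
                             config = analysisConfig(),
                             timeIndices = NULL) {
  stopifnot(is(epochs, "OrientationEpochs"), label %in% .DECODE_LABELS)
  trials <- validateTrialTable(trials)
  m <- match(epochs@trialIds, trials$trial_id)
  if (anyNA(m))
    stop("epochs contain trial_ids absent from the trial table")
  ori <- .labelOrientations(trials[m, , drop = FALSE], label)
  keep <- which(!is.na(ori))
  if (length(keep) == 0L) stop("no eligible trials for label '", label, "'")
  if (length(keep) < 20L)
    warning("only ", length(keep), " eligible trials for label '", label, "'")
  ep <- epochs[keep, ]
  ori <- ori[keep]
  w <- config@windowSamples
  if (is.null(timeIndices)) timeIndices <- seq.int(w, nTimes(ep))
  skip <- timeIndices < w | timeIndices > nTimes(ep)
  if (any(skip)) {
    message("skipping ", sum(skip),
            " time point(s) where the window is truncated")
    timeIndices <- timeIndices[!skip]
  }
  if (!length(timeIndices)) stop("no valid time points to decode")
  nB <- config@nBins
  n <- nTrials(ep)
  tuning <- array(NA_real_, dim = c(n, nB, length(timeIndices)))
  for (ti in seq_along(timeIndices)) {
    feats <- buildFeatures(ep, timeIndices[ti], w)
    if (config@pcaFoldwise) {
      sim <- matrix(NA_real_, n, nB)
      for (i in seq_len(n)) {
        tr <- setdiff(seq_len(n), i)
        pca <- reduceDimensionality(feats[tr, , drop = FALSE],
                                    config@pcaVariance)
        Xall <- rbind(projectFeatures(pca, feats[i, , drop = FALSE]),
                      pca$scores)
        covArg <- if (config@covEstimator == "shrinkage") "shrinkage"
                  else NULL
        sim[i, ] <- tuningCurveLoo(Xall, c(ori[i], ori[tr]), 1L,
                                   cov = covArg, nBins = nB)
      }
    } else {
      pca <- reduceDimensionality(feats, config@pcaVariance)
      Xw <- .whitenPatterns(pca$scores, ori, config@covEstimator)
      sim <- .tuningCurvesAll(Xw, ori, nB)
    }
    tuning[, , ti] <- sim
  }
  centers <- orientationBinCenters(nB)
  wts <- cos(2 * centers * pi / 180)
  evid <- apply(tuning, 3, function(s) as.vector(s %*% wts) / nB)
  evid <- matrix(evid, n, length(timeIndices))
  new("DecodingResult",
      evidence = evid, tuning = tuning,
      times = ep@times[timeIndices], trialIds = ep@trialIds,
      label = label, lockEvent = ep@lockEvent, binCenters = centers)
}

#' Re-epoch trials around the response
#'
#' Re-aligns probe-locked epochs so that time zero is the moment the report
#' was completed (probe onset + RT). Trials whose RT is missing or outside
#' \code{rtBounds}, or whose requested span falls outside the source epoch,
#' are excluded (counts reported via a message).
#'
#' @param epochs Probe-locked [OrientationEpochs-class].
#' @param trials Trial data.frame with the \code{rt} column.
#' @param rtBounds Inclusive RT bounds in seconds (default
#'   \code{c(0.65, 11.85)}).
#' @param span Length-2 numeric: new epoch limits in seconds relative to the
#'   response (default \code{c(-2, 0)}).
#' @return A response-locked \code{OrientationEpochs} containing the
#'   surviving trials.
#' @export
responseLock <- function(epochs, trials, rtBounds = c(0.65, 11.85),
                         span = c(-2, 0)) {
  stopifnot(is(epochs, "OrientationEpochs"))
  trials <- validateTrialTable(trials)
  m <- match(epochs@trialIds, trials$trial_id)
  if (anyNA(m))
    stop("epochs contain trial_ids absent from the trial table")
  rt <- trials$rt[m]
  sf <- epochs@sfreq
  nNew <- round(diff(span) * sf) + 1L
  tNew <- span[1] + (seq_len(nNew) - 1L) / sf
  t0 <- epochs@times[1]
  reasons <- character(nTrials(epochs))
  reasons[is.na(rt)] <- "rt_missing"
  oob <- !is.na(rt) & (rt < rtBounds[1] | rt > rtBounds[2])
  reasons[oob] <- "rt_out_of_bounds"
  idxList <- vector("list", nTrials(epochs))
  for (i in seq_len(nTrials(epochs))) {
    if (nzchar(reasons[i])) next
    idx <- round((rt[i] + tNew - t0) * sf) + 1L
    if (idx[1] < 1L || idx[nNew] > nTimes(epochs)) {
      reasons[i] <- "span_outside_epoch"
      next
    }
    idxList[[i]] <- idx
  }
  keep <- which(!nzchar(reasons))
  if (!length(keep)) stop("no trials survive response locking")
  dropped <- table(reasons[nzchar(reasons)])
  if (length(dropped))
    message("responseLock: excluded ", sum(dropped), " trial(s) [",
            paste(names(dropped), dropped, sep = "=", collapse = ", "), "]")
  data <- array(0, dim = c(length(keep), nSensors(epochs), nNew))
  for (j in seq_along(keep))
    data[j, , ] <- epochs@data[keep[j], , idxList[[keep[j]]]]
  OrientationEpochs(data, times = tNew, sfreq = sf,
                    sensorIds = epochs@sensorIds,
                    sensorPos = epochs@sensorPos,
                    lockEvent = "response",
                    trialIds = epochs@trialIds[keep])
}
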