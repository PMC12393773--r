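#' @import methods
NULL

.LOCK_EVENTS <- c("stimulus", "probe", "response")

#' OrientationEpochs: epoched multichannel recordings
#'
#' Container for epoched neural data: a trials x sensors x times tensor with a
#' uniform time axis relative to a lock event, sensor identifiers and
#' positions, and trial identifiers aligning the tensor to a trial table.
#'
#' @slot data Three-dimensional numeric array, trials x sensors x times.
#' @slot times Numeric vector of sample times in seconds relative to the lock
#'   event; strictly increasing with uniform step \code{1/sfreq}. Sample i
#'   covers the half-open interval \code{[times[i], times[i] + 1/sfreq)}.
#' @slot sfreq Sampling frequency in Hz.
#' @slot sensorIds Character vector of sensor identifiers.
#' @slot sensorPos Numeric matrix of sensor coordinates (sensors x 2 or
#'   sensors x 3).
#' @slot lockEvent One of \code{"stimulus"}, \code{"probe"}, \code{"response"}.
#' @slot trialIds Integer vector of trial identifiers, unique, aligned to the
#'   first dimension of \code{data}.
#'
#' @seealso [OrientationEpochs()] for the constructor, [readEpochs()] and
#'   [writeEpochs()] for the on-disk container.
#' @export
setClass("OrientationEpochs",
  representation(
    data = "array",
    times = "numeric",
    sfreq = "numeric",
    sensorIds = "character",
    sensorPos = "matrix",
    lockEvent = "character",
    trialIds = "integer"
  )
)

setValidity("OrientationEpochs", function(object) {
  msg <- character()
  d <- object@data
  if (length(dim(d)) != 3L)
    msg <- c(msg, "'data' must be a 3-d array (trials x sensors x times)")
  else {
    if (dim(d)[2] != length(object@sensorIds))
      msg <- c(msg, "dim(data)[2] does not match length(sensorIds)")
    if (dim(d)[3] != length(object@times))
      msg <- c(msg, "dim(data)[3] does not match length(times)")
    if (dim(d)[1] != length(object@trialIds))
      msg <- c(msg, "dim(data)[1] does not match length(trialIds)")
    if (length(d) && !all(is.finite(d)))
      msg <- c(msg, "'data' contains non-finite values")
  }
  if (length(object@sfreq) != 1L || object@sfreq <= 0)
    msg <- c(msg, "'sfreq' must be a positive scalar")
  if (length(object@times) > 1L) {
    steps <- diff(object@times)
    if (any(steps <= 0))
      msg <- c(msg, "'times' must be strictly increasing")
    else if (max(abs(steps - 1 / object@sfreq)) > 1e-6 / object@sfreq)
      msg <- c(msg, "'times' step does not equal 1/sfreq")
  }
  if (nrow(object@sensorPos) != length(object@sensorIds))
    msg <- c(msg, "nrow(sensorPos) does not match length(sensorIds)")
  if (!ncol(object@sensorPos) %in% c(2L, 3L))
    msg <- c(msg, "'sensorPos' must have 2 or 3 columns")
  if (length(object@lockEvent) != 1L ||
      !object@lockEvent %in% .LOCK_EVENTS)
    msg <- c(msg, sprintf("'lockEvent' must be one of %s",
                          paste(.LOCK_EVENTS, collapse = ", ")))
  if (anyDuplicated(object@trialIds))
    msg <- c(msg, "'trialIds' must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct an OrientationEpochs object
#'
#' @param data Numeric array, trials x sensors x times.
#' @param times Numeric vector of sample times in seconds (uniform step
#'   \code{1/sfreq}).
#' @param sfreq Sampling frequency in Hz.
#' @param sensorIds Character vector of sensor names; defaults to
#'   \code{"S001"}, \code{"S002"}, ...
#' @param sensorPos Numeric matrix of sensor coordinates (sensors x 2 or x 3).
#' @param lockEvent Lock event the time axis is relative to: \code{"stimulus"},
#'   \code{"probe"} or \code{"response"}.
#' @param trialIds Integer trial identifiers aligned to rows of \code{data}.
#' @return A validated [OrientationEpochs-class] object.
#' @examples
#' e <- OrientationEpochs(array(0, c(2, 3, 4)), times = (0:3) / 100,
#'                        sfreq = 100, lockEvent = "probe")
#' nTrials(e)
#' @export
OrientationEpochs <- function(data, times, sfreq,
                              sensorIds = NULL, sensorPos = NULL,
                              lockEvent = "probe", trialIds = NULL) {
  data <- as.array(data)
  ns <- if (length(dim(data)) == 3L) dim(data)[2] else 0L
  if (is.null(sensorIds)) sensorIds <- sprintf("S%03d", seq_len(ns))
  if (is.null(sensorPos)) {
    pos <- sensorGridPositions(length(sensorIds))
    sensorPos <- pos
  }
  if (is.null(trialIds)) trialIds <- seq_len(dim(data)[1])
  new("OrientationEpochs",
      data = data, times = as.numeric(times), sfreq = as.numeric(sfreq),
      sensorIds = as.character(sensorIds),
      sensorPos = as.matrix(sensorPos),
      lockEvent = lockEvent, trialIds = as.integer(trialIds))
}

#' AnalysisConfig: tunable parameters of the decoding pipeline
#'
#' Bundles every tunable parameter of the decoding and inference pipeline
#' with the package defaults: a 37-sample sliding feature window, PCA
#' retaining 90 percent of variance, 10 relative-orientation bins, three
#' clockwise/counterclockwise flanking bins for the asymmetry index, 100,000
#' permutations for cluster inference, and response-time bounds of
#' 0.65-11.85 s for response-locked analyses.
#'
#' @slot windowSamples Integer >= 1; sliding-window length in samples.
#' @slot pcaVariance Fraction in (0, 1]; explained-variance ratio the PCA
#'   retains.
#' @slot nBins Even integer; number of relative-orientation bins.
#' @slot asymCwBins,asymCcwBins Integer bin indices (1-based over the bins in
#'   increasing center order) contributing clockwise / counterclockwise
#'   evidence to the asymmetry index.
#' @slot nPermutations Integer; permutations for cluster inference.
#' @slot clusterAlpha Cluster-forming alpha (two-tailed, sample level).
#' @slot rtBounds Length-2 numeric; inclusive RT bounds in seconds outside of
#'   which trials are dropped from response-locked analyses.
#' @slot covEstimator \code{"shrinkage"} or \code{"identity"}; covariance used
#'   for Mahalanobis whitening.
#' @slot pcaFoldwise Logical; refit the PCA inside each leave-one-out fold
#'   (leakage-free) instead of once on all trials.
#' @slot seed Integer seed recorded with pipeline runs.
#' @export
setClass("AnalysisConfig",
  representation(
    windowSamples = "integer",
    pcaVariance = "numeric",
    nBins = "integer",
    asymCwBins = "integer",
    asymCcwBins = "integer",
    nPermutations = "integer",
    clusterAlpha = "numeric",
    rtBounds = "numeric",
    covEstimator = "character",
    pcaFoldwise = "logical",
    seed = "integer"
  ),
  prototype(
    windowSamples = 37L,
    pcaVariance = 0.90,
    nBins = 10L,
    asymCwBins = 2:4,
    asymCcwBins = 7:9,
    nPermutations = 100000L,
    clusterAlpha = 0.05,
    rtBounds = c(0.65, 11.85),
    covEstimator = "shrinkage",
    pcaFoldwise = FALSE,
    seed = 1L
  )
)

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  if (object@windowSamples < 1L)
    msg <- c(msg, "'windowSamples' must be >= 1")
  if (object@pcaVariance <= 0 || object@pcaVariance > 1)
    msg <- c(msg, "'pcaVariance' must be in (0, 1]")
  if (object@nBins < 2L || object@nBins %% 2L != 0L)
    msg <- c(msg, "'nBins' must be an even integer >= 2")
  cw <- object@asymCwBins; ccw <- object@asymCcwBins
  if (length(intersect(cw, ccw)))
    msg <- c(msg, "asymmetry bin sets must be disjoint")
  if (any(c(cw, ccw) < 1L) || any(c(cw, ccw) > object@nBins))
    msg <- c(msg, "asymmetry bin indices out of range")
  # mirror symmetry about 0 degrees: bin i mirrors bin nBins + 1 - i
  if (!setequal(object@nBins + 1L - cw, ccw))
    msg <- c(msg, "asymmetry bin sets must be mirror-symmetric about 0 degrees")
  if (object@nPermutations < 1L)
    msg <- c(msg, "'nPermutations' must be >= 1")
  if (object@clusterAlpha <= 0 || object@clusterAlpha >= 1)
    msg <- c(msg, "'clusterAlpha' must be in (0, 1)")
  if (length(object@rtBounds) != 2L || object@rtBounds[1] >= object@rtBounds[2])
    msg <- c(msg, "'rtBounds' must be an increasing pair of seconds")
  if (!object@covEstimator %in% c("shrinkage", "identity"))
    msg <- c(msg, "'covEstimator' must be \"shrinkage\" or \"identity\"")
  if (length(msg)) msg else TRUE
})

#' Construct an AnalysisConfig
#'
#' @param windowSamples Sliding feature-window length in samples (default 37,
#'   i.e. 148 ms at 250 Hz).
#' @param pcaVariance Explained-variance fraction retained by PCA
#'   (default 0.90).
#' @param nBins Number of relative-orientation bins (default 10, 18 degrees
#'   each over the 180-degree circle).
#' @param asymCwBins,asymCcwBins Bin indices used as clockwise /
#'   counterclockwise evidence; the defaults are the three flanking bins on
#'   each side (centers -63, -45, -27 and +27, +45, +63 degrees), excluding
#'   the two central and two extreme bins.
#' @param nPermutations Permutations for cluster-based inference
#'   (default 100000).
#' @param clusterAlpha Sample-level cluster-forming alpha (default 0.05).
#' @param rtBounds Response-time bounds in seconds for response-locked
#'   analyses (default \code{c(0.65, 11.85)}).
#' @param covEstimator \code{"shrinkage"} (default) or \code{"identity"}.
#' @param pcaFoldwise Refit PCA within each leave-one-out fold (default
#'   \code{FALSE}: PCA is fit once per time point on all trials).
#' @param seed Integer seed recorded in pipeline manifests.
#' @return A validated [AnalysisConfig-class] object.
#' @examples
#' cfg <- analysisConfig(windowSamples = 5, nPermutations = 1000)
#' @export
analysisConfig <- function(windowSamples = 37L, pcaVariance = 0.90,
                           nBins = 10L, asymCwBins = 2:4, asymCcwBins = 7:9,
                           nPermutations = 100000L, clusterAlpha = 0.05,
                           rtBounds = c(0.65, 11.85),
                           covEstimator = "shrinkage",
                           pcaFoldwise = FALSE, seed = 1L) {
  new("AnalysisConfig",
      windowSamples = as.integer(windowSamples),
      pcaVariance = pcaVariance,
      nBins = as.integer(nBins),
      asymCwBins = as.integer(asymCwBins),
      asymCcwBins = as.integer(asymCcwBins),
      nPermutations = as.integer(nPermutations),
      clusterAlpha = clusterAlpha,
      rtBounds = rtBounds,
      covEstimator = covEstimator,
      pcaFoldwise = pcaFoldwise,
      seed = as.integer(seed))
}

#' DecodingResult: per-trial tuning curves and decoding evidence
#'
#' Output of [decodeTimecourse()]: per-trial, per-time tuning curves
#' (mean-centered, sign-reversed Mahalanobis similarities over the
#' relative-orientation bins) together with the cosine-projected decoding
#' evidence.
#'
#' @slot evidence Numeric matrix, trials x times; decoding evidence. \code{NA}
#'   where the tuning curve was undefined (empty bin or truncated window).
#' @slot tuning Numeric array, trials x bins x times of similarities.
#' @slot times Numeric vector of decoded sample times (seconds).
#' @slot trialIds Integer identifiers of the decoded trials.
#' @slot label Decoded item: \code{"target"}, \code{"previous_target"},
#'   \code{"sample1"}, \code{"sample2"} or \code{"report"}.
#' @slot lockEvent Lock event of the source epochs.
#' @slot binCenters Bin centers in degrees.
#' @export
setClass("DecodingResult",
  representation(
    evidence = "matrix",
    tuning = "array",
    times = "numeric",
    trialIds = "integer",
    label = "character",
    lockEvent = "character",
    binCenters = "numeric"
  )
)

#' ClusterResult: cluster-based permutation test outcome
#'
#' @slot clusters A data.frame with one row per supra-threshold cluster:
#'   \code{t_start}, \code{t_end} (seconds), \code{mass} (summed t values) and
#'   \code{p} (permutation p-value).
#' @slot nPermutations Number of sign-flip permutations used.
#' @slot clusterAlpha Sample-level cluster-forming alpha.
#' @slot tail Always \code{"two"}: positive and negative clusters are pooled
#'   against the max-|mass| null.
#' @export
setClass("ClusterResult",
  representation(
    clusters = "data.frame",
    nPermutations = "integer",
    clusterAlpha = "numeric",
    tail = "character"
  )
)

setValidity("ClusterResult", function(object) {
  cl <- object@clusters
  msg <- character()
  need <- c("t_start", "t_end", "mass", "p")
  if (!all(need %in% names(cl)))
    msg <- c(msg, "clusters must have columns t_start, t_end, mass, p")
  else if (nrow(cl)) {
    if (any(cl$p < 1 / (object@nPermutations + 1) - 1e-12))
      msg <- c(msg, "cluster p-values below 1/(nPermutations + 1)")
    if (is.unsorted(cl$t_start))
      msg <- c(msg, "clusters must be ordered by onset")
    if (nrow(cl) > 1L && any(cl$t_start[-1] <= cl$t_end[-nrow(cl)]))
      msg <- c(msg, "clusters must be non-overlapping")
  }
  if (length(msg)) msg else TRUE
})
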