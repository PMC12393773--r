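#' @rdname OrientationEpochs-class
#' @export
setMethod("epochsData", "OrientationEpochs", function(x) x@data)

#' @rdname OrientationEpochs-class
#' @export
setMethod("epochTimes", "OrientationEpochs", function(x) x@times)

#' @rdname OrientationEpochs-class
#' @export
setMethod("samplingRate", "OrientationEpochs", function(x) x@sfreq)

#' @rdname OrientationEpochs-class
#' @export
setMethod("sensorIds", "OrientationEpochs", function(x) x@sensorIds)

#' @rdname OrientationEpochs-class
#' @export
setMethod("sensorPositions", "OrientationEpochs", function(x) x@sensorPos)

#' @rdname OrientationEpochs-class
#' @export
setMethod("lockEvent", "OrientationEpochs", function(x) x@lockEvent)

#' @rdname OrientationEpochs-class
#' @export
setMethod("trialIds", "OrientationEpochs", function(x) x@trialIds)

#' @rdname OrientationEpochs-class
#' @export
setMethod("nTrials", "OrientationEpochs", function(x) dim(x@data)[1])

#' @rdname OrientationEpochs-class
#' @export
setMethod("nSensors", "OrientationEpochs", function(x) dim(x@data)[2])

#' @rdname OrientationEpochs-class
#' @export
setMethod("nTimes", "OrientationEpochs", function(x) dim(x@data)[3])

#' Subset epochs by trial and sensor
#'
#' \code{x[i, j]} keeps trials \code{i} (positions or logical over rows) and
#' sensors \code{j}; the time axis is untouched.
#'
#' @param x An \code{OrientationEpochs}.
#' @param i Trial subscript (integer positions or logical).
#' @param j Sensor subscript.
#' @param ... Ignored.
#' @param drop Ignored (dimensions are always kept).
#' @export
setMethod("[", "OrientationEpochs", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nTrials(x))
  if (missing(j)) j <- seq_len(nSensors(x))
  initialize(x,
             data = x@data[i, j, , drop = FALSE],
             sensorIds = x@sensorIds[j],
             sensorPos = x@sensorPos[j, , drop = FALSE],
             trialIds = x@trialIds[i])
})

#' Crop epochs to a time interval
#'
#' Keeps samples whose times fall in \code{[tmin, tmax]} (inclusive).
#'
#' @param x An \code{OrientationEpochs}.
#' @param tmin,tmax Interval bounds in seconds.
#' @return An \code{OrientationEpochs} restricted to the interval.
#' @export
cropEpochs <- function(x, tmin = -Inf, tmax = Inf) {
  keep <- which(x@times >= tmin & x@times <= tmax)
  if (!length(keep))
    stop("cropEpochs: no samples in [", tmin, ", ", tmax, "]")
  initialize(x, data = x@data[, , keep, drop = FALSE], times = x@times[keep])
}

setMethod("show", "OrientationEpochs", function(object) {
  cat("OrientationEpochs:", nTrials(object), "trials x",
      nSensors(object), "sensors x", nTimes(object), "samples\n")
  if (nTimes(object))
    cat(sprintf("  time: %.3f .. %.3f s (%g Hz), locked to %s\n",
                min(object@times), max(object@times), object@sfreq,
                object@lockEvent))
  invisible(NULL)
})

setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig\n")
  cat("  windowSamples:", object@windowSamples,
      " pcaVariance:", object@pcaVariance,
      " nBins:", object@nBins, "\n")
  cat("  asymmetry bins (cw | ccw):",
      paste(object@asymCwBins, collapse = ","), "|",
      paste(object@asymCcwBins, collapse = ","), "\n")
  cat("  nPermutations:", object@nPermutations,
      " clusterAlpha:", object@clusterAlpha, "\n")
  cat("  rtBounds:", paste(object@rtBounds, collapse = "-"),
      "s  cov:", object@covEstimator,
      " pcaFoldwise:", object@pcaFoldwise, "\n")
  invisible(NULL)
})

#' @rdname DecodingResult-class
#' @export
setMethod("decodingEvidenceMatrix", "DecodingResult", function(x) x@evidence)

#' @rdname DecodingResult-class
#' @export
setMethod("tuningCurves", "DecodingResult", function(x) x@tuning)

setMethod("show", "DecodingResult", function(object) {
  cat("DecodingResult:", object@label, "(", object@lockEvent, "-locked )\n")
  cat("  ", nrow(object@evidence), "trials x", length(object@times),
      "time points;", sum(is.na(object@evidence)), "missing cells\n")
  ev <- colMeans(object@evidence, na.rm = TRUE)
  if (length(ev))
    cat(sprintf("  mean evidence: %.4f (range %.4f .. %.4f)\n",
                mean(ev, na.rm = TRUE), min(ev, na.rm = TRUE),
                max(ev, na.rm = TRUE)))
  invisible(NULL)
})

#' @rdname ClusterResult-class
#' @export
setMethod("clusters", "ClusterResult", function(x) x@clusters)

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult:", nrow(object@clusters), "cluster(s),",
      object@nPermutations, "permutations\n")
  if (nrow(object@clusters)) {
    for (i in seq_len(nrow(object@clusters))) {
      cl <- object@clusters[i, ]
      cat(sprintf("  %.3f .. %.3f s  mass %.2f  p = %.5g\n",
                  cl$t_start, cl$t_end, cl$mass, cl$p))
    }
  }
  invisible(NULL)
})
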