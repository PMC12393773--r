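# Sensor-space searchlight maps and topography comparison.

#' Sensor neighborhoods by Euclidean distance
#'
#' For each sensor, the indices of the \code{k} nearest sensors (itself
#' included; ties broken by sensor index).
#'
#' @param sensorPos Numeric matrix of sensor coordinates (sensors x 2 or 3).
#' @param k Neighborhood size, \code{1 <= k <= nrow(sensorPos)}.
#' @return Integer matrix, sensors x k; row s holds the neighborhood of
#'   sensor s.
#' @export
sensorNeighborhoods <- function(sensorPos, k) {
  n <- nrow(sensorPos)
  if (k > n) stop("k = ", k, " exceeds the number of sensors (", n, ")")
  if (k < 1L) stop("k must be >= 1")
  D <- as.matrix(stats::dist(sensorPos))
  t(apply(D, 1, function(d) order(d, seq_len(n))[seq_len(k)]))
}

#' Searchlight topography of decoding evidence or neural bias
#'
#' For each sensor, repeats the full analysis (leave-one-trial-out decoding,
#' and for \code{statistic = "bias"} the inducer-sorted asymmetry
#' difference) on the sensor plus its \code{k - 1} nearest neighbors, and
#' averages the result over the given time window. The default neighborhood
#' size of 48 corresponds to a sensor plus its 47 closest neighbors.
#'
#' @param epochs The participant's [OrientationEpochs-class].
#' @param trials The participant's trial data.frame.
#' @param statistic \code{"evidence"} (decoding evidence of \code{label}) or
#'   \code{"bias"} (neural-bias index for \code{inducer}).
#' @param label Item to decode (default \code{"target"}).
#' @param inducer Inducer for \code{statistic = "bias"}.
#' @param window Time window \code{c(t0, t1)} in seconds over which the
#'   statistic is averaged; default: the whole decoded range.
#' @param k Neighborhood size (default 48).
#' @param config An [analysisConfig()].
#' @param timeIndices Optional sample indices passed to
#'   [decodeTimecourse()].
#' @return A data.frame with one row per sensor: \code{sensor_id},
#'   \code{x}, \code{y} and \code{value}.
#' @export
searchlightMap <- function(epochs, trials,
                           statistic = c("evidence", "bias"),
                           label = "target", inducer = "previous_target",
                           window = NULL, k = 48L,
                           config = analysisConfig(), timeIndices = NULL) {
  statistic <- match.arg(statistic)
  nb <- sensorNeighborhoods(sensorPositions(epochs), k)
  vals <- numeric(nSensors(epochs))
  for (s in seq_len(nSensors(epochs))) {
    sub <- epochs[, nb[s, ]]
    if (statistic == "evidence") {
      res <- decodeTimecourse(sub, trials, label, config, timeIndices)
      tc <- colMeans(decodingEvidenceMatrix(res), na.rm = TRUE)
      win <- if (is.null(window)) range(res@times) else window
      vals[s] <- windowAverage(tc, res@times, win)
    } else {
      res <- decodeTimecourse(sub, trials, "target", config, timeIndices)
      win <- if (is.null(window)) range(res@times) else window
      vals[s] <- participantNeuralBias(sub, trials, inducer, win,
                                       config, result = res)
    }
  }
  data.frame(sensor_id = sensorIds(epochs),
             x = sensorPositions(epochs)[, 1],
             y = sensorPositions(epochs)[, 2],
             value = vals, stringsAsFactors = FALSE)
}

#' Pearson correlation between two sensor topographies
#'
#' @param mapA,mapB Numeric vectors of per-sensor values, or data.frames
#'   from [searchlightMap()] (matched by \code{sensor_id}).
#' @return A list with \code{rho} (Pearson correlation across sensors) and
#'   \code{p} (two-sided).
#' @export
topographyCorrelation <- function(mapA, mapB) {
  if (is.data.frame(mapA)) {
    stopifnot(is.data.frame(mapB))
    m <- match(mapA$sensor_id, mapB$sensor_id)
    stopifnot(!anyNA(m))
    a <- mapA$value; b <- mapB$value[m]
  } else {
    a <- mapA; b <- mapB
  }
  stopifnot(length(a) == length(b))
  ct <- stats::cor.test(a, b, method = "pearson")
  list(rho = unname(ct$estimate), p = ct$p.value)
}
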