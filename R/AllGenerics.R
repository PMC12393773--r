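#' @rdname OrientationEpochs-class
#' @param object,x An object.
#' @export
setGeneric("epochsData", function(x) standardGeneric("epochsData"))

#' @rdname OrientationEpochs-class
#' @export
setGeneric("epochTimes", function(x) standardGeneric("epochTimes"))

#' @rdname OrientationEpochs-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname OrientationEpochs-class
#' @export
setGeneric("sensorIds", function(x) standardGeneric("sensorIds"))

#' @rdname OrientationEpochs-class
#' @export
setGeneric("sensorPositions", function(x) standardGeneric("sensorPositions"))

#' @rdname OrientationEpochs-class
#' @export
setGeneric("lockEvent", function(x) standardGeneric("lockEvent"))

#' @rdname OrientationEpochs-class
#' @export
setGeneric("trialIds", function(x) standardGeneric("trialIds"))

#' @rdname OrientationEpochs-class
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname OrientationEpochs-class
#' @export
setGeneric("nSensors", function(x) standardGeneric("nSensors"))

#' @rdname OrientationEpochs-class
#' @export
setGeneric("nTimes", function(x) standardGeneric("nTimes"))

#' @rdname DecodingResult-class
#' @param x A \code{DecodingResult}.
#' @export
setGeneric("decodingEvidenceMatrix",
           function(x) standardGeneric("decodingEvidenceMatrix"))

#' @rdname DecodingResult-class
#' @export
setGeneric("tuningCurves", function(x) standardGeneric("tuningCurves"))

#' @rdname ClusterResult-class
#' @param x A \code{ClusterResult}.
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))
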