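# Asymmetry-index estimation of neural representational biases.

#' Asymmetry index of a tuning curve
#'
#' Mean similarity over the clockwise evidence bins minus the mean over the
#' counterclockwise bins (defaults: the three flanking bins on each side,
#' centers -63, -45, -27 vs +27, +45, +63 degrees). Positive values indicate
#' a clockwise-shifted neural representation. Exactly invariant to adding a
#' constant to the whole curve, so per-participant mean-centering cannot
#' change it.
#'
#' @param curve Numeric vector of bin similarities (a tuning curve), or a
#'   matrix with one curve per row, bins in increasing-center order.
#' @param cwBins,ccwBins Integer bin indices for the clockwise /
#'   counterclockwise evidence (defaults \code{2:4} and \code{7:9} of 10).
#' @return Scalar index (or one value per row for matrix input); \code{NA}
#'   where the curve is missing.
#' @export
asymmetryIndex <- function(curve, cwBins = 2:4, ccwBins = 7:9) {
  if (is.matrix(curve)) {
    return(rowMeans(curve[, cwBins, drop = FALSE]) -
           rowMeans(curve[, ccwBins, drop = FALSE]))
  }
  mean(curve[cwBins]) - mean(curve[ccwBins])
}

#' Sort trials into clockwise- and counterclockwise-inducer groups
#'
#' Trials where the inducer lies clockwise of the target (relative
#' orientation < 0) versus counterclockwise (> 0). Trials whose relative
#' orientation is exactly 0 or exactly +/-90 degrees are excluded from both
#' groups (the two closed intervals would otherwise double-count them); the
#' exclusion counts are reported via a message. For \code{inducer =
#' "report"}, the stimulus-dependent report bias is corrected per participant
#' first (see [correctStimulusDependentBias()]) and the sorting uses the
#' corrected report orientation.
#'
#' @param trials A validated trial data.frame (one participant).
#' @param inducer \code{"previous_target"}, \code{"sample1"} or
#'   \code{"report"}.
#' @param correctReport Apply the stimulus-dependent-bias correction before
#'   report-sorting (default \code{TRUE}).
#' @return A list with \code{cw_ids}, \code{ccw_ids} (trial ids),
#'   \code{n_excluded_boundary} and \code{n_missing}.
#' @export
sortByInducer <- function(trials,
                          inducer = c("previous_target", "sample1",
                                      "report"),
                          correctReport = TRUE) {
  inducer <- match.arg(inducer)
  trials <- validateTrialTable(trials)
  if (inducer == "report" && correctReport) {
    corrected <- correctStimulusDependentBias(trials$signed_error,
                                              trials$target_orientation)
    indOri <- wrapOrientation(trials$target_orientation +
                                as.numeric(corrected))
  } else {
    indOri <- switch(inducer,
                     previous_target = trials$previous_target_orientation,
                     sample1 = trials$sample1_orientation,
                     report = trials$report_orientation)
  }
  delta <- relativeOrientation(indOri, trials$target_orientation)
  missing <- is.na(delta)
  boundary <- !missing & (delta == 0 | abs(delta) == 90)
  cw <- !missing & !boundary & delta < 0
  ccw <- !missing & !boundary & delta > 0
  if (any(boundary))
    message("sortByInducer: excluded ", sum(boundary),
            " boundary trial(s) (relative orientation exactly 0 or 90)")
  if (!any(cw) || !any(ccw))
    warning("sortByInducer: empty ", if (!any(cw)) "clockwise"
            else "counterclockwise",
            " group; bias undefined for this participant")
  list(cw_ids = trials$trial_id[cw], ccw_ids = trials$trial_id[ccw],
       n_excluded_boundary = sum(boundary), n_missing = sum(missing))
}

#' Neural-bias time course from per-trial asymmetry indices
#'
#' For each time point, the asymmetry index is averaged within the
#' clockwise-inducer and counterclockwise-inducer trial groups and the
#' difference (clockwise minus counterclockwise) taken. A clockwise inducer
#' attracting the representation shifts it clockwise (positive asymmetry),
#' so positive bias = attraction toward the inducer.
#'
#' @param asym Numeric matrix of asymmetry indices, trials x times (e.g.
#'   \code{asymmetryIndex(tuningCurves(result)[, , t])} stacked over time, or
#'   see [participantNeuralBias()]).
#' @param trialIds Trial ids aligned to rows of \code{asym}.
#' @param sorting A list from [sortByInducer()].
#' @return Numeric vector: bias per time point (positive = attraction).
#' @export
neuralBiasTimecourse <- function(asym, trialIds, sorting) {
  stopifnot(is.matrix(asym), nrow(asym) == length(trialIds))
  cw <- trialIds %in% sorting$cw_ids
  ccw <- trialIds %in% sorting$ccw_ids
  colMeans(asym[cw, , drop = FALSE], na.rm = TRUE) -
    colMeans(asym[ccw, , drop = FALSE], na.rm = TRUE)
}

#' Average a time course over a fixed window
#'
#' @param values Numeric vector (one value per time point) or matrix
#'   (trials x times).
#' @param times Sample times in seconds aligned to \code{values}.
#' @param window Length-2 numeric: inclusive window \code{[t0, t1]} in
#'   seconds.
#' @return The mean over in-window samples (per row for matrix input).
#' @export
windowAverage <- function(values, times, window) {
  sel <- which(times >= window[1] & times <= window[2])
  if (!length(sel)) stop("window [", window[1], ", ", window[2],
                         "] contains no samples")
  if (is.matrix(values)) {
    stopifnot(ncol(values) == length(times))
    return(rowMeans(values[, sel, drop = FALSE], na.rm = TRUE))
  }
  stopifnot(length(values) == length(times))
  mean(values[sel], na.rm = TRUE)
}

#' Average per-trial time courses over per-trial variable windows
#'
#' For each trial, averages the samples from \code{startTime} up to (but
#' excluding) that trial's rotation-start time, then returns the per-trial
#' means. Trials whose window contains no samples are dropped (\code{NA})
#' and counted in the \code{"n_empty"} attribute.
#'
#' @param values Numeric matrix, trials x times.
#' @param times Sample times in seconds.
#' @param startTime Window start in seconds (e.g. retrocue or probe onset).
#' @param rotationStart Numeric vector of per-trial rotation-start times in
#'   seconds (same trial order as the rows of \code{values}).
#' @return Numeric vector of per-trial means (\code{NA} for empty windows),
#'   with attribute \code{"n_empty"}.
#' @export
perTrialWindowAverage <- function(values, times, startTime, rotationStart) {
  stopifnot(is.matrix(values), ncol(values) == length(times),
            nrow(values) == length(rotationStart))
  out <- rep(NA_real_, nrow(values))
  for (i in seq_len(nrow(values))) {
    rs <- rotationStart[i]
    if (is.na(rs)) next
    sel <- which(times >= startTime & times < rs)
    if (length(sel))
      out[i] <- mean(values[i, sel], na.rm = TRUE)
  }
  attr(out, "n_empty") <- sum(is.na(out))
  out
}

#' Per-participant neural-bias index
#'
#' Convenience wrapper running the full neural-bias estimation for one
#' participant: decode the target with leave-one-trial-out tuning curves,
#' compute per-trial asymmetry indices over time, sort trials by the
#' inducer, difference the group means, and average over the requested
#' window.
#'
#' @param epochs The participant's [OrientationEpochs-class].
#' @param trials The participant's trial data.frame.
#' @param inducer \code{"previous_target"}, \code{"sample1"} or
#'   \code{"report"}.
#' @param window Fixed window \code{c(t0, t1)} in seconds, or \code{NULL} to
#'   return the full time course.
#' @param config An [analysisConfig()].
#' @param timeIndices Optional sample indices passed to
#'   [decodeTimecourse()].
#' @param result Optionally, a precomputed [DecodingResult-class] for the
#'   target (skips the decode).
#' @return If \code{window} is \code{NULL}, a list with \code{times} and
#'   \code{bias} (the time course); otherwise the scalar windowed bias
#'   (positive = attraction toward the inducer).
#' @export
participantNeuralBias <- function(epochs, trials,
                                  inducer = "previous_target",
                                  window = NULL,
                                  config = analysisConfig(),
                                  timeIndices = NULL, result = NULL) {
  if (is.null(result))
    result <- decodeTimecourse(epochs, trials, "target", config, timeIndices)
  tun <- tuningCurves(result)
  asym <- sapply(seq_along(result@times), function(t)
    asymmetryIndex(tun[, , t, drop = TRUE],
                   config@asymCwBins, config@asymCcwBins))
  asym <- matrix(asym, nrow = dim(tun)[1])
  m <- match(result@trialIds, trials$trial_id)
  sorting <- sortByInducer(trials[m, , drop = FALSE], inducer)
  bias <- neuralBiasTimecourse(asym, result@trialIds, sorting)
  if (is.null(window))
    return(list(times = result@times, bias = bias))
  windowAverage(bias, result@times, window)
}
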