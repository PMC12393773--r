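# Model-free behavioral serial-bias estimation and stimulus-dependent-bias
# correction.

#' Model-free serial-bias index
#'
#' The averaged signed report error is computed separately for trials where
#' the inducer lies within 45 degrees counterclockwise (\code{delta} in
#' \code{(0, 45]}) versus clockwise (\code{delta} in \code{[-45, 0)}) of the
#' target; the index is their difference. Positive values indicate attraction
#' toward the inducer. Trials with \code{delta} exactly 0 are excluded from
#' both sides; \code{|delta| > 45} trials do not enter.
#'
#' @param errors Signed report errors in degrees.
#' @param deltas Inducer orientation relative to the target, degrees in
#'   \code{(-90, 90]} (from [relativeOrientation()]).
#' @return The serial-bias index in degrees.
#' @examples
#' serialBiasIndex(c(2, 2, -2, -2), c(10, 30, -10, -30))  # +4: attraction
#' @export
serialBiasIndex <- function(errors, deltas) {
  stopifnot(length(errors) == length(deltas))
  ok <- !is.na(errors) & !is.na(deltas)
  errors <- errors[ok]; deltas <- deltas[ok]
  if (any(deltas <= -90 | deltas > 90))
    stop("deltas must lie in (-90, 90]")
  ccw <- deltas > 0 & deltas <= 45
  cw <- deltas < 0 & deltas >= -45
  if (!any(ccw))
    stop("serial-bias index undefined: no trials on the counterclockwise ",
         "(delta in (0, 45]) side")
  if (!any(cw))
    stop("serial-bias index undefined: no trials on the clockwise ",
         "(delta in [-45, 0)) side")
  mean(errors[ccw]) - mean(errors[cw])
}

#' Overlapping-bin smoothing of the bias curve (visualization only)
#'
#' Bins the inducer's relative orientation into \code{nBins} evenly spaced,
#' overlapping bins over \code{(-90, 90]}; each bin averages the errors of
#' the \code{frac} fraction of trials closest (in circular distance on the
#' 180-degree circle) to its center. Intended purely for plotting; never
#' feeds inference.
#'
#' @param errors Signed report errors in degrees.
#' @param deltas Inducer-relative orientations in \code{(-90, 90]}.
#' @param nBins Number of bin centers (default 64).
#' @param frac Fraction of trials per bin (default 0.25).
#' @return A data.frame with \code{bin_center}, \code{mean_error}, \code{n}.
#' @export
smoothBiasCurve <- function(errors, deltas, nBins = 64L, frac = 0.25) {
  ok <- !is.na(errors) & !is.na(deltas)
  errors <- errors[ok]; deltas <- deltas[ok]
  N <- length(errors)
  m <- round(frac * N)
  if (N * frac < 1)
    stop("smoothBiasCurve: frac * N < 1; no trials per bin")
  centers <- -90 + seq_len(nBins) * 180 / nBins
  mean_error <- vapply(centers, function(ctr) {
    d <- abs(relativeOrientation(deltas, ctr))
    mean(errors[order(d)[seq_len(m)]])
  }, numeric(1))
  data.frame(bin_center = centers, mean_error = mean_error, n = m)
}

#' Correct stimulus-dependent (cardinal/oblique) report biases
#'
#' Fits a sum of three sinusoids of the target orientation to the report
#' errors of one participant and subtracts the fit. Frequencies are searched
#' exhaustively over all triples of integer harmonics (1-8 cycles per 180
#' degrees); for each triple, amplitude and phase are estimated by
#' closed-form least squares in the sine/cosine parameterization, and the
#' triple with the lowest residual sum of squares wins. The procedure is
#' deterministic and its RSS never exceeds that of the zero model.
#'
#' @param errors Signed report errors in degrees (one participant).
#' @param targets Target orientations in degrees, \code{[0, 180)}.
#' @param maxHarmonic Highest candidate frequency in cycles per 180 degrees
#'   (default 8).
#' @return Numeric vector of corrected errors (\code{errors - fitted}), with
#'   attributes \code{"frequencies"} (the winning harmonic triple),
#'   \code{"fitted"} and \code{"rss"}.
#' @examples
#' th <- runif(200) * 180
#' err <- 3 * sin(4 * th * pi / 180) + rnorm(200, 0, 0.1)
#' corrected <- correctStimulusDependentBias(err, th)
#' sd(corrected)  # residual noise only
#' @export
correctStimulusDependentBias <- function(errors, targets, maxHarmonic = 8L) {
  ok <- !is.na(errors) & !is.na(targets)
  if (sum(ok) < 7L) {
    warning("too few trials to fit the 3-sinusoid correction; ",
            "returning errors unchanged")
    out <- errors
    attr(out, "frequencies") <- integer(0)
    attr(out, "fitted") <- rep(0, length(errors))
    attr(out, "rss") <- sum(errors[ok]^2)
    return(out)
  }
  y <- errors[ok]
  th <- targets[ok]
  combos <- utils::combn(seq_len(maxHarmonic), 3L)
  basis <- lapply(seq_len(maxHarmonic), function(f) {
    ang <- 2 * pi * f * th / 180
    cbind(sin(ang), cos(ang))
  })
  best <- list(rss = Inf)
  for (j in seq_len(ncol(combos))) {
    fr <- combos[, j]
    X <- do.call(cbind, basis[fr])
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    if (rss < best$rss)
      best <- list(rss = rss, freqs = fr, coef = fit$coefficients)
  }
  fitted_all <- rep(0, length(errors))
  Xall <- do.call(cbind, lapply(best$freqs, function(f) {
    ang <- 2 * pi * f * targets / 180
    cbind(sin(ang), cos(ang))
  }))
  cf <- best$coef
  cf[is.na(cf)] <- 0
  fitted_all[!is.na(targets)] <-
    (Xall %*% cf)[!is.na(targets)]
  out <- errors - fitted_all
  attr(out, "frequencies") <- best$freqs
  attr(out, "fitted") <- fitted_all
  attr(out, "rss") <- best$rss
  out
}

#' Per-participant serial-bias estimates for a given inducer
#'
#' Applies [serialBiasIndex()] participant-wise after selecting the trials
#' eligible for the requested inducer: \code{"previous_target"} uses every
#' trial with a previous target; \code{"sample1"} uses sample-2-cued trials
#' where sample 1 was shown; \code{"sample2_on_sample1"} uses sample-1-cued
#' trials where sample 2 was shown.
#'
#' @param trials A validated trial data.frame (possibly many participants).
#' @param inducer One of \code{"previous_target"}, \code{"sample1"},
#'   \code{"sample2_on_sample1"}.
#' @param correctCardinal Subtract the 3-sinusoid stimulus-dependent-bias fit
#'   (per participant) before computing the index (default \code{FALSE}).
#' @return A data.frame with one row per participant: \code{participant_id},
#'   \code{inducer}, \code{index} (degrees, positive = attraction),
#'   \code{n_cw}, \code{n_ccw}.
#' @export
serialBiasEstimates <- function(trials,
                                inducer = c("previous_target", "sample1",
                                            "sample2_on_sample1"),
                                correctCardinal = FALSE) {
  inducer <- match.arg(inducer)
  trials <- validateTrialTable(trials)
  res <- lapply(split(trials, trials$participant_id), function(tt) {
    err <- tt$signed_error
    if (correctCardinal)
      err <- as.numeric(correctStimulusDependentBias(
        err, tt$target_orientation))
    sel_delta <- switch(inducer,
      previous_target = relativeOrientation(
        tt$previous_target_orientation, tt$target_orientation),
      sample1 = ifelse(tt$cued_item == "sample2",
        relativeOrientation(tt$sample1_orientation, tt$target_orientation),
        NA_real_),
      sample2_on_sample1 = ifelse(tt$cued_item == "sample1",
        relativeOrientation(tt$sample2_orientation, tt$target_orientation),
        NA_real_))
    ok <- !is.na(sel_delta) & !is.na(err)
    d <- sel_delta[ok]; e <- err[ok]
    data.frame(participant_id = tt$participant_id[1],
               inducer = inducer,
               index = serialBiasIndex(e, d),
               n_cw = sum(d < 0 & d >= -45),
               n_ccw = sum(d > 0 & d <= 45),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Correlate serial bias with recall performance across participants
#'
#' Pearson correlation between per-participant bias indices and mean absolute
#' recall error.
#'
#' @param bias Numeric vector of per-participant bias indices.
#' @param meanAbsError Numeric vector of per-participant mean absolute recall
#'   errors (same order).
#' @return A list with \code{r} (Pearson correlation) and \code{p}
#'   (two-sided).
#' @export
biasPerformanceCorrelation <- function(bias, meanAbsError) {
  stopifnot(length(bias) == length(meanAbsError))
  ct <- stats::cor.test(bias, meanAbsError, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
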