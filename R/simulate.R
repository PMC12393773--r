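# Synthetic task sequences, biased behavioral reports, and orientation-tuned
# multichannel epochs. All generators are pure functions of (inputs, seed).

.withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Sensor positions on a regular grid within a disc
#'
#' Lays \code{n} sensors on a square grid restricted to the unit disc
#' (densest grid whose in-disc point count reaches \code{n}), mimicking a
#' planar sensor-array geometry for the searchlight and spatial-noise models.
#'
#' @param n Number of sensors.
#' @return An \code{n} x 2 numeric matrix of coordinates in the unit disc.
#' @export
sensorGridPositions <- function(n) {
  if (n < 1L) return(matrix(numeric(0), 0, 2))
  m <- ceiling(sqrt(n))
  repeat {
    g <- seq(-1, 1, length.out = m)
    pts <- as.matrix(expand.grid(x = g, y = g))
    keep <- pts[, 1]^2 + pts[, 2]^2 <= 1 + 1e-9
    pts <- pts[keep, , drop = FALSE]
    if (nrow(pts) >= n) {
      ord <- order(pts[, 1]^2 + pts[, 2]^2, pts[, 1], pts[, 2])
      pts <- pts[ord[seq_len(n)], , drop = FALSE]
      rownames(pts) <- NULL
      return(pts)
    }
    m <- m + 1L
  }
}

#' Parameters of the behavioral report generator
#'
#' Defaults emulate the serial biases the package is built to measure: an
#' attractive previous-target bias and a repulsive within-trial sample-1 bias
#' of a few degrees, a cardinal (stimulus-dependent) repulsion, circular
#' Gaussian report noise, rare swap errors and log-normal response times.
#'
#' @param dogAmpPrev Peak shift (degrees) of the previous-target
#'   derivative-of-Gaussian bias; positive = attraction (default 2).
#' @param dogWidthPrev Width (degrees) at which the previous-target bias
#'   peaks (default 20).
#' @param dogAmpS1 Peak shift of the within-trial sample-1 bias on
#'   sample-2-cued reports; negative = repulsion (default -1.5).
#' @param dogWidthS1 Width of the sample-1 bias (default 25).
#' @param cardinalAmp Amplitude (degrees) of the stimulus-dependent
#'   (cardinal/oblique) bias (default 2).
#' @param cardinalFreq Frequency of that bias in cycles per 180 degrees
#'   (default 2, i.e. a sin(4 theta) family term).
#' @param reportNoiseSd Circular Gaussian report noise s.d. in degrees
#'   (default 8).
#' @param swapRate Probability of reporting the uncued item when one exists
#'   (default 0.02).
#' @param rtLognormMu,rtLognormSigma Log-mean and log-s.d. (log-seconds) of
#'   the response-time distribution (defaults log(2) and 0.35).
#' @return A list of class \code{"BehaviorParams"}.
#' @export
behaviorParams <- function(dogAmpPrev = 2, dogWidthPrev = 20,
                           dogAmpS1 = -1.5, dogWidthS1 = 25,
                           cardinalAmp = 2, cardinalFreq = 2,
                           reportNoiseSd = 8, swapRate = 0.02,
                           rtLognormMu = log(2), rtLognormSigma = 0.35) {
  stopifnot(dogWidthPrev > 0, dogWidthS1 > 0, reportNoiseSd > 0,
            swapRate >= 0, swapRate < 1)
  structure(list(dogAmpPrev = dogAmpPrev, dogWidthPrev = dogWidthPrev,
                 dogAmpS1 = dogAmpS1, dogWidthS1 = dogWidthS1,
                 cardinalAmp = cardinalAmp, cardinalFreq = cardinalFreq,
                 reportNoiseSd = reportNoiseSd, swapRate = swapRate,
                 rtLognormMu = rtLognormMu, rtLognormSigma = rtLognormSigma),
            class = "BehaviorParams")
}

#' Parameters of the neural epoch generator
#'
#' @param nSensors Number of sensors (default 24; positions on a grid in a
#'   disc, see [sensorGridPositions()]).
#' @param tuningGain Signal amplitude (a.u.) of the orientation-tuned
#'   component (default 1).
#' @param tuningWidth Half-width (degrees) at which the tuning profile
#'   crosses zero; 45 (the default) gives the pure doubled-angle cosine
#'   profile \code{cos(2 (theta - phi))}.
#' @param noiseCovType \code{"spatially_correlated"} (default) or
#'   \code{"diagonal"}.
#' @param noiseRho Correlation length (in sensor-position units) of the
#'   exponentially decaying spatial noise covariance (default 0.5).
#' @param noiseSd Marginal noise s.d. per sensor (a.u., default 1.5).
#' @param noiseAr Temporal AR(1) coefficient of the noise (default 0.7),
#'   giving noise autocorrelation comparable to band-limited recordings.
#' @param biasSchedule List of representational-bias windows; each element is
#'   \code{list(window = c(t0, t1), inducer = "previous_target"|"sample1",
#'   shiftDeg = <signed degrees>)}. Positive \code{shiftDeg} shifts the
#'   represented orientation toward the inducer, negative away from it.
#' @param signalWindow Length-2 numeric; seconds during which the
#'   orientation-tuned signal is on (default \code{c(0.1, 1.0)}).
#' @return A list of class \code{"NeuralParams"}.
#' @export
neuralParams <- function(nSensors = 24L, tuningGain = 1, tuningWidth = 45,
                         noiseCovType = c("spatially_correlated", "diagonal"),
                         noiseRho = 0.5, noiseSd = 1.5, noiseAr = 0.7,
                         biasSchedule = list(),
                         signalWindow = c(0.1, 1.0)) {
  noiseCovType <- match.arg(noiseCovType)
  stopifnot(nSensors >= 1L, tuningGain >= 0, tuningWidth > 0,
            tuningWidth <= 90, noiseSd > 0, noiseAr >= 0, noiseAr < 1,
            length(signalWindow) == 2L, signalWindow[1] < signalWindow[2])
  for (b in biasSchedule) {
    stopifnot(is.list(b), length(b$window) == 2L,
              b$inducer %in% c("previous_target", "sample1"),
              abs(b$shiftDeg) < 90)
  }
  structure(list(nSensors = as.integer(nSensors), tuningGain = tuningGain,
                 tuningWidth = tuningWidth, noiseCovType = noiseCovType,
                 noiseRho = noiseRho, noiseSd = noiseSd, noiseAr = noiseAr,
                 biasSchedule = biasSchedule, signalWindow = signalWindow),
            class = "NeuralParams")
}

#' Derivative-of-Gaussian serial-bias kernel
#'
#' The standard first-derivative-of-Gaussian kernel describing how the report
#' error depends on the inducer's relative orientation:
#' \deqn{f(\delta) = a \frac{\delta}{w} \exp(1/2 - \delta^2 / (2 w^2))}
#' It is odd in \code{delta}, zero at 0, and reaches its peak magnitude
#' \code{a} exactly at \code{|delta| = w}.
#'
#' @param delta Relative orientation(s) in degrees, in \code{(-90, 90]}.
#' @param amplitude Peak shift \code{a} in degrees (sign free; positive =
#'   attraction toward the inducer).
#' @param width Width \code{w} in degrees (> 0).
#' @return Shift in degrees, same length as \code{delta}.
#' @examples
#' dogKernel(20, amplitude = 2, width = 20)  # peak: 2
#' @export
dogKernel <- function(delta, amplitude, width) {
  stopifnot(width > 0)
  amplitude * (delta / width) * exp(0.5 - delta^2 / (2 * width^2))
}

#' Generate task sequences for the two retro-cue working-memory designs
#'
#' \code{design = "meg"}: per participant, 400 trials in 4 conditions (100
#' both-shown sample-1-cued, 100 both-shown sample-2-cued, 100 first-only,
#' 100 second-only), randomly mixed over 8 blocks of 50 trials.
#' \code{design = "eeg"}: per participant, 2 sessions of 6 cued-recall blocks
#' of 84 trials (1,008 trials), both samples always shown, cued item
#' balanced within block. Orientations are i.i.d. uniform on \code{[0, 180)};
#' previous-target links never cross block boundaries.
#'
#' @param design \code{"meg"} or \code{"eeg"}.
#' @param nParticipants Number of participants.
#' @param seed Integer seed; the generator is a pure function of
#'   (design, nParticipants, seed).
#' @return A trial data.frame (see [validateTrialTable()]) with behavioral
#'   columns (\code{report_orientation}, \code{signed_error}, \code{rt},
#'   \code{rotation_start}) still missing; fill them with
#'   [generateBehavior()].
#' @export
generateTaskSequence <- function(design = c("meg", "eeg"),
                                 nParticipants = 1L, seed = 1L) {
  design <- match.arg(design)
  .withSeed(seed, {
    out <- vector("list", nParticipants)
    for (p in seq_len(nParticipants)) {
      pid <- sprintf("P%02d", p)
      if (design == "meg") {
        cond <- c(rep("both_shown", 200L),
                  rep("first_only", 100L), rep("second_only", 100L))
        cue <- c(rep("sample1", 100L), rep("sample2", 100L),
                 rep("sample1", 100L), rep("sample2", 100L))
        ord <- sample.int(400L)
        cond <- cond[ord]; cue <- cue[ord]
        block <- rep(seq_len(8L), each = 50L)
      } else {
        nb <- 12L
        cond <- rep("cued_recall", nb * 84L)
        cue <- unlist(lapply(seq_len(nb), function(b)
          sample(rep(c("sample1", "sample2"), each = 42L))))
        block <- rep(seq_len(nb), each = 84L)
      }
      n <- length(cond)
      s1 <- ifelse(cond == "second_only", NA_real_, stats::runif(n) * 180)
      s2 <- ifelse(cond == "first_only", NA_real_, stats::runif(n) * 180)
      target <- ifelse(cue == "sample1", s1, s2)
      first <- c(TRUE, block[-1] != block[-n])
      prev <- c(NA_real_, target[-n])
      prev[first] <- NA_real_
      out[[p]] <- data.frame(
        participant_id = pid,
        trial_id = seq_len(n),
        block_id = block,
        condition = cond,
        cued_item = cue,
        sample1_orientation = s1,
        sample2_orientation = s2,
        target_orientation = target,
        previous_target_orientation = prev,
        report_orientation = NA_real_,
        signed_error = NA_real_,
        rt = NA_real_,
        rotation_start = NA_real_,
        first_in_block = first,
        stringsAsFactors = FALSE)
    }
    validateTrialTable(do.call(rbind, out))
  })
}

#' Generate biased behavioral reports
#'
#' Fills \code{report_orientation}, \code{signed_error}, \code{rt} and
#' \code{rotation_start}. The report error is built additively from a
#' derivative-of-Gaussian bias toward/away from the previous target (all
#' trials with a previous target), a derivative-of-Gaussian bias from sample
#' 1 (sample-2-cued trials where sample 1 was shown), a sinusoidal
#' stimulus-dependent (cardinal) bias of the target orientation, and circular
#' Gaussian noise. With probability \code{swapRate}, trials with an uncued
#' item report that item instead (a swap error). Response times are
#' log-normal and the rotation-start time is a random fraction (0.3-0.7) of
#' the RT.
#'
#' @param trials A trial data.frame from [generateTaskSequence()].
#' @param params A [behaviorParams()] list.
#' @param seed Integer seed.
#' @return The trial data.frame with the behavioral columns filled.
#' @export
generateBehavior <- function(trials, params = behaviorParams(), seed = 1L) {
  stopifnot(inherits(params, "BehaviorParams"))
  trials <- validateTrialTable(trials)
  .withSeed(seed, {
    n <- nrow(trials)
    bias <- numeric(n)
    dprev <- relativeOrientation(trials$previous_target_orientation,
                                 trials$target_orientation)
    hasPrev <- !is.na(dprev)
    bias[hasPrev] <- bias[hasPrev] +
      dogKernel(dprev[hasPrev], params$dogAmpPrev, params$dogWidthPrev)
    s1case <- trials$cued_item == "sample2" &
      !is.na(trials$sample1_orientation)
    ds1 <- relativeOrientation(trials$sample1_orientation,
                               trials$target_orientation)
    bias[s1case] <- bias[s1case] +
      dogKernel(ds1[s1case], params$dogAmpS1, params$dogWidthS1)
    bias <- bias + params$cardinalAmp *
      sin(2 * pi * params$cardinalFreq * trials$target_orientation / 180)
    base <- trials$target_orientation
    uncued <- ifelse(trials$cued_item == "sample1",
                     trials$sample2_orientation, trials$sample1_orientation)
    swap <- stats::runif(n) < params$swapRate & !is.na(uncued)
    base[swap] <- uncued[swap]
    bias[swap] <- 0
    noise <- stats::rnorm(n, 0, params$reportNoiseSd)
    report <- wrapOrientation(base + bias + noise)
    rt <- exp(stats::rnorm(n, params$rtLognormMu, params$rtLognormSigma))
    rot <- rt * stats::runif(n, 0.3, 0.7)
    trials$report_orientation <- report
    trials$signed_error <- relativeOrientation(report,
                                               trials$target_orientation)
    trials$rt <- rt
    trials$rotation_start <- rot
    trials
  })
}

# Tuning profile on the doubled angle; width = zero-crossing half-width in
# degrees. width == 45 reduces exactly to cos(2 * delta).
.tuningProfile <- function(deltaDeg, width) {
  if (abs(width - 45) < 1e-9) return(cos(2 * deltaDeg * pi / 180))
  # von Mises bump on the doubled angle, rescaled to [-1, 1], with
  # concentration chosen so the profile crosses 0 at |delta| = width
  target <- cos(2 * width * pi / 180)
  f <- function(k) {
    mn <- exp(-2 * k)
    # delta where rescaled profile crosses zero: cos(2 d) solves
    # exp(k (c - 1)) = (1 + mn) / 2  =>  c = 1 + log((1 + mn) / 2) / k
    c0 <- 1 + log((1 + mn) / 2) / k
    c0 - target
  }
  k <- stats::uniroot(f, c(1e-6, 50))$root
  raw <- exp(k * (cos(2 * deltaDeg * pi / 180) - 1))
  mn <- exp(-2 * k)
  2 * (raw - mn) / (1 - mn) - 1
}

# 50-ms cosine-ramped window envelope evaluated on a time axis
.rampedWindow <- function(times, window, rampSec = 0.05) {
  w <- numeric(length(times))
  t0 <- window[1]; t1 <- window[2]
  inside <- times >= t0 & times <= t1
  w[inside] <- 1
  up <- inside & times < t0 + rampSec
  w[up] <- 0.5 - 0.5 * cos(pi * (times[up] - t0) / rampSec)
  dn <- inside & times > t1 - rampSec
  w[dn] <- pmin(w[dn], 0.5 - 0.5 * cos(pi * (t1 - times[dn]) / rampSec))
  w
}

#' Generate orientation-tuned multichannel epochs
#'
#' Each sensor \code{s} has a preferred orientation \code{phi_s} (evenly
#' spread over \code{[0, 180)}). Within the signal window sensor \code{s}
#' carries \code{gain * cos(2 (theta_repr - phi_s))} plus noise; outside all
#' windows, pure noise. The represented orientation \code{theta_repr} equals
#' the target plus, within each bias-schedule window, a shift of
#' \code{shiftDeg} degrees applied along the sign of the inducer's relative
#' orientation (positive \code{shiftDeg} = toward the inducer). Window edges
#' carry 50-ms cosine ramps. Noise is Gaussian with the configured spatial
#' covariance (exponentially decaying with sensor distance, or diagonal) and
#' temporal AR(1) correlation.
#'
#' @param trials Trial data.frame for one participant (one row per epoch).
#' @param params A [neuralParams()] list.
#' @param lockEvent Lock event of the epoch time axis (default
#'   \code{"probe"}).
#' @param epochSpan Length-2 numeric, epoch limits in seconds (default
#'   \code{c(-0.2, 1.2)}).
#' @param sfreq Sampling rate in Hz (default 100).
#' @param seed Integer seed.
#' @return An [OrientationEpochs-class] with one epoch per trial row.
#' @export
generateEpochs <- function(trials, params = neuralParams(),
                           lockEvent = "probe", epochSpan = c(-0.2, 1.2),
                           sfreq = 100, seed = 1L) {
  stopifnot(inherits(params, "NeuralParams"))
  nT <- round(diff(epochSpan) * sfreq) + 1L
  times <- epochSpan[1] + (seq_len(nT) - 1L) / sfreq
  .checkWindow <- function(w, what) {
    if (w[1] < times[1] - 1e-9 || w[2] > times[nT] + 1e-9)
      stop(what, " [", w[1], ", ", w[2], "] lies outside the epoch")
  }
  .checkWindow(params$signalWindow, "signal window")
  for (b in params$biasSchedule) .checkWindow(b$window, "bias window")

  n <- nrow(trials)
  S <- params$nSensors
  pos <- sensorGridPositions(S)
  phi <- (seq_len(S) - 1L) * 180 / S

  .withSeed(seed, {
    # represented orientation per trial and time
    thetaRepr <- matrix(trials$target_orientation, n, nT)
    for (b in params$biasSchedule) {
      indOri <- switch(b$inducer,
                       previous_target = trials$previous_target_orientation,
                       sample1 = trials$sample1_orientation)
      d <- relativeOrientation(indOri, trials$target_orientation)
      m <- ifelse(is.na(d), 0, b$shiftDeg * sign(d))
      thetaRepr <- thetaRepr + outer(m, .rampedWindow(times, b$window))
    }
    env <- .rampedWindow(times, params$signalWindow)
    data <- array(0, dim = c(n, S, nT))
    for (s in seq_len(S)) {
      prof <- .tuningProfile(thetaRepr - phi[s], params$tuningWidth)
      data[, s, ] <- params$tuningGain * prof *
        matrix(env, n, nT, byrow = TRUE)
    }
    # noise: spatially correlated across sensors, AR(1) in time,
    # stationary marginal s.d. = noiseSd
    z <- matrix(stats::rnorm(n * nT * S), n * nT, S)
    if (params$noiseCovType == "spatially_correlated" && S > 1L) {
      D <- as.matrix(stats::dist(pos))
      R <- exp(-D / params$noiseRho)
      z <- z %*% chol(R)
    }
    noise <- array(aperm(array(z, dim = c(n, nT, S)), c(1, 3, 2)),
                   dim = c(n, S, nT))
    if (params$noiseAr > 0 && nT > 1L) {
      a <- params$noiseAr
      sc <- sqrt(1 - a^2)
      for (t in 2:nT)
        noise[, , t] <- a * noise[, , t - 1L] + sc * noise[, , t]
    }
    data <- data + params$noiseSd * noise
    OrientationEpochs(data, times = times, sfreq = sfreq,
                      sensorIds = sprintf("S%03d", seq_len(S)),
                      sensorPos = pos, lockEvent = lockEvent,
                      trialIds = trials$trial_id)
  })
}
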