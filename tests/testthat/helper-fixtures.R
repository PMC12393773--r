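# Small programmatic fixtures shared across tests.

# a minimal valid trial table built by hand
makeToyTrials <- function(n = 10, seed = 42) {
  set.seed(seed)
  target <- runif(n) * 180
  prev <- c(NA, target[-n])
  report <- wrapOrientation(target + rnorm(n, 0, 5))
  data.frame(
    participant_id = "P01",
    trial_id = seq_len(n),
    block_id = 1L,
    condition = "second_only",
    cued_item = "sample2",
    sample1_orientation = NA_real_,
    sample2_orientation = target,
    target_orientation = target,
    previous_target_orientation = prev,
    report_orientation = report,
    signed_error = relativeOrientation(report, target),
    rt = runif(n, 1, 3),
    rotation_start = runif(n, 0.4, 0.9),
    first_in_block = c(TRUE, rep(FALSE, n - 1)),
    stringsAsFactors = FALSE)
}

# random epochs with no structure
makeToyEpochs <- function(nTrials = 6, nSensors = 4, nTimes = 20,
                          sfreq = 100, seed = 7, lockEvent = "probe") {
  set.seed(seed)
  OrientationEpochs(array(rnorm(nTrials * nSensors * nTimes),
                          c(nTrials, nSensors, nTimes)),
                    times = (seq_len(nTimes) - 1) / sfreq,
                    sfreq = sfreq, lockEvent = lockEvent,
                    trialIds = seq_len(nTrials))
}

# fast small config used throughout
smallConfig <- function(...) {
  analysisConfig(windowSamples = 5L, nPermutations = 1000L, ...)
}

# a tuned one-participant dataset for decoder recovery tests
makeTunedDataset <- function(seed = 1, shiftDeg = 0, nSensors = 16,
                             nParticipants = 1,
                             signalWindow = c(0.1, 1.15),
                             biasWindow = c(0.6, 1.1),
                             inducer = "previous_target",
                             gain = 1, sfreq = 100,
                             epochSpan = c(-0.2, 1.2)) {
  trials <- generateTaskSequence("meg", nParticipants, seed = seed)
  trials <- generateBehavior(trials, behaviorParams(), seed = seed + 1)
  sched <- if (shiftDeg != 0)
    list(list(window = biasWindow, inducer = inducer, shiftDeg = shiftDeg))
  else list()
  np <- neuralParams(nSensors = nSensors, tuningGain = gain,
                     biasSchedule = sched, signalWindow = signalWindow)
  eps <- lapply(unique(trials$participant_id), function(pid) {
    tt <- trials[trials$participant_id == pid, ]
    generateEpochs(tt, np, epochSpan = epochSpan, sfreq = sfreq,
                   seed = seed + 2 + match(pid, unique(trials$participant_id)))
  })
  list(trials = trials, epochs = eps)
}
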