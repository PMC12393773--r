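# serialdep

Serial dependence — the pull of today's percept toward (or away from)
what was seen a moment ago — is a signature of how the brain smooths noisy
input over time. `serialdep` is an R package for quantifying serial
dependence in orientation working-memory tasks at two levels:

* **Behavior.** A model-free serial-bias index: the mean signed report
  error for trials whose *inducer* (the previous trial's target, or the
  other grating in the same trial) lies up to 45° counterclockwise of the
  target, minus the mean for trials where it lies up to 45° clockwise.
  Positive values mean the report is attracted toward the inducer. A
  deterministic three-sinusoid fit removes stimulus-dependent
  (cardinal/oblique) report biases before report-sorted analyses.

* **Neural representations.** Orientation is decoded from epoched
  multichannel recordings (trials × sensors × time) with cross-validated
  Mahalanobis-distance tuning curves: at each time point, a trailing
  window of samples from all sensors is concatenated, reduced by PCA to
  90 % variance, and each held-out trial is compared with the mean pattern
  of the training trials in each of 10 relative-orientation bins
  (18° wide over the 180°-periodic circle), using distances whitened by a
  shrinkage covariance. Negated, mean-centered distances form a tuning
  curve; its projection on cos(2θ) is the *decoding evidence*, and the
  difference between its clockwise and counterclockwise flanks is the
  *asymmetry index*. Sorting trials by whether the inducer is clockwise or
  counterclockwise of the target and differencing the group asymmetries
  gives the *neural bias index*: positive = the represented orientation is
  attracted toward the inducer.

Group inference uses cluster-based sign-flip permutation tests and
windowed one-sample t-tests; sensor contributions are mapped with a
searchlight (each sensor plus its 47 nearest neighbors by default). A
synthetic-data generator emulates the two task designs the package
targets — a 400-trial two-grating retro-cue design and a 1,008-trial cued
recall design — with injectable behavioral and representational biases, so
every stage is testable end to end without recordings.

## Worked example

Simulate one participant whose late-trial target representation is shifted
8° toward the previous trial's target, then recover that bias:

```r
library(serialdep)

trials <- generateTaskSequence("meg", nParticipants = 1, seed = 2)
trials <- generateBehavior(trials, behaviorParams(), seed = 3)

np <- neuralParams(nSensors = 16,
                   biasSchedule = list(list(window = c(0.6, 1.1),
                                            inducer = "previous_target",
                                            shiftDeg = 8)),
                   signalWindow = c(0.1, 1.15))
epochs <- generateEpochs(trials, np, epochSpan = c(-0.2, 1.2),
                         sfreq = 100, seed = 4)

cfg <- analysisConfig(windowSamples = 15)        # 150 ms at 100 Hz
res <- decodeTimecourse(epochs, trials, "target", cfg,
                        timeIndices = seq(25, 141, by = 12))
round(colMeans(decodingEvidenceMatrix(res)), 3)
#> [1] 0.004 0.106 0.688 0.658 0.570 0.709 0.399 0.423 0.402 0.493

participantNeuralBias(epochs, trials, "previous_target",
                      window = c(0.7, 1.1), config = cfg, result = res)
#> [1] 0.7202482
participantNeuralBias(epochs, trials, "previous_target",
                      window = c(0.1, 0.5), config = cfg, result = res)
#> [1] -0.1331989
```

Evidence is near zero before the orientation-tuned signal switches on at
0.1 s and clearly positive afterwards (a perfectly tuned cos(2θ) curve
would give 0.5). The neural bias index is positive (attraction) inside the
0.6–1.1 s window where the shift was injected and near zero before it.
The behavioral side of the same dataset:

```r
serialBiasEstimates(trials, "previous_target")$index
#> [1] 1.477164    # degrees; positive = attraction toward previous target
```

A paired down pipeline run with TSV/JSON outputs and a reproducibility
manifest:

```r
runPipeline(analysisConfig(windowSamples = 5, seed = 1), outDir = "run1",
            stages = c("simulate", "behavior", "decode", "bias", "stats"),
            nParticipants = 3,
            neural = neuralParams(nSensors = 6,
                                  signalWindow = c(0.1, 0.5)),
            epochSpan = c(-0.1, 0.6), sfreq = 50,
            timeIndices = c(15, 25, 35), biasWindow = c(0.2, 0.6))
```

`inst/scripts/serialdep.R` wraps the same pipeline for shell use.

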