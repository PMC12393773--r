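test_that("MEG task sequence reproduces the four condition counts", {
  tr <- generateTaskSequence("meg", nParticipants = 2, seed = 5)
  for (tt in split(tr, tr$participant_id)) {
    expect_equal(nrow(tt), 400)
    expect_equal(sum(tt$condition == "both_shown"), 200)
    expect_equal(sum(tt$condition == "both_shown" &
                       tt$cued_item == "sample1"), 100)
    expect_equal(sum(tt$condition == "both_shown" &
                       tt$cued_item == "sample2"), 100)
    expect_equal(sum(tt$condition == "first_only"), 100)
    expect_equal(sum(tt$condition == "second_only"), 100)
    # target always equals the cued item's orientation
    cued <- ifelse(tt$cued_item == "sample1", tt$sample1_orientation,
                   tt$sample2_orientation)
    expect_equal(tt$target_orientation, cued)
  }
})

test_that("EEG cued-recall sequence has 12 blocks of 84 trials", {
  tr <- generateTaskSequence("eeg", nParticipants = 1, seed = 6)
  expect_equal(nrow(tr), 1008)
  expect_equal(as.vector(table(tr$block_id)), rep(84L, 12))
  expect_true(all(tr$condition == "cued_recall"))
  # cued item balanced within block
  byblk <- tapply(tr$cued_item == "sample1", tr$block_id, sum)
  expect_true(all(byblk == 42))
})

test_that("previous-target links respect block boundaries", {
  tr <- generateTaskSequence("meg", 1, seed = 9)
  firsts <- which(tr$first_in_block)
  expect_true(all(is.na(tr$previous_target_orientation[firsts])))
  others <- which(!tr$first_in_block)
  expect_equal(tr$previous_target_orientation[others],
               tr$target_orientation[others - 1])
})

test_that("generators are pure functions of their seed", {
  a <- generateTaskSequence("meg", 1, seed = 33)
  b <- generateTaskSequence("meg", 1, seed = 33)
  expect_identical(a, b)
  ba <- generateBehavior(a, behaviorParams(), seed = 2)
  bb <- generateBehavior(b, behaviorParams(), seed = 2)
  expect_identical(ba, bb)
  np <- neuralParams(nSensors = 6, signalWindow = c(0.1, 0.4))
  ea <- generateEpochs(ba[ba$participant_id == "P01", ][1:20, ], np,
                       epochSpan = c(-0.1, 0.5), sfreq = 50, seed = 4)
  eb <- generateEpochs(bb[bb$participant_id == "P01", ][1:20, ], np,
                       epochSpan = c(-0.1, 0.5), sfreq = 50, seed = 4)
  expect_identical(epochsData(ea), epochsData(eb))
})

test_that("DoG kernel is odd, zero at zero, and peaks at |delta| = width", {
  w <- 23.7; a <- 2.4
  expect_equal(dogKernel(0, a, w), 0)
  d <- seq(-89, 90, by = 0.5)
  expect_equal(dogKernel(-d, a, w), -dogKernel(d, a, w))
  # brute force over a dense grid: the peak sits at delta = width with
  # value = amplitude
  grid <- seq(0.01, 90, by = 0.01)
  v <- dogKernel(grid, a, w)
  expect_equal(grid[which.max(abs(v))], w, tolerance = 1e-3)
  expect_equal(max(v), a, tolerance = 1e-6)
})

test_that("noiseless zero-bias behavior reproduces the target exactly", {
  tr <- generateTaskSequence("meg", 1, seed = 3)
  p0 <- behaviorParams(dogAmpPrev = 0, dogAmpS1 = 0, cardinalAmp = 0,
                       reportNoiseSd = 1e-9, swapRate = 0)
  out <- generateBehavior(tr, p0, seed = 8)
  expect_equal(out$report_orientation, out$target_orientation,
               tolerance = 1e-6)
  expect_equal(out$signed_error, rep(0, nrow(out)), tolerance = 1e-6)
  expect_true(all(out$rt > 0))
  expect_true(all(out$rotation_start > 0 & out$rotation_start < out$rt))
})

test_that("swap errors create apparent sample-2-on-sample-1 attraction", {
  tr <- generateTaskSequence("meg", 6, seed = 13)
  pswap <- behaviorParams(dogAmpPrev = 0, dogAmpS1 = 0, cardinalAmp = 0,
                          reportNoiseSd = 8, swapRate = 0.2)
  out <- generateBehavior(tr, pswap, seed = 14)
  est <- serialBiasEstimates(out, "sample2_on_sample1")
  # mixture oracle: reporting sample 2 on 20% of sample-1-cued trials pulls
  # the mean error toward sample 2, so the index must be clearly positive
  expect_gt(mean(est$index), 1)
})

test_that("injected DoG bias is recovered near its numeric expectation", {
  amp <- 2; width <- 20
  tr <- generateTaskSequence("meg", 6, seed = 21)
  pb <- behaviorParams(dogAmpPrev = amp, dogWidthPrev = width,
                       dogAmpS1 = 0, cardinalAmp = 0, swapRate = 0)
  out <- generateBehavior(tr, pb, seed = 22)
  est <- serialBiasEstimates(out, "previous_target")
  # numeric-integration oracle: deltas are uniform, so the expected index is
  # the mean kernel value over (0, 45] minus over [-45, 0)
  expected <- 2 * stats::integrate(function(d) dogKernel(d, amp, width),
                                   0, 45)$value / 45
  expect_gt(mean(est$index), 0)
  expect_lt(abs(mean(est$index) - expected), expected)  # within 2x
})

test_that("epochs generator validates bias windows against the epoch", {
  tr <- generateTaskSequence("meg", 1, seed = 2)[1:10, ]
  np <- neuralParams(nSensors = 4, signalWindow = c(0, 0.3),
                     biasSchedule = list(list(window = c(0.5, 2),
                                              inducer = "previous_target",
                                              shiftDeg = 5)))
  expect_error(generateEpochs(tr, np, epochSpan = c(-0.1, 0.6), sfreq = 50),
               "outside the epoch")
})

test_that("sensor tuning follows the doubled-angle cosine in the window", {
  tr <- makeToyTrials(4)
  tr$target_orientation <- c(0, 45, 90, 135)
  tr$sample2_orientation <- tr$target_orientation
  tr$report_orientation <- tr$target_orientation
  tr$signed_error <- 0
  np <- neuralParams(nSensors = 8, tuningGain = 2, noiseSd = 1e-9,
                     noiseAr = 0, noiseCovType = "diagonal",
                     signalWindow = c(0.2, 0.4))
  ep <- generateEpochs(tr, np, epochSpan = c(0, 0.6), sfreq = 50, seed = 1)
  phi <- (0:7) * 180 / 8
  mid <- which.min(abs(epochTimes(ep) - 0.3))  # plateau of the window
  for (i in 1:4) {
    expect_equal(epochsData(ep)[i, , mid],
                 2 * cos(2 * (tr$target_orientation[i] - phi) * pi / 180),
                 tolerance = 1e-6)
  }
  # outside all windows: pure (here: negligible) noise
  expect_lt(max(abs(epochsData(ep)[, , 2])), 1e-6)
})

test_that("sensor grid lies in the unit disc with the requested count", {
  pos <- sensorGridPositions(24)
  expect_equal(dim(pos), c(24L, 2L))
  expect_true(all(rowSums(pos^2) <= 1 + 1e-9))
  expect_equal(nrow(sensorGridPositions(1)), 1L)
})
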