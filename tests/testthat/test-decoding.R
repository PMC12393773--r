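test_that("feature windows concatenate sensors x samples", {
  ep <- makeToyEpochs(nTrials = 3, nSensors = 4, nTimes = 20)
  f <- buildFeatures(ep, 10, windowSamples = 3)
  expect_equal(dim(f), c(3, 12))
  # sensor-major layout: first block is sensor 1's window
  expect_equal(f[2, 1:3], epochsData(ep)[2, 1, 8:10])
  expect_equal(f[2, 4:6], epochsData(ep)[2, 2, 8:10])
  # window of 1 is the raw slice
  f1 <- buildFeatures(ep, 5, windowSamples = 1)
  expect_equal(f1, matrix(epochsData(ep)[, , 5], 3, 4))
  expect_error(buildFeatures(ep, 2, windowSamples = 5), "truncated")
})

test_that("a 306-sensor 37-sample window yields 11,322 features", {
  ep <- OrientationEpochs(array(0, c(2, 306, 40)), times = (0:39) / 250,
                          sfreq = 250, lockEvent = "probe")
  expect_equal(ncol(buildFeatures(ep, 40, 37)), 11322)
})

test_that("PCA keeps the smallest k reaching the variance target", {
  set.seed(31)
  # rank-1 data
  v <- rnorm(20)
  X <- outer(rnorm(15), v)
  expect_equal(reduceDimensionality(X, 0.9)$k, 1L)
  # variance = 1 keeps the full rank
  X2 <- matrix(rnorm(30 * 8), 30, 8)
  expect_equal(reduceDimensionality(X2, 1.0)$k, 8L)
  # isotropic noise: k approximately 0.9 * n_features
  X3 <- matrix(rnorm(4000 * 50), 4000, 50)
  k <- reduceDimensionality(X3, 0.9)$k
  expect_gt(k, 0.8 * 50); expect_lt(k, 1.0 * 50)
  expect_error(reduceDimensionality(X2[1, , drop = FALSE]), "2 rows")
})

test_that("PCA transform reproduces scores on held-out rows", {
  set.seed(32)
  X <- matrix(rnorm(40 * 12), 40, 12)
  pca <- reduceDimensionality(X[1:30, ], 0.95)
  proj <- projectFeatures(pca, X[1:30, ])
  expect_equal(proj, pca$scores)
  held <- projectFeatures(pca, X[31:40, ])
  expect_equal(dim(held), c(10L, pca$k))
})

test_that("Mahalanobis distance matches its closed forms and an oracle", {
  expect_equal(mahalanobisDistance(c(0, 0), c(3, 4)), 5)
  expect_equal(mahalanobisDistance(c(2, 0), c(0, 0), diag(c(4, 1))), 1)
  set.seed(33)
  for (rep in 1:100) {
    p <- sample(2:5, 1)
    x <- rnorm(p); y <- rnorm(p)
    A <- matrix(rnorm(p * p), p)
    cov <- crossprod(A) + diag(p) * 0.5
    oracle <- sqrt(drop(t(x - y) %*% solve(cov) %*% (x - y)))
    expect_equal(mahalanobisDistance(x, y, cov), oracle, tolerance = 1e-10)
  }
  expect_error(mahalanobisDistance(c(1, 0), c(0, 0),
                                   matrix(c(1, 1, 1, 1), 2)),
               "singular|positive definite")
})

test_that("shrinkage covariance is positive definite with p > n", {
  set.seed(34)
  X <- matrix(rnorm(10 * 40), 10, 40)
  S <- shrinkageCovariance(X)
  expect_true(all(eigen(S, symmetric = TRUE, only.values = TRUE)$values > 0))
  lam <- attr(S, "shrinkage")
  expect_true(lam >= 0 && lam <= 1)
})

test_that("tuning curves sum to zero and mark empty bins missing", {
  set.seed(35)
  X <- matrix(rnorm(40 * 6), 40, 6)
  ori <- runif(40) * 180
  cv <- tuningCurveLoo(X, ori, 1)
  expect_equal(sum(cv), 0, tolerance = 1e-12)
  # with few trials some bin is empty -> all NA
  cv2 <- tuningCurveLoo(X[1:5, ], ori[1:5], 1)
  expect_true(all(is.na(cv2)))
})

test_that("the bin containing a matching mean pattern wins", {
  set.seed(36)
  # 10 well-separated bin patterns; test trial equals bin 6's pattern
  centers <- orientationBinCenters()
  pats <- matrix(rnorm(10 * 8, sd = 5), 10, 8)
  ori <- wrapOrientation(90 + centers)   # training ori so delta = centers
  X <- rbind(rep(0, 8), pats + matrix(rnorm(80, sd = 0.01), 10, 8))
  X[1, ] <- pats[6, ]
  cv <- tuningCurveLoo(X, c(90, ori), 1)
  expect_equal(which.max(cv), 6L)
})

test_that("identity-covariance decoder equals the Euclidean oracle", {
  set.seed(37)
  n <- 20
  X <- matrix(rnorm(n * 5), n, 5)
  ori <- runif(n) * 180
  oracle <- euclideanTuningOracle(X, ori)
  for (i in seq_len(n)) {
    got <- tuningCurveLoo(X, ori, i, cov = NULL)
    expect_equal(as.numeric(got), oracle[i, ], tolerance = 1e-8)
  }
  # and the vectorized all-trials path agrees with the per-trial path
  fast <- serialdep:::.tuningCurvesAll(X, ori)
  expect_equal(fast, oracle, tolerance = 1e-8)
})

test_that("decoding evidence uses doubled-angle cosine weights", {
  ctr <- orientationBinCenters()
  expect_equal(decodingEvidence(rep(1, 10)), 0)           # flat curve
  expect_equal(decodingEvidence(cos(2 * ctr * pi / 180)), 0.5)
  expect_equal(decodingEvidence(cos(2 * (ctr - 90) * pi / 180)), -0.5)
  # invariance to adding a constant
  set.seed(38)
  cv <- rnorm(10)
  expect_equal(decodingEvidence(cv + 3), decodingEvidence(cv))
})

test_that("decodeTimecourse recovers signal inside the tuned window", {
  ds <- makeTunedDataset(seed = 301, nSensors = 12,
                         signalWindow = c(0.3, 1.0))
  cfg <- analysisConfig(windowSamples = 10)
  res <- decodeTimecourse(ds$epochs[[1]], ds$trials, "target", cfg,
                          timeIndices = c(25, 70, 110))
  ev <- colMeans(decodingEvidenceMatrix(res))
  expect_lt(abs(ev[1]), 0.1)   # pre-signal (window ends at 0.04 s)
  expect_gt(ev[2], 0.2)        # inside the signal window
  expect_gt(ev[3], 0.2)
  expect_s4_class(res, "DecodingResult")
  expect_equal(dim(tuningCurves(res)), c(400L, 10L, 3L))
})

test_that("previous-target decoding is null without carry-over signal", {
  ds <- makeTunedDataset(seed = 303, nSensors = 12,
                         signalWindow = c(0.3, 1.0))
  cfg <- analysisConfig(windowSamples = 10)
  res <- decodeTimecourse(ds$epochs[[1]], ds$trials, "previous_target",
                          cfg, timeIndices = c(70, 110))
  ev <- decodingEvidenceMatrix(res)
  n <- nrow(ev)
  se <- apply(ev, 2, sd) / sqrt(n)
  expect_true(all(abs(colMeans(ev)) < 3 * se))
  # first-in-block trials are excluded
  expect_equal(n, sum(!ds$trials$first_in_block))
})

test_that("fold-wise PCA produces similar evidence on a tuned toy set", {
  ds <- makeTunedDataset(seed = 305, nSensors = 6)
  tt <- ds$trials[1:60, ]
  ep <- ds$epochs[[1]][1:60, ]
  cfgA <- analysisConfig(windowSamples = 5, pcaFoldwise = FALSE)
  cfgB <- analysisConfig(windowSamples = 5, pcaFoldwise = TRUE)
  a <- decodeTimecourse(ep, tt, "target", cfgA, timeIndices = 60)
  b <- decodeTimecourse(ep, tt, "target", cfgB, timeIndices = 60)
  evA <- mean(decodingEvidenceMatrix(a), na.rm = TRUE)
  evB <- mean(decodingEvidenceMatrix(b), na.rm = TRUE)
  expect_gt(evA, 0.1)
  expect_gt(evB, 0.1)
})

test_that("response locking shifts windows and applies RT bounds", {
  set.seed(39)
  n <- 10
  sfreq <- 50
  times <- seq(-0.5, 6, by = 1 / sfreq)
  Tn <- length(times)
  # encode the original time in the data so the re-epoching is checkable
  data <- array(rep(times, each = n * 2), c(n, 2, Tn))
  tr <- makeToyTrials(n)
  tr$rt <- c(0.5, 12, rep(2, n - 2))   # two out-of-bounds trials
  ep <- OrientationEpochs(data, times = times, sfreq = sfreq,
                          lockEvent = "probe", trialIds = tr$trial_id)
  expect_message(rl <- responseLock(ep, tr, span = c(-2, 0)),
                 "excluded 2")
  expect_equal(nTrials(rl), 8)
  expect_equal(lockEvent(rl), "response")
  expect_false(any(c(1L, 2L) %in% trialIds(rl)))
  # trial with rt = 2 s and span (-2, 0): data covers 0..2 s post-probe
  expect_equal(epochsData(rl)[1, 1, ], seq(0, 2, by = 1 / sfreq),
               tolerance = 1e-9)
  expect_equal(epochTimes(rl), seq(-2, 0, by = 1 / sfreq))
})

test_that("trials whose span leaves the epoch are excluded with a reason", {
  tr <- makeToyTrials(4)
  tr$rt <- c(5.5, 2, 2, NA)   # 5.5 + (-2 .. 0) exceeds a short epoch
  ep <- makeToyEpochs(nTrials = 4, nTimes = 200, sfreq = 50)
  ep@trialIds <- tr$trial_id
  # epoch covers 0 .. 3.98 s
  expect_message(rl <- responseLock(ep, tr, span = c(-2, 0)),
                 "span_outside_epoch=1.*|rt_missing")
  expect_equal(nTrials(rl), 2)
})
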