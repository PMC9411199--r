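test_that("connective mean trace: constants and explicit two-pixel mask", {
  st <- FrameStack(array(3, c(4, 6, 6)))
  mask <- matrix(TRUE, 6, 6)
  expect_equal(as.vector(traceValues(connectiveMeanTrace(st, mask))),
               rep(3, 4))
  dat <- array(0, c(1, 2, 2))
  dat[1, , ] <- matrix(c(1, 3, 9, 9), 2, 2)
  m2 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(as.vector(traceValues(connectiveMeanTrace(FrameStack(dat), m2))), 2)
  expect_error(connectiveMeanTrace(st, matrix(FALSE, 6, 6)), "no pixels")
})

test_that("normalization constant is the 99th linear-interpolation percentile", {
  expect_equal(computeNormalization(SampledTrace(rep(5, 100), 16)), 5)
  # oracle: sort 1..100, interpolate at rank 1 + 0.99 * 99 = 99.01
  expect_equal(computeNormalization(SampledTrace(sample(1:100), 16)), 99.01)
  expect_error(computeNormalization(list()), "at least one")
})

test_that("max normalized activity is exactly 1 on the defining period and scales linearly", {
  set.seed(1)
  v <- 10 + abs(rnorm(500))
  tr <- SampledTrace(v, 16)
  norm <- computeNormalization(tr)
  expect_equal(maxNormalizedActivity(tr, norm), 1, tolerance = 1e-12)
  tr3 <- SampledTrace(3 * v, 16)
  expect_equal(maxNormalizedActivity(tr3, norm),
               3 * maxNormalizedActivity(tr, norm))
})

test_that("Mann-Whitney U: worked values under complete separation", {
  a <- c(4, 5, 6); b <- c(1, 2, 3)
  # oracle: z = (9 - 4.5 - 0.5) / sqrt(5.25), upper tail
  pOracle <- pnorm((9 - 4.5 - 0.5) / sqrt(5.25), lower.tail = FALSE)
  expect_equal(mannWhitneyU(a, b, "one", "normal_cc"), pOracle)
  expect_equal(round(mannWhitneyU(a, b, "one", "normal_cc"), 3), 0.040)
  expect_equal(mannWhitneyU(a, b, "one", "exact"), 1 / 20)
  a5 <- 6:10; b5 <- 1:5
  expect_equal(mannWhitneyU(a5, b5, "two", "exact"), 2 / 252)
})

test_that("Mann-Whitney U agrees with wilcox.test and handles full ties", {
  set.seed(2)
  for (i in 1:5) {
    a <- rnorm(6); b <- rnorm(4, 0.5)
    expect_equal(mannWhitneyU(a, b, "two", "normal_cc"),
                 wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value,
                 tolerance = 1e-12)
    expect_equal(mannWhitneyU(a, b, "one", "exact"),
                 wilcox.test(a, b, alternative = "greater",
                             exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  expect_warning(p <- mannWhitneyU(c(1, 1), c(1, 1, 1)), "tied")
  expect_equal(p, 1)
})

test_that("normal approximation tracks the exact method under separation", {
  for (m in 3:8) {
    a <- seq_len(m) + 100
    b <- seq_len(m)
    pcc <- mannWhitneyU(a, b, "one", "normal_cc")
    pex <- mannWhitneyU(a, b, "one", "exact")
    expect_lt(abs(pcc - pex), 0.02)
  }
})

test_that("ROI trace normalization maps to [0, 1] and is affine-invariant", {
  set.seed(3)
  v <- cumsum(rnorm(200))
  tr <- SampledTrace(v, 16)
  out <- as.vector(traceValues(roiTraceNormalize(tr)))
  expect_equal(range(out), c(0, 1))
  tr2 <- SampledTrace(2.5 * v + 7, 16)
  expect_equal(as.vector(traceValues(roiTraceNormalize(tr2))), out,
               tolerance = 1e-12)
  expect_error(roiTraceNormalize(SampledTrace(rep(1, 50), 16)), "constant")
})

test_that("smoothing keeps a symmetric impulse centered", {
  x <- rep(0, 201); x[100] <- 1
  out <- as.vector(traceValues(roiTraceNormalize(SampledTrace(x, 16))))
  expect_equal(which.max(out), 100L)
})

test_that("global peak time: bump location and earliest-tie rule", {
  fr <- 16
  tt <- (0:319) / fr
  bump <- pmax(0, 1 - abs(tt - 12))
  expect_equal(globalPeakTime(SampledTrace(bump, fr)), 12)
  twin <- rep(0, 320)
  twin[5 * fr + 1] <- 1; twin[9 * fr + 1] <- 1
  expect_equal(globalPeakTime(SampledTrace(twin, fr)), 5)
})

test_that("a spatially uniform flash maps every pixel to time zero", {
  fr <- 16
  T <- 40 * fr
  tt <- (seq_len(T) - 1) / fr
  flash <- exp(-(tt - 20)^2 / 2)
  dat <- array(rep(flash, 16), c(T, 4, 4))
  st <- FrameStack(dat, fr)
  pm <- pixelPeakTimeMap(st, 20)
  expect_equal(max(abs(pm)), 0)
})

test_that("peak-time maps recover the wave's spatial order", {
  fr <- 16
  w <- waveSpec(onsetTime = 12, interRegionLag = 1, amplitude = 4,
                duration = 6)
  sim <- generateConnectiveMovie(nFrames = 25 * fr, height = 64, width = 96,
                                 nAxons = 16, motionAmplitude = 0,
                                 nonrigidAmplitude = 0, noiseSd = 0,
                                 fluctuationSd = 0, wave = w, seed = 5)
  mask <- sim$truth$roiMasks > 0
  tPeak <- globalPeakTime(connectiveMeanTrace(sim$green, mask))
  pm <- suppressWarnings(pixelPeakTimeMap(sim$green, tPeak))
  labels <- sim$truth$roiMasks
  ids <- sort(unique(labels[labels > 0]))
  rec <- vapply(ids, function(id) median(pm[labels == id]), numeric(1))
  truth <- sim$truth$wavePeakTimes[ids]
  ok <- !is.na(truth)
  expect_gte(cor(truth[ok], rec[ok], method = "spearman"), 0.9)

  # region order exact for a 2-frame lag, noise free
  w2 <- waveSpec(onsetTime = 12, interRegionLag = 2 / fr, amplitude = 4,
                 duration = 6)
  sim2 <- generateConnectiveMovie(nFrames = 25 * fr, height = 64, width = 96,
                                  nAxons = 16, motionAmplitude = 0,
                                  nonrigidAmplitude = 0, noiseSd = 0,
                                  fluctuationSd = 0, wave = w2, seed = 6)
  labels2 <- sim2$truth$roiMasks
  mask2 <- labels2 > 0
  tPeak2 <- globalPeakTime(connectiveMeanTrace(sim2$green, mask2))
  pm2 <- suppressWarnings(pixelPeakTimeMap(sim2$green, tPeak2))
  reg <- sim2$truth$roiRegions
  regMed <- vapply(w2$regionOrder, function(r) {
    ids <- as.integer(names(reg)[reg == r])
    median(unlist(lapply(ids, function(id) pm2[labels2 == id])))
  }, numeric(1))
  expect_true(all(diff(regMed) > 0))
})

test_that("peak-time maps are time-translation equivariant", {
  fr <- 16
  w <- waveSpec(onsetTime = 14, interRegionLag = 0.5, amplitude = 4,
                duration = 4)
  sim <- generateConnectiveMovie(nFrames = 30 * fr, height = 48, width = 64,
                                 nAxons = 10, motionAmplitude = 0,
                                 nonrigidAmplitude = 0, noiseSd = 0,
                                 fluctuationSd = 0, wave = w, seed = 7)
  dat <- frameData(sim$green)
  k <- 32L   # 2 s shift; both search windows stay inside the recording
  shifted <- dat[c((k + 1):dim(dat)[1], 1:k), , ]
  mask <- sim$truth$roiMasks > 0
  t1 <- globalPeakTime(connectiveMeanTrace(sim$green, mask))
  st2 <- FrameStack(shifted, fr)
  t2 <- globalPeakTime(connectiveMeanTrace(st2, mask))
  expect_equal(t1 - t2, k / fr)
  pm1 <- pixelPeakTimeMap(sim$green, t1)
  pm2 <- pixelPeakTimeMap(st2, t2)
  # compare where a wave actually peaks; constant background pixels are
  # argmax ties resolved to the window start
  expect_lte(max(abs(pm1[mask] - pm2[mask])), 1 / fr + 1e-9)
})

test_that("non-moving mean image reduces to the expected frame means", {
  dat <- array(0, c(2, 3, 3))
  dat[1, , ] <- 1; dat[2, , ] <- 5
  st <- FrameStack(dat)
  expect_equal(nonmovingMeanImage(st, c(TRUE, TRUE)), matrix(3, 3, 3))
  expect_equal(nonmovingMeanImage(st, c(TRUE, FALSE)), matrix(1, 3, 3))
  expect_error(nonmovingMeanImage(st, c(FALSE, FALSE)), "stationary")
})
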