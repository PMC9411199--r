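test_that("COM registration: single frame is identity with zero offset", {
  img <- smoothTestImage(32, 40)
  st <- FrameStack(array(img, c(1, 32, 40)))
  res <- centerOfMassRegister(st)
  expect_equal(res$offsets[1, ], c(dy = 0L, dx = 0L))
  expect_equal(frameData(res$registered)[1, , ], img)
})

test_that("COM registration recovers a circular shift and is idempotent", {
  # compact-support image: circular shift acts as a pure translation
  y <- matrix(1:48, 48, 56); x <- matrix(1:56, 48, 56, byrow = TRUE)
  ref <- 200 * exp(-((y - 24)^2 + (x - 28)^2) / 40)
  shifted <- ref[c(46:48, 1:45), c(52:56, 1:51)]  # content moved by (3, 5)
  dat <- array(0, c(2, 48, 56)); dat[1, , ] <- ref; dat[2, , ] <- shifted
  st <- FrameStack(dat)
  res <- centerOfMassRegister(st)
  expect_equal(res$offsets[2, ], c(dy = 3L, dx = 5L))
  res2 <- centerOfMassRegister(res$registered)
  expect_equal(unname(res2$offsets), matrix(0L, 2, 2))
})

test_that("all-zero frames pass through with a warning", {
  dat <- array(0, c(2, 16, 16))
  dat[1, 8, 8] <- 5
  st <- FrameStack(dat)
  expect_warning(res <- centerOfMassRegister(st), "COM undefined")
  expect_equal(res$offsets[2, ], c(dy = 0L, dx = 0L))
})

test_that("centered crop removes margins with the high-side tie-break", {
  dat <- array(seq_len(3 * 10 * 10), c(3, 10, 10))
  st <- FrameStack(dat)
  cr <- cropCenter(st, 7, 7)
  # margin 3: 1 removed low side, 2 removed high side (rows/cols 2..8)
  expect_equal(frameData(cr)[2, , ], dat[2, 2:8, 2:8])
  expect_equal(frameData(cropCenter(st, 10, 10)), dat)
  expect_error(cropCenter(st, 12, 5), "exceeds")
  # acquisition-scale arithmetic: 480 x 736 -> 352 x 576 removes 64 / 80
  expect_equal((480 - 352) / 2, 64)
  expect_equal((736 - 576) / 2, 80)
})

test_that("motion field between identical frames is essentially zero", {
  img <- smoothTestImage(48, 48, seed = 5)
  f <- estimateMotionField(img, img)
  expect_lt(mean(sqrt(f@dy^2 + f@dx^2)), 0.05)
})

test_that("motion field recovers a pure translation, checked against brute-force shift", {
  ref <- smoothTestImage(64, 64, seed = 6)
  # content moved by (0, +2): frame(p) = ref(p - (0, 2))
  shifted <- warp_bilinear_cpp(ref, matrix(0, 64, 64), matrix(-2, 64, 64))
  # independent oracle: exhaustive integer cross-correlation
  expect_equal(bruteShift(shifted, ref, 4L), c(0L, 2L))
  f <- estimateMotionField(shifted, ref)
  interior <- as.matrix(expand.grid(10:54, 10:54))
  expect_lt(abs(median(f@dy[interior])), 0.25)
  expect_lt(abs(median(f@dx[interior]) - 2), 0.25)
})

test_that("stronger smoothness penalty yields a smoother field", {
  ref <- smoothTestImage(48, 48, seed = 7)
  mov <- warp_bilinear_cpp(ref, matrix(0.8, 48, 48),
                           matrix(-0.5, 48, 48))
  f800 <- estimateMotionField(mov, ref, opticFlowParams(lambdaSmooth = 800))
  fBig <- estimateMotionField(mov, ref, opticFlowParams(lambdaSmooth = 1e6))
  expect_lt(fieldGradientEnergy(fBig), fieldGradientEnergy(f800))
})

test_that("solver energy is non-increasing within every linearization", {
  sim <- generateConnectiveMovie(nFrames = 3, height = 48, width = 64,
                                 nAxons = 10, motionAmplitude = 3,
                                 nonrigidAmplitude = 1, noiseSd = 2,
                                 seed = 8)
  f <- estimateMotionField(frameData(sim$red)[3, , ],
                           frameData(sim$red)[1, , ])
  for (e in attr(f, "energy")) {
    if (length(e) > 1L) expect_true(all(diff(e) <= 1e-8 * e[1L]))
  }
})

test_that("bilinear warping: zero field identity, integer shift, round trip", {
  img <- smoothTestImage(40, 40, seed = 9)
  zero <- MotionField(matrix(0, 40, 40), matrix(0, 40, 40))
  expect_equal(warpBilinear(img, zero), img)

  shift2 <- MotionField(matrix(0, 40, 40), matrix(2, 40, 40))
  out <- warpBilinear(img, shift2)
  expect_equal(out[, 1:38], img[, 3:40])

  set.seed(10)
  fy <- smoothImageGauss(matrix(rnorm(1600), 40, 40), 6)
  fy <- fy / max(abs(fy)) * 1.5
  fx <- smoothImageGauss(matrix(rnorm(1600), 40, 40), 6)
  fx <- fx / max(abs(fx)) * 1.5
  fwd <- MotionField(fy, fx)
  bwd <- MotionField(-fy, -fx)
  back <- warpBilinear(warpBilinear(img, fwd), bwd)
  interior <- 5:36
  err <- mean(abs(back[interior, interior] - img[interior, interior]))
  expect_lt(err, 0.01 * diff(range(img)))
})

test_that("two-channel correction recovers truth fields and helps every frame", {
  sim <- generateConnectiveMovie(nFrames = 6, height = 64, width = 96,
                                 nAxons = 14, motionAmplitude = 4,
                                 nonrigidAmplitude = 1.5, noiseSd = 2,
                                 seed = 11)
  corr <- suppressWarnings(correctTwoChannel(sim$red, sim$green))
  epe <- meanEndpointError(corr$fields, corr$comOffsets,
                           sim$truth$trueMotionFields)
  expect_lt(mean(epe), 0.5)

  ref <- frameData(sim$red)[1, , ]
  for (t in 2:6) {
    rawCor <- cor(as.vector(frameData(sim$red)[t, , ]), as.vector(ref))
    corCor <- cor(as.vector(frameData(corr$red)[t, , ]), as.vector(ref))
    expect_gte(corCor, rawCor)
  }
})

test_that("a static green channel stays static after red-driven correction", {
  sim <- generateConnectiveMovie(nFrames = 4, height = 48, width = 64,
                                 nAxons = 10, motionAmplitude = 3,
                                 nonrigidAmplitude = 1, noiseSd = 0,
                                 fluctuationSd = 0, seed = 12)
  corr <- suppressWarnings(correctTwoChannel(sim$red, sim$green))
  g <- frameData(corr$green)
  rng <- diff(range(g[1, , ]))
  interior <- list(6:43, 6:59)
  for (t in 2:4) {
    err <- mean(abs(g[t, interior[[1]], interior[[2]]] -
                    g[1, interior[[1]], interior[[2]]]))
    expect_lt(err, 0.01 * rng)
  }
})

test_that("subpixel translation registration recovers known shifts", {
  ref <- smoothTestImage(72, 72, seed = 13)
  expect_equal(unname(registerTranslation(ref, ref)), c(0, 0))
  shifted <- warp_bilinear_cpp(ref, matrix(4, 72, 72), matrix(-7, 72, 72))
  rec <- registerTranslation(shifted, ref)
  expect_lt(abs(rec["dy"] - (-4)), 0.1)
  expect_lt(abs(rec["dx"] - 7), 0.1)
  expect_warning(registerTranslation(matrix(1, 8, 8), matrix(1, 8, 8)),
                 "constant")
})

test_that("zero-motion fixed point holds across random smooth images", {
  for (s in 1:4) {
    img <- smoothTestImage(40, 48, seed = 20 + s)
    f <- estimateMotionField(img, img)
    expect_lt(mean(sqrt(f@dy^2 + f@dx^2)), 0.05)
  }
})
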