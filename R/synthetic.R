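#' Wave specification for synthetic connective movies
#'
#' Describes a large traveling wave of activity sweeping across connective
#' regions in a fixed order (as seen after high-dose caffeine ingestion):
#' activity begins dorsomedially, then dorsolaterally, then ventrally, with
#' the giant-fiber axons last.
#'
#' @param onsetTime time of the first region's peak (s).
#' @param regionOrder ordered character vector of region labels; subsets of
#'   `c("dorsomedial", "dorsolateral", "ventral", "giant")`.
#' @param interRegionLag lag between successive regions' peaks (s, >= 0).
#' @param amplitude wave amplitude as a multiple of the locomotor
#'   fluctuation amplitude (> 0).
#' @param duration wave duration (s); the waveform is a Gaussian bump with
#'   sigma `duration / 4`.
#' @return A named list describing the wave.
#' @export
waveSpec <- function(onsetTime, regionOrder = c("dorsomedial", "dorsolateral",
                                                "ventral", "giant"),
                     interRegionLag = 1, amplitude = 4, duration = 6) {
  stopifnot(interRegionLag >= 0, amplitude > 0, duration > 0,
            length(regionOrder) >= 1)
  list(onsetTime = onsetTime, regionOrder = regionOrder,
       interRegionLag = interRegionLag, amplitude = amplitude,
       duration = duration)
}

# Smooth low-order sinusoidal displacement basis fields (<= 3), scaled so
# the combined field peaks at `amplitude` pixels.
nonrigidBasis <- function(H, W) {
  y <- matrix(seq_len(H) / H, H, W)
  x <- matrix(seq_len(W) / W, H, W, byrow = TRUE)
  list(sin(pi * y) * sin(pi * x),
       sin(pi * y) * cos(pi * x),
       sin(2 * pi * y) * sin(pi * x))
}

ellipseBlob <- function(H, W, cy, cx, sy, sx) {
  y <- matrix(seq_len(H), H, W)
  x <- matrix(seq_len(W), H, W, byrow = TRUE)
  g <- exp(-((y - cy)^2 / (2 * sy^2) + (x - cx)^2 / (2 * sx^2)))
  mask <- ((y - cy) / (2.5 * sy))^2 + ((x - cx) / (2.5 * sx))^2 <= 1
  g * mask
}

# Region layout of a coronal connective cross-section (fractional boxes).
connectiveRegionBox <- function(region, side = 1L) {
  switch(region,
    dorsomedial = c(0.30, 0.42, 0.38, 0.62),
    dorsolateral = if (side == 1L) c(0.28, 0.46, 0.08, 0.26)
                   else c(0.28, 0.46, 0.74, 0.92),
    ventral = c(0.58, 0.85, 0.18, 0.82),
    giant = c(0.10, 0.18, 0.42, 0.58),
    stop("unknown region: ", region))
}

#' Generate a synthetic two-channel connective movie with ground truth
#'
#' Emulates coronal two-photon cross-sections of the cervical connective:
#' elliptical axon cross-sections (truncated 2-D Gaussians) on a dim
#' background, assigned to four regions (dorsomedial, dorsolateral,
#' ventral, giant fiber). Both channels share the same geometry and motion
#' (rigid sinusoidal translation plus a smooth low-order non-rigid field);
#' the red channel is static anatomy, the green channel scales each axon by
#' its calcium trace (locomotor-locked fluctuations plus an optional
#' traveling wave). A left-right linear illumination gain multiplies both
#' channels, and additive Gaussian noise (clipped at 0) is applied last.
#' Motion is zero on the first frame, so truth motion fields are relative
#' to the recorded reference frame.
#'
#' @param nFrames number of frames.
#' @param frameRate frames per second (default 16).
#' @param height,width frame size in pixels (default 128 x 192, a reduced
#'   test scale; the full acquisition scale 480 x 736 is supported).
#' @param nAxons number of axon cross-sections (default 30, two of which
#'   are the giant-fiber pair).
#' @param motionAmplitude peak rigid translation (pixels).
#' @param nonrigidAmplitude peak non-rigid displacement (pixels).
#' @param illuminationSlope fractional gain change per pixel along x
#'   (default 0.002).
#' @param backgroundTextureSd sd of the static smoothed speckle texture on
#'   the background (a.u., default 8): two-photon background is structured
#'   tissue autofluorescence, not a flat field, and this texture is what
#'   makes motion observable away from the axons.
#' @param noiseSd additive Gaussian noise sd (a.u.).
#' @param wave optional [waveSpec()].
#' @param fluctuationSd sd of locomotor-locked calcium fluctuations
#'   (fraction of baseline trace level, default 0.3).
#' @param walkingIntervals optional list of `c(start, end)` (s); locomotor
#'   fluctuations are restricted to these intervals (default: whole
#'   recording).
#' @param seed integer seed; identical seed and parameters give
#'   bit-identical output.
#' @return A list with `red` and `green` [FrameStack-class] objects and
#'   `truth`: `trueMotionFields` (list of [MotionField-class] in the
#'   correction convention), `roiMasks` (labeled matrix), `roiRegions`
#'   (region per ROI label), `trueCalciumTraces` ([SampledTrace-class],
#'   one column per ROI), `illuminationGain` (per-pixel multiplier),
#'   `wavePeakTimes` (per ROI, s; `NA` without wave), `walkingIntervals`.
#' @export
generateConnectiveMovie <- function(nFrames, frameRate = 16, height = 128,
                                    width = 192, nAxons = 30,
                                    motionAmplitude = 3,
                                    nonrigidAmplitude = 1,
                                    illuminationSlope = 0.002,
                                    backgroundTextureSd = 8, noiseSd = 2,
                                    wave = NULL, fluctuationSd = 0.3,
                                    walkingIntervals = NULL, seed = NULL) {
  stopifnot(nFrames >= 1, height >= 16, width >= 16, nAxons >= 4,
            motionAmplitude >= 0, nonrigidAmplitude >= 0, noiseSd >= 0,
            fluctuationSd >= 0)
  withSeed(seed, {
    H <- height; W <- width; T <- as.integer(nFrames)
    tGrid <- (seq_len(T) - 1L) / frameRate

    # --- anatomy template and ROI labels ---
    regions <- c("giant", "giant",
                 rep(c("dorsomedial", "dorsolateral", "ventral"),
                     length.out = nAxons - 2L))
    shapes <- matrix(0, H * W, nAxons)
    labels <- matrix(0L, H, W)
    ampRed <- runif(nAxons, 80, 160)
    ampGreen <- runif(nAxons, 60, 120)
    margin <- motionAmplitude + nonrigidAmplitude + 2
    for (a in seq_len(nAxons)) {
      side <- if (a %% 2L == 0L) 1L else 2L
      box <- connectiveRegionBox(regions[a], side)
      if (regions[a] == "giant")
        box[3:4] <- if (a == 1L) c(0.42, 0.47) else c(0.53, 0.58)
      sy <- runif(1, 2.2, 3.6); sx <- runif(1, 2.2, 3.6)
      if (regions[a] == "giant") { sy <- sy + 0.8; sx <- sx + 0.8 }
      cy <- runif(1, box[1L] * H, box[2L] * H)
      cx <- runif(1, box[3L] * W, box[4L] * W)
      cy <- min(max(cy, margin + 2.5 * sy), H - margin - 2.5 * sy)
      cx <- min(max(cx, margin + 2.5 * sx), W - margin - 2.5 * sx)
      blob <- ellipseBlob(H, W, cy, cx, sy, sx)
      shapes[, a] <- as.vector(blob)
      labels[blob > 0.05 & labels == 0L] <- a
    }
    bgRed <- 30; bgGreen <- 10
    speckle <- matrix(0, H, W)
    if (backgroundTextureSd > 0) {
      speckle <- smoothImageGauss(matrix(rnorm(H * W), H, W), 2)
      speckle <- speckle / sd(speckle) * backgroundTextureSd
      speckle <- pmax(speckle, -bgRed + 1)   # keep templates positive
    }
    templateRed <- matrix(bgRed, H, W) + speckle +
      matrix(shapes %*% ampRed, H, W)

    # --- calcium traces ---
    refAmp <- if (fluctuationSd > 0) fluctuationSd else 0.3
    traces <- matrix(1, T, nAxons)
    if (fluctuationSd > 0 && T > 1L) {
      smSigma <- max(1, 0.3 * frameRate)
      for (a in seq_len(nAxons)) {
        f <- smoothGauss1d(rnorm(T), smSigma)
        s <- sd(f)
        if (s > 0) f <- f / s * fluctuationSd
        if (!is.null(walkingIntervals)) {
          inWalk <- rep(FALSE, T)
          for (iv in walkingIntervals)
            inWalk <- inWalk | (tGrid >= iv[1L] & tGrid < iv[2L])
          f[!inWalk] <- 0
        }
        traces[, a] <- traces[, a] + f
      }
    }
    wavePeakTimes <- rep(NA_real_, nAxons)
    if (!is.null(wave)) {
      rank <- match(regions, wave$regionOrder)
      sig <- wave$duration / 4
      for (a in seq_len(nAxons)) {
        if (is.na(rank[a])) next
        pk <- wave$onsetTime + (rank[a] - 1L) * wave$interRegionLag
        wavePeakTimes[a] <- pk
        traces[, a] <- traces[, a] +
          wave$amplitude * refAmp * exp(-(tGrid - pk)^2 / (2 * sig^2))
      }
    }
    traces <- pmax(traces, 0.05)

    # --- motion fields ---
    basis <- nonrigidBasis(H, W)
    fRig <- runif(2, 0.1, 0.3)
    fNr <- runif(3, 0.1, 0.25)
    wNr <- runif(3, 0.5, 1)
    sgn <- sample(c(-1, 1), 3, replace = TRUE)
    # worst-case per-axis peak of the basis mixes, so the combined field
    # never exceeds the nominal non-rigid amplitude
    mixPeakY <- max(abs(basis[[1]] * wNr[1]) + abs(basis[[3]] * wNr[3]))
    mixPeakX <- max(abs(basis[[2]] * wNr[2]) + abs(basis[[1]] * wNr[1]))
    gain <- matrix(1 + illuminationSlope * (seq_len(W) - (W + 1) / 2),
                   H, W, byrow = TRUE)
    if (any(gain <= 0)) stop("illuminationSlope too steep: gain must stay positive")

    zero <- matrix(0, H, W)
    red <- array(0, c(T, H, W))
    green <- array(0, c(T, H, W))
    fields <- vector("list", T)
    for (t in seq_len(T)) {
      tt <- tGrid[t]
      # content displacement (how far frame content moved from reference)
      dRigY <- motionAmplitude * sin(2 * pi * fRig[1L] * tt)
      dRigX <- motionAmplitude * sin(2 * pi * fRig[2L] * tt)
      dNrY <- zero; dNrX <- zero
      if (nonrigidAmplitude > 0) {
        dNrY <- (nonrigidAmplitude / mixPeakY) *
          (basis[[1]] * wNr[1] * sin(2 * pi * fNr[1] * tt) +
           basis[[3]] * wNr[3] * sgn[1] * sin(2 * pi * fNr[3] * tt))
        dNrX <- (nonrigidAmplitude / mixPeakX) *
          (basis[[2]] * wNr[2] * sin(2 * pi * fNr[2] * tt) +
           basis[[1]] * wNr[1] * sgn[2] * sin(2 * pi * fNr[1] * tt))
      }
      dY <- dRigY + dNrY
      dX <- dRigX + dNrX
      # synthesis by backward warp: frame(p) = template(p - d(p)) = warp by -d
      fy <- -dY; fx <- -dX
      templateGreen <- matrix(bgGreen, H, W) + 0.3 * pmax(speckle, -bgGreen / 0.3 + 1) +
        matrix(shapes %*% (ampGreen * traces[t, ]), H, W)
      if (motionAmplitude > 0 || nonrigidAmplitude > 0) {
        redF <- warp_bilinear_cpp(templateRed, fy, fx)
        greenF <- warp_bilinear_cpp(templateGreen, fy, fx)
        # correction field g solves g(p) = d(p + g(p)) (fixed point)
        gy <- dY; gx <- dX
        for (k in 1:6) {
          gy2 <- warp_bilinear_cpp(dY, gy, gx)
          gx2 <- warp_bilinear_cpp(dX, gy, gx)
          gy <- gy2; gx <- gx2
        }
        fields[[t]] <- MotionField(gy, gx, t)
      } else {
        redF <- templateRed
        greenF <- templateGreen
        fields[[t]] <- MotionField(zero, zero, t)
      }
      redF <- redF * gain
      greenF <- greenF * gain
      if (noiseSd > 0) {
        redF <- pmax(redF + matrix(rnorm(H * W, 0, noiseSd), H, W), 0)
        greenF <- pmax(greenF + matrix(rnorm(H * W, 0, noiseSd), H, W), 0)
      }
      red[t, , ] <- redF
      green[t, , ] <- greenF
    }
    roiRegions <- regions
    names(roiRegions) <- as.character(seq_len(nAxons))
    list(red = FrameStack(red, frameRate, "red"),
         green = FrameStack(green, frameRate, "green"),
         truth = list(
           trueMotionFields = fields,
           roiMasks = labels,
           roiRegions = roiRegions,
           trueCalciumTraces = SampledTrace(traces, frameRate),
           illuminationGain = gain,
           wavePeakTimes = wavePeakTimes,
           walkingIntervals = walkingIntervals))
  })
}

#' Generate synthetic optic-flow sensor traces with ground truth
#'
#' Builds body-frame forward/sideways/turning rotation-rate series from the
#' requested segments (zero elsewhere), pushes them through the documented
#' two-sensor forward model (the map inverted by [sensorsToVelocities()],
#' so round trips are exact), and adds Gaussian sensor noise.
#'
#' @param duration total duration (s).
#' @param rate sampling rate (Hz, default 400).
#' @param ballDiameter ball diameter in mm (default 10).
#' @param segments list of `list(start, end, forward, sideways, turning)`
#'   with times in s and rates in rotations/s; segments must be
#'   non-overlapping and inside `[0, duration]`.
#' @param sensorNoiseSd sensor noise sd (rotations/s, default 0.005).
#' @param seed integer seed.
#' @return A list with `traces` (raw 4-channel [SampledTrace-class]) and
#'   `truth`: `trueVelocities` (noise-free 3-channel trace),
#'   `stationaryIntervals` (list of `c(start, end)` where all true rates
#'   are zero), `stationaryMask` (per sample).
#' @export
generateSensorTraces <- function(duration, rate = 400, ballDiameter = 10,
                                 segments = list(), sensorNoiseSd = 0.005,
                                 seed = NULL) {
  stopifnot(duration > 0, rate > 0, sensorNoiseSd >= 0)
  segs <- lapply(segments, function(s) {
    s <- as.list(s)
    stopifnot(length(s) == 5L)
    names(s) <- c("start", "end", "forward", "sideways", "turning")
    if (s$start < 0 || s$end > duration || s$end <= s$start)
      stop("segment outside [0, duration]")
    s
  })
  if (length(segs) > 1L) {
    o <- order(vapply(segs, `[[`, numeric(1), "start"))
    segs <- segs[o]
    starts <- vapply(segs, `[[`, numeric(1), "start")
    ends <- vapply(segs, `[[`, numeric(1), "end")
    if (any(starts[-1L] < ends[-length(ends)])) stop("segments overlap")
  }
  withSeed(seed, {
    n <- as.integer(round(duration * rate))
    tt <- (seq_len(n) - 1L) / rate
    vel <- matrix(0, n, 3L,
                  dimnames = list(NULL, c("forward", "sideways", "turning")))
    for (s in segs) {
      idx <- tt >= s$start & tt < s$end
      vel[idx, ] <- matrix(c(s$forward, s$sideways, s$turning),
                           sum(idx), 3L, byrow = TRUE)
    }
    A <- sensorForwardMatrix()
    readings <- vel %*% t(A)
    if (sensorNoiseSd > 0)
      readings <- readings + matrix(rnorm(length(readings), 0, sensorNoiseSd),
                                    nrow = n)
    moving <- rowSums(vel != 0) > 0L
    r <- rle(!moving)
    ends <- cumsum(r$lengths)
    starts <- c(1L, head(ends, -1L) + 1L)
    iv <- lapply(which(r$values), function(k)
      c((starts[k] - 1L) / rate, ends[k] / rate))
    list(traces = SampledTrace(readings, rate),
         truth = list(trueVelocities = SampledTrace(vel, rate),
                      stationaryIntervals = iv,
                      stationaryMask = !moving,
                      ballDiameter = ballDiameter))
  })
}

#' Generate a synthetic arena trajectory with ground truth
#'
#' Emulates an optogenetic backward-walking session: the centroid walks
#' forward along a fixed heading at `baselineSpeed` for the spontaneous
#' period; at each stimulation onset the translational velocity ramps down
#' at `-responseSlope` to `-backwardPeakSpeed`, holds, and relaxes back at
#' `+responseSlope` during the inter-stimulus interval. Positions integrate
#' the velocity by a left Riemann sum; Gaussian position noise is added
#' last. True per-epoch metrics (slope, left-Riemann backward distance over
#' negative frames, minimum velocity) are computed from the noise-free
#' sampled velocity with the same discrete definitions the analysis uses.
#'
#' @param cameraRate camera rate (Hz, default 80).
#' @param spontaneousDuration spontaneous period (s, default 30).
#' @param nStims number of stimulation epochs (default 3).
#' @param stimDuration epoch duration (s, default 3).
#' @param interStimInterval inter-stimulus interval (s, default 10).
#' @param baselineSpeed forward speed (mm/s, default 5).
#' @param backwardPeakSpeed peak backward speed (mm/s, default 10).
#' @param responseSlope ramp rate (mm/s^2, default 20); `Inf` switches
#'   instantaneously.
#' @param noiseSd centroid position noise sd (mm, default 0.05).
#' @param seed integer seed.
#' @return A list with `trajectory` (a [Trajectory-class]), and `truth`:
#'   `epochs` (the [sessionSchedule()]), `trueMetrics` (data.frame with
#'   `epoch`, `responseSlope`, `backwardDistance`, `maxNegativeVelocity`),
#'   `trueVelocity` (noise-free [SampledTrace-class]).
#' @export
generateArenaTrajectory <- function(cameraRate = 80, spontaneousDuration = 30,
                                    nStims = 3, stimDuration = 3,
                                    interStimInterval = 10, baselineSpeed = 5,
                                    backwardPeakSpeed = 10, responseSlope = 20,
                                    noiseSd = 0.05, seed = NULL) {
  stopifnot(cameraRate > 0, spontaneousDuration > 0, stimDuration > 0,
            interStimInterval > 0, nStims >= 0, baselineSpeed >= 0,
            backwardPeakSpeed >= 0, responseSlope > 0, noiseSd >= 0)
  sched <- sessionSchedule(spontaneousDuration, nStims, stimDuration,
                           interStimInterval)
  withSeed(seed, {
    n <- as.integer(round(sched$totalDuration * cameraRate))
    tt <- (seq_len(n) - 1L) / cameraRate
    # transient response: smooth (half-cosine, C1) descent to the peak
    # backward speed with mean ramp rate responseSlope, then a 2x slower
    # half-cosine relaxation back to baseline (the backward run is
    # strongest early and adapts); smooth kinks keep the Savitzky-Golay
    # derivative faithful
    v <- rep(baselineSpeed, n)
    A <- baselineSpeed + backwardPeakSpeed
    for (ep in sched$epochs) {
      o <- ep$onset; e <- ep$onset + ep$duration
      if (is.infinite(responseSlope)) {
        v[tt >= o & tt < e] <- -backwardPeakSpeed
        v[tt >= e] <- baselineSpeed
      } else {
        d <- A / responseSlope
        tMin <- o + d
        down <- tt >= o & tt < tMin
        up <- tt >= tMin & tt < tMin + 2 * d
        v[down] <- baselineSpeed - (A / 2) * (1 - cos(pi * (tt[down] - o) / d))
        v[up] <- -backwardPeakSpeed +
          (A / 2) * (1 - cos(pi * (tt[up] - tMin) / (2 * d)))
        v[tt >= tMin + 2 * d] <- baselineSpeed
      }
    }
    metrics <- do.call(rbind, lapply(seq_along(sched$epochs), function(k) {
      ep <- sched$epochs[[k]]
      idx <- which(tt >= ep$onset & tt < ep$onset + ep$duration)
      ve <- v[idx]
      iMin <- which.min(ve)
      slope <- if (iMin == 1L) 0 else (ve[iMin] - ve[1L]) / ((iMin - 1L) / cameraRate)
      data.frame(epoch = k, responseSlope = slope,
                 backwardDistance = sum(ve[ve < 0]) / cameraRate,
                 maxNegativeVelocity = min(ve))
    }))
    x <- cumsum(c(0, v[-n])) / cameraRate
    centroid <- cbind(x = x, y = rep(0, n))
    if (noiseSd > 0)
      centroid <- centroid + matrix(rnorm(2L * n, 0, noiseSd), n, 2L)
    heading <- cbind(rep(1, n), rep(0, n))
    list(trajectory = Trajectory(centroid, heading, cameraRate),
         truth = list(epochs = sched$epochs,
                      trueMetrics = if (is.null(metrics))
                        data.frame(epoch = integer(), responseSlope = numeric(),
                                   backwardDistance = numeric(),
                                   maxNegativeVelocity = numeric()) else metrics,
                      trueVelocity = SampledTrace(v, cameraRate)))
  })
}

#' Daily image series for one fly
#'
#' Light-weight container for longitudinal single-plane projections.
#'
#' @param images `D x H x W` array, one projection per day.
#' @param days strictly increasing day indices (dpi); the first day must be
#'   present.
#' @param flyId identifier string.
#' @param group `"intact"` or `"amputated"`.
#' @return An object of class `DailySeries` (a validated list).
#' @export
dailySeries <- function(images, days, flyId, group = c("intact", "amputated")) {
  group <- match.arg(group)
  stopifnot(length(dim(images)) == 3L, dim(images)[1L] == length(days),
            all(diff(days) > 0), length(days) >= 1L)
  structure(list(images = images, days = days, flyId = flyId, group = group),
            class = "DailySeries")
}

#' Generate a synthetic longitudinal degradation experiment
#'
#' Emulates daily projections of chordotonal-organ axon terminals in the T1
#' neuromere: every fly photobleaches at `bleachRate`; in amputated flies
#' the designated ROI additionally decays at `amputationDecayRate` starting
#' the day after amputation at 2 dpi, so the noise-free ROI mean on day `d`
#' equals the day-1 mean times `exp(-k (d - 2))` for `d >= 2`. Each day's
#' image is translated by a recorded random jitter before noise is added.
#'
#' @param nDays days imaged (default 15, i.e. 1..15 dpi).
#' @param height,width image size (default 80 x 96).
#' @param bleachRate photobleaching rate (1/day, all ROIs, default 0.03).
#' @param amputationDecayRate additional decay (1/day) of the designated
#'   ROI in amputated flies (default 0.2).
#' @param jitter day-to-day translation amplitude (pixels, uniform in
#'   `[-jitter, jitter]`; day 1 is never jittered).
#' @param noiseSd additive Gaussian noise sd (a.u., default 2).
#' @param nFliesPerGroup flies per group (default 5).
#' @param nRois ROIs per fly (default 3; ROI 1 is the designated one).
#' @param seed integer seed.
#' @return A list with `flies` (list of [dailySeries()] objects) and
#'   `truth`: `roiMasks` (per fly, labeled matrix in day-1 coordinates),
#'   `jitterOffsets` (per fly, `D x 2`), `trueDecayRates` (per fly, per-ROI
#'   1/day, excluding bleach), `bleachRate`, `day1Means`.
#' @export
generateDegradationSeries <- function(nDays = 15, height = 80, width = 96,
                                      bleachRate = 0.03,
                                      amputationDecayRate = 0.2, jitter = 1.5,
                                      noiseSd = 2, nFliesPerGroup = 5,
                                      nRois = 3, seed = NULL) {
  if (nDays < 2) stop("need at least two days")
  stopifnot(bleachRate >= 0, amputationDecayRate >= 0, jitter >= 0,
            noiseSd >= 0, nFliesPerGroup >= 1, nRois >= 1)
  withSeed(seed, {
    H <- height; W <- width
    flies <- list()
    truth <- list(roiMasks = list(), jitterOffsets = list(),
                  trueDecayRates = list(), bleachRate = bleachRate,
                  day1Means = list())
    centers <- cbind(y = H * seq(0.25, 0.75, length.out = nRois),
                     x = W * rep(c(0.3, 0.7), length.out = nRois))
    fi <- 0L
    for (group in c("intact", "amputated")) {
      for (f in seq_len(nFliesPerGroup)) {
        fi <- fi + 1L
        flyId <- sprintf("%s_%02d", group, f)
        base <- matrix(10, H, W)
        labels <- matrix(0L, H, W)
        for (r in seq_len(nRois)) {
          cy <- centers[r, 1L] + runif(1, -3, 3)
          cx <- centers[r, 2L] + runif(1, -3, 3)
          sy <- runif(1, 4, 6); sx <- runif(1, 4, 6)
          blob <- ellipseBlob(H, W, cy, cx, sy, sx)
          base <- base + runif(1, 90, 110) * blob
          labels[blob > 0.05 & labels == 0L] <- r
        }
        decayRates <- rep(0, nRois)
        if (group == "amputated") decayRates[1L] <- amputationDecayRate
        offs <- matrix(0, nDays, 2L, dimnames = list(NULL, c("dy", "dx")))
        imgs <- array(0, c(nDays, H, W))
        for (d in seq_len(nDays)) {
          img <- base * exp(-bleachRate * (d - 1L))
          for (r in which(decayRates > 0)) {
            fac <- exp(-decayRates[r] * max(0L, d - 2L))
            img[labels == r] <- img[labels == r] * fac
          }
          if (jitter > 0 && d > 1L) {
            offs[d, ] <- runif(2, -jitter, jitter)
            # content moves by offs: sample at p - offs
            img <- warp_bilinear_cpp(img, matrix(-offs[d, 1L], H, W),
                                     matrix(-offs[d, 2L], H, W))
          }
          if (noiseSd > 0)
            img <- pmax(img + matrix(rnorm(H * W, 0, noiseSd), H, W), 0)
          imgs[d, , ] <- img
        }
        flies[[flyId]] <- dailySeries(imgs, seq_len(nDays), flyId, group)
        truth$roiMasks[[flyId]] <- labels
        truth$jitterOffsets[[flyId]] <- offs
        truth$trueDecayRates[[flyId]] <- decayRates
        truth$day1Means[[flyId]] <- vapply(seq_len(nRois), function(r)
          mean(base[labels == r]), numeric(1))
      }
    }
    list(flies = flies, truth = truth)
  })
}
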