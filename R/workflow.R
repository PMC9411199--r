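#' Pipeline configuration
#'
#' One configuration object drives the three synthetic studies; every
#' numeric default mirrors the acquisition and analysis settings of the
#' experiments the pipelines emulate (lambda = 800, median kernel (71, 91),
#' sigma values, thresholds, windows, session protocol). Reduced movie
#' dimensions keep a full run fast; the acquisition scale is available by
#' overriding `movie` entries.
#'
#' @param seed master seed; all pipeline randomness derives from it.
#' @param movie connective-movie settings (list; see
#'   [generateConnectiveMovie()]).
#' @param flow [opticFlowParams()].
#' @param photometry [photometryParams()].
#' @param stationarity [stationarityParams()].
#' @param waveTiming [waveTimingParams()].
#' @param caffeine caffeine-study settings: flies per condition, trial
#'   duration (s), wave description.
#' @param arena arena-study settings (see [generateArenaTrajectory()]).
#' @param degradation degradation-study settings (see
#'   [generateDegradationSeries()]).
#' @return A nested configuration list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(seed = 1L,
                           movie = list(height = 48, width = 72, nAxons = 20,
                                        frameRate = 16, motionAmplitude = 0,
                                        nonrigidAmplitude = 0, noiseSd = 1,
                                        illuminationSlope = 0.002,
                                        fluctuationSd = 0.3),
                           flow = opticFlowParams(),
                           photometry = NULL,
                           stationarity = stationarityParams(),
                           waveTiming = waveTimingParams(),
                           caffeine = list(nFliesPerCondition = 3,
                                           nPreTrials = 2,
                                           trialDuration = 25,
                                           waveAmplitude = 4,
                                           waveLag = 1,
                                           waveDuration = 6),
                           arena = list(nFlies = 5, noiseSd = 0.05,
                                        savgolWindow = 15),
                           degradation = list(nDays = 15, nFliesPerGroup = 5,
                                              bleachRate = 0.03,
                                              amputationDecayRate = 0.2,
                                              jitter = 1.5, noiseSd = 2)) {
  if (is.null(photometry)) {
    # default median kernel scaled inside fitIlluminationProfile when the
    # frame is smaller than the acquisition scale
    photometry <- photometryParams(centralWidth = min(200, movie$width - 2))
  }
  structure(list(seed = as.integer(seed), movie = movie, flow = flow,
                 photometry = photometry, stationarity = stationarity,
                 waveTiming = waveTiming, caffeine = caffeine, arena = arena,
                 degradation = degradation),
            class = "PipelineConfig")
}

configChecksum <- function(config) {
  s <- paste(deparse(config), collapse = "")
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %% 1e9
}

provenance <- function(config) {
  list(seed = config$seed, configChecksum = configChecksum(config),
       packageVersion = as.character(utils::packageVersion("flyvnc")))
}

caffeineBins <- function() c("pre", "during", "lt9", "lt19", "lt29", "lt38")

# One trial: generate movie, optionally motion-correct, return the
# connective-mean trace (and the corrected green stack if requested).
caffeineTrial <- function(config, withWave, keepStack = FALSE) {
  mv <- config$movie
  cf <- config$caffeine
  T <- as.integer(round(cf$trialDuration * mv$frameRate))
  wave <- if (withWave)
    waveSpec(onsetTime = cf$trialDuration / 2, interRegionLag = cf$waveLag,
             amplitude = cf$waveAmplitude, duration = cf$waveDuration)
    else NULL
  sim <- generateConnectiveMovie(
    nFrames = T, frameRate = mv$frameRate, height = mv$height,
    width = mv$width, nAxons = mv$nAxons,
    motionAmplitude = mv$motionAmplitude,
    nonrigidAmplitude = mv$nonrigidAmplitude,
    illuminationSlope = mv$illuminationSlope, noiseSd = mv$noiseSd,
    fluctuationSd = mv$fluctuationSd, wave = wave)
  green <- sim$green
  if (mv$motionAmplitude > 0 || mv$nonrigidAmplitude > 0) {
    corr <- correctTwoChannel(sim$red, sim$green, params = config$flow)
    green <- corr$green
  }
  mask <- sim$truth$roiMasks > 0
  trace <- connectiveMeanTrace(green, mask)
  out <- list(trace = trace, truth = sim$truth)
  if (keepStack) out$green <- green
  out
}

#' Run the synthetic caffeine-wave study end to end
#'
#' Generates pre-feeding and post-feeding trials for three conditions
#' (sucrose, low caffeine, high caffeine; waves appear only in the
#' high-caffeine 29-38 min bin), normalizes each fly's connective-mean
#' fluorescence to its 99th pre-feeding percentile, computes the maximum
#' normalized activity per period, tests high caffeine against each
#' control per period (one-sided Mann-Whitney, continuity-corrected
#' normal), and maps the pixel-wise wave peak times for one high-caffeine
#' wave trial. A bin is declared significant when both comparisons give
#' p < 0.05.
#'
#' @param config a [pipelineConfig()].
#' @return A list: `activities` (data.frame fly x bin), `stats` (per-bin
#'   p-values and significance), `peakMap` (pixel peak times), `peakTruth`
#'   (per-ROI true wave peak times and recovered per-ROI median peak
#'   times), `provenance`.
#' @export
runCaffeinePipeline <- function(config = pipelineConfig()) {
  withSeed(config$seed, {
    conditions <- c("sucrose", "low_caffeine", "high_caffeine")
    bins <- caffeineBins()
    cf <- config$caffeine
    rows <- list()
    peakMap <- NULL
    peakTruth <- NULL
    for (cond in conditions) {
      for (fly in seq_len(cf$nFliesPerCondition)) {
        flyId <- sprintf("%s_%d", cond, fly)
        preTraces <- lapply(seq_len(cf$nPreTrials), function(k)
          caffeineTrial(config, withWave = FALSE)$trace)
        norm <- computeNormalization(preTraces)
        for (bin in bins) {
          if (bin == "pre") {
            # the pre-feeding period is the very data that defined the
            # normalization constant, so this is exactly 1
            preAll <- SampledTrace(
              unlist(lapply(preTraces, function(tr) as.vector(traceValues(tr)))),
              traceRate(preTraces[[1L]]))
            act <- maxNormalizedActivity(preAll, norm)
          } else {
            withWave <- cond == "high_caffeine" && bin == "lt38"
            keep <- withWave && is.null(peakMap)
            trial <- caffeineTrial(config, withWave = withWave,
                                   keepStack = keep)
            act <- maxNormalizedActivity(trial$trace, norm)
            if (keep) {
              tPeak <- globalPeakTime(trial$trace)
              timing <- config$waveTiming
              pm <- suppressWarnings(
                pixelPeakTimeMap(trial$green, tPeak, timing))
              labels <- trial$truth$roiMasks
              ids <- sort(unique(labels[labels > 0]))
              recovered <- vapply(ids, function(id)
                median(pm[labels == id]), numeric(1))
              peakMap <- pm
              peakTruth <- data.frame(
                roi = ids,
                region = unname(trial$truth$roiRegions[as.character(ids)]),
                truePeakTime = trial$truth$wavePeakTimes[ids],
                recoveredPeakTime = recovered)
            }
          }
          rows[[length(rows) + 1L]] <- data.frame(
            flyId = flyId, condition = cond, bin = bin,
            maxNormalizedActivity = act)
        }
      }
    }
    activities <- do.call(rbind, rows)
    stats <- do.call(rbind, lapply(bins, function(bin) {
      sub <- activities[activities$bin == bin, ]
      hi <- sub$maxNormalizedActivity[sub$condition == "high_caffeine"]
      su <- sub$maxNormalizedActivity[sub$condition == "sucrose"]
      lo <- sub$maxNormalizedActivity[sub$condition == "low_caffeine"]
      pSu <- suppressWarnings(mannWhitneyU(hi, su, sides = "one"))
      pLo <- suppressWarnings(mannWhitneyU(hi, lo, sides = "one"))
      data.frame(bin = bin, pVsSucrose = pSu, pVsLowCaffeine = pLo,
                 significant = pSu < 0.05 && pLo < 0.05)
    }))
    list(activities = activities, stats = stats, peakMap = peakMap,
         peakTruth = peakTruth, provenance = provenance(config))
  })
}

#' Run the synthetic arena locomotion study
#'
#' Generates one session per fly (default protocol: 30 s spontaneous,
#' three 3 s stimulations, 10 s intervals — 59 s total), computes signed
#' translational velocities with the Savitzky-Golay derivative, applies the
#' exclusion rules and extracts the three backward-walking metrics per
#' kept epoch.
#'
#' @param config a [pipelineConfig()].
#' @return A list: `metrics` (data.frame fly x epoch with slope, distance,
#'   min velocity, exclusion), `session` (protocol summary incl. total
#'   duration), `truth` (per-fly generator truth), `provenance`.
#' @export
runArenaPipeline <- function(config = pipelineConfig()) {
  withSeed(config$seed, {
    ar <- config$arena
    sched <- sessionSchedule()
    rows <- list()
    truths <- list()
    for (fly in seq_len(ar$nFlies)) {
      flyId <- sprintf("fly_%02d", fly)
      sim <- generateArenaTrajectory(noiseSd = ar$noiseSd)
      vel <- translationalVelocity(sim$trajectory,
                                   savgolWindow = ar$savgolWindow)
      excl <- excludeEpochs(sim$trajectory, sim$truth$epochs)
      for (k in seq_along(sim$truth$epochs)) {
        ep <- sim$truth$epochs[[k]]
        kept <- excl$kept[k]
        rows[[length(rows) + 1L]] <- data.frame(
          flyId = flyId, epoch = k, kept = kept,
          reason = excl$reason[k],
          responseSlope = if (kept) responseSlope(vel, ep) else NA_real_,
          backwardDistance = if (kept) backwardDistance(vel, ep) else NA_real_,
          maxNegativeVelocity = if (kept) maxNegativeVelocity(vel, ep)
                                else NA_real_)
      }
      truths[[flyId]] <- sim$truth
    }
    list(metrics = do.call(rbind, rows),
         session = list(totalDuration = sched$totalDuration,
                        nEpochs = length(sched$epochs),
                        onsets = vapply(sched$epochs, `[[`, numeric(1),
                                        "onset")),
         truth = truths, provenance = provenance(config))
  })
}

#' Run the synthetic degradation study
#'
#' Generates daily projections for intact and amputated flies, aligns each
#' series to day 1, extracts per-ROI means, normalizes to day 1 and
#' compares the groups per day (two-sided exact Mann-Whitney).
#'
#' @param config a [pipelineConfig()].
#' @return A list: `table` (normalized per-day per-ROI fluorescence),
#'   `stats` (per-day p-values for the designated ROI), `truth`,
#'   `provenance`.
#' @export
runDegradationPipeline <- function(config = pipelineConfig()) {
  withSeed(config$seed, {
    dg <- config$degradation
    sim <- generateDegradationSeries(
      nDays = dg$nDays, bleachRate = dg$bleachRate,
      amputationDecayRate = dg$amputationDecayRate, jitter = dg$jitter,
      noiseSd = dg$noiseSd, nFliesPerGroup = dg$nFliesPerGroup)
    tabs <- lapply(sim$flies, function(series) {
      aligned <- if (dg$jitter > 0) alignSeries(series) else series
      roiMeanByDay(aligned, sim$truth$roiMasks[[series$flyId]])
    })
    table <- normalizeToFirstDay(do.call(rbind, tabs))
    stats <- compareGroupsByDay(table, roiId = 1L)
    list(table = table, stats = stats, truth = sim$truth,
         provenance = provenance(config))
  })
}
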