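#' Mean fluorescence trace over the connective
#'
#' Per-frame mean over the masked pixels (the entire cervical connective,
#' or any region of it).
#'
#' @param stack a [FrameStack-class].
#' @param mask logical or 0/1 matrix selecting pixels.
#' @return A [SampledTrace-class] with one column.
#' @export
connectiveMeanTrace <- function(stack, mask) {
  mask <- mask != 0
  if (!any(mask)) stop("mask selects no pixels")
  dat <- frameData(stack)
  if (!identical(dim(mask), dim(dat)[2:3]))
    stop("mask shape does not match stack")
  m <- matrix(dat, nrow = dim(dat)[1L])
  vals <- rowMeans(m[, as.vector(mask), drop = FALSE])
  SampledTrace(vals, frameRate(stack))
}

#' Pre-feeding normalization constant
#'
#' Concatenates the connective-mean traces of all pre-feeding trials of one
#' fly and takes the 99th percentile (linear-interpolation definition).
#' Normalizing all of the fly's trials by this value makes the maximum
#' normalized pre-feeding fluorescence unity by construction.
#'
#' @param preFeedingTraces a list of [SampledTrace-class] objects (or one).
#' @return The normalization constant (scalar, a.u.).
#' @export
computeNormalization <- function(preFeedingTraces) {
  if (inherits(preFeedingTraces, "SampledTrace"))
    preFeedingTraces <- list(preFeedingTraces)
  if (length(preFeedingTraces) < 1L) stop("need at least one pre-feeding trial")
  all <- unlist(lapply(preFeedingTraces, function(tr) as.vector(traceValues(tr))))
  v <- percentileLinear(all, 0.99)
  if (v <= 0) stop("normalization constant must be positive")
  v
}

#' Maximum normalized activity within a period
#'
#' The "maximum" is the upper boundary of the 99% percentile of the
#' normalized trace, i.e. the 99th percentile of `trace / norm`, not the
#' raw maximum — this makes the statistic robust to single-sample spikes.
#'
#' @param trace a [SampledTrace-class] (the period of interest).
#' @param norm normalization constant from [computeNormalization()].
#' @return Scalar maximum normalized activity.
#' @export
maxNormalizedActivity <- function(trace, norm) {
  stopifnot(norm > 0)
  v <- as.vector(traceValues(trace))
  if (length(v) == 0L) stop("empty period")
  percentileLinear(v / norm, 0.99)
}

#' Mann-Whitney U test
#'
#' Rank-sum test between two independent groups. `method = "normal_cc"`
#' uses the tie-corrected variance with a continuity-corrected normal
#' approximation (at n = 3 vs 3 under complete separation this gives
#' p = 0.0404 one-sided); `method = "exact"` enumerates the permutation
#' null (all `choose(m + n, m)` group assignments; intended for group
#' sizes <= 8). One-sided tests the alternative that `groupA` is
#' stochastically greater than `groupB`.
#'
#' @param groupA,groupB numeric vectors, both nonempty.
#' @param sides `"one"` or `"two"`.
#' @param method `"normal_cc"` or `"exact"`.
#' @return The p-value.
#' @export
mannWhitneyU <- function(groupA, groupB, sides = c("one", "two"),
                         method = c("normal_cc", "exact")) {
  sides <- match.arg(sides)
  method <- match.arg(method)
  m <- length(groupA); n <- length(groupB)
  if (m < 1L || n < 1L) stop("both groups must be nonempty")
  pooled <- c(groupA, groupB)
  if (length(unique(pooled)) == 1L) {
    warning("all values tied across both groups; p = 1")
    return(1)
  }
  r <- rank(pooled)
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  if (method == "exact") {
    uDist <- exactUDistribution(m, n, pooled)
    if (sides == "one") {
      p <- mean(uDist >= U)
    } else {
      p <- min(1, 2 * min(mean(uDist >= U), mean(uDist <= U)))
    }
    return(p)
  }
  mu <- m * n / 2
  ties <- table(pooled)
  N <- m + n
  tieCorr <- sum(ties^3 - ties) / (N * (N - 1))
  sig2 <- m * n / 12 * ((N + 1) - tieCorr)
  if (sig2 <= 0) {
    warning("zero variance after tie correction; p = 1")
    return(1)
  }
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
  if (sides == "one") pnorm(z, lower.tail = FALSE)
  else 2 * pnorm(abs(z), lower.tail = FALSE)
}

# Null distribution of U by enumeration of all group-A index subsets.
exactUDistribution <- function(m, n, pooled) {
  r <- rank(pooled)
  combos <- utils::combn(m + n, m)
  apply(combos, 2L, function(idx) sum(r[idx])) - m * (m + 1) / 2
}

#' Smooth and min-max normalize an ROI trace
#'
#' Gaussian smoothing (sigma in samples, default 3, ~0.18 s at 16 Hz)
#' followed by rescaling to `[0, 1]`; used to display per-region wave
#' time courses on a common scale.
#'
#' @param trace a [SampledTrace-class], nonconstant.
#' @param sigma Gaussian sigma in samples.
#' @return The normalized [SampledTrace-class].
#' @export
roiTraceNormalize <- function(trace, sigma = 3) {
  v <- as.vector(traceValues(trace))
  sm <- smoothGauss1d(v, sigma)
  rng <- range(sm)
  if (rng[1L] == rng[2L]) stop("constant trace: min-max rescale undefined")
  SampledTrace((sm - rng[1L]) / (rng[2L] - rng[1L]), traceRate(trace),
               trace@t0)
}

#' Time of global peak fluorescence
#'
#' Time of the maximum of the connective-mean trace (T_peak); ties are
#' broken by the earliest time.
#'
#' @param trace a [SampledTrace-class].
#' @return Peak time in seconds (on the trace's own clock).
#' @export
globalPeakTime <- function(trace) {
  v <- as.vector(traceValues(trace))
  if (length(v) == 0L) stop("empty trace")
  traceTimes(trace)[which.max(v)]
}

#' Wave-timing parameters
#'
#' @param searchHalfwidth half width of the peak search window around
#'   T_peak (s, default 10).
#' @param temporalSigma temporal Gaussian sigma (samples, default 10,
#'   ~0.62 s at 16 Hz).
#' @param spatialSigma spatial Gaussian sigma (pixels, default 1).
#' @param traceSigma sigma for ROI trace smoothing (samples, default 3).
#' @return A named parameter list.
#' @export
waveTimingParams <- function(searchHalfwidth = 10, temporalSigma = 10,
                             spatialSigma = 1, traceSigma = 3) {
  stopifnot(searchHalfwidth > 0, temporalSigma > 0, spatialSigma > 0,
            traceSigma > 0)
  list(searchHalfwidth = searchHalfwidth, temporalSigma = temporalSigma,
       spatialSigma = spatialSigma, traceSigma = traceSigma)
}

#' Pixel-wise peak-time map around the global peak
#'
#' Applies a temporal Gaussian filter (sigma 10 samples) and a spatial
#' Gaussian filter (sigma 1 px) to the stack, then reports, per pixel, the
#' time of the maximum within `tPeak +- searchHalfwidth`, relative to
#' `tPeak`. A window extending beyond the recording is clipped with a
#' warning.
#'
#' @param stack a [FrameStack-class].
#' @param tPeak global peak time (s) from [globalPeakTime()].
#' @param timing a [waveTimingParams()] list.
#' @return Matrix of per-pixel peak times (s, relative to `tPeak`).
#' @export
pixelPeakTimeMap <- function(stack, tPeak, timing = waveTimingParams()) {
  dat <- frameData(stack)
  T <- dim(dat)[1L]
  fr <- frameRate(stack)
  tt <- (seq_len(T) - 1L) / fr
  lo <- tPeak - timing$searchHalfwidth
  hi <- tPeak + timing$searchHalfwidth
  if (lo < tt[1L] || hi > tt[T])
    warning("search window exceeds the recording; clipped")
  win <- which(tt >= lo & tt <= hi)
  if (length(win) == 0L) stop("empty search window")
  m <- matrix(dat, nrow = T)
  sm <- apply(m, 2L, smoothGauss1d, sigma = timing$temporalSigma)
  Sy <- gaussSmoothingMatrix(dim(dat)[2L], timing$spatialSigma)
  Sx <- t(gaussSmoothingMatrix(dim(dat)[3L], timing$spatialSigma))
  peaks <- matrix(0, dim(dat)[2L], dim(dat)[3L])
  smWin <- array(t(sm[win, , drop = FALSE]), c(dim(dat)[2:3], length(win)))
  for (k in seq_along(win))
    smWin[, , k] <- Sy %*% smWin[, , k] %*% Sx
  idx <- apply(smWin, c(1L, 2L), which.max)
  matrix(tt[win][idx] - tPeak, nrow(idx), ncol(idx))
}

#' Mean image over stationary frames
#'
#' Mean fluorescence over frames during which the fly was not moving the
#' ball; used to display anatomy-like activity maps uncontaminated by
#' locomotor fluctuations.
#'
#' @param stack a [FrameStack-class].
#' @param stationaryMask logical vector, one entry per frame.
#' @return Matrix of per-pixel means.
#' @export
nonmovingMeanImage <- function(stack, stationaryMask) {
  dat <- frameData(stack)
  stopifnot(length(stationaryMask) == dim(dat)[1L])
  if (!any(stationaryMask)) stop("no stationary frames")
  apply(dat[stationaryMask, , , drop = FALSE], c(2L, 3L), mean)
}
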