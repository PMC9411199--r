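#' Stationarity classification parameters
#'
#' @param speedThreshold rotation-rate threshold (rotations/s, default
#'   0.01; equivalently 0.31 mm/s surface speed on a 10 mm ball, since
#'   0.01 rot/s x pi x 10 mm = 0.314 mm/s).
#' @param contextHalfwidth half width of the context window (s, default
#'   0.5).
#' @param minFraction minimum fraction of sub-threshold samples within the
#'   context window (default 0.75); this removes short pauses between
#'   walking bouts.
#' @return A named parameter list.
#' @export
stationarityParams <- function(speedThreshold = 0.01, contextHalfwidth = 0.5,
                               minFraction = 0.75) {
  stopifnot(speedThreshold > 0, contextHalfwidth >= 0, minFraction > 0,
            minFraction <= 1)
  list(speedThreshold = speedThreshold, contextHalfwidth = contextHalfwidth,
       minFraction = minFraction)
}

#' Moving average of a trace
#'
#' Centered moving mean over `window` samples (80 samples ~ 200 ms at
#' 400 Hz), applied per signal; edges are truncated and renormalized, so
#' length and rate are unchanged. This suppresses the intrinsic noise of
#' the optic-flow sensors.
#'
#' @param trace a [SampledTrace-class].
#' @param window window length in samples (default 80).
#' @return The smoothed [SampledTrace-class].
#' @export
movingAverage <- function(trace, window = 80L) {
  v <- traceValues(trace)
  if (window < 1L || window > nrow(v))
    stop("window must be between 1 and the trace length")
  out <- apply(v, 2L, movingMean, window = as.integer(window))
  if (is.null(dim(out))) out <- matrix(out, ncol = ncol(v))
  colnames(out) <- colnames(v)
  SampledTrace(out, traceRate(trace), trace@t0)
}

# Two optic-flow sensors view the ball equator at +-45 deg azimuth. Each
# sensor reads a horizontal (equatorial) and a vertical flow component, in
# ball rotations/s:
#   sensor0 (at -45 deg): x = turn,  y = (forward - sideways) / sqrt(2)
#   sensor1 (at +45 deg): x = turn,  y = (forward + sideways) / sqrt(2)
sensorForwardMatrix <- function() {
  s <- 1 / sqrt(2)
  # rows: s0x, s0y, s1x, s1y; cols: forward, sideways, turning
  matrix(c(0, 0, 1,
           s, -s, 0,
           0, 0, 1,
           s, s, 0),
         nrow = 4L, byrow = TRUE,
         dimnames = list(c("sensor0_x", "sensor0_y", "sensor1_x", "sensor1_y"),
                         c("forward", "sideways", "turning")))
}

#' Convert raw sensor readings to body-frame ball velocities
#'
#' Applies the fixed linear map of the two-sensor (+-45 deg equatorial)
#' geometry to recover forward, sideways and turning rotation rates. The
#' map is the pseudoinverse of the documented forward model (the same model
#' used by [generateSensorTraces()]), so noise-free synthetic readings
#' round-trip exactly. Multiply rotation rates by `pi * ballDiameter` for
#' surface speed in mm/s.
#'
#' @param traces a [SampledTrace-class] with 4 columns
#'   (sensor0_x, sensor0_y, sensor1_x, sensor1_y), in rotations/s.
#' @param ballDiameter ball diameter in mm (default 10; recorded as an
#'   attribute for unit conversion).
#' @return A [SampledTrace-class] with columns forward, sideways, turning
#'   (rotations/s); attribute `ballDiameter` carries the diameter.
#' @export
sensorsToVelocities <- function(traces, ballDiameter = 10) {
  v <- traceValues(traces)
  if (ncol(v) != 4L) stop("expected 4 sensor channels (2 sensors x 2 axes)")
  A <- sensorForwardMatrix()
  pinv <- solve(crossprod(A), t(A))   # exact left inverse: A has full rank
  out <- v %*% t(pinv)
  colnames(out) <- colnames(A)
  res <- SampledTrace(out, traceRate(traces), traces@t0)
  attr(res, "ballDiameter") <- ballDiameter
  res
}

#' Classify stationary periods
#'
#' A sample is stationary iff (i) the absolute forward, sideways and
#' turning rates are all below `speedThreshold` and (ii) at least
#' `minFraction` of the samples within +-`contextHalfwidth` seconds satisfy
#' (i). Windows truncate at the trace edges and the fraction is computed
#' over the available samples.
#'
#' @param vel a [SampledTrace-class] of forward/sideways/turning rates
#'   (rotations/s).
#' @param params a [stationarityParams()] list.
#' @return A logical vector, one entry per sample.
#' @export
classifyStationary <- function(vel, params = stationarityParams()) {
  v <- traceValues(vel)
  below <- rowSums(abs(v) >= params$speedThreshold) == 0L
  n <- length(below)
  hw <- as.integer(round(params$contextHalfwidth * traceRate(vel)))
  if (hw == 0L) return(below)
  cs <- cumsum(c(0L, as.integer(below)))
  i <- seq_len(n)
  a <- pmax(i - hw, 1L)
  b <- pmin(i + hw, n)
  frac <- (cs[b + 1L] - cs[a]) / (b - a + 1L)
  below & frac >= params$minFraction
}

#' Downsample a trace to the imaging frame clock
#'
#' Frame `i` aggregates all samples with time in
#' `[(i-1)/frameRate, i/frameRate)` (times relative to the trace origin):
#' numeric signals by the mean, logical signals by majority vote. A frame
#' interval containing no samples (possible only if the sample rate is
#' below the frame rate) yields `NA` with a warning.
#'
#' @param trace a [SampledTrace-class] (numeric or logical values).
#' @param frameRate imaging frame rate (Hz, default 16).
#' @param nFrames number of imaging frames to produce.
#' @return A matrix `nFrames x k` of per-frame values.
#' @export
downsampleToFrames <- function(trace, frameRate = 16, nFrames) {
  v <- traceValues(trace)
  isLogical <- is.logical(v) || all(v %in% c(0, 1))
  tt <- traceTimes(trace) - trace@t0
  idx <- floor(tt * frameRate) + 1L
  keep <- idx >= 1L & idx <= nFrames
  out <- matrix(NA_real_, nFrames, ncol(v))
  colnames(out) <- colnames(v)
  for (j in seq_len(ncol(v))) {
    sums <- tapply(v[keep, j], idx[keep], mean)
    out[as.integer(names(sums)), j] <- sums
  }
  if (anyNA(out))
    warning("some frame intervals contain no samples; returned NA")
  if (isLogical) out <- out > 0.5
  out
}

#' Convert rotation rates to surface speed
#'
#' @param rotationsPerS rotation rate (rotations/s).
#' @param ballDiameter ball diameter in mm (default 10).
#' @return Surface speed in mm/s (`rotations/s * pi * diameter`).
#' @export
rotationsToMmPerS <- function(rotationsPerS, ballDiameter = 10) {
  rotationsPerS * pi * ballDiameter
}
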