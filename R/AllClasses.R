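#' FrameStack: a single-channel imaging movie
#'
#' Container for a two-photon movie: a `T x Y x X` array of non-negative
#' intensities (arbitrary units) together with its frame rate and a channel
#' tag. The green (GCaMP) channel carries the time-varying fluorescence `F`
#' of the dF/F computation; the red (tdTomato) channel is the
#' activity-independent anatomical signal used for motion estimation.
#'
#' @slot data numeric array, `T x Y x X`.
#' @slot frameRate frames per second (Hz).
#' @slot channel one of `"red"`, `"green"`, `"mono"`.
#' @export
setClass("FrameStack",
  representation(data = "array", frameRate = "numeric", channel = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a T x Y x X array")
    else if (dim(object@data)[1L] < 1L)
      msg <- c(msg, "need at least one frame")
    if (!all(is.finite(object@data)))
      msg <- c(msg, "data must be finite")
    if (length(object@frameRate) != 1L || object@frameRate <= 0)
      msg <- c(msg, "frameRate must be a single positive number")
    if (!object@channel %in% c("red", "green", "mono"))
      msg <- c(msg, "channel must be one of red/green/mono")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct a FrameStack
#'
#' @param data `T x Y x X` numeric array of intensities.
#' @param frameRate frame rate in Hz (default 16, typical for a
#'   galvo-resonance two-photon scanner).
#' @param channel channel tag, `"red"`, `"green"` or `"mono"`.
#' @return A [FrameStack-class] object.
#' @export
FrameStack <- function(data, frameRate = 16, channel = "mono") {
  new("FrameStack", data = data, frameRate = frameRate, channel = channel)
}

#' MotionField: dense per-frame displacement
#'
#' Per-pixel displacement `(dy, dx)` in pixels, in the correction
#' (backward-warping) convention: the field maps reference-frame coordinates
#' to the coordinates in the moving frame at which to sample, so that
#' `corrected(p) = frame(p + field(p))`.
#'
#' @slot dy,dx numeric matrices (pixels), same shape as the frame.
#' @slot frameIndex index of the frame this field corrects (1-based).
#' @export
setClass("MotionField",
  representation(dy = "matrix", dx = "matrix", frameIndex = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!identical(dim(object@dy), dim(object@dx)))
      msg <- c(msg, "dy and dx must have identical shape")
    if (!all(is.finite(object@dy)) || !all(is.finite(object@dx)))
      msg <- c(msg, "displacements must be finite")
    if (is.null(msg)) TRUE else msg
  }
)

#' @rdname MotionField-class
#' @param dy,dx displacement matrices (pixels).
#' @param frameIndex frame index the field belongs to.
#' @export
MotionField <- function(dy, dx, frameIndex = 1L) {
  new("MotionField", dy = dy, dx = dx, frameIndex = as.integer(frameIndex))
}

#' SampledTrace: a uniformly sampled time series
#'
#' Holds sensor readings, velocities, or fluorescence traces: an `n x k`
#' matrix of samples (one column per signal), a sampling rate and a time
#' origin.
#'
#' @slot values numeric matrix, `n` samples by `k` signals.
#' @slot rate sampling rate (Hz).
#' @slot t0 time of the first sample (s).
#' @export
setClass("SampledTrace",
  representation(values = "matrix", rate = "numeric", t0 = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!all(is.finite(object@values))) msg <- c(msg, "values must be finite")
    if (length(object@rate) != 1L || object@rate <= 0)
      msg <- c(msg, "rate must be a single positive number")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct a SampledTrace
#'
#' @param values numeric vector or `n x k` matrix of samples.
#' @param rate sampling rate (Hz).
#' @param t0 time of the first sample (s), default 0.
#' @return A [SampledTrace-class] object.
#' @export
SampledTrace <- function(values, rate, t0 = 0) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  new("SampledTrace", values = values, rate = rate, t0 = t0)
}

#' BaselineImage: per-pixel fluorescence baseline F0
#'
#' The pixel-wise baseline `F0` of the dF/F computation, floored at a small
#' positive `epsilon` so that the ratio is always defined.
#'
#' @slot f0 numeric matrix of baseline values (a.u.), all `>= epsilon`.
#' @slot epsilon positive floor value (a.u.).
#' @export
setClass("BaselineImage",
  representation(f0 = "matrix", epsilon = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@epsilon <= 0) msg <- c(msg, "epsilon must be positive")
    if (any(object@f0 < object@epsilon))
      msg <- c(msg, "f0 must be >= epsilon everywhere")
    if (is.null(msg)) TRUE else msg
  }
)

#' IlluminationProfile: left-right gain model
#'
#' A per-column multiplicative gain along the medial-lateral (x) axis,
#' summarized by the straight line fitted to the central columns of the
#' smoothed mean-image profile.
#'
#' @slot gain per-column gain (unitless), normalized to 1 at the image
#'   center.
#' @slot fitSlope slope of the fitted line (gain per pixel).
#' @slot fitIntercept intercept of the fitted line at column 1.
#' @slot centralWidth number of central columns used for the fit.
#' @export
setClass("IlluminationProfile",
  representation(gain = "numeric", fitSlope = "numeric",
                 fitIntercept = "numeric", centralWidth = "integer"),
  validity = function(object) {
    if (any(object@gain <= 0)) "gain must be positive" else TRUE
  }
)

#' Trajectory: arena centroid track
#'
#' Centroid positions and headings of a freely walking fly in a
#' rounded-square arena, at the behavior-camera frame rate, with per-frame
#' wall-contact and dorsally-flipped annotations used by the exclusion
#' rules.
#'
#' @slot centroid `n x 2` matrix of (x, y) positions in mm.
#' @slot heading `n x 2` matrix of unit heading vectors.
#' @slot rate camera frame rate (Hz).
#' @slot wallContact,flipped logical vectors, length `n`.
#' @export
setClass("Trajectory",
  representation(centroid = "matrix", heading = "matrix", rate = "numeric",
                 wallContact = "logical", flipped = "logical"),
  validity = function(object) {
    msg <- NULL
    n <- nrow(object@centroid)
    if (ncol(object@centroid) != 2L) msg <- c(msg, "centroid must be n x 2")
    if (!identical(dim(object@heading), c(n, 2L)))
      msg <- c(msg, "heading must match centroid shape")
    if (length(object@wallContact) != n || length(object@flipped) != n)
      msg <- c(msg, "annotation vectors must have one entry per frame")
    if (!all(is.finite(object@centroid))) msg <- c(msg, "centroid must be finite")
    if (length(object@rate) != 1L || object@rate <= 0)
      msg <- c(msg, "rate must be positive")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct a Trajectory
#'
#' @param centroid `n x 2` matrix of (x, y) positions (mm).
#' @param heading `n x 2` matrix of unit heading vectors (rows are
#'   normalized on construction).
#' @param rate camera frame rate (Hz), default 80.
#' @param wallContact,flipped per-frame logical annotations (default all
#'   `FALSE`).
#' @return A [Trajectory-class] object.
#' @export
Trajectory <- function(centroid, heading, rate = 80,
                       wallContact = NULL, flipped = NULL) {
  n <- nrow(centroid)
  nrm <- sqrt(rowSums(heading^2))
  nrm[nrm == 0] <- 1
  heading <- heading / nrm
  if (is.null(wallContact)) wallContact <- rep(FALSE, n)
  if (is.null(flipped)) flipped <- rep(FALSE, n)
  new("Trajectory", centroid = centroid, heading = heading, rate = rate,
      wallContact = wallContact, flipped = flipped)
}
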