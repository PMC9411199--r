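#' Accessors for flyvnc data classes
#'
#' Small accessor generics in place of direct slot access: `frameData()`
#' returns the `T x Y x X` array of a [FrameStack-class], `frameRate()` its
#' rate, `nFrames()` its length, `channelTag()` its channel;
#' `traceValues()`, `traceRate()` and `traceTimes()` access a
#' [SampledTrace-class]; `baselineValues()` the `F0` matrix of a
#' [BaselineImage-class]; `gainVector()` the per-column gain of an
#' [IlluminationProfile-class].
#'
#' @param x an object of the documented class.
#' @return The slot contents (see Description).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frameData", function(x) standardGeneric("frameData"))
#' @rdname accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("channelTag", function(x) standardGeneric("channelTag"))
#' @rdname accessors
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))
#' @rdname accessors
#' @export
setGeneric("traceRate", function(x) standardGeneric("traceRate"))
#' @rdname accessors
#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))
#' @rdname accessors
#' @export
setGeneric("baselineValues", function(x) standardGeneric("baselineValues"))
#' @rdname accessors
#' @export
setGeneric("gainVector", function(x) standardGeneric("gainVector"))

#' @rdname accessors
setMethod("frameData", "FrameStack", function(x) x@data)
#' @rdname accessors
setMethod("frameRate", "FrameStack", function(x) x@frameRate)
#' @rdname accessors
setMethod("nFrames", "FrameStack", function(x) dim(x@data)[1L])
#' @rdname accessors
setMethod("channelTag", "FrameStack", function(x) x@channel)
#' @rdname accessors
setMethod("traceValues", "SampledTrace", function(x) x@values)
#' @rdname accessors
setMethod("traceRate", "SampledTrace", function(x) x@rate)
#' @rdname accessors
setMethod("traceTimes", "SampledTrace",
  function(x) x@t0 + (seq_len(nrow(x@values)) - 1L) / x@rate)
#' @rdname accessors
setMethod("baselineValues", "BaselineImage", function(x) x@f0)
#' @rdname accessors
setMethod("gainVector", "IlluminationProfile", function(x) x@gain)

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("FrameStack (%s): %d frames of %d x %d px at %g Hz\n",
              object@channel, d[1L], d[2L], d[3L], object@frameRate))
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "SampledTrace", function(object) {
  cat(sprintf("SampledTrace: %d samples x %d signals at %g Hz (t0 = %g s)\n",
              nrow(object@values), ncol(object@values), object@rate,
              object@t0))
})

setMethod("show", "MotionField", function(object) {
  cat(sprintf("MotionField for frame %d: %d x %d px, mean |d| = %.3f px\n",
              object@frameIndex, nrow(object@dy), ncol(object@dy),
              mean(sqrt(object@dy^2 + object@dx^2))))
})

setMethod("show", "BaselineImage", function(object) {
  cat(sprintf("BaselineImage: %d x %d px, range [%.3g, %.3g] (eps = %g)\n",
              nrow(object@f0), ncol(object@f0), min(object@f0),
              max(object@f0), object@epsilon))
})

setMethod("show", "IlluminationProfile", function(object) {
  cat(sprintf(
    "IlluminationProfile: slope %.4g/px over central %d columns\n",
    object@fitSlope, object@centralWidth))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frames at %g Hz (%.1f s)\n",
              nrow(object@centroid), object@rate,
              nrow(object@centroid) / object@rate))
})
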