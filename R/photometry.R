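#' Photometry parameters
#'
#' Smoothing parameters for illumination correction and dF/F baseline
#' estimation.
#'
#' @param medianKernel median-filter size `(y, x)` in pixels applied to the
#'   temporal-mean image before profile fitting (default `c(71, 91)`; both
#'   odd).
#' @param profileSigma Gaussian sigma (pixels) applied after the median
#'   filter (default 3).
#' @param centralWidth number of central columns used for the straight-line
#'   fit (default 200).
#' @param baselineSpatialSigma spatial Gaussian sigma for the baseline
#'   (pixels, default 10).
#' @param baselineTemporalWindow temporal boxcar width for the baseline
#'   (samples, default 10, around 0.6 s at 16 Hz).
#' @param denoiseHalfWindow frames on each side used by the temporal
#'   denoiser (default 30, around 2 s at 16 Hz).
#' @return A named parameter list.
#' @export
photometryParams <- function(medianKernel = c(71, 91), profileSigma = 3,
                             centralWidth = 200, baselineSpatialSigma = 10,
                             baselineTemporalWindow = 10,
                             denoiseHalfWindow = 30) {
  stopifnot(length(medianKernel) == 2L, all(medianKernel %% 2 == 1),
            all(medianKernel > 0), profileSigma > 0, centralWidth > 1,
            baselineSpatialSigma > 0, baselineTemporalWindow >= 1,
            denoiseHalfWindow >= 1)
  list(medianKernel = as.integer(medianKernel), profileSigma = profileSigma,
       centralWidth = as.integer(centralWidth),
       baselineSpatialSigma = baselineSpatialSigma,
       baselineTemporalWindow = as.integer(baselineTemporalWindow),
       denoiseHalfWindow = as.integer(denoiseHalfWindow))
}

#' Fit the left-right illumination profile
#'
#' Fluorescence falls off along the medial-lateral (x) axis (scattering by
#' displaced thoracic organs). The temporal-mean image is median filtered
#' and Gaussian low-pass filtered to remove individual neurons, averaged
#' over y to an x profile, and a straight line is fitted to the most central
#' `centralWidth` columns. The per-column gain is that line normalized to 1
#' at the image center.
#'
#' @param meanImage the temporal mean of a motion-corrected stack (matrix).
#' @param params a [photometryParams()] list.
#' @return An [IlluminationProfile-class].
#' @export
fitIlluminationProfile <- function(meanImage, params = photometryParams()) {
  W <- ncol(meanImage)
  if (W <= params$centralWidth)
    stop("image width must exceed the central fitting width")
  ky <- min(params$medianKernel[1L], nrow(meanImage) - (nrow(meanImage) + 1) %% 2)
  kx <- min(params$medianKernel[2L], W - (W + 1) %% 2)
  sm <- median_filter2d_cpp(meanImage, ky, kx)
  sm <- smoothImageGauss(sm, params$profileSigma)
  profile <- colMeans(sm)
  xc <- (W + 1) / 2
  lo <- as.integer(floor(xc - params$centralWidth / 2)) + 1L
  cols <- lo:(lo + params$centralWidth - 1L)
  fit <- lm(profile[cols] ~ cols)
  a <- unname(coef(fit)[1L]); b <- unname(coef(fit)[2L])
  lineAll <- a + b * seq_len(W)
  center <- a + b * xc
  if (center <= 0 || any(lineAll <= 0))
    stop("degenerate illumination fit: line non-positive within the frame")
  new("IlluminationProfile", gain = lineAll / center, fitSlope = b / center,
      fitIntercept = a / center, centralWidth = params$centralWidth)
}

#' Apply illumination correction to a stack
#'
#' Multiplies every pixel in column x by the inverse of the fitted line.
#' The correction only aids visualization: dF/F is invariant to it because
#' signal and baseline of a pixel are multiplied by the same constant.
#'
#' @param stack a [FrameStack-class].
#' @param profile an [IlluminationProfile-class] covering the stack width.
#' @return The corrected [FrameStack-class].
#' @export
applyIlluminationCorrection <- function(stack, profile) {
  g <- gainVector(profile)
  d <- dim(frameData(stack))
  if (length(g) != d[3L]) stop("profile width does not match stack width")
  if (any(g <= 0)) stop("degenerate illumination fit: non-positive gain")
  dat <- frameData(stack)
  inv <- 1 / g
  dat <- sweep(dat, 3L, inv, "*")
  FrameStack(dat, frameRate(stack), channelTag(stack))
}

# Spatial Gaussian + centered temporal boxcar smoothing of one stack.
smoothStackForBaseline <- function(dat, spatialSigma, temporalWindow) {
  T <- dim(dat)[1L]
  if (spatialSigma > 0) {
    Sy <- gaussSmoothingMatrix(dim(dat)[2L], spatialSigma)
    Sx <- t(gaussSmoothingMatrix(dim(dat)[3L], spatialSigma))
    for (t in seq_len(T)) dat[t, , ] <- Sy %*% dat[t, , ] %*% Sx
  }
  if (temporalWindow > 1L && T > 1L) {
    w <- min(temporalWindow, T)
    m <- matrix(dat, nrow = T)
    m <- apply(m, 2L, movingMean, window = w)
    dat <- array(m, dim = dim(dat))
  }
  dat
}

#' Compute the pixel-wise dF/F baseline F0
#'
#' Each trial is spatially Gaussian filtered (sigma 10 px) and each pixel
#' convolved with a centered temporal boxcar of 10 samples (~0.6 s at
#' 16 Hz); F0 is the minimum fluorescence of each pixel across all frames
#' of all trials, floored at a small epsilon.
#'
#' @param trials a list of [FrameStack-class] objects sharing one shape.
#' @param params a [photometryParams()] list.
#' @return A [BaselineImage-class].
#' @export
computeBaseline <- function(trials, params = photometryParams()) {
  if (length(trials) < 1L) stop("need at least one trial")
  if (inherits(trials, "FrameStack")) trials <- list(trials)
  shapes <- lapply(trials, function(s) dim(frameData(s))[2:3])
  if (!all(vapply(shapes, identical, logical(1), shapes[[1L]])))
    stop("trials must share the same frame shape")
  gmax <- max(vapply(trials, function(s) max(frameData(s)), numeric(1)))
  f0 <- NULL
  for (tr in trials) {
    sm <- smoothStackForBaseline(frameData(tr), params$baselineSpatialSigma,
                                 params$baselineTemporalWindow)
    mn <- apply(sm, c(2L, 3L), min)
    f0 <- if (is.null(f0)) mn else pmin(f0, mn)
  }
  eps <- max(1e-6 * gmax, .Machine$double.eps)
  new("BaselineImage", f0 = pmax(f0, eps), epsilon = eps)
}

#' Compute dF/F
#'
#' Elementwise `(F - F0) / F0`; always `>= -1` because fluorescence is
#' non-negative and F0 is positive.
#'
#' @param stack a [FrameStack-class] carrying F.
#' @param baseline a [BaselineImage-class] carrying F0.
#' @return A [FrameStack-class] of dF/F values.
#' @export
computeDff <- function(stack, baseline) {
  f0 <- baselineValues(baseline)
  d <- dim(frameData(stack))
  if (!identical(dim(f0), d[2:3])) stop("baseline shape does not match stack")
  dat <- frameData(stack)
  dat <- sweep(sweep(dat, c(2L, 3L), f0, "-"), c(2L, 3L), f0, "/")
  FrameStack(dat, frameRate(stack), channelTag(stack))
}

#' Temporal denoising by neighborhood interpolation
#'
#' Each interior frame is predicted per pixel from the 30 frames before and
#' 30 frames after it (the frame itself excluded) by local linear
#' regression against time. With this symmetric, center-excluded design the
#' least-squares prediction at the target time equals the neighborhood
#' mean, which removes temporally independent noise while retaining
#' components that evolve slowly across frames. Border frames (closer than
#' the half window to either end) are returned unmodified and flagged.
#'
#' @param stack a [FrameStack-class] with more than `2 * denoiseHalfWindow`
#'   frames.
#' @param params a [photometryParams()] list.
#' @return A [FrameStack-class]; attribute `modified` is a logical vector
#'   marking frames that were denoised.
#' @export
temporalDenoise <- function(stack, params = photometryParams()) {
  h <- params$denoiseHalfWindow
  dat <- frameData(stack)
  T <- dim(dat)[1L]
  if (T <= 2L * h) stop("stack too short for the denoising window")
  m <- matrix(dat, nrow = T)
  # symmetric window excluding the center: prediction = neighbor mean
  k <- c(rep(1, h), 0, rep(1, h)) / (2 * h)
  sm <- apply(m, 2L, function(col) stats::filter(col, k, sides = 2))
  out <- m
  interior <- (h + 1L):(T - h)
  out[interior, ] <- sm[interior, ]
  res <- FrameStack(array(out, dim = dim(dat)), frameRate(stack),
                    channelTag(stack))
  modified <- rep(FALSE, T)
  modified[interior] <- TRUE
  attr(res, "modified") <- modified
  res
}
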