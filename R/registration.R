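#' Optic-flow parameters
#'
#' Parameters of the variational motion-field estimator. The energy is a
#' brightness-constancy data term plus `lambdaSmooth` times the squared
#' gradient of the displacement field (smoothness prior), minimized
#' coarse-to-fine over an image pyramid.
#'
#' @param lambdaSmooth regularization weight on the field gradient
#'   (unitless, default 800).
#' @param nPyramidLevels number of pyramid levels (downscale factor 2
#'   between levels, default 3).
#' @param iterationsPerLevel Gauss-Seidel sweeps per linearization
#'   (default 50).
#' @param convergenceTol stop a level early when the mean per-pixel
#'   displacement change per sweep falls below this (pixels, default 1e-3).
#' @param nWarps re-linearizations (warp iterations) per level (default 3).
#' @return A named list of validated parameters.
#' @export
opticFlowParams <- function(lambdaSmooth = 800, nPyramidLevels = 3,
                            iterationsPerLevel = 50, convergenceTol = 1e-3,
                            nWarps = 3) {
  stopifnot(lambdaSmooth > 0, nPyramidLevels >= 1, iterationsPerLevel >= 1,
            convergenceTol > 0, nWarps >= 1)
  list(lambdaSmooth = lambdaSmooth, nPyramidLevels = as.integer(nPyramidLevels),
       iterationsPerLevel = as.integer(iterationsPerLevel),
       convergenceTol = convergenceTol, nWarps = as.integer(nWarps))
}

# Integer-pixel shift with zero fill: out(p) = mat(p + c(dy, dx)).
shiftInteger <- function(mat, dy, dx, fill = 0) {
  H <- nrow(mat); W <- ncol(mat)
  out <- matrix(fill, H, W)
  ys <- seq_len(H) + dy
  xs <- seq_len(W) + dx
  okY <- ys >= 1 & ys <= H
  okX <- xs >= 1 & xs <= W
  if (any(okY) && any(okX))
    out[which(okY), which(okX)] <- mat[ys[okY], xs[okX], drop = FALSE]
  out
}

# Background-robust center of mass: the per-frame median (background
# level) is subtracted and negative values clipped, so a bright uniform
# background does not dilute the COM shift of the moving content.
frameCOM <- function(mat) {
  w <- pmax(mat - median(mat), 0)
  s <- sum(w)
  if (s == 0) return(c(NA_real_, NA_real_))
  c(sum(row(mat) * w), sum(col(mat) * w)) / s
}

#' Center-of-mass registration
#'
#' Removes large translations by shifting every frame (integer pixels, zero
#' fill) so that its intensity center of mass matches that of the reference
#' frame. Residual subpixel and non-rigid motion is left to the optic-flow
#' stage.
#'
#' @param stack a [FrameStack-class].
#' @param referenceIndex reference frame (1-based, default 1, the first
#'   recorded frame).
#' @return A list with `registered` (the shifted [FrameStack-class]) and
#'   `offsets`, a `T x 2` integer matrix of (dy, dx) per frame; the offset
#'   is how far the frame's center of mass lies from the reference's, so the
#'   applied shift samples at `p + offset`. Reusable on the paired channel
#'   via [applyFrameOffsets()].
#' @export
centerOfMassRegister <- function(stack, referenceIndex = 1L) {
  dat <- frameData(stack)
  T <- dim(dat)[1L]
  stopifnot(referenceIndex >= 1L, referenceIndex <= T)
  comRef <- frameCOM(dat[referenceIndex, , ])
  if (any(is.na(comRef))) stop("reference frame is all zero: COM undefined")
  offsets <- matrix(0L, T, 2L, dimnames = list(NULL, c("dy", "dx")))
  out <- dat
  for (t in seq_len(T)) {
    com <- frameCOM(dat[t, , ])
    if (any(is.na(com))) {
      warning(sprintf("frame %d is all zero: COM undefined, passed through", t))
      next
    }
    off <- as.integer(round(com - comRef))
    offsets[t, ] <- off
    if (any(off != 0L)) out[t, , ] <- shiftInteger(dat[t, , ], off[1L], off[2L])
  }
  list(registered = FrameStack(out, frameRate(stack), channelTag(stack)),
       offsets = offsets)
}

#' Apply precomputed per-frame integer offsets to a stack
#'
#' @param stack a [FrameStack-class].
#' @param offsets `T x 2` matrix of (dy, dx) as returned by
#'   [centerOfMassRegister()].
#' @return The shifted [FrameStack-class].
#' @export
applyFrameOffsets <- function(stack, offsets) {
  dat <- frameData(stack)
  stopifnot(nrow(offsets) == dim(dat)[1L])
  for (t in seq_len(dim(dat)[1L])) {
    if (any(offsets[t, ] != 0L))
      dat[t, , ] <- shiftInteger(dat[t, , ], offsets[t, 1L], offsets[t, 2L])
  }
  FrameStack(dat, frameRate(stack), channelTag(stack))
}

#' Centered crop of a stack
#'
#' Removes equal margins from both sides (background around the neck
#' connective); when a margin is odd the extra pixel is removed from the
#' high-index side.
#'
#' @param stack a [FrameStack-class].
#' @param targetHeight,targetWidth crop size in pixels.
#' @return The cropped [FrameStack-class].
#' @export
cropCenter <- function(stack, targetHeight, targetWidth) {
  d <- dim(frameData(stack))
  if (targetHeight > d[2L] || targetWidth > d[3L])
    stop("crop target exceeds stack dimensions")
  loY <- (d[2L] - targetHeight) %/% 2L
  loX <- (d[3L] - targetWidth) %/% 2L
  FrameStack(frameData(stack)[, loY + seq_len(targetHeight),
                              loX + seq_len(targetWidth), drop = FALSE],
             frameRate(stack), channelTag(stack))
}

pyramidSizes <- function(H, W, levels) {
  lapply(seq_len(levels) - 1L, function(l)
    c(max(8L, as.integer(round(H / 2^l))), max(8L, as.integer(round(W / 2^l)))))
}

#' Estimate a dense motion field between two frames
#'
#' Minimizes a classical quadratic (Horn-Schunck-type) variational energy:
#' a linearized brightness-constancy data term plus `lambdaSmooth` times the
#' squared gradient of the displacement field, solved coarse-to-fine with
#' exact per-pixel block Gauss-Seidel sweeps (so the per-level energy is
#' non-increasing across sweeps). The returned field is in the correction
#' convention: `corrected(p) = frame(p + field(p))`.
#'
#' @param frame,reference numeric matrices of the same shape (pre-aligned by
#'   center of mass).
#' @param params an [opticFlowParams()] list.
#' @param frameIndex index recorded in the returned field.
#' @param warnNonConvergence warn when the iteration budget is reached
#'   before the tolerance (default `TRUE`; [correctTwoChannel()] disables
#'   this and emits one summary warning instead).
#' @return A [MotionField-class]; attribute `energy` holds one vector of
#'   energies per linearization (coarsest level first) and attribute
#'   `converged` a logical flag.
#' @export
estimateMotionField <- function(frame, reference, params = opticFlowParams(),
                                frameIndex = 1L, warnNonConvergence = TRUE) {
  if (!all(is.finite(frame)) || !all(is.finite(reference)))
    stop("frames must be finite")
  stopifnot(identical(dim(frame), dim(reference)))
  H <- nrow(reference); W <- ncol(reference)
  sc <- max(abs(reference), abs(frame))
  sc <- if (sc > 0) 255 / sc else 1
  refS <- reference * sc
  movS <- frame * sc
  sizes <- rev(pyramidSizes(H, W, params$nPyramidLevels))  # coarsest first
  energies <- list()
  dy <- dx <- NULL
  converged <- TRUE
  for (li in seq_along(sizes)) {
    sz <- sizes[[li]]
    refL <- resize_bilinear_cpp(refS, sz[1L], sz[2L])
    movL <- resize_bilinear_cpp(movS, sz[1L], sz[2L])
    if (is.null(dy)) {
      dy <- dx <- matrix(0, sz[1L], sz[2L])
    } else {
      fy <- if (nrow(dy) > 1) (sz[1L] - 1) / (nrow(dy) - 1) else 1
      fx <- if (ncol(dx) > 1) (sz[2L] - 1) / (ncol(dx) - 1) else 1
      dy <- resize_bilinear_cpp(dy, sz[1L], sz[2L]) * fy
      dx <- resize_bilinear_cpp(dx, sz[1L], sz[2L]) * fx
    }
    for (w in seq_len(params$nWarps)) {
      movw <- warp_bilinear_cpp(movL, dy, dx)
      res <- hs_level_cpp(refL, movw, dy, dx, params$lambdaSmooth,
                          params$iterationsPerLevel, params$convergenceTol)
      dy <- res$dy; dx <- res$dx
      energies[[length(energies) + 1L]] <- res$energy
      if (length(res$energy) >= params$iterationsPerLevel) converged <- FALSE
    }
  }
  field <- MotionField(dy, dx, frameIndex)
  attr(field, "energy") <- energies
  attr(field, "converged") <- converged
  if (!converged && warnNonConvergence)
    warning("motion field did not reach convergence tolerance; returning best field")
  field
}

#' Warp a frame by a motion field (bilinear)
#'
#' `out(p) = frame(p + field(p))`, sampling bilinearly; out-of-bounds
#' samples take the nearest edge value.
#'
#' @param frame numeric matrix.
#' @param field a [MotionField-class] of the same shape.
#' @return The warped matrix.
#' @export
warpBilinear <- function(frame, field) {
  if (!identical(dim(frame), dim(field@dy)))
    stop("frame and field shapes differ")
  warp_bilinear_cpp(frame, field@dy, field@dx)
}

#' Two-channel motion correction
#'
#' Motion is estimated on the red (anatomy, tdTomato) channel only — the
#' calcium channel is too dim and activity-dependent for registration — and
#' the identical COM offsets and motion fields are applied to both channels.
#'
#' @param red,green [FrameStack-class] objects of identical shape and
#'   length.
#' @param referenceIndex reference frame (default 1).
#' @param params an [opticFlowParams()] list.
#' @return A list with `red`, `green` (corrected stacks), `fields` (list of
#'   [MotionField-class], flow component only), `comOffsets` (`T x 2`
#'   integer matrix). The total correction applied to frame `t` at pixel `p`
#'   is `fields[[t]](p) + comOffsets[t, ]`.
#' @export
correctTwoChannel <- function(red, green, referenceIndex = 1L,
                              params = opticFlowParams()) {
  if (!identical(dim(frameData(red)), dim(frameData(green))))
    stop("red and green stacks must have identical shape")
  com <- centerOfMassRegister(red, referenceIndex)
  redReg <- com$registered
  greenReg <- applyFrameOffsets(green, com$offsets)
  ref <- frameData(redReg)[referenceIndex, , ]
  T <- nFrames(red)
  fields <- vector("list", T)
  redOut <- frameData(redReg)
  greenOut <- frameData(greenReg)
  nNotConverged <- 0L
  for (t in seq_len(T)) {
    f <- estimateMotionField(frameData(redReg)[t, , ], ref, params,
                             frameIndex = t, warnNonConvergence = FALSE)
    if (!isTRUE(attr(f, "converged"))) nNotConverged <- nNotConverged + 1L
    fields[[t]] <- f
    redOut[t, , ] <- warpBilinear(frameData(redReg)[t, , ], f)
    greenOut[t, , ] <- warpBilinear(frameData(greenReg)[t, , ], f)
  }
  if (nNotConverged > 0L)
    warning(sprintf(
      "%d of %d motion fields did not reach the convergence tolerance within the iteration budget",
      nNotConverged, T))
  list(red = FrameStack(redOut, frameRate(red), "red"),
       green = FrameStack(greenOut, frameRate(green), "green"),
       fields = fields, comOffsets = com$offsets)
}

#' Endpoint error between recovered and reference motion fields
#'
#' Per-frame mean Euclidean distance between the total recovered correction
#' (flow field plus COM offset) and a reference field, evaluated over the
#' central analysis region. The excluded `margin` mirrors the background
#' crop of the correction pipeline: integer COM shifts fill the frame edges
#' with zeros, so the border carries no usable signal and is cropped before
#' analysis (the acquisition-scale pipeline crops 480 x 736 to 352 x 576
#' for the same reason).
#'
#' @param fields list of recovered [MotionField-class] objects.
#' @param comOffsets `T x 2` integer matrix of COM offsets.
#' @param reference list of reference [MotionField-class] objects.
#' @param margin border width excluded from the evaluation (pixels,
#'   default 12).
#' @return Numeric vector of per-frame mean endpoint errors (pixels).
#' @export
meanEndpointError <- function(fields, comOffsets, reference, margin = 12L) {
  stopifnot(length(fields) == length(reference))
  vapply(seq_along(fields), function(t) {
    f <- fields[[t]]
    g <- reference[[t]]
    H <- nrow(f@dy); W <- ncol(f@dy)
    ys <- (1L + margin):(H - margin)
    xs <- (1L + margin):(W - margin)
    e <- sqrt((f@dy[ys, xs] + comOffsets[t, 1L] - g@dy[ys, xs])^2 +
              (f@dx[ys, xs] + comOffsets[t, 2L] - g@dx[ys, xs])^2)
    mean(e)
  }, numeric(1))
}

#' Subpixel translation between two images
#'
#' Two-stage estimate of the shift `(dy, dx)` by which `image` content is
#' displaced relative to `reference` (i.e.
#' `image(p) ~ reference(p - shift)`): the integer peak of the
#' Hann-windowed FFT cross-correlation, refined to subpixel precision by
#' minimizing the mean squared residual between the back-shifted (bilinear)
#' image and the reference over a successively finer local grid.
#'
#' @param image,reference numeric matrices of the same shape.
#' @return Numeric `c(dy, dx)` in pixels.
#' @export
registerTranslation <- function(image, reference) {
  stopifnot(identical(dim(image), dim(reference)))
  if (sd(image) == 0 || sd(reference) == 0) {
    warning("constant image: translation undefined, returning (0, 0)")
    return(c(dy = 0, dx = 0))
  }
  H <- nrow(image); W <- ncol(image)
  hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  win <- outer(hann(H), hann(W))
  a <- (image - mean(image)) * win
  b <- (reference - mean(reference)) * win
  CC <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  pk <- arrayInd(which.max(CC), dim(CC))
  wrap <- function(k, n) if (k > n / 2) k - n else k
  dy <- wrap(pk[1L] - 1L, H)
  dx <- wrap(pk[2L] - 1L, W)
  # local refinement: residual after undoing the candidate shift
  marg <- min(8L, floor(min(H, W) / 4))
  ys <- (1L + marg):(H - marg)
  xs <- (1L + marg):(W - marg)
  resid <- function(sy, sx) {
    und <- warp_bilinear_cpp(image, matrix(sy, H, W), matrix(sx, H, W))
    mean((und[ys, xs] - reference[ys, xs])^2)
  }
  best <- c(dy, dx)
  for (step in c(1, 0.5, 0.25, 0.05, 0.01)) {
    for (iter in 1:10) {   # walk until the local grid centers on the min
      grid <- expand.grid(sy = best[1L] + step * (-2:2),
                          sx = best[2L] + step * (-2:2))
      vals <- mapply(resid, grid$sy, grid$sx)
      nxt <- as.numeric(grid[which.min(vals), ])
      if (all(nxt == best)) break
      best <- nxt
    }
  }
  c(dy = best[1L], dx = best[2L])
}
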