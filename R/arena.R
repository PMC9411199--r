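#' Stimulation schedule of an arena session
#'
#' The default protocol is 30 s of spontaneous behavior followed by three
#' 3 s optogenetic stimulation epochs with 10 s inter-stimulus intervals:
#' onsets at 30, 43 and 56 s, total 30 + 3*3 + 2*10 = 59 s.
#'
#' @param spontaneousDuration spontaneous period (s, default 30).
#' @param nStims number of stimulation epochs (default 3).
#' @param stimDuration epoch duration (s, default 3).
#' @param interStimInterval interval between epochs (s, default 10).
#' @return A list with `epochs` (list of `list(onset, duration)`) and
#'   `totalDuration` (s).
#' @export
sessionSchedule <- function(spontaneousDuration = 30, nStims = 3,
                            stimDuration = 3, interStimInterval = 10) {
  stopifnot(spontaneousDuration > 0, stimDuration > 0, interStimInterval > 0,
            nStims >= 0)
  epochs <- lapply(seq_len(nStims), function(k)
    list(onset = spontaneousDuration +
           (k - 1) * (stimDuration + interStimInterval),
         duration = stimDuration))
  total <- spontaneousDuration + nStims * stimDuration +
    max(0L, nStims - 1L) * interStimInterval
  list(epochs = epochs, totalDuration = total)
}

#' Signed translational velocity from centroid positions
#'
#' Applies a second-order Savitzky-Golay filter with a first-order
#' derivative to the centroid positions; the speed is the magnitude of the
#' derivative and the sign is set negative for movement counter to the
#' animal's heading direction (dot product of displacement and heading).
#' Order-2 differentiation is exact on linear and quadratic motion at
#' interior frames.
#'
#' @param traj a [Trajectory-class].
#' @param savgolWindow filter window length in frames (odd, default 15,
#'   i.e. 187.5 ms at 80 fps).
#' @param order polynomial order (default 2).
#' @return A [SampledTrace-class] of signed velocities (mm/s).
#' @export
translationalVelocity <- function(traj, savgolWindow = 15L, order = 2L) {
  if (savgolWindow %% 2L == 0L || savgolWindow <= order)
    stop("window must be odd and larger than the polynomial order")
  pos <- traj@centroid
  if (nrow(pos) < savgolWindow) stop("trajectory shorter than the filter window")
  dt <- 1 / traj@rate
  vx <- signal::sgolayfilt(pos[, 1L], p = order, n = savgolWindow, m = 1L,
                           ts = dt)
  vy <- signal::sgolayfilt(pos[, 2L], p = order, n = savgolWindow, m = 1L,
                           ts = dt)
  speed <- sqrt(vx^2 + vy^2)
  sgn <- sign(vx * traj@heading[, 1L] + vy * traj@heading[, 2L])
  sgn[sgn == 0] <- 1
  SampledTrace(speed * sgn, traj@rate)
}

#' Apply the wall-contact and flip exclusion rules to epochs
#'
#' An epoch is excluded iff cumulative wall contact during it exceeds
#' 0.3 s (strictly more), or the fly is dorsally flipped at any frame
#' during it.
#'
#' @param traj a [Trajectory-class].
#' @param epochs list of `list(onset, duration)` (s).
#' @param maxWallContact exclusion threshold (s, default 0.3).
#' @return A data.frame with `epoch`, `kept`, `reason` (empty string when
#'   kept).
#' @export
excludeEpochs <- function(traj, epochs, maxWallContact = 0.3) {
  n <- nrow(traj@centroid)
  tt <- (seq_len(n) - 1L) / traj@rate
  out <- lapply(seq_along(epochs), function(k) {
    ep <- epochs[[k]]
    idx <- tt >= ep$onset & tt < ep$onset + ep$duration
    if (!any(idx)) stop("epoch outside trajectory span")
    contact <- sum(traj@wallContact[idx]) / traj@rate
    flip <- any(traj@flipped[idx])
    reason <- if (flip) "flipped"
      else if (contact > maxWallContact) "wall_contact"
      else ""
    data.frame(epoch = k, kept = reason == "", reason = reason,
               wallContactS = contact)
  })
  do.call(rbind, out)
}

epochIndices <- function(vel, epoch) {
  tt <- traceTimes(vel)
  idx <- which(tt >= epoch$onset & tt < epoch$onset + epoch$duration)
  if (length(idx) == 0L) stop("empty epoch")
  idx
}

#' Backward-walking response slope
#'
#' Acceleration from the beginning of the stimulation epoch to the minimum
#' velocity (maximum backward speed) reached within it:
#' `(min(v) - v(onset)) / (t(min) - onset)`. If the minimum occurs at the
#' onset the slope is 0 with a warning.
#'
#' @param vel a [SampledTrace-class] of signed velocities (mm/s).
#' @param epoch `list(onset, duration)` (s).
#' @return Slope in mm/s^2 (negative for backward acceleration).
#' @export
responseSlope <- function(vel, epoch) {
  idx <- epochIndices(vel, epoch)
  v <- as.vector(traceValues(vel))[idx]
  iMin <- which.min(v)
  if (iMin == 1L) {
    warning("velocity minimum at epoch onset; slope undefined, returning 0")
    return(0)
  }
  (v[iMin] - v[1L]) / ((iMin - 1L) / traceRate(vel))
}

#' Backward-walking distance
#'
#' Left Riemann sum of the velocity over the epoch, counting only frames
#' with negative velocity: `sum(v[v < 0]) / rate`. Always `<= 0`.
#'
#' @inheritParams responseSlope
#' @return Signed distance in mm.
#' @export
backwardDistance <- function(vel, epoch) {
  idx <- epochIndices(vel, epoch)
  v <- as.vector(traceValues(vel))[idx]
  sum(v[v < 0]) / traceRate(vel)
}

#' Maximum negative translational velocity
#'
#' The minimum velocity value reached during the epoch (reported as-is,
#' also when positive).
#'
#' @inheritParams responseSlope
#' @return Minimum velocity in mm/s.
#' @export
maxNegativeVelocity <- function(vel, epoch) {
  idx <- epochIndices(vel, epoch)
  min(as.vector(traceValues(vel))[idx])
}
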