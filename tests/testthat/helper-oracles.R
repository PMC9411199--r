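# Independent brute-force oracles used across the suite.

# Centered moving mean with edge truncation, offsets -(w %/% 2)..(w-1) %/% 2,
# written as an explicit loop.
bruteMovingMean <- function(x, w) {
  n <- length(x)
  out <- numeric(n)
  lo <- -(w %/% 2L)
  hi <- (w - 1L) %/% 2L
  for (i in seq_len(n)) {
    idx <- (i + lo):(i + hi)
    idx <- idx[idx >= 1L & idx <= n]
    out[i] <- mean(x[idx])
  }
  out
}

# Integer-shift estimate by exhaustive cross-correlation over candidate
# shifts (independent of the FFT path).
bruteShift <- function(img, ref, maxShift = 6L) {
  best <- c(0L, 0L); bestV <- -Inf
  H <- nrow(img); W <- ncol(img)
  for (dy in -maxShift:maxShift) {
    for (dx in -maxShift:maxShift) {
      ys <- max(1, 1 + dy):min(H, H + dy)
      xs <- max(1, 1 + dx):min(W, W + dx)
      v <- stats::cor(as.vector(img[ys, xs]),
                      as.vector(ref[ys - dy, xs - dx]))
      if (v > bestV) { bestV <- v; best <- c(dy, dx) }
    }
  }
  best
}

# Stationarity classification by explicit window counting.
bruteStationary <- function(vel, rate, threshold = 0.01, halfwidth = 0.5,
                            minFrac = 0.75) {
  below <- apply(abs(vel), 1L, max) < threshold
  n <- length(below)
  hw <- as.integer(round(halfwidth * rate))
  out <- logical(n)
  for (i in seq_len(n)) {
    idx <- max(1L, i - hw):min(n, i + hw)
    out[i] <- below[i] && mean(below[idx]) >= minFrac
  }
  out
}

# Smooth test image with broad structure for flow/translation tests.
smoothTestImage <- function(H = 64, W = 64, seed = 1) {
  set.seed(seed)
  y <- matrix(seq_len(H) / H, H, W)
  x <- matrix(seq_len(W) / W, H, W, byrow = TRUE)
  img <- 100 + 60 * sin(2 * pi * y) * cos(2 * pi * x) +
    40 * sin(4 * pi * x + 1) + 30 * cos(3 * pi * y + 0.5)
  img - min(img) + 10
}

# Spatial gradient energy of a motion field (forward differences).
fieldGradientEnergy <- function(field) {
  g <- function(m) sum(diff(m)^2) + sum(t(diff(t(m)))^2)
  g(field@dy) + g(field@dx)
}
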