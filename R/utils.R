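#' @useDynLib flyvnc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats quantile rnorm runif sd coef lm median fft mvfft pnorm
#' @importFrom utils head tail write.csv read.csv
NULL

# Evaluate expr with a locally seeded RNG, restoring global state afterwards.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Truncated Gaussian kernel, radius 4*sigma, normalized to sum 1.
gaussKernel1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# 1-D Gaussian smoothing with renormalized (edge-truncated) kernel weights.
smoothGauss1d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  k <- gaussKernel1d(sigma)
  n <- length(x)
  r <- (length(k) - 1L) %/% 2L
  xp <- c(rep(0, r), x, rep(0, r))
  wp <- c(rep(0, r), rep(1, n), rep(0, r))
  num <- stats::filter(xp, k, sides = 2)[(r + 1L):(r + n)]
  den <- stats::filter(wp, k, sides = 2)[(r + 1L):(r + n)]
  as.numeric(num / den)
}

# Row-stochastic banded smoothing matrix: out = S %*% x smooths along x.
gaussSmoothingMatrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  S <- exp(-d^2 / (2 * sigma^2))
  S[d > r] <- 0
  S / rowSums(S)
}

# Separable 2-D Gaussian smoothing of a matrix (renormalized truncation at
# the borders, consistent with smoothGauss1d).
smoothImageGauss <- function(img, sigma) {
  if (sigma <= 0) return(img)
  Sy <- gaussSmoothingMatrix(nrow(img), sigma)
  Sx <- gaussSmoothingMatrix(ncol(img), sigma)
  Sy %*% img %*% t(Sx)
}

# Centered moving mean with edge truncation and renormalized weights.
# For even windows the span is offsets -(w %/% 2) .. (w - 1) %/% 2.
movingMean <- function(x, window) {
  n <- length(x)
  stopifnot(window >= 1, window <= n)
  lo <- -(window %/% 2L)
  hi <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  a <- pmax(i + lo, 1L)
  b <- pmin(i + hi, n)
  (cs[b + 1L] - cs[a]) / (b - a + 1L)
}

# Linear-interpolation percentile (quantile type 7), the convention used for
# every percentile in this package.
percentileLinear <- function(x, p) {
  unname(stats::quantile(x, probs = p, type = 7, names = FALSE))
}
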