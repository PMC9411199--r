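#' Read and write FrameStacks as multi-page TIFF
#'
#' Stacks are stored one channel per file, axis order (T, Y, X). TIFF
#' samples are normalized to `[0, 1]`; the scale factor, frame rate and
#' channel tag are kept in a JSON sidecar (`<path>.json`) so the stack
#' round-trips exactly up to the sample quantization.
#'
#' @param stack a [FrameStack-class].
#' @param path TIFF file path (sidecar written next to it).
#' @return `writeFrameStackTiff` returns `path` invisibly;
#'   `readFrameStackTiff` returns a [FrameStack-class].
#' @export
writeFrameStackTiff <- function(stack, path) {
  dat <- frameData(stack)
  lo <- min(dat)
  sc <- max(dat) - lo
  if (sc == 0) sc <- 1
  norm <- (dat - lo) / sc
  pages <- lapply(seq_len(dim(dat)[1L]), function(t) norm[t, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(offset = lo, scale = sc, frameRate = frameRate(stack),
         channel = channelTag(stack)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeFrameStackTiff
#' @export
readFrameStackTiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  H <- nrow(pages[[1L]]); W <- ncol(pages[[1L]])
  dat <- array(0, c(length(pages), H, W))
  for (t in seq_along(pages)) dat[t, , ] <- pages[[t]] * meta$scale + meta$offset
  FrameStack(dat, meta$frameRate, meta$channel)
}

#' Read and write SampledTraces as CSV
#'
#' CSV with a `time_s` column followed by one column per signal.
#'
#' @param trace a [SampledTrace-class].
#' @param path file path.
#' @return `writeTraceCsv` returns `path` invisibly; `readTraceCsv`
#'   returns a [SampledTrace-class] (rate recovered from the time column).
#' @export
writeTraceCsv <- function(trace, path) {
  v <- traceValues(trace)
  cn <- colnames(v)
  if (is.null(cn)) cn <- paste0("signal", seq_len(ncol(v)))
  df <- data.frame(time_s = traceTimes(trace))
  for (j in seq_len(ncol(v))) df[[cn[j]]] <- v[, j]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTraceCsv
#' @export
readTraceCsv <- function(path) {
  df <- read.csv(path)
  stopifnot("time_s" %in% names(df), nrow(df) >= 2L)
  rate <- 1 / median(diff(df$time_s))
  v <- as.matrix(df[setdiff(names(df), "time_s")])
  SampledTrace(v, rate, df$time_s[1L])
}
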