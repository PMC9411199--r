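#' Align a daily series to its first day
#'
#' Each day's projection is registered to the day-1 image by subpixel
#' translation ([registerTranslation()]) and resampled bilinearly. A day
#' whose registration is undefined (constant image) is flagged and left
#' unaligned.
#'
#' @param series a [dailySeries()] object with at least 2 days.
#' @return The aligned `DailySeries`; attribute `offsets` holds the
#'   recovered `D x 2` translations and attribute `failed` the indices of
#'   unaligned days.
#' @export
alignSeries <- function(series) {
  stopifnot(inherits(series, "DailySeries"))
  imgs <- series$images
  D <- dim(imgs)[1L]
  if (D < 2L) stop("need at least two days to align")
  ref <- imgs[1L, , ]
  offsets <- matrix(0, D, 2L, dimnames = list(NULL, c("dy", "dx")))
  failed <- integer()
  for (d in 2:D) {
    img <- imgs[d, , ]
    if (sd(img) == 0) {
      warning(sprintf("day %d image is constant; left unaligned", d))
      failed <- c(failed, d)
      next
    }
    off <- registerTranslation(img, ref)
    offsets[d, ] <- off
    # content displaced by off: sample at p + off to undo
    H <- nrow(img); W <- ncol(img)
    imgs[d, , ] <- warp_bilinear_cpp(img, matrix(off[1L], H, W),
                                     matrix(off[2L], H, W))
  }
  out <- dailySeries(imgs, series$days, series$flyId, series$group)
  attr(out, "offsets") <- offsets
  attr(out, "failed") <- failed
  out
}

#' Per-day, per-ROI mean fluorescence
#'
#' @param series a [dailySeries()] object (typically aligned first).
#' @param rois labeled integer matrix (0 = background), drawn on the day-1
#'   image and propagated unchanged.
#' @return A data.frame with `flyId`, `group`, `day`, `roiId`,
#'   `meanFluorescence`.
#' @export
roiMeanByDay <- function(series, rois) {
  stopifnot(inherits(series, "DailySeries"))
  if (!identical(dim(rois), dim(series$images)[2:3]))
    stop("ROI mask shape does not match images")
  ids <- sort(unique(rois[rois > 0]))
  if (length(ids) == 0L) stop("ROI mask is empty")
  rows <- list()
  for (d in seq_along(series$days)) {
    img <- series$images[d, , ]
    for (r in ids) {
      rows[[length(rows) + 1L]] <- data.frame(
        flyId = series$flyId, group = series$group, day = series$days[d],
        roiId = r, meanFluorescence = mean(img[rois == r]))
    }
  }
  do.call(rbind, rows)
}

#' Normalize ROI fluorescence to the first day
#'
#' Adds a `normalized` column: each (fly, ROI) series divided by its mean
#' fluorescence on the first day present, so day 1 is exactly 1 and the
#' values are invariant to overall intensity scaling.
#'
#' @param table output of [roiMeanByDay()] (possibly several flies
#'   row-bound).
#' @return The table with a `normalized` column.
#' @export
normalizeToFirstDay <- function(table) {
  key <- interaction(table$flyId, table$roiId, drop = TRUE)
  out <- lapply(split(table, key), function(df) {
    df <- df[order(df$day), , drop = FALSE]
    ref <- df$meanFluorescence[1L]
    if (ref <= 0) stop(sprintf("non-positive first-day mean for %s ROI %d",
                               df$flyId[1L], df$roiId[1L]))
    df$normalized <- df$meanFluorescence / ref
    df
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare intact vs amputated groups per day
#'
#' Two-sided Mann-Whitney U test on normalized values per day (exact
#' enumeration for group sizes <= 8, continuity-corrected normal
#' approximation otherwise). Days lacking one of the groups are skipped
#' with a warning.
#'
#' @param table normalized table from [normalizeToFirstDay()].
#' @param roiId restrict to one ROI (default: the designated ROI 1).
#' @return A data.frame with `day`, `nIntact`, `nAmputated`, `p`.
#' @export
compareGroupsByDay <- function(table, roiId = 1L) {
  tab <- table[table$roiId == roiId, , drop = FALSE]
  days <- sort(unique(tab$day))
  rows <- list()
  for (d in days) {
    td <- tab[tab$day == d, , drop = FALSE]
    a <- td$normalized[td$group == "intact"]
    b <- td$normalized[td$group == "amputated"]
    if (length(a) == 0L || length(b) == 0L) {
      warning(sprintf("day %d lacks one group; skipped", d))
      next
    }
    method <- if (length(a) <= 8L && length(b) <= 8L) "exact" else "normal_cc"
    p <- suppressWarnings(mannWhitneyU(a, b, sides = "two", method = method))
    rows[[length(rows) + 1L]] <- data.frame(day = d, nIntact = length(a),
                                            nAmputated = length(b), p = p)
  }
  do.call(rbind, rows)
}
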