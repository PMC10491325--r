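## Empty-band quantification of elastin projections: max projection,
## binarization, 30x30 grid area-fraction profile, mean - 2 SD threshold,
## contiguous-band detection and per-sample averaging.

#' Construct a ProjectionImage
#'
#' @param pixels Numeric matrix (grayscale, values in \[0, 1\]).
#' @param pixelSize Micrometers per pixel.
#' @param intimaSide Side of the image the intima faces (`"left"` default).
#' @return A [ProjectionImage].
#' @export
projectionImage <- function(pixels, pixelSize, intimaSide = "left") {
  new("ProjectionImage", pixels = pixels, pixelSize = as.numeric(pixelSize),
      intimaSide = intimaSide)
}

#' Maximum intensity projection of a z-stack
#'
#' @param zstack 3D numeric array (y, x, z) or list of equally sized
#'   matrices.
#' @param pixelSize Micrometers per pixel of the stack.
#' @param intimaSide Passed through to the projection.
#' @return A [ProjectionImage] whose pixels are the per-pixel maximum over
#'   depth.
#' @export
maxProjection <- function(zstack, pixelSize, intimaSide = "left") {
  if (is.list(zstack)) {
    stopIfNot(length(zstack) >= 1, "empty stack", "invalidInput")
    proj <- Reduce(pmax, zstack)
  } else {
    stopIfNot(is.array(zstack) && length(dim(zstack)) == 3 && dim(zstack)[3] >= 1,
              "zstack must be a 3D array or list of matrices", "invalidInput")
    proj <- zstack[, , 1]
    if (dim(zstack)[3] > 1)
      for (k in 2:dim(zstack)[3]) proj <- pmax(proj, zstack[, , k])
  }
  projectionImage(proj, pixelSize, intimaSide)
}

#' Binarize a projection image
#'
#' Thresholds the projection to separate elastin signal (foreground) from
#' background. Foreground means signal pixels irrespective of display
#' polarity. With `method = "otsu"` the threshold is computed by Otsu's
#' method; a numeric `method` is used as a fixed cutoff (pixels > cutoff are
#' foreground).
#'
#' @param img A [ProjectionImage] (or plain matrix; then `pixelSize` must be
#'   given).
#' @param method `"otsu"` or a numeric threshold in \[0, 1\].
#' @param pixelSize Only used when `img` is a bare matrix.
#' @return A [ProjectionImage] with pixels in {0, 1} (1 = foreground).
#' @export
binarizeImage <- function(img, method = "otsu", pixelSize = NULL) {
  if (is.matrix(img)) {
    stopIfNot(!is.null(pixelSize), "pixelSize required for a bare matrix",
              "invalidInput")
    img <- projectionImage(img, pixelSize)
  }
  stopIfNot(is(img, "ProjectionImage"), "img must be a ProjectionImage",
            "invalidInput")
  px <- img@pixels
  if (identical(method, "otsu")) {
    stopIfNot(diff(range(px)) > 0,
              "constant image: Otsu threshold undefined, supply a fixed threshold",
              "constantImage")
    thr <- EBImage::otsu(EBImage::Image(px), range = range(px))
  } else {
    stopIfNot(is.numeric(method) && length(method) == 1,
              "method must be 'otsu' or a numeric threshold", "invalidInput")
    thr <- method
  }
  projectionImage((px > thr) * 1, img@pixelSize, img@intimaSide)
}

#' 30 x 30 grid area-fraction profile of a binarized ROI
#'
#' Partitions a rectangular region of interest of the binarized projection
#' into a 30 x 30 grid of near-equal cells (remainder pixels attach to the
#' last row/column so total area is conserved), computes the foreground area
#' fraction of each cell, and averages each column of cells into the radial
#' area-fraction profile. Grid columns run along the radial axis (image x).
#'
#' @param binary A binarized [ProjectionImage] (pixels in {0, 1}).
#' @param regions Named list of grid-column ranges `c(first, last)` for at
#'   least `media` and `adventitia` (optionally `intima`), ordered along the
#'   radial axis.
#' @param roi Optional `c(x0, x1, y0, y1)` pixel indices (inclusive) of the
#'   ROI; default is the full image.
#' @param n Grid size (default 30).
#' @return A [GridProfile].
#' @export
gridAreaFractions <- function(binary, regions, roi = NULL, n = 30L) {
  stopIfNot(is(binary, "ProjectionImage"), "binary must be a ProjectionImage",
            "invalidInput")
  px <- binary@pixels
  stopIfNot(all(px %in% c(0, 1)), "image must be binarized first", "invalidInput")
  if (is.null(roi)) roi <- c(1L, ncol(px), 1L, nrow(px))
  stopIfNot(length(roi) == 4 && roi[1] >= 1 && roi[3] >= 1 &&
              roi[2] <= ncol(px) && roi[4] <= nrow(px),
            "roi must be c(x0, x1, y0, y1) inside the image", "invalidInput")
  sub <- px[roi[3]:roi[4], roi[1]:roi[2], drop = FALSE]
  stopIfNot(nrow(sub) >= n && ncol(sub) >= n,
            sprintf("roi smaller than the %d x %d grid", n, n), "roiTooSmall")

  # near-equal partition; remainder pixels attach to the last row/column
  cuts <- function(m) {
    w <- rep(m %/% n, n)
    w[n] <- w[n] + m %% n
    ends <- cumsum(w)
    cbind(start = c(1L, ends[-n] + 1L), end = ends)
  }
  rc <- cuts(nrow(sub)); cc <- cuts(ncol(sub))
  cf <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    cf[i, j] <- mean(sub[rc[i, 1]:rc[i, 2], cc[j, 1]:cc[j, 2]])
  new("GridProfile", cellFractions = cf, columnMeans = colMeans(cf),
      columnWidth = ncol(sub) * binary@pixelSize / n,
      regions = regions)
}

#' Empty-band area-fraction threshold
#'
#' The empty band is defined as columns whose area fraction falls two
#' standard deviations below the media mean; the cutoff is
#' max(0, mediaMean - 2 * mediaSd). With the cohort's media statistics
#' (mean 31.8%, SD 8.5%) this yields the 14.8% cutoff.
#'
#' @param mediaMean Mean media column area fraction (0-1, or percent if both
#'   arguments use the same scale).
#' @param mediaSd Standard deviation of the media column area fractions.
#' @return Threshold on the same scale as the inputs, floored at 0.
#' @examples
#' bandThreshold(0.318, 0.085)   # 0.148
#' @export
bandThreshold <- function(mediaMean, mediaSd) {
  stopIfNot(mediaSd >= 0, "mediaSd must be >= 0", "invalidInput")
  max(0, mediaMean - 2 * mediaSd)
}

#' Detect the empty band in a column area-fraction profile
#'
#' Searches grid columns from the start of the media range through the end
#' of the adventitia range, flags columns whose mean area fraction is below
#' the threshold, and reports the longest contiguous flagged run as the
#' band (a band is contiguous by definition). Ties between equally long runs
#' are broken toward the run closest to the media-adventitia boundary, where
#' the band forms. If no column is flagged the width is 0.
#'
#' @param profile A [GridProfile] with declared `media` and `adventitia`
#'   column ranges.
#' @param threshold Area-fraction cutoff (e.g. from [bandThreshold()]);
#'   default computes mediaMean - 2 * mediaSd from the profile's own media
#'   columns.
#' @return A [BandCall].
#' @export
detectBand <- function(profile, threshold = NULL) {
  stopIfNot(is(profile, "GridProfile"), "profile must be a GridProfile",
            "invalidInput")
  reg <- profile@regions
  stopIfNot(!is.null(reg$media) && !is.null(reg$adventitia),
            "media and adventitia column ranges must be declared",
            "regionsUndeclared")
  med <- reg$media; adv <- reg$adventitia
  if (is.null(threshold)) {
    mcols <- profile@columnMeans[med[1]:med[2]]
    threshold <- bandThreshold(mean(mcols), stats::sd(mcols))
  }
  window <- med[1]:adv[2]
  flagged <- window[profile@columnMeans[window] < threshold]
  if (length(flagged) == 0)
    return(new("BandCall", threshold = threshold, flaggedColumns = integer(),
               bandColumns = integer(), width = 0, contiguous = TRUE))
  runs <- split(flagged, cumsum(c(1L, diff(flagged) != 1L)))
  len <- lengths(runs)
  # interface column between media end and adventitia start
  boundary <- (med[2] + adv[1]) / 2
  dist <- vapply(runs, function(r) min(abs(r - boundary)), numeric(1))
  best <- order(-len, dist)[1]
  band <- runs[[best]]
  new("BandCall", threshold = threshold,
      flaggedColumns = as.integer(flagged),
      bandColumns = as.integer(band),
      width = length(band) * profile@columnWidth,
      contiguous = length(runs) == 1L)
}

#' Average band width over measurement locations
#'
#' A sample's empty-band distance is the arithmetic mean of the band widths
#' measured at several (conventionally four) locations around the cross
#' section.
#'
#' @param calls List of [BandCall] objects, or a numeric vector of widths
#'   (micrometers).
#' @param expected Number of locations expected (default 4); fewer triggers
#'   a warning, an empty list an error.
#' @return Mean band width (micrometers).
#' @examples
#' sampleBandWidth(c(10, 20, 30, 40))
#' @export
sampleBandWidth <- function(calls, expected = 4L) {
  if (is.list(calls)) calls <- vapply(calls, bandWidth, numeric(1))
  stopIfNot(is.numeric(calls) && length(calls) >= 1,
            "at least one band call required", "invalidInput")
  if (length(calls) < expected)
    warning(sprintf("only %d of %d expected locations measured",
                    length(calls), expected))
  mean(calls)
}
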