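## Readers and writers. Units live in the column names (pressure_mmHg,
## outer_diameter_mm, axial_force_mN) and are validated, never guessed:
## the mmHg/kPa boundary is the likeliest silent-failure point.

.MYO_COLS <- c("pressure_mmHg", "outer_diameter_mm", "axial_force_mN")

#' Read a myograph recording from CSV
#'
#' Expects columns `pressure_mmHg`, `outer_diameter_mm`, `axial_force_mN`
#' (one row per logged point of one cycle). A JSON sidecar may carry the
#' segment metadata (`L_mm`, `l_mm`, `outer_perimeter_mm`,
#' `inner_perimeter_mm`, `lambda_z`). Malformed input is rejected with an
#' error naming the offending column or row, never silently coerced.
#'
#' @param path CSV path.
#' @param metaPath Optional sidecar JSON path; default looks for
#'   `<path without .csv>.json` and uses it when present.
#' @return A [MyographRecording]; when metadata is available, the attribute
#'   `"geometry"` holds the [ReferenceGeometry] and `"lambda_z"` the axial
#'   stretch.
#' @export
readMyographCsv <- function(path, metaPath = NULL) {
  stopIfNot(file.exists(path), paste0("no such file: ", path), "parseError")
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.MYO_COLS, names(df))
  stopIfNot(length(miss) == 0,
            paste0("missing column(s): ", paste(miss, collapse = ", ")),
            "parseError")
  for (col in .MYO_COLS) {
    v <- df[[col]]
    bad <- which(!is.finite(suppressWarnings(as.numeric(v))))
    stopIfNot(length(bad) == 0,
              sprintf("non-numeric value in column '%s', row %d", col, bad[1]),
              "parseError")
    df[[col]] <- as.numeric(v)
  }
  bad <- which(df$outer_diameter_mm <= 0)
  stopIfNot(length(bad) == 0,
            sprintf("non-positive outer diameter in row %d", bad[1]),
            "parseError")
  if (is.null(metaPath)) {
    cand <- sub("\\.csv$", ".json", path)
    if (file.exists(cand) && cand != path) metaPath <- cand
  }
  lMm <- NA_real_
  geom <- NULL
  lambdaZ <- NULL
  if (!is.null(metaPath)) {
    stopIfNot(file.exists(metaPath), paste0("no such sidecar: ", metaPath),
              "parseError")
    meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
    if (!is.null(meta$l_mm)) lMm <- meta$l_mm
    if (!is.null(meta$outer_perimeter_mm) && !is.null(meta$inner_perimeter_mm) &&
        !is.null(meta$L_mm))
      geom <- radiiFromPerimeters(meta$outer_perimeter_mm,
                                  meta$inner_perimeter_mm, meta$L_mm)
    lambdaZ <- meta$lambda_z
  }
  rec <- myographRecording(df$pressure_mmHg, df$outer_diameter_mm,
                           df$axial_force_mN, stretchedLength = lMm)
  attr(rec, "geometry") <- geom
  attr(rec, "lambda_z") <- lambdaZ
  rec
}

#' Write a myograph recording to CSV (plus optional JSON sidecar)
#'
#' @param rec A [MyographRecording].
#' @param path Output CSV path.
#' @param geom Optional [ReferenceGeometry] for the sidecar.
#' @param lambdaZ Optional axial stretch for the sidecar.
#' @return `path`, invisibly.
#' @export
writeMyographCsv <- function(rec, path, geom = NULL, lambdaZ = NULL) {
  df <- data.frame(pressure_mmHg = rec@pressure,
                   outer_diameter_mm = rec@outerDiameter,
                   axial_force_mN = rec@axialForce)
  write.csv(df, path, row.names = FALSE)
  if (!is.null(geom) || !is.null(lambdaZ) || !is.na(rec@stretchedLength)) {
    meta <- list(l_mm = rec@stretchedLength)
    if (!is.null(geom))
      meta <- c(meta, list(L_mm = geom@L,
                           outer_perimeter_mm = 2 * pi * geom@Ro,
                           inner_perimeter_mm = 2 * pi * geom@Ri))
    if (!is.null(lambdaZ)) meta$lambda_z <- lambdaZ
    jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a grayscale image or z-stack (TIFF/PNG)
#'
#' Multi-page TIFFs become z-stacks (3D arrays); single pages become
#' [ProjectionImage]s. RGB input is rejected unless a channel is selected.
#'
#' @param path Image path (.tif/.tiff/.png).
#' @param pixelSize Micrometers per pixel (required; image files do not
#'   carry it reliably).
#' @param channel Optional channel index for RGB input.
#' @return A [ProjectionImage] (2D) or a 3D array with attribute
#'   `"pixelSize"` (stack).
#' @export
readImage <- function(path, pixelSize, channel = NULL) {
  stopIfNot(file.exists(path), paste0("no such file: ", path), "parseError")
  ext <- tolower(tools::file_ext(path))
  dropChannel <- function(m) {
    if (length(dim(m)) == 2) return(m)
    stopIfNot(!is.null(channel),
              "RGB image: select a channel with the 'channel' argument",
              "channelSelectionRequired")
    m[, , channel]
  }
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    pages <- lapply(pages, dropChannel)
    if (length(pages) == 1) return(projectionImage(pages[[1]], pixelSize))
    stack <- array(0, dim = c(dim(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) stack[, , k] <- pages[[k]]
    attr(stack, "pixelSize") <- pixelSize
    stack
  } else if (ext == "png") {
    projectionImage(dropChannel(png::readPNG(path)), pixelSize)
  } else {
    stop(errorCondition(paste0("unsupported image format: .", ext),
                        class = c("parseError", "arteryMechError")))
  }
}

#' Write a grayscale image or z-stack as 16-bit TIFF
#'
#' @param x A [ProjectionImage], matrix, or 3D array (y, x, z).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeImageTiff <- function(x, path) {
  if (is(x, "ProjectionImage")) x <- x@pixels
  pages <- if (length(dim(x)) == 3)
    lapply(seq_len(dim(x)[3]), function(k) x[, , k])
  else list(x)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
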