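## S4 classes for the mechanics, imaging and synthetic-data layers.

#' ReferenceGeometry: undeformed vessel segment geometry
#'
#' Holds the traction-free reference configuration of a cylindrical artery
#' segment: outer radius \code{Ro}, inner radius \code{Ri} (both mm, usually
#' obtained from ring perimeters) and the unloaded suture-to-suture length
#' \code{L} (mm).
#'
#' @slot Ro Undeformed outer radius (mm).
#' @slot Ri Undeformed inner radius (mm).
#' @slot L Unloaded suture-to-suture length (mm).
#' @seealso [referenceGeometry()], [radiiFromPerimeters()]
#' @export
setClass("ReferenceGeometry",
  slots = c(Ro = "numeric", Ri = "numeric", L = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@Ro) != 1 || length(object@Ri) != 1 || length(object@L) != 1)
      msg <- c(msg, "Ro, Ri and L must be scalars")
    else {
      if (!is.finite(object@Ri) || object@Ri <= 0) msg <- c(msg, "Ri must be > 0")
      if (!is.finite(object@Ro) || object@Ro <= object@Ri)
        msg <- c(msg, "Ro must exceed Ri (0 < Ri < Ro)")
      if (!is.finite(object@L) || object@L <= 0) msg <- c(msg, "L must be > 0")
    }
    if (length(msg)) msg else TRUE
  })

#' MyographRecording: one pressure-diameter-force loading cycle
#'
#' A series of simultaneous transmural pressure (mmHg), deformed outer
#' diameter (mm) and axial force (mN) readings acquired at a single axial
#' stretch, as exported by a pressure myograph.
#'
#' @slot pressure Transmural pressures (mmHg), within \[0, 200\].
#' @slot outerDiameter Deformed outer diameters (mm), > 0.
#' @slot axialForce Axial forces (mN).
#' @slot stretchedLength Stretched axial length l (mm); may be `NA` when the
#'   axial stretch is supplied separately.
#' @slot cycleLabel Free-text tag, e.g. `"unloading"`.
#' @seealso [myographRecording()], [processRecording()]
#' @export
setClass("MyographRecording",
  slots = c(pressure = "numeric", outerDiameter = "numeric",
            axialForce = "numeric", stretchedLength = "numeric",
            cycleLabel = "character"),
  validity = function(object) {
    n <- length(object@pressure)
    msg <- character()
    if (n < 1) msg <- c(msg, "recording must contain at least one point")
    if (length(object@outerDiameter) != n || length(object@axialForce) != n)
      msg <- c(msg, "pressure, outerDiameter and axialForce must have equal length")
    if (any(!is.finite(object@pressure)) ||
        any(object@pressure < 0) || any(object@pressure > 200))
      msg <- c(msg, "pressures must lie within [0, 200] mmHg")
    if (any(!is.finite(object@outerDiameter)) || any(object@outerDiameter <= 0))
      msg <- c(msg, "outer diameters must be > 0")
    if (length(object@stretchedLength) != 1 ||
        (!is.na(object@stretchedLength) && object@stretchedLength <= 0))
      msg <- c(msg, "stretchedLength must be a positive scalar or NA")
    if (length(msg)) msg else TRUE
  })

#' StressStretchCurve: processed biaxial response of one cycle
#'
#' Per-pressure deformed states together with the normalized circumferential
#' stretch (equal to 1 at the 0 mmHg anchor point of the cycle) and the
#' circumferential and axial Cauchy stresses (kPa). Points are ordered by
#' increasing pressure.
#'
#' @slot pressure Pressures (mmHg), increasing.
#' @slot normalizedStretch Circumferential stretch divided by its value at
#'   0 mmHg; exactly 1 at the anchor.
#' @slot sigmaTheta Circumferential Cauchy stress (kPa).
#' @slot sigmaZ Axial Cauchy stress (kPa).
#' @slot states data.frame of deformed states (`ro`, `ri`, `lambda_z`,
#'   `lambda_theta`, `sigma_theta_kPa`, `sigma_z_kPa`), one row per point.
#' @slot anchorIndex Index of the 0 mmHg anchor point.
#' @export
setClass("StressStretchCurve",
  slots = c(pressure = "numeric", normalizedStretch = "numeric",
            sigmaTheta = "numeric", sigmaZ = "numeric",
            states = "data.frame", anchorIndex = "integer"),
  validity = function(object) {
    n <- length(object@pressure)
    msg <- character()
    if (length(object@normalizedStretch) != n || length(object@sigmaTheta) != n ||
        length(object@sigmaZ) != n || nrow(object@states) != n)
      msg <- c(msg, "curve slots must be aligned")
    if (length(object@anchorIndex) != 1 || object@anchorIndex < 1 ||
        object@anchorIndex > n)
      msg <- c(msg, "anchorIndex out of range")
    else if (object@normalizedStretch[object@anchorIndex] != 1)
      msg <- c(msg, "normalized stretch must equal 1 exactly at the anchor")
    if (length(msg)) msg else TRUE
  })

#' ExponentialFit: fitted exponential stress-stretch law
#'
#' Parameters of the least-squares fit sigma(lambda) = a * (exp(b *
#' (lambda - 1)) - 1) to a normalized stress-stretch curve. The form passes
#' through (1, 0), matching the zero-stress state at 0 mmHg, and its analytic
#' derivative a * b * exp(b * (lambda - 1)) is the tangent stiffness.
#'
#' @slot a Stress scale (kPa), > 0.
#' @slot b Dimensionless stiffening exponent.
#' @slot rmse Root-mean-square residual (kPa).
#' @slot direction `"circumferential"` or `"longitudinal"`.
#' @slot converged Logical convergence flag from the optimizer.
#' @export
setClass("ExponentialFit",
  slots = c(a = "numeric", b = "numeric", rmse = "numeric",
            direction = "character", converged = "logical"),
  validity = function(object) {
    if (length(object@a) != 1 || !is.finite(object@a) || object@a <= 0)
      return("a must be a positive scalar (kPa)")
    if (length(object@b) != 1 || !is.finite(object@b))
      return("b must be a finite scalar")
    TRUE
  })

#' ProjectionImage: 2D grayscale projection with physical pixel size
#'
#' A single-channel image (values in \[0, 1\]) of an arterial cross-section
#' wall, assumed rotated so the wall runs vertically: image columns advance
#' along the radial axis, with the intima at the declared side.
#'
#' @slot pixels Numeric matrix, rows = y, columns = x (radial axis).
#' @slot pixelSize Physical pixel size (micrometers per pixel), > 0.
#' @slot intimaSide `"left"` or `"right"`.
#' @export
setClass("ProjectionImage",
  slots = c(pixels = "matrix", pixelSize = "numeric", intimaSide = "character"),
  validity = function(object) {
    if (!is.numeric(object@pixels)) return("pixels must be numeric")
    if (length(dim(object@pixels)) != 2) return("pixels must be a 2D matrix")
    if (length(object@pixelSize) != 1 || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0)
      return("pixelSize must be a positive scalar (um/px)")
    if (!object@intimaSide %in% c("left", "right"))
      return("intimaSide must be 'left' or 'right'")
    TRUE
  })

#' GridProfile: 30 x 30 area-fraction grid of a wall ROI
#'
#' Foreground (signal) area fractions of a binarized projection ROI
#' discretized into a 30 x 30 grid, with per-column means forming the radial
#' area-fraction profile used for empty-band detection.
#'
#' @slot cellFractions 30 x 30 matrix of per-cell foreground fractions.
#' @slot columnMeans Mean fraction of each grid column (length 30).
#' @slot columnWidth Physical width of one grid column (micrometers).
#' @slot regions Named list of grid-column index ranges, at least `media`
#'   and `adventitia` (each `c(first, last)`), optionally `intima`; ordered
#'   intima < media < adventitia along the radial axis.
#' @export
setClass("GridProfile",
  slots = c(cellFractions = "matrix", columnMeans = "numeric",
            columnWidth = "numeric", regions = "list"),
  validity = function(object) {
    msg <- character()
    if (!all(dim(object@cellFractions) == c(30L, 30L)))
      msg <- c(msg, "cellFractions must be 30 x 30")
    if (any(object@cellFractions < 0) || any(object@cellFractions > 1))
      msg <- c(msg, "cell fractions must lie in [0, 1]")
    if (length(object@columnMeans) != 30)
      msg <- c(msg, "columnMeans must have length 30")
    if (max(abs(object@columnMeans - colMeans(object@cellFractions))) > 1e-12)
      msg <- c(msg, "columnMeans must equal colMeans(cellFractions)")
    if (length(object@columnWidth) != 1 || object@columnWidth <= 0)
      msg <- c(msg, "columnWidth must be a positive scalar (um)")
    ok <- .validRegions(object@regions)
    if (!isTRUE(ok)) msg <- c(msg, ok)
    if (length(msg)) msg else TRUE
  })

.validRegions <- function(regions) {
  if (!is.list(regions)) return("regions must be a named list")
  need <- c("media", "adventitia")
  if (!all(need %in% names(regions)))
    return("regions must declare at least 'media' and 'adventitia'")
  rr <- regions[intersect(c("intima", "media", "adventitia"), names(regions))]
  for (r in rr) {
    if (length(r) != 2 || any(r < 1) || any(r > 30) || r[1] > r[2])
      return("each region must be c(first, last) within 1..30")
  }
  bounds <- do.call(rbind, rr)
  if (any(diff(as.vector(t(bounds))) < 0) ||
      any(bounds[-1, 1] <= bounds[-nrow(bounds), 2]))
    return("regions must be disjoint and ordered intima < media < adventitia")
  TRUE
}

#' BandCall: detected empty band in a radial area-fraction profile
#'
#' Result of thresholding the column profile of a [GridProfile]: the columns
#' whose mean area fraction falls below the threshold, the contiguous run
#' reported as the band, and its physical width.
#'
#' @slot threshold Area-fraction cutoff used (0-1).
#' @slot flaggedColumns All grid columns below threshold inside the search
#'   window.
#' @slot bandColumns The contiguous run reported as the band (possibly empty).
#' @slot width Band width in micrometers (run length x column width).
#' @slot contiguous TRUE when all flagged columns form a single run.
#' @export
setClass("BandCall",
  slots = c(threshold = "numeric", flaggedColumns = "integer",
            bandColumns = "integer", width = "numeric", contiguous = "logical"),
  validity = function(object) {
    if (object@width < 0) return("width must be >= 0")
    TRUE
  })

#' ConstitutiveParams: forward model for synthetic inflation data
#'
#' Parameters of the phenomenological material law used by the generators:
#' circumferential stress aTheta * (exp(bTheta * (lambdaTheta - 1)) - 1) and
#' axial stress aZ * (exp(bZ * (lambdaZ - 1)) - 1) + coupling *
#' (lambdaTheta - 1), plus the engineered in-vivo axial stretch
#' `lambdaZStar` at which the axial force stays flat during inflation.
#'
#' @slot aTheta,bTheta Circumferential law parameters (kPa, dimensionless), > 0.
#' @slot aZ,bZ Axial law parameters.
#' @slot coupling Circumferential-axial coupling (kPa).
#' @slot lambdaZStar Engineered force-flat axial stretch.
#' @export
setClass("ConstitutiveParams",
  slots = c(aTheta = "numeric", bTheta = "numeric", aZ = "numeric",
            bZ = "numeric", coupling = "numeric", lambdaZStar = "numeric"),
  validity = function(object) {
    if (object@aTheta <= 0 || object@bTheta <= 0)
      return("aTheta and bTheta must be > 0 (stiffening law)")
    if (object@lambdaZStar <= 0) return("lambdaZStar must be > 0")
    TRUE
  })

#' ImageSpec: layout of a synthetic two-layer wall image
#'
#' Describes a synthetic multiphoton-like elastin projection: a vertical
#' wall with (left to right) an intima margin, a media strip, an optional
#' zero-signal gap, and an adventitia strip, rendered as elongated fiber
#' blobs at target area fractions over a noisy background.
#'
#' @slot sizePx Image side length in pixels (square image).
#' @slot pixelSize Micrometers per pixel.
#' @slot mediaFraction,adventitiaFraction Target foreground area fractions.
#' @slot gapWidth True gap width (micrometers, >= 0).
#' @slot intimaWidth,mediaWidth,adventitiaWidth Strip widths (micrometers).
#' @slot depth Number of z-slices in the generated stack.
#' @slot noiseSd Gaussian background noise SD (intensity units).
#' @export
setClass("ImageSpec",
  slots = c(sizePx = "integer", pixelSize = "numeric",
            mediaFraction = "numeric", adventitiaFraction = "numeric",
            gapWidth = "numeric", intimaWidth = "numeric",
            mediaWidth = "numeric", adventitiaWidth = "numeric",
            depth = "integer", noiseSd = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@sizePx < 30) msg <- c(msg, "sizePx must be >= 30")
    if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
    for (f in c(object@mediaFraction, object@adventitiaFraction))
      if (f <= 0 || f >= 1) msg <- c(msg, "area fractions must lie in (0, 1)")
    if (object@gapWidth < 0) msg <- c(msg, "gapWidth must be >= 0")
    tot <- object@intimaWidth + object@mediaWidth + object@gapWidth +
      object@adventitiaWidth
    if (tot > object@sizePx * object@pixelSize)
      msg <- c(msg, "strips (intima + media + gap + adventitia) exceed the field of view")
    if (object@depth < 1) msg <- c(msg, "depth must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' StretchSweep: family of recordings over candidate axial stretches
#'
#' Output of [simulateStretchSweep()]: one inflation recording per candidate
#' axial stretch, plus the generator's ground-truth force-flat stretch.
#'
#' @slot candidates Candidate axial stretches.
#' @slot recordings List of [MyographRecording] objects, one per candidate.
#' @slot lambdaZStar Ground-truth force-flat axial stretch.
#' @export
setClass("StretchSweep",
  slots = c(candidates = "numeric", recordings = "list", lambdaZStar = "numeric"),
  validity = function(object) {
    if (length(object@candidates) < 1) return("at least one candidate required")
    if (length(object@recordings) != length(object@candidates))
      return("one recording per candidate required")
    TRUE
  })
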