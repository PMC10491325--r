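## Generics and accessors. Slot access from user code should go through
## these rather than `@`.

#' @rdname ReferenceGeometry-class
#' @param object,x An object.
#' @export
setGeneric("outerRadius", function(x) standardGeneric("outerRadius"))
#' @rdname ReferenceGeometry-class
#' @export
setGeneric("innerRadius", function(x) standardGeneric("innerRadius"))
#' @rdname ReferenceGeometry-class
#' @export
setGeneric("segmentLength", function(x) standardGeneric("segmentLength"))

#' @export
#' @rdname ReferenceGeometry-class
setMethod("outerRadius", "ReferenceGeometry", function(x) x@Ro)
#' @export
#' @rdname ReferenceGeometry-class
setMethod("innerRadius", "ReferenceGeometry", function(x) x@Ri)
#' @export
#' @rdname ReferenceGeometry-class
setMethod("segmentLength", "ReferenceGeometry", function(x) x@L)

#' Tangent stiffness of a fitted exponential stress-stretch law
#'
#' Evaluates the analytic derivative a * b * exp(b * (lambda - 1)) of the
#' fitted law at the given normalized stretch. For b > 0 this is strictly
#' increasing in lambda, the hallmark of exponential strain stiffening.
#'
#' @param fit An [ExponentialFit].
#' @param lambda Normalized circumferential stretch(es) at which to evaluate.
#' @return Tangent stiffness in kPa (same length as `lambda`).
#' @examples
#' f <- new("ExponentialFit", a = 5, b = 12, rmse = 0,
#'          direction = "circumferential", converged = TRUE)
#' tangentStiffness(f, 1)      # a * b
#' tangentStiffness(f, 1.05)
#' @export
setGeneric("tangentStiffness", function(fit, lambda) standardGeneric("tangentStiffness"))

#' Estimate the in-vivo axial stretch from axial-force invariance
#'
#' During inflation at the in-vivo axial stretch the axial force of an
#' artery stays nearly constant. Given recordings of a pressure ramp at
#' several candidate axial stretches, this selects the candidate whose
#' axial-force series has minimal variance over the ramp; ties are broken
#' toward the smaller stretch.
#'
#' @param recordings A [StretchSweep], or a list of [MyographRecording]
#'   objects (one per candidate).
#' @param lambdaZ Candidate axial stretches (required for the list method).
#' @return The selected axial stretch (dimensionless scalar).
#' @examples
#' geom <- referenceGeometry(Ro = 1.3, Ri = 1.0, L = 12)
#' sw <- simulateStretchSweep(geom, constitutiveParams(),
#'                            candidates = c(1.05, 1.12, 1.20), seed = 1)
#' estimateInVivoStretch(sw)
#' @export
setGeneric("estimateInVivoStretch",
           function(recordings, lambdaZ) standardGeneric("estimateInVivoStretch"))

#' Width of a detected empty band
#'
#' @param x A [BandCall].
#' @return Band width in micrometers.
#' @export
setGeneric("bandWidth", function(x) standardGeneric("bandWidth"))
#' @rdname bandWidth
#' @export
setMethod("bandWidth", "BandCall", function(x) x@width)

#' Column area-fraction profile of a grid
#'
#' @param x A [GridProfile].
#' @return Numeric vector of 30 per-column mean foreground fractions.
#' @export
setGeneric("columnProfile", function(x) standardGeneric("columnProfile"))
#' @rdname columnProfile
#' @export
setMethod("columnProfile", "GridProfile", function(x) x@columnMeans)

setMethod("show", "ReferenceGeometry", function(object) {
  cat(sprintf("ReferenceGeometry: Ro = %.4g mm, Ri = %.4g mm, L = %.4g mm (h = %.4g mm)\n",
              object@Ro, object@Ri, object@L, object@Ro - object@Ri))
})

setMethod("show", "MyographRecording", function(object) {
  cat(sprintf("MyographRecording (%s): %d points, P %.1f-%.1f mmHg, l = %s mm\n",
              object@cycleLabel, length(object@pressure),
              min(object@pressure), max(object@pressure),
              format(object@stretchedLength)))
})

setMethod("show", "StressStretchCurve", function(object) {
  cat(sprintf("StressStretchCurve: %d points, lambda 1.000-%.3f, sigma_theta up to %.3g kPa\n",
              length(object@pressure), max(object@normalizedStretch),
              max(object@sigmaTheta)))
})

setMethod("show", "ExponentialFit", function(object) {
  cat(sprintf("ExponentialFit (%s): a = %.4g kPa, b = %.4g, RMSE = %.3g kPa\n",
              object@direction, object@a, object@b, object@rmse))
})

setMethod("show", "ProjectionImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ProjectionImage: %d x %d px, %.3f um/px (%.0f x %.0f um), intima %s\n",
              d[1], d[2], object@pixelSize, d[1] * object@pixelSize,
              d[2] * object@pixelSize, object@intimaSide))
})

setMethod("show", "GridProfile", function(object) {
  cat(sprintf("GridProfile: 30 x 30 grid, column width %.2f um; media cols %d-%d, adventitia cols %d-%d\n",
              object@columnWidth,
              object@regions$media[1], object@regions$media[2],
              object@regions$adventitia[1], object@regions$adventitia[2]))
})

setMethod("show", "BandCall", function(object) {
  cat(sprintf("BandCall: threshold %.3f, %d flagged column(s), band width %.1f um\n",
              object@threshold, length(object@flaggedColumns), object@width))
})

setMethod("show", "StretchSweep", function(object) {
  cat(sprintf("StretchSweep: candidates {%s}, force-flat at %.3f\n",
              paste(format(object@candidates), collapse = ", "),
              object@lambdaZStar))
})
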