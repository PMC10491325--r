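## Biaxial extension-inflation mechanics: thin-wall kinematics and stress,
## exponential fitting, tangent stiffness, in-vivo stretch estimation.

#' Construct a ReferenceGeometry
#'
#' @param Ro Undeformed outer radius (mm).
#' @param Ri Undeformed inner radius (mm), 0 < Ri < Ro.
#' @param L Unloaded suture-to-suture length (mm).
#' @return A [ReferenceGeometry].
#' @examples
#' referenceGeometry(Ro = 1.3, Ri = 1.0, L = 12)
#' @export
referenceGeometry <- function(Ro, Ri, L) {
  new("ReferenceGeometry", Ro = as.numeric(Ro), Ri = as.numeric(Ri),
      L = as.numeric(L))
}

#' Construct a MyographRecording
#'
#' @param pressure Transmural pressures (mmHg).
#' @param outerDiameter Deformed outer diameters (mm).
#' @param axialForce Axial forces (mN).
#' @param stretchedLength Stretched segment length l (mm), or `NA`.
#' @param cycleLabel Cycle tag (default `"unloading"`: analysis conventionally
#'   uses the final unloading cycle of a repeated protocol).
#' @return A [MyographRecording].
#' @export
myographRecording <- function(pressure, outerDiameter, axialForce,
                              stretchedLength = NA_real_,
                              cycleLabel = "unloading") {
  new("MyographRecording", pressure = as.numeric(pressure),
      outerDiameter = as.numeric(outerDiameter),
      axialForce = as.numeric(axialForce),
      stretchedLength = as.numeric(stretchedLength),
      cycleLabel = cycleLabel)
}

#' Reference radii from measured ring perimeters
#'
#' The undeformed radii of a segment are obtained from the outer and inner
#' perimeters of thin rings cut from its ends: R = perimeter / (2 * pi).
#'
#' @param outerPerimeter Outer ring perimeter (mm).
#' @param innerPerimeter Inner ring perimeter (mm), < outerPerimeter.
#' @param L Unloaded suture-to-suture length (mm).
#' @return A [ReferenceGeometry].
#' @examples
#' radiiFromPerimeters(2 * pi, pi, 10)   # Ro = 1, Ri = 0.5
#' @export
radiiFromPerimeters <- function(outerPerimeter, innerPerimeter, L) {
  stopIfNot(is.numeric(outerPerimeter) && is.numeric(innerPerimeter) &&
              length(outerPerimeter) == 1 && length(innerPerimeter) == 1,
            "perimeters must be numeric scalars", "invalidGeometry")
  stopIfNot(innerPerimeter > 0 && outerPerimeter > innerPerimeter,
            "perimeters must satisfy 0 < inner < outer", "invalidGeometry")
  referenceGeometry(Ro = outerPerimeter / (2 * pi),
                    Ri = innerPerimeter / (2 * pi), L = L)
}

#' Axial stretch ratio
#'
#' @param l Stretched length (mm), > 0.
#' @param L Unloaded length (mm), > 0.
#' @return lambda_z = l / L.
#' @examples
#' axialStretch(13.2, 12)
#' @export
axialStretch <- function(l, L) {
  stopIfNot(is.numeric(l) && is.numeric(L) && all(l > 0) && all(L > 0),
            "lengths must be positive", "invalidGeometry")
  l / L
}

#' Deformed inner radius under incompressibility
#'
#' With the wall assumed incompressible, the deformed inner radius follows
#' from conservation of wall volume at axial stretch lambda_z:
#' ri = sqrt(ro^2 - (Ro^2 - Ri^2) / lambda_z).
#'
#' @param ro Deformed outer radius (mm).
#' @param geom A [ReferenceGeometry].
#' @param lambdaZ Axial stretch (dimensionless), > 0.
#' @return Deformed inner radius ri (mm).
#' @examples
#' g <- referenceGeometry(1.30, 1.00, 12)
#' deformedInnerRadius(1.25, g, 1.10)
#' @export
deformedInnerRadius <- function(ro, geom, lambdaZ) {
  stopIfNot(is(geom, "ReferenceGeometry"), "geom must be a ReferenceGeometry",
            "invalidGeometry")
  stopIfNot(all(lambdaZ > 0), "lambdaZ must be > 0", "invalidGeometry")
  rad <- ro^2 - (geom@Ro^2 - geom@Ri^2) / lambdaZ
  stopIfNot(all(rad > 0),
            "infeasible geometry: wall volume exceeds what the deformed outer radius allows",
            "infeasibleGeometry")
  sqrt(rad)
}

#' Circumferential stretch (mid-wall mean-radius ratio)
#'
#' @param ro,ri Deformed outer and inner radii (mm), 0 < ri < ro.
#' @param geom A [ReferenceGeometry].
#' @return lambda_theta = (ro + ri) / (Ro + Ri).
#' @export
circumferentialStretch <- function(ro, ri, geom) {
  stopIfNot(is(geom, "ReferenceGeometry"), "geom must be a ReferenceGeometry",
            "invalidGeometry")
  stopIfNot(all(ri > 0) && all(ri < ro),
            "deformed radii must satisfy 0 < ri < ro", "invalidGeometry")
  (ro + ri) / (geom@Ro + geom@Ri)
}

#' Mean circumferential and axial wall stress
#'
#' Thin-wall (Laplace-type) mean Cauchy stresses of a pressurized,
#' axially loaded cylinder: sigma_theta = P * ri / (ro - ri) and
#' sigma_z = (fT + P * pi * ri^2) / (pi * (ro - ri) * (ri + ro)), with the
#' pressure converted from mmHg to kPa. Forces in mN and lengths in mm give
#' stresses directly in kPa (mN/mm^2).
#'
#' @param P Transmural pressure (mmHg), >= 0.
#' @param ro,ri Deformed outer and inner radii (mm), 0 < ri < ro.
#' @param fT Axial force (mN).
#' @return Named list with `sigma_theta` and `sigma_z` in kPa.
#' @examples
#' wallStresses(P = 80, ro = 1.25, ri = 0.9671, fT = 20)
#' @export
wallStresses <- function(P, ro, ri, fT) {
  stopIfNot(all(ro > ri), "degenerate wall: ro must exceed ri", "degenerateWall")
  stopIfNot(all(ri > 0) && all(P >= 0),
            "require ri > 0 and P >= 0", "invalidGeometry")
  Pk <- mmHgToKPa(P)
  h <- ro - ri
  list(sigma_theta = Pk * ri / h,
       sigma_z = (fT + Pk * pi * ri^2) / (pi * h * (ri + ro)))
}

#' Process a myograph recording into a stress-stretch curve
#'
#' Chains the kinematic and stress computations point by point: deformed
#' inner radius from incompressibility, circumferential stretch from the
#' mid-wall mean radius, and thin-wall stresses from pressure and axial
#' force. Points are re-ordered by increasing pressure and the
#' circumferential stretch is normalized by its value at the 0 mmHg point of
#' the cycle, so the curve starts at (1, 0).
#'
#' @param rec A [MyographRecording].
#' @param geom A [ReferenceGeometry].
#' @param lambdaZ Axial stretch; defaults to `stretchedLength(rec) / L`.
#' @param anchorTol Pressure tolerance (mmHg) for locating the 0 mmHg anchor
#'   point (default 0.5; instrument exports rarely log exactly 0).
#' @return A [StressStretchCurve].
#' @examples
#' g <- referenceGeometry(1.30, 1.00, 12)
#' rec <- simulateInflation(g, constitutiveParams(), lambdaZ = 1.10,
#'                          pressures = seq(0, 80, 10))
#' processRecording(rec, g)
#' @export
processRecording <- function(rec, geom, lambdaZ = NULL, anchorTol = 0.5) {
  stopIfNot(is(rec, "MyographRecording") && is(geom, "ReferenceGeometry"),
            "rec must be a MyographRecording and geom a ReferenceGeometry",
            "invalidInput")
  if (is.null(lambdaZ)) {
    stopIfNot(!is.na(rec@stretchedLength),
              "lambdaZ not given and recording has no stretched length",
              "invalidInput")
    lambdaZ <- axialStretch(rec@stretchedLength, geom@L)
  }
  ord <- order(rec@pressure)
  P <- rec@pressure[ord]
  ro <- rec@outerDiameter[ord] / 2
  fT <- rec@axialForce[ord]

  anchor <- which(abs(P) <= anchorTol)
  stopIfNot(length(anchor) >= 1,
            sprintf("normalization anchor missing: no point within %.2f mmHg of 0", anchorTol),
            "normalizationAnchorMissing")
  anchor <- anchor[which.min(abs(P[anchor]))][1]

  ri <- deformedInnerRadius(ro, geom, lambdaZ)
  lt <- circumferentialStretch(ro, ri, geom)
  s <- wallStresses(P, ro, ri, fT)
  states <- data.frame(pressure_mmHg = P, ro = ro, ri = ri,
                       lambda_z = lambdaZ, lambda_theta = lt,
                       sigma_theta_kPa = s$sigma_theta,
                       sigma_z_kPa = s$sigma_z)
  nl <- lt / lt[anchor]
  nl[anchor] <- 1  # exact, independent of floating-point division
  new("StressStretchCurve", pressure = P, normalizedStretch = nl,
      sigmaTheta = s$sigma_theta, sigmaZ = s$sigma_z, states = states,
      anchorIndex = as.integer(anchor))
}

#' Fit an exponential law to a stress-stretch curve
#'
#' Least-squares fit of sigma(lambda) = a * (exp(b * (lambda - 1)) - 1) to
#' the normalized stress-stretch data (Levenberg-Marquardt, fixed initial
#' guess a = 1 kPa, b = 1, convergence tolerance 1e-10), so the fit is
#' deterministic. The form is anchored at (1, 0), matching the zero-stress
#' state of the normalized curve. Near-linear data yield a small b, not an
#' error.
#'
#' @param curve A [StressStretchCurve], or a list/data.frame with elements
#'   `lambda` and `sigma` (kPa).
#' @param direction `"circumferential"` (fits sigma_theta, default) or
#'   `"longitudinal"` (fits sigma_z against the same normalized
#'   circumferential stretch axis).
#' @return An [ExponentialFit].
#' @examples
#' lam <- seq(1, 1.10, 0.01)
#' fitExponential(list(lambda = lam, sigma = 5 * (exp(12 * (lam - 1)) - 1)))
#' @export
fitExponential <- function(curve, direction = c("circumferential", "longitudinal")) {
  direction <- match.arg(direction)
  if (is(curve, "StressStretchCurve")) {
    lam <- curve@normalizedStretch
    sig <- if (direction == "circumferential") curve@sigmaTheta else curve@sigmaZ
  } else {
    lam <- curve$lambda
    sig <- curve$sigma
  }
  stopIfNot(length(lam) >= 3, "at least 3 points required for the fit", "fitFailure")
  stopIfNot(diff(range(lam)) > 0, "stretches must not all be identical", "fitFailure")
  df <- data.frame(lam = lam, sig = sig)
  fit <- tryCatch(
    minpack.lm::nlsLM(sig ~ a * (exp(b * (lam - 1)) - 1), data = df,
                      start = list(a = 1, b = 1),
                      lower = c(1e-12, -Inf),
                      control = minpack.lm::nls.lm.control(
                        ftol = 1e-10, ptol = 1e-10, maxiter = 500)),
    error = function(e) stop(errorCondition(
      paste0("exponential fit failed to converge: ", conditionMessage(e)),
      class = c("fitFailure", "arteryMechError"))))
  cf <- stats::coef(fit)
  rmse <- sqrt(mean(stats::resid(fit)^2))
  new("ExponentialFit", a = unname(cf["a"]), b = unname(cf["b"]),
      rmse = rmse, direction = direction,
      converged = fit$convInfo$isConv %||% TRUE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @rdname tangentStiffness
#' @export
setMethod("tangentStiffness", "ExponentialFit", function(fit, lambda) {
  fit@a * fit@b * exp(fit@b * (lambda - 1))
})

#' Tangent stiffness at a given transmural pressure
#'
#' Locates the normalized stretch reached at pressure `P` on the recorded
#' curve (linear interpolation between recorded points) and evaluates the
#' fitted tangent stiffness there. Used e.g. to compare groups at the mean
#' arterial pressure of 80 mmHg.
#'
#' @param curve A [StressStretchCurve].
#' @param fit An [ExponentialFit] of that curve.
#' @param P Pressure (mmHg), inside the recorded range.
#' @return Tangent stiffness (kPa).
#' @export
stiffnessAtPressure <- function(curve, fit, P) {
  stopIfNot(is(curve, "StressStretchCurve") && is(fit, "ExponentialFit"),
            "need a StressStretchCurve and an ExponentialFit", "invalidInput")
  rng <- range(curve@pressure)
  stopIfNot(P >= rng[1] && P <= rng[2],
            sprintf("P = %.1f mmHg outside recorded range [%.1f, %.1f]; refusing to extrapolate",
                    P, rng[1], rng[2]),
            "extrapolationError")
  lam <- stats::approx(curve@pressure, curve@normalizedStretch, xout = P,
                       ties = "ordered")$y
  tangentStiffness(fit, lam)
}

#' @rdname estimateInVivoStretch
#' @export
setMethod("estimateInVivoStretch", signature("StretchSweep", "missing"),
  function(recordings, lambdaZ) {
    estimateInVivoStretch(recordings@recordings, recordings@candidates)
  })

#' @rdname estimateInVivoStretch
#' @export
setMethod("estimateInVivoStretch", signature("list", "numeric"),
  function(recordings, lambdaZ) {
    stopIfNot(length(recordings) >= 1, "empty candidate list", "invalidInput")
    stopIfNot(length(recordings) == length(lambdaZ),
              "one recording per candidate stretch required", "invalidInput")
    v <- vapply(recordings, function(r) stats::var(r@axialForce), numeric(1))
    # order() on (variance, stretch) implements the tie rule: smaller lambdaZ wins
    lambdaZ[order(v, lambdaZ)[1]]
  })
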