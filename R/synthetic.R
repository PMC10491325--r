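## Seeded synthetic-data generators: inflation forward model (root-found
## pressure-diameter response from a known constitutive law), axial-stretch
## sweeps with an engineered force-flat stretch, two-layer fiber images with
## a ground-truth gap, cohort tables and abundance tables.

#' Construct ConstitutiveParams
#'
#' Defaults give a stiffening response of cerebral-artery magnitude
#' (circumferential stress of a few tens of kPa at 80 mmHg) with the
#' force-flat axial stretch at 1.12, inside the 1.10-1.13 range typical of
#' such vessels.
#'
#' @param aTheta,bTheta Circumferential law sigma = aTheta *
#'   (exp(bTheta * (lambda - 1)) - 1); kPa and dimensionless.
#' @param aZ,bZ Axial law parameters.
#' @param coupling Circumferential-axial coupling (kPa).
#' @param lambdaZStar Engineered force-flat axial stretch.
#' @return A [ConstitutiveParams].
#' @export
constitutiveParams <- function(aTheta = 5, bTheta = 12, aZ = 3, bZ = 8,
                               coupling = 5, lambdaZStar = 1.12) {
  new("ConstitutiveParams", aTheta = aTheta, bTheta = bTheta, aZ = aZ,
      bZ = bZ, coupling = coupling, lambdaZStar = lambdaZStar)
}

# Deformed outer radius at pressure P (mmHg): root of
# sigma_model(lambda_theta(ro)) - P * ri / (ro - ri) = 0, bracketed between
# the incompressibility feasibility bound and 3 Ro (guaranteed sign change
# for stiffening laws).
.solveOuterRadius <- function(P, geom, params, lambdaZ) {
  W <- geom@Ro^2 - geom@Ri^2
  Pk <- mmHgToKPa(P)
  f <- function(ro) {
    ri <- sqrt(ro^2 - W / lambdaZ)
    lt <- (ro + ri) / (geom@Ro + geom@Ri)
    params@aTheta * (exp(params@bTheta * (lt - 1)) - 1) - Pk * ri / (ro - ri)
  }
  lower <- sqrt(W / lambdaZ) * (1 + 1e-9)
  upper <- 3 * geom@Ro
  stopIfNot(f(lower) < 0 && f(upper) > 0,
            "root not bracketed: non-physical constitutive parameters or geometry",
            "generatorError")
  stats::uniroot(f, c(lower, upper), tol = 1e-12)$root
}

#' Simulate an extension-inflation recording from a known material law
#'
#' Forward model for one loading cycle at fixed axial stretch: for each
#' pressure the deformed outer radius solves the thin-wall equilibrium of
#' the circumferential law (bracketed scalar root-find, tolerance 1e-12),
#' the inner radius follows from incompressibility, and the axial force is
#' back-computed from the axial law so that the analysis chain's stress
#' formulas invert it exactly. Optional Gaussian measurement noise is added
#' to the logged diameter and force.
#'
#' Noiseless output is an exact fixed point of the analysis: processing the
#' recording and fitting the exponential law recovers (aTheta, bTheta).
#'
#' @param geom A [ReferenceGeometry].
#' @param params A [ConstitutiveParams].
#' @param lambdaZ Axial stretch of the cycle.
#' @param pressures Pressure grid (mmHg), must include 0 (the protocol
#'   unloads to zero pressure in 10 mmHg steps, so the default is 0-80 by 10).
#' @param noiseSd Length-2 numeric: SD of diameter noise (mm) and force
#'   noise (mN).
#' @param seed Integer seed; same seed, same recording.
#' @return A [MyographRecording] (with `stretchedLength = lambdaZ * L`).
#' @examples
#' g <- referenceGeometry(1.30, 1.00, 12)
#' rec <- simulateInflation(g, constitutiveParams(), lambdaZ = 1.10)
#' @export
simulateInflation <- function(geom, params, lambdaZ,
                              pressures = seq(0, 80, by = 10),
                              noiseSd = c(0, 0), seed = NULL) {
  stopIfNot(is(geom, "ReferenceGeometry") && is(params, "ConstitutiveParams"),
            "need a ReferenceGeometry and ConstitutiveParams", "invalidInput")
  stopIfNot(any(pressures == 0), "pressure grid must include 0 mmHg",
            "invalidInput")
  stopIfNot(!is.unsorted(pressures), "pressures must be sorted", "invalidInput")
  ro <- vapply(pressures, .solveOuterRadius, numeric(1),
               geom = geom, params = params, lambdaZ = lambdaZ)
  ri <- sqrt(ro^2 - (geom@Ro^2 - geom@Ri^2) / lambdaZ)
  lt <- (ro + ri) / (geom@Ro + geom@Ri)
  sigZ <- params@aZ * (exp(params@bZ * (lambdaZ - 1)) - 1) +
    params@coupling * (lt - 1)
  fT <- sigZ * pi * (ro - ri) * (ro + ri) - mmHgToKPa(pressures) * pi * ri^2
  withSeed(seed, {
    d <- 2 * ro + stats::rnorm(length(ro), 0, noiseSd[1])
    f <- fT + stats::rnorm(length(fT), 0, noiseSd[2])
    myographRecording(pressures, d, f, stretchedLength = lambdaZ * geom@L)
  })
}

#' Simulate a sweep of inflation recordings over candidate axial stretches
#'
#' Generates one pressure-ramp recording per candidate axial stretch with
#' the axial force engineered to be flat (pressure-independent up to noise)
#' at `lambdaZStar` and to pick up a pressure slope proportional to the
#' distance from it: fT(P) = fT0(lambdaZ) + slope * (lambdaZ -
#' lambdaZStar) * P. The force-variance criterion of
#' [estimateInVivoStretch()] is therefore minimized at the candidate nearest
#' the ground truth.
#'
#' @param geom A [ReferenceGeometry].
#' @param params A [ConstitutiveParams] (supplies `lambdaZStar` and the
#'   baseline axial law).
#' @param candidates Candidate axial stretches (>= 1).
#' @param pressures Pressure grid (mmHg).
#' @param forceNoiseSd SD of Gaussian force noise (mN).
#' @param slope Force-pressure slope gained per unit axial stretch away from
#'   the flat point (mN/kPa); default 20.
#' @param seed Integer seed.
#' @return A [StretchSweep].
#' @export
simulateStretchSweep <- function(geom, params, candidates,
                                 pressures = seq(0, 80, by = 10),
                                 forceNoiseSd = 0, slope = 20, seed = NULL) {
  stopIfNot(length(candidates) >= 1, "empty candidate list", "invalidInput")
  withSeed(seed, {
    recs <- lapply(candidates, function(lz) {
      rec <- simulateInflation(geom, params, lz, pressures)
      fT0 <- params@aZ * (exp(params@bZ * (lz - 1)) - 1) *
        pi * (geom@Ro^2 - geom@Ri^2) + 10
      fT <- fT0 + slope * (lz - params@lambdaZStar) * mmHgToKPa(pressures) +
        stats::rnorm(length(pressures), 0, forceNoiseSd)
      myographRecording(rec@pressure, rec@outerDiameter, fT,
                        stretchedLength = lz * geom@L)
    })
    new("StretchSweep", candidates = as.numeric(candidates),
        recordings = recs, lambdaZStar = params@lambdaZStar)
  })
}

#' Construct an ImageSpec
#'
#' Defaults emulate a 425 x 425 micrometer multiphoton field of view at
#' 512 px with the media and adventitia at the area fractions measured for
#' elastin in such projections (0.318 and 0.478).
#'
#' @param sizePx Square image side (pixels).
#' @param pixelSize Micrometers per pixel (default 425/512).
#' @param mediaFraction,adventitiaFraction Target foreground fractions.
#' @param gapWidth True empty-band width (micrometers; 0 = no gap).
#' @param intimaWidth,mediaWidth,adventitiaWidth Strip widths (micrometers).
#' @param depth Z-stack depth (slices).
#' @param noiseSd Background noise SD (intensity units).
#' @return An [ImageSpec].
#' @export
imageSpec <- function(sizePx = 512L, pixelSize = 425 / 512,
                      mediaFraction = 0.318, adventitiaFraction = 0.478,
                      gapWidth = 0, intimaWidth = 40, mediaWidth = 160,
                      adventitiaWidth = 150, depth = 6L, noiseSd = 0.03) {
  new("ImageSpec", sizePx = as.integer(sizePx), pixelSize = pixelSize,
      mediaFraction = mediaFraction, adventitiaFraction = adventitiaFraction,
      gapWidth = gapWidth, intimaWidth = intimaWidth, mediaWidth = mediaWidth,
      adventitiaWidth = adventitiaWidth, depth = as.integer(depth),
      noiseSd = noiseSd)
}

# Stamp one elongated fiber blob (rotated ellipse, roughly wall-parallel)
# into a slice; returns the affected pixel indices within colRange.
.blobPixels <- function(n, colRange, cx, cy, h1, h2, angle) {
  half <- ceiling(h1) + 2L
  rows <- max(1L, cy - half):min(n, cy + half)
  cols <- max(colRange[1], cx - half):min(colRange[2], cx + half)
  gr <- expand.grid(r = rows, c = cols)
  dy <- gr$r - cy; dx <- gr$c - cx
  u <- dy * cos(angle) + dx * sin(angle)
  v <- -dy * sin(angle) + dx * cos(angle)
  inside <- (u / h1)^2 + (v / h2)^2 <= 1
  cbind(gr$r[inside], gr$c[inside])
}

#' Simulate a two-layer wall image with a ground-truth gap
#'
#' Renders a z-stack of a vertically aligned arterial wall: an intima
#' margin, a media strip and an adventitia strip filled with elongated,
#' wall-parallel fiber blobs until the target foreground area fractions are
#' reached (within 0.03), separated by a zero-signal gap strip of the
#' specified width, over Gaussian background noise. Pixel intensities are
#' quantized to 16-bit levels so TIFF round trips are exact. Seeded and
#' bit-reproducible.
#'
#' @param spec An [ImageSpec].
#' @param seed Integer seed.
#' @return List with `stack` (3D array y, x, z), `pixelSize`, `regions`
#'   (grid-column ranges for intima/media/adventitia, for the full-image
#'   ROI under a 30-column grid), `gapColumns` (grid columns inside the true
#'   gap), `trueGapWidth` (micrometers), and `achievedFractions`.
#' @examples
#' sim <- simulateWallImage(imageSpec(gapWidth = 30), seed = 1)
#' img <- maxProjection(sim$stack, sim$pixelSize)
#' @export
simulateWallImage <- function(spec, seed = NULL) {
  stopIfNot(is(spec, "ImageSpec"), "spec must be an ImageSpec", "invalidInput")
  n <- spec@sizePx
  ps <- spec@pixelSize
  b <- cumsum(c(spec@intimaWidth, spec@mediaWidth, spec@gapWidth,
                spec@adventitiaWidth))  # strip boundaries, micrometers
  xc <- (seq_len(n) - 0.5) * ps
  mediaCols <- range(which(xc > b[1] & xc <= b[2]))
  gapCols <- if (spec@gapWidth > 0) which(xc > b[2] & xc <= b[3]) else integer()
  advCols <- range(which(xc > b[3] & xc <= b[4]))

  withSeed(seed, {
    stack <- array(0, dim = c(n, n, spec@depth))
    achieved <- c(media = NA_real_, adventitia = NA_real_)
    for (reg in c("media", "adventitia")) {
      colRange <- if (reg == "media") mediaCols else advCols
      target <- if (reg == "media") spec@mediaFraction else spec@adventitiaFraction
      cov <- matrix(FALSE, n, diff(colRange) + 1L)
      area <- length(cov)
      it <- 0L
      while (sum(cov) / area < target) {
        it <- it + 1L
        stopIfNot(it < 50000L, "target area fraction unreachable", "generatorError")
        pxy <- .blobPixels(n, colRange,
                           cx = sample(colRange[1]:colRange[2], 1),
                           cy = sample.int(n, 1),
                           h1 = stats::runif(1, 8, 20),
                           h2 = stats::runif(1, 1.5, 3),
                           angle = stats::rnorm(1, 0, 5 * pi / 180))
        if (nrow(pxy) == 0) next
        z <- sample.int(spec@depth, 1)
        val <- stats::runif(1, 0.6, 1)
        idx <- cbind(pxy, z)
        stack[idx] <- pmax(stack[idx], val)
        cov[cbind(pxy[, 1], pxy[, 2] - colRange[1] + 1L)] <- TRUE
      }
      achieved[reg] <- sum(cov) / area
    }
    if (length(gapCols)) stack[, gapCols, ] <- 0
    if (spec@noiseSd > 0)
      stack <- stack + stats::rnorm(length(stack), 0, spec@noiseSd)
    stack <- pmin(pmax(stack, 0), 1)
    stack <- round(stack * 65535) / 65535

    W <- n * ps
    gridCols <- function(lo, hi) {
      j <- which((seq_len(30) - 1) * W / 30 >= lo & seq_len(30) * W / 30 <= hi)
      if (length(j)) c(min(j), max(j)) else NULL
    }
    regions <- list(intima = gridCols(0, b[1]),
                    media = gridCols(b[1], b[2]),
                    adventitia = gridCols(b[3], b[4]))
    regions <- regions[!vapply(regions, is.null, logical(1))]
    gapGrid <- if (spec@gapWidth > 0)
      which(seq_len(30) * W / 30 > b[2] & (seq_len(30) - 1) * W / 30 < b[3])
    else integer()
    list(stack = stack, pixelSize = ps, regions = regions,
         gapColumns = gapGrid, trueGapWidth = spec@gapWidth,
         achievedFractions = achieved)
  })
}

#' Simulate a cohort table
#'
#' Draws per-segment records for each group from Gaussian distributions
#' truncated at zero for the dimensions. Defaults mirror the reference
#' cohort's group sizes, means and SDs (see [acaCohort()]).
#'
#' @param groupSpecs Named list (names = group labels); each element a list
#'   with `n` and length-2 `c(mean, sd)` entries `age`, `thickness`,
#'   `inner`, `outer`.
#' @param seed Integer seed.
#' @return A cohort data.frame (one donor per segment row).
#' @export
simulateCohort <- function(groupSpecs = NULL, seed = NULL) {
  if (is.null(groupSpecs)) {
    groupSpecs <- list(
      early        = list(n = 6,  age = c(69.8, 8.2),  thickness = c(0.27, 0.05),
                          inner = c(1.80, 0.22), outer = c(2.34, 0.30)),
      intermediate = list(n = 4,  age = c(75.0, 5.3),  thickness = c(0.30, 0.06),
                          inner = c(1.80, 0.24), outer = c(2.41, 0.34)),
      advanced     = list(n = 10, age = c(73.0, 12.6), thickness = c(0.29, 0.05),
                          inner = c(1.87, 0.15), outer = c(2.44, 0.22)),
      control      = list(n = 8,  age = c(71.5, 9.8),  thickness = c(0.31, 0.03),
                          inner = c(1.98, 0.20), outer = c(2.60, 0.22)))
  }
  truncNorm <- function(n, m, s) {
    x <- stats::rnorm(n, m, s)
    while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), m, s)
    x
  }
  withSeed(seed, {
    rows <- lapply(names(groupSpecs), function(gname) {
      gs <- groupSpecs[[gname]]
      data.frame(group = gname,
                 donor = paste0(gname, "_", seq_len(gs$n)),
                 age = truncNorm(gs$n, gs$age[1], gs$age[2]),
                 sex = sample(c("male", "female"), gs$n, replace = TRUE),
                 thickness_mm = truncNorm(gs$n, gs$thickness[1], gs$thickness[2]),
                 inner_diameter_mm = truncNorm(gs$n, gs$inner[1], gs$inner[2]),
                 outer_diameter_mm = truncNorm(gs$n, gs$outer[1], gs$outer[2]))
    })
    validateCohortTable(do.call(rbind, rows))
  })
}

#' Simulate a collagen abundance table
#'
#' Draws per-sample label-free-quantitation-style abundances log-normally
#' around `composition x total`, where the composition of each group is the
#' baseline percentage vector plus that group's additive shift
#' (renormalized to 100). With `dispersion = 0` every sample's relative
#' abundances equal its group composition exactly.
#'
#' @param nPerGroup Named integer vector of samples per group.
#' @param baseline Named percentage vector summing to 100; default is the
#'   control composition of [collagenSummary()] (renormalized).
#' @param groupShifts Named list of named percentage-point shift vectors,
#'   e.g. `list(advanced = c(I = 10))`.
#' @param dispersion Log-normal sdlog of multiplicative sample noise.
#' @param totalAbundance Expected total collagen abundance per sample
#'   (arbitrary units).
#' @param seed Integer seed.
#' @return An abundance data.frame (`sample`, `group`, one column per type).
#' @export
simulateAbundances <- function(nPerGroup = c(control = 5, advanced = 6),
                               baseline = NULL, groupShifts = list(),
                               dispersion = 0.3, totalAbundance = 1e6,
                               seed = NULL) {
  if (is.null(baseline)) {
    cs <- collagenSummary()
    baseline <- stats::setNames(cs$control_mean_pct, cs$type)
    baseline <- 100 * baseline / sum(baseline)
  }
  stopIfNot(abs(sum(baseline) - 100) < 1e-6,
            "baseline composition must sum to 100", "invalidInput")
  withSeed(seed, {
    rows <- lapply(names(nPerGroup), function(gname) {
      comp <- baseline
      sh <- groupShifts[[gname]]
      if (!is.null(sh)) {
        stopIfNot(all(names(sh) %in% names(comp)),
                  "shift names must match baseline collagen types", "invalidInput")
        comp[names(sh)] <- comp[names(sh)] + sh
        stopIfNot(all(comp >= 0), "shifted composition has negative entries",
                  "invalidInput")
        comp <- 100 * comp / sum(comp)
      }
      n <- nPerGroup[[gname]]
      ab <- t(vapply(seq_len(n), function(i) {
        mult <- if (dispersion > 0)
          stats::rlnorm(length(comp), meanlog = -dispersion^2 / 2,
                        sdlog = dispersion)
        else rep(1, length(comp))
        comp / 100 * totalAbundance * mult
      }, numeric(length(comp))))
      colnames(ab) <- names(comp)
      cbind(data.frame(sample = paste0(gname, "_", seq_len(n)), group = gname),
            as.data.frame(ab))
    })
    do.call(rbind, rows)
  })
}
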