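test_that("reference radii follow from ring perimeters", {
  g <- radiiFromPerimeters(2 * pi, pi, 10)
  expect_equal(outerRadius(g), 1.0)
  expect_equal(innerRadius(g), 0.5)
  expect_equal(segmentLength(g), 10)

  g2 <- radiiFromPerimeters(8.1681, 6.2832, 12)
  expect_equal(outerRadius(g2), 8.1681 / (2 * pi), tolerance = 1e-12)
  expect_equal(round(outerRadius(g2), 4), 1.3000)
  expect_equal(round(innerRadius(g2), 4), 1.0000)

  expect_error(radiiFromPerimeters(5.0, 6.0, 10), class = "invalidGeometry")
  expect_error(radiiFromPerimeters(-1, -2, 10), class = "invalidGeometry")
})

test_that("axial stretch is the length ratio and rejects bad lengths", {
  expect_equal(axialStretch(10, 10), 1.0)
  expect_equal(axialStretch(13.2, 12.0), 1.10)
  expect_error(axialStretch(0, 10), class = "invalidGeometry")
  expect_error(axialStretch(10, -1), class = "invalidGeometry")
})

test_that("deformed inner radius conserves wall volume", {
  g <- refGeom()
  # identity deformation
  expect_equal(deformedInnerRadius(outerRadius(g), g, 1), innerRadius(g),
               tolerance = 1e-12)
  # worked case: volume-conservation oracle at 1e-12
  ri <- deformedInnerRadius(1.25, g, 1.10)
  expect_equal(round(ri, 4), 0.9671)
  expect_equal(pi * (1.25^2 - ri^2) * 1.10, pi * (1.30^2 - 1.00^2),
               tolerance = 1e-12)
  expect_error(deformedInnerRadius(0.5, g, 1.0), class = "infeasibleGeometry")
})

test_that("volume conservation holds over 1000 random feasible states", {
  set.seed(101)
  worst <- 0
  for (k in 1:1000) {
    tp <- randomFeasibleTuple()
    g <- referenceGeometry(tp$Ro, tp$Ri, 10)
    ri <- deformedInnerRadius(tp$ro, g, tp$lz)
    W <- pi * (tp$Ro^2 - tp$Ri^2)
    worst <- max(worst, abs(pi * (tp$ro^2 - ri^2) * tp$lz - W) / W)
  }
  expect_lt(worst, 1e-9)
})

test_that("circumferential stretch is the mid-wall mean-radius ratio", {
  g <- refGeom()
  expect_equal(circumferentialStretch(1.30, 1.00, g), 1.0)
  expect_equal(round(circumferentialStretch(1.25, 0.9671, g), 4), 0.9640)
  expect_error(circumferentialStretch(1.0, 1.0, g), class = "invalidGeometry")
})

test_that("wall stresses match an independent recomputation incl. unit conversion", {
  expect_equal(unlist(wallStresses(0, 1.25, 0.9671, 0)),
               c(sigma_theta = 0, sigma_z = 0))
  s <- wallStresses(80, 1.25, 0.9671, 20)
  o <- oracleStresses(80, 1.25, 0.9671, 20)
  expect_equal(s$sigma_theta, unname(o["sigma_theta"]), tolerance = 1e-12)
  expect_equal(s$sigma_z, unname(o["sigma_z"]), tolerance = 1e-12)
  expect_equal(round(s$sigma_theta, 1), 36.5)
  expect_equal(round(s$sigma_z, 1), 26.1)
  # unit contract: forgetting the mmHg -> kPa conversion is detectable
  expect_false(isTRUE(all.equal(s$sigma_theta, 80 * 0.9671 / (1.25 - 0.9671))))
  expect_error(wallStresses(80, 1.0, 1.0, 0), class = "degenerateWall")
})

test_that("stresses are monotone in their loads at fixed geometry", {
  P <- seq(0, 120, by = 5)
  st <- vapply(P, function(p) wallStresses(p, 1.25, 0.9671, 20)$sigma_theta,
               numeric(1))
  expect_true(all(diff(st) > 0))
  fT <- seq(-5, 40, by = 5)
  sz <- vapply(fT, function(f) wallStresses(60, 1.25, 0.9671, f)$sigma_z,
               numeric(1))
  expect_true(all(diff(sz) > 0))
})

test_that("processRecording normalizes at the 0 mmHg anchor and carries stresses", {
  g <- refGeom()
  one <- myographRecording(0, 2.3, 0, stretchedLength = 12)
  cv <- processRecording(one, g)
  expect_identical(cv@normalizedStretch, 1)
  expect_equal(cv@sigmaTheta, 0)

  # no anchor -> error
  bad <- myographRecording(c(10, 20), c(2.4, 2.5), c(1, 2), stretchedLength = 12)
  expect_error(processRecording(bad, g), class = "normalizationAnchorMissing")

  # noiseless forward model is an exact fixed point of the analysis chain
  params <- defaultParams()
  rec <- simulateInflation(g, params, lambdaZ = 1.10)
  cv <- processRecording(rec, g)
  lawStress <- 5 * (exp(12 * (cv@states$lambda_theta - 1)) - 1)
  expect_equal(cv@sigmaTheta, lawStress, tolerance = 1e-6)
  # at 0 mmHg the stretch itself is 1, so normalization is the identity
  expect_equal(cv@states$lambda_theta[cv@anchorIndex], 1, tolerance = 1e-9)
})

test_that("exponential fit recovers generating parameters and is robust near-linear", {
  lam <- seq(1, 1.10, by = 0.01)
  f <- fitExponential(list(lambda = lam, sigma = 5 * (exp(12 * (lam - 1)) - 1)))
  expect_equal(f@a, 5, tolerance = 1e-6)
  expect_equal(f@b, 12, tolerance = 1e-6)
  expect_lt(f@rmse, 1e-8)

  expect_error(fitExponential(list(lambda = c(1, 1), sigma = c(0, 0))),
               class = "fitFailure")

  # near-linear data give a small b, not an error
  fl <- fitExponential(list(lambda = lam, sigma = 3 * (lam - 1)))
  expect_lt(abs(fl@b), 1)

  # seeded noise: median relative error of b over 100 replicates < 15%
  set.seed(202)
  errs <- replicate(100, {
    noisy <- 5 * (exp(12 * (lam - 1)) - 1) + rnorm(length(lam), 0, 0.5)
    abs(fitExponential(list(lambda = lam, sigma = noisy))@b - 12) / 12
  })
  expect_lt(median(errs), 0.15)
})

test_that("tangent stiffness is the analytic derivative and increases with stretch", {
  f <- new("ExponentialFit", a = 5, b = 12, rmse = 0,
           direction = "circumferential", converged = TRUE)
  expect_equal(tangentStiffness(f, 1), 5 * 12)
  expect_equal(tangentStiffness(f, 1.05), 5 * 12 * exp(0.6), tolerance = 1e-12)
  # central finite-difference oracle of the fitted form
  h <- 1e-6
  sig <- function(l) 5 * (exp(12 * (l - 1)) - 1)
  fd <- (sig(1.05 + h) - sig(1.05 - h)) / (2 * h)
  expect_equal(tangentStiffness(f, 1.05), fd, tolerance = 1e-6)
  lams <- seq(1, 1.2, by = 0.01)
  expect_true(all(diff(tangentStiffness(f, lams)) > 0))
})

test_that("stiffness at pressure interpolates the recorded curve", {
  g <- refGeom()
  rec <- simulateInflation(g, defaultParams(), lambdaZ = 1.10)
  cv <- processRecording(rec, g)
  fit <- fitExponential(cv)
  # grid point: exactly the stiffness at that point's stretch
  i40 <- which(cv@pressure == 40)
  expect_equal(stiffnessAtPressure(cv, fit, 40),
               tangentStiffness(fit, cv@normalizedStretch[i40]))
  # oracle at 80 mmHg through the generating law
  lam80 <- cv@normalizedStretch[cv@pressure == 80]
  expect_equal(stiffnessAtPressure(cv, fit, 80), 5 * 12 * exp(12 * (lam80 - 1)),
               tolerance = 1e-6)
  expect_error(stiffnessAtPressure(cv, fit, 120), class = "extrapolationError")
})

test_that("in-vivo stretch selection minimizes force variance with ties to smaller", {
  g <- refGeom()
  mk <- function(f) myographRecording(c(0, 40, 80), c(2.3, 2.4, 2.5), f,
                                      stretchedLength = 13)
  # single candidate
  expect_equal(estimateInVivoStretch(list(mk(c(1, 2, 3))), 1.1), 1.1)
  # engineered flatness at 1.12
  sw <- simulateStretchSweep(refGeom(), defaultParams(), c(1.05, 1.12, 1.20))
  expect_equal(estimateInVivoStretch(sw), 1.12)
  # identical variance -> smaller stretch
  expect_equal(estimateInVivoStretch(list(mk(c(1, 2, 3)), mk(c(4, 5, 6))),
                                     c(1.2, 1.1)), 1.1)
  expect_error(estimateInVivoStretch(list(), numeric()), class = "invalidInput")
})
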