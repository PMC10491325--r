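# Shared fixtures: a cerebral-artery-sized reference geometry and the
# default stiffening material used by the generators.

refGeom <- function() referenceGeometry(Ro = 1.30, Ri = 1.00, L = 12)

defaultParams <- function() constitutiveParams()  # aTheta 5, bTheta 12

# Independent full-precision recomputation of the thin-wall stresses,
# written as plain arithmetic so it shares no code with wallStresses().
oracleStresses <- function(P_mmHg, ro, ri, fT) {
  P <- P_mmHg * 0.133322
  c(sigma_theta = P * ri / (ro - ri),
    sigma_z = (fT + P * pi * ri * ri) / (pi * (ro - ri) * (ri + ro)))
}

# Random feasible (Ro, Ri, lambda_z, ro) tuples for kinematics properties.
randomFeasibleTuple <- function() {
  Ri <- runif(1, 0.5, 2)
  Ro <- Ri + runif(1, 0.1, 1)
  lz <- runif(1, 0.9, 1.4)
  roMin <- sqrt((Ro^2 - Ri^2) / lz)
  ro <- runif(1, roMin * 1.05, roMin * 2)
  list(Ro = Ro, Ri = Ri, lz = lz, ro = ro)
}

# Half-up rounding, the convention of printed summary tables (round()'s
# half-even would turn an exact 2.595 into 2.59, not 2.60).
roundHalfUp <- function(x, d) floor(x * 10^d + 0.5 + 1e-9) / 10^d

# Build a GridProfile directly from a 30-vector of column fractions
# (constant down each column), bypassing the image path.
profileFromColumns <- function(colFracs, columnWidth = 425 / 30,
                               media = c(4, 14), adventitia = c(18, 26)) {
  cf <- matrix(rep(colFracs, each = 30), nrow = 30)
  new("GridProfile", cellFractions = cf, columnMeans = colMeans(cf),
      columnWidth = columnWidth,
      regions = list(media = media, adventitia = adventitia))
}
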