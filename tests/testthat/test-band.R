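test_that("max projection equals a brute-force per-pixel loop", {
  # degenerate cases
  m <- matrix(runif(64), 8, 8)
  expect_equal(maxProjection(array(m, c(8, 8, 1)), 1)@pixels, m)
  z <- array(0, c(8, 8, 2)); z[3, 5, 2] <- 1
  p <- maxProjection(z, 1)@pixels
  expect_equal(sum(p), 1); expect_equal(p[3, 5], 1)

  set.seed(7)
  stack <- array(runif(10 * 12 * 5), c(10, 12, 5))
  proj <- maxProjection(stack, 0.5)
  oracle <- matrix(0, 10, 12)
  for (i in 1:10) for (j in 1:12) oracle[i, j] <- max(stack[i, j, ])
  expect_identical(proj@pixels, oracle)
  expect_equal(proj@pixelSize, 0.5)
  expect_error(maxProjection(list(), 1), class = "invalidInput")
})

test_that("binarization separates a two-Gaussian mixture and handles edge cases", {
  # fixed threshold on an already-binary image is the identity
  bin <- matrix(sample(c(0, 1), 400, replace = TRUE), 20, 20)
  expect_equal(binarizeImage(projectionImage(bin, 1), method = 0.5)@pixels, bin)

  set.seed(8)
  truth <- matrix(runif(200 * 200) < 0.4, 200, 200)
  img <- matrix(rnorm(length(truth), ifelse(truth, 0.8, 0.2), 0.08), 200, 200)
  out <- binarizeImage(projectionImage(pmin(pmax(img, 0), 1), 1))
  expect_lt(mean((out@pixels == 1) != truth), 0.01)

  expect_error(binarizeImage(projectionImage(matrix(0.5, 10, 10), 1)),
               class = "constantImage")
})

test_that("grid area fractions match a per-pixel counting oracle", {
  regions <- list(media = c(4, 14), adventitia = c(18, 26))
  # all-foreground
  allfg <- binarizeImage(projectionImage(matrix(1, 60, 60), 1), method = 0.5)
  expect_error(gridAreaFractions(allfg, regions), NA)
  pr <- gridAreaFractions(binarizeImage(projectionImage(matrix(0.9, 60, 60), 1),
                                        method = 0.5), regions)
  expect_true(all(pr@cellFractions == 1))
  expect_true(all(columnProfile(pr) == 1))
  expect_equal(pr@columnWidth, 2)

  # left half foreground
  half <- cbind(matrix(1, 300, 150), matrix(0, 300, 150))
  pr <- gridAreaFractions(projectionImage(half, 425 / 300), regions)
  expect_equal(columnProfile(pr), rep(c(1, 0), each = 15))

  # seeded random image vs counting oracle (divisible roi: exact)
  set.seed(9)
  bin <- matrix(sample(c(0, 1), 90 * 90, replace = TRUE), 90, 90)
  pr <- gridAreaFractions(projectionImage(bin, 1), regions)
  oracle <- vapply(1:30, function(j)
    mean(bin[, (3 * (j - 1) + 1):(3 * j)]), numeric(1))
  expect_equal(columnProfile(pr), oracle, tolerance = 1e-12)
  # conservation: grand mean of cells equals the roi-wide fraction exactly
  expect_equal(mean(pr@cellFractions), mean(bin), tolerance = 1e-12)

  expect_error(gridAreaFractions(projectionImage(matrix(1, 10, 10), 1), regions),
               class = "roiTooSmall")
})

test_that("remainder pixels attach to the last row/column deterministically", {
  # 95 = 30 * 3 + 5: last cell gets 3 + 5 = 8 pixels per side
  bin <- matrix(0, 95, 95)
  bin[, 93:95] <- 1  # only inside the last grid column
  pr <- gridAreaFractions(projectionImage(bin, 1),
                          list(media = c(4, 14), adventitia = c(18, 26)))
  expect_equal(columnProfile(pr)[30], 3 / 8)
  expect_true(all(columnProfile(pr)[1:29] == 0))
})

test_that("band threshold is mean minus two SD, floored at zero", {
  expect_equal(bandThreshold(0.318, 0.085), 0.148)
  expect_equal(bandThreshold(0.50, 0.10), 0.30)
  expect_equal(bandThreshold(0.10, 0.10), 0)
  expect_error(bandThreshold(0.3, -0.1), class = "invalidInput")
})

test_that("band detection flags sub-threshold columns and reports the longest run", {
  base <- rep(0.35, 30)
  # no column below threshold -> width 0
  call <- detectBand(profileFromColumns(base), threshold = 0.148)
  expect_equal(bandWidth(call), 0)

  # constructed three-column band at the grid scale of a 425 um field
  cols <- base; cols[16:18] <- 0.05
  call <- detectBand(profileFromColumns(cols), threshold = 0.148)
  expect_equal(call@bandColumns, 16:18)
  expect_equal(bandWidth(call), 3 * 425 / 30, tolerance = 1e-12)
  expect_equal(round(bandWidth(call), 1), 42.5)

  # two runs: the longer wins
  cols <- base; cols[c(6, 7)] <- 0.01; cols[15:18] <- 0.01
  call <- detectBand(profileFromColumns(cols), threshold = 0.148)
  expect_equal(call@bandColumns, 15:18)
  expect_false(call@contiguous)

  # equal-length runs: the one nearest the media-adventitia boundary wins
  cols <- base; cols[c(5, 6)] <- 0.01; cols[16:17] <- 0.01
  call <- detectBand(profileFromColumns(cols), threshold = 0.148)
  expect_equal(call@bandColumns, 16:17)

  # default threshold comes from the profile's own media columns
  cols <- base; cols[16] <- 0.05
  call <- detectBand(profileFromColumns(cols))
  expect_equal(call@threshold, bandThreshold(mean(cols[4:14]), sd(cols[4:14])))

  noreg <- profileFromColumns(base)
  noreg@regions <- list()
  expect_error(detectBand(noreg, 0.1), class = "regionsUndeclared")
})

test_that("sample band width averages locations and warns when short", {
  expect_equal(sampleBandWidth(c(10, 20, 30, 40)), 25)
  expect_equal(sampleBandWidth(c(0, 0, 0, 0)), 0)
  calls <- lapply(c(10, 20), function(w)
    new("BandCall", threshold = 0.1, flaggedColumns = 1L, bandColumns = 1L,
        width = w, contiguous = TRUE))
  expect_warning(m <- sampleBandWidth(calls), "2 of 4")
  expect_equal(m, 15)
  expect_error(sampleBandWidth(numeric()), class = "invalidInput")
})

test_that("gap width is recovered within one grid column on synthetic walls", {
  thr <- bandThreshold(0.318, 0.085)
  colWidth <- 425 / 30
  for (gw in c(0, 30)) {
    sim <- simulateWallImage(imageSpec(gapWidth = gw), seed = 5)
    proj <- maxProjection(sim$stack, sim$pixelSize)
    prof <- gridAreaFractions(binarizeImage(proj), sim$regions)
    w <- bandWidth(detectBand(prof, threshold = thr))
    expect_lte(abs(w - gw), colWidth)
  }
})

test_that("widening the true gap never narrows the detected band", {
  thr <- bandThreshold(0.318, 0.085)
  widths <- vapply(c(15, 30, 45), function(gw) {
    sim <- simulateWallImage(imageSpec(gapWidth = gw), seed = 6)
    prof <- gridAreaFractions(
      binarizeImage(maxProjection(sim$stack, sim$pixelSize)), sim$regions)
    bandWidth(detectBand(prof, threshold = thr))
  }, numeric(1))
  expect_true(all(diff(widths) >= 0))
})
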