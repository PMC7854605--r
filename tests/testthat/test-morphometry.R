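# PED morphometry: height map, maximum height, area, Cavalieri volume,
# peak/slope partition.

.flatSeg <- function(nx = 8, ny = 6, depth = 100, margin = NULL) {
  if (is.null(margin)) margin <- matrix(TRUE, nx, ny)
  SegmentationSet(matrix(depth, nx, ny), matrix(depth, nx, ny), margin)
}

test_that("height map converts index differences to mm and zeroes outside the margin", {
  seg <- .flatSeg()
  hm <- heightMap(seg, 3.5, c(0.01, 0.02))
  expect_true(all(mapValues(hm) == 0))

  seg2 <- .flatSeg(margin = matrix(c(TRUE, rep(FALSE, 47)), 8, 6))
  seg2@rpeOuter[1, 1] <- 80               # 20-pixel elevation on one A-line
  hm2 <- heightMap(seg2, 3.5, c(0.01, 0.02))
  expect_equal(mapValues(hm2)[1, 1], 0.070)
  expect_true(all(mapValues(hm2)[-1] == 0))
})

test_that("inverted surfaces are rejected with the offending A-lines named", {
  seg <- .flatSeg()
  seg@rpeOuter[3, 2] <- 120               # below Bruch: impossible
  expect_error(heightMap(seg, 3.5, c(0.01, 0.02)), "inverted.*3,2")
})

test_that("maximum height handles ties by first raster position and flags empty margins", {
  m <- matrix(0, 4, 4)
  expect_equal(as.numeric(maxPedHeight(m)), 0)
  m[2, 3] <- m[3, 1] <- 0.5               # tie; (3,1) comes first in fast-first order
  mx <- maxPedHeight(m)
  expect_equal(as.numeric(mx), 0.5)
  expect_equal(attr(mx, "location"), c(3L, 1L))
  expect_error(maxPedHeight(m, margin = matrix(FALSE, 4, 4)), "empty")
})

test_that("PED area is pixel count times true pixel area", {
  expect_equal(pedArea(matrix(FALSE, 10, 10), 0.001), 0)
  expect_equal(pedArea(matrix(TRUE, 512, 256)), 36.0)  # full 6 x 6 mm scan
  # pixelated disc of radius a approximates pi a^2 at instrument resolution
  tp <- phantomTruth(phantomConfig(pedRadiusMm = 1.5))
  a <- pedArea(marginMask(tp$segmentation), (6 / 512) * (6 / 256))
  expect_lt(abs(a - pi * 1.5^2) / (pi * 1.5^2), 0.02)
})

test_that("Cavalieri volume matches the closed-form spherical cap within 2%", {
  cfg <- phantomConfig(pedRadiusMm = 1.529, pedMaxHeightMm = 0.288,
                       domeProfile = "spherical_cap")
  tp <- phantomTruth(cfg)
  vol <- pedVolumeCavalieri(tp$segmentation, bscanSpacingMm = 6 / 256,
                            pixelWidthMm = 6 / 512, axialPitchUm = 3.5)
  a <- 1.529; h <- 0.288
  capVol <- pi * h * (3 * a^2 + h^2) / 6
  expect_lt(abs(vol - capVol) / capVol, 0.02)
  expect_equal(tp$truth@pedVolumeMm3, capVol, tolerance = 1e-12)

  # Cavalieri consistency: halving the B-scan sampling moves the estimate < 2%
  cfg2 <- phantomConfig(nBscans = 128L, pedRadiusMm = 1.529,
                        pedMaxHeightMm = 0.288)
  tp2 <- phantomTruth(cfg2)
  vol2 <- pedVolumeCavalieri(tp2$segmentation, bscanSpacingMm = 6 / 128,
                             pixelWidthMm = 6 / 512, axialPitchUm = 3.5)
  expect_lt(abs(vol2 - vol) / vol, 0.02)
})

test_that("Cavalieri volume converges to the analytic cap volume with grid refinement", {
  # fine axial pitch (1 um) so the en-face discretization error dominates
  # over the axial height quantization
  a <- 1.4; h <- 0.26
  capVol <- pi * h * (3 * a^2 + h^2) / 6
  errs <- vapply(c(64L, 128L, 256L), function(nx) {
    ny <- nx %/% 2L
    tp <- phantomTruth(phantomConfig(nAlines = nx, nBscans = ny,
                                     nDepth = 480L, axialPitchUm = 1,
                                     pedRadiusMm = a, pedMaxHeightMm = h))
    v <- pedVolumeCavalieri(tp$segmentation, 6 / ny, 6 / nx, 1)
    abs(v - capVol) / capVol
  }, numeric(1))
  # boundary pixelation makes the error oscillate at the 1e-4 level, so
  # compare coarsest to finest rather than successive grids
  expect_lt(errs[3], errs[1])
  expect_true(all(errs < 0.002))
  expect_lt(errs[3], 1e-4)
})

test_that("zero-height segmentation yields zero volume", {
  expect_equal(pedVolumeCavalieri(.flatSeg(), 0.02, 0.01, 3.5), 0)
})

test_that("the peak region is the fractional-height super-level set", {
  cfg <- phantomConfig(domeProfile = "gaussian", domeSigmaMm = 0.5,
                       pedRadiusMm = 1.5, pedMaxHeightMm = 0.288)
  tp <- phantomTruth(cfg)
  hm <- heightMap(tp$segmentation, 3.5, c(6 / 512, 6 / 256))
  part <- partitionRegions(hm, marginMask(tp$segmentation), 0.7)
  # closed-form level-set radius of a Gaussian dome
  rPeak <- 0.5 * sqrt(-2 * log(0.7))
  peakArea <- sum(peakMask(part)) * pixelArea(part)
  expect_lt(abs(peakArea - pi * rPeak^2) / (pi * rPeak^2), 0.03)
  # slope is an annulus: all margin pixels beyond the peak radius
  expect_true(all((peakMask(part) | slopeMask(part)) == wholeMask(part)))

  # fraction 0: the whole PED is peak, slope empty -> ratio 0
  part0 <- partitionRegions(hm, marginMask(tp$segmentation), 0)
  expect_equal(sum(slopeMask(part0)), 0)
  expect_equal(slopeAreaRatio(part0), 0)
})

test_that("partition areas are exactly additive and the ratio bounds behave", {
  sh <- sharedLesionPhantom()
  tr <- sh$phantom$truth
  part <- tr@partition
  expect_identical(sum(peakMask(part)) + sum(slopeMask(part)),
                   sum(wholeMask(part)))
  r <- slopeAreaRatio(part)
  expect_true(r > 0 && r < 1)
})

test_that("a flat PED falls entirely into the slope region with a warning", {
  hm <- EnFaceMap(matrix(0, 6, 6), "mm", c(0.01, 0.01))
  expect_warning(part <- partitionRegions(hm, matrix(TRUE, 6, 6)), "flat")
  expect_equal(sum(peakMask(part)), 0)
  expect_equal(slopeAreaRatio(part), 1)   # peak empty -> ratio 1
  expect_error(partitionRegions(hm, matrix(FALSE, 6, 6)), "empty")
})

test_that("slope area ratio grows as the peak fraction rises on a strict dome", {
  tp <- phantomTruth(smallPhantomConfig())
  hm <- heightMap(tp$segmentation, 3.5, c(6 / 96, 6 / 48))
  ratios <- vapply(c(0.3, 0.5, 0.7, 0.9), function(f)
    slopeAreaRatio(partitionRegions(hm, marginMask(tp$segmentation), f)),
    numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("the morphometry wrapper recovers the phantom design parameters", {
  cfg <- phantomConfig(pedRadiusMm = 1.529, pedMaxHeightMm = 0.288)
  tp <- phantomTruth(cfg)
  m <- pedMorphometry(tp$segmentation, 3.5, c(6 / 512, 6 / 256))
  expect_lt(abs(m@maxHeightMm - 0.288), 3.5 / 1000)        # one axial pixel
  expect_lt(abs(m@pedAreaMm2 - pi * 1.529^2) / (pi * 1.529^2), 0.02)
  expect_lt(abs(m@pedVolumeMm3 - tp$truth@pedVolumeMm3) / tp$truth@pedVolumeMm3,
            0.02)
})
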