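# DOPU, attenuation-coefficient estimation and flow binarization.

test_that("DOPU is 1 for uniform polarization and 0 for exactly cancelling states", {
  d <- c(5, 5, 1)
  s0 <- array(2, d)
  sv <- StokesVolume(s0, 0.6 * s0, 0 * s0, 0.8 * s0)
  expect_equal(unname(dopu(computeDopu(sv))[3, 3, 1]), 1)
  expect_true(all(dopu(computeDopu(sv)) == 1))

  # 3x3 window holding four +u voxels, four -u voxels and one unpolarized
  # centre: component means cancel exactly
  u <- c(0.48, -0.6, 0.64)
  sgn <- matrix(c(1, -1, 1, -1, 0, -1, 1, -1, 1), 3, 3)
  s0 <- array(1, c(3, 3, 1))
  sv <- StokesVolume(s0, array(sgn * u[1], c(3, 3, 1)),
                     array(sgn * u[2], c(3, 3, 1)),
                     array(sgn * u[3], c(3, 3, 1)))
  expect_equal(unname(dopu(computeDopu(sv))[2, 2, 1]), 0)
})

test_that("vectorized DOPU equals the naive kernel-mean oracle on random fields", {
  set.seed(42)
  d <- c(16, 16, 16)
  n <- prod(d)
  s0 <- array(runif(n, 0.5, 2), d)
  dir <- randomStokesDirections(n)
  sv <- StokesVolume(s0, array(s0 * dir[, 1], d), array(s0 * dir[, 2], d),
                     array(s0 * dir[, 3], d))
  got <- dopu(computeDopu(sv, kernel = c(3L, 3L)))
  want <- naiveDopu(sv@s0, sv@s1, sv@s2, sv@s3, 3L, 3L)
  expect_lt(max(abs(got - want)), 1e-12)
})

test_that("DOPU is invariant under global rescaling of the Stokes components", {
  set.seed(11)
  d <- c(8, 7, 3)
  s0 <- array(runif(prod(d), 0.2, 1), d)
  dir <- randomStokesDirections(prod(d))
  sv <- StokesVolume(s0, array(s0 * dir[, 1], d), array(s0 * dir[, 2], d),
                     array(s0 * dir[, 3], d))
  sv2 <- StokesVolume(3.7 * sv@s0, 3.7 * sv@s1, 3.7 * sv@s2, 3.7 * sv@s3)
  expect_equal(dopu(computeDopu(sv2)), dopu(computeDopu(sv)), tolerance = 1e-12)
})

test_that("1x1 kernel with zero noise returns the per-voxel degree of polarization", {
  set.seed(5)
  d <- c(6, 6, 2)
  s0 <- array(runif(prod(d), 0.5, 1.5), d)
  p <- runif(prod(d))                     # per-voxel degree of polarization
  dir <- randomStokesDirections(prod(d))
  sv <- StokesVolume(s0, array(s0 * p * dir[, 1], d),
                     array(s0 * p * dir[, 2], d), array(s0 * p * dir[, 3], d))
  expect_equal(as.vector(dopu(computeDopu(sv, kernel = c(1L, 1L)))), p,
               tolerance = 1e-12)
})

test_that("signal-free kernels are emitted as DOPU 1 and flagged", {
  d <- c(9, 4, 1)
  s0 <- array(0, d)
  s0[1:3, , ] <- 1                       # signal only near the top
  sv <- StokesVolume(s0, 0 * s0, 0 * s0, s0)
  dv <- computeDopu(sv)
  expect_true(all(dopu(dv)[6:9, , ] == 1))
  expect_true(all(undefinedMask(dv)[6:9, , ]))
  expect_false(any(undefinedMask(dv)[1:3, , ]))
})

test_that("DOPU rejects even or non-positive kernels and negative noise", {
  sv <- StokesVolume(array(1, c(3, 3, 1)), array(0, c(3, 3, 1)),
                     array(0, c(3, 3, 1)), array(1, c(3, 3, 1)))
  expect_error(computeDopu(sv, kernel = c(2L, 3L)), "odd")
  expect_error(computeDopu(sv, noiseVariance = -1), "non-negative")
})

test_that("attenuation estimator recovers a single-exponential decay within 2%", {
  mu0 <- 2                                # mm^-1
  pitch <- 3.5                            # um
  nz <- 800
  z <- (seq_len(nz) - 1) * pitch / 1000
  I <- array(exp(-2 * mu0 * z), c(nz, 2, 2))
  att <- computeAttenuation(I, pitch)
  # away from the tail: leave 2.3/mu0 mm so truncation bias stays below 1%
  zTop <- nz - ceiling(2.3 / (mu0 * pitch / 1000))
  body <- mu(att)[10:zTop, 1, 1]
  expect_lt(max(abs(body - mu0) / mu0), 0.02)
})

test_that("attenuation of a two-layer medium is recovered stepwise within 5%", {
  pitch <- 2
  nz <- 1500
  z <- (seq_len(nz) - 1) * pitch / 1000
  muTrue <- ifelse(z < 1, 1, 4)
  I <- array(muTrue * exp(-2 * cumsum(muTrue * pitch / 1000)), c(nz, 1, 1))
  att <- computeAttenuation(I, pitch)
  iface <- which(muTrue == 4)[1]
  layer1 <- 10:(iface - 10)
  layer2 <- (iface + 10):round(0.8 * nz)
  expect_lt(max(abs(mu(att)[layer1, 1, 1] - 1)), 0.05)
  expect_lt(max(abs(mu(att)[layer2, 1, 1] - 4) / 4), 0.05)
})

test_that("attenuation handles zero intensity and is scale-equivariant", {
  I0 <- array(0, c(10, 3, 2))
  att0 <- computeAttenuation(I0, 3.5)
  expect_true(all(mu(att0) == 0))
  expect_true(all(undefinedMask(att0)))

  set.seed(3)
  I <- array(runif(300, 0.1, 1), c(25, 4, 3))
  a1 <- computeAttenuation(I, 3.5)
  a2 <- computeAttenuation(17.3 * I, 3.5)
  expect_equal(mu(a2), mu(a1), tolerance = 1e-12)
})

test_that("attenuation mu_norm is mu clipped to the reference scale", {
  I <- array(exp(-2 * 3 * (seq_len(400) - 1) * 0.0035), c(400, 1, 1))
  att <- computeAttenuation(I, 3.5, muRefMmInv = 10)
  expect_true(all(muNorm(att) >= 0 & muNorm(att) <= 1))
  expect_equal(muNorm(att)[50, 1, 1], mu(att)[50, 1, 1] / 10, tolerance = 1e-12)
})

test_that("OCTA binarization thresholds at >= and validates input", {
  f <- array(0, c(4, 4, 2))
  expect_true(all(flowMask(binarizeOcta(f, 0.5)) == 0))
  f1 <- array(1, c(4, 4, 2))
  expect_true(all(flowMask(binarizeOcta(f1, 0.99)) == 1))
  f[1, 1, 1] <- 0.5
  expect_equal(flowMask(binarizeOcta(f, 0.5))[1, 1, 1], 1)  # inclusive
  expect_error(binarizeOcta(f, 0), "strictly inside")
  f[2, 2, 2] <- NA
  expect_error(binarizeOcta(f, 0.5), "finite")
})
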