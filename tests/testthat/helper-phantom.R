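# Shared fixtures: reduced-grid phantom configurations and a memoized
# phantom so several test files can reuse one volumetric generation.

smallPhantomConfig <- function(seed = 1L, lesions = list(), nAlines = 96L,
                               nBscans = 48L, nDepth = 240L,
                               pedRadiusMm = 1.4, pedMaxHeightMm = 0.26, ...) {
  phantomConfig(nAlines = nAlines, nBscans = nBscans, nDepth = nDepth,
                pedRadiusMm = pedRadiusMm, pedMaxHeightMm = pedMaxHeightMm,
                lesions = lesions, seed = seed, ...)
}

tinyPhantomConfig <- function(seed = 1L, ...) {
  phantomConfig(nAlines = 48L, nBscans = 24L, nDepth = 200L,
                pedRadiusMm = 1.2, pedMaxHeightMm = 0.2, seed = seed, ...)
}

.phantomCache <- new.env(parent = emptyenv())

# One lesion-bearing phantom with its full contrast stack, shared across
# test files (peak + slope lesions, both well inside their regions).
sharedLesionPhantom <- function() {
  if (is.null(.phantomCache$lesion)) {
    cfg <- smallPhantomConfig(
      seed = 7L,
      lesions = list(list(region = "peak", radiusMm = 0.30, addedUm = 70),
                     list(region = "slope", radiusMm = 0.25, addedUm = 70)))
    ph <- generatePhantom(cfg)
    dop <- computeDopu(stokesVolume(ph$volume))
    att <- computeAttenuation(intensityVolume(ph$volume),
                              axialPitch(ph$volume))
    fm <- binarizeOcta(flowVolume(ph$volume))
    fr <- computeFrpe(att, dop, fm)
    .phantomCache$lesion <- list(config = cfg, phantom = ph, dopu = dop,
                                 attenuation = att, flow = fm, frpe = fr)
  }
  .phantomCache$lesion
}

# Random unit vectors on the Poincare sphere.
randomStokesDirections <- function(n) {
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

# Independent per-voxel kernel-mean DOPU oracle (naive loops).
naiveDopu <- function(s0, s1, s2, s3, kz = 3L, kx = 3L) {
  d <- dim(s0)
  hz <- (kz - 1L) %/% 2L; hx <- (kx - 1L) %/% 2L
  out <- array(1, d)
  for (k in seq_len(d[3])) for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    ri <- max(1L, i - hz):min(d[1], i + hz)
    rj <- max(1L, j - hx):min(d[2], j + hx)
    m0 <- mean(s0[ri, rj, k])
    if (m0 <= 0) next
    v <- sqrt(mean(s1[ri, rj, k])^2 + mean(s2[ri, rj, k])^2 +
              mean(s3[ri, rj, k])^2) / m0
    out[i, j, k] <- min(1, v)
  }
  out
}
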