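# Polarimetric and attenuation primitives: DOPU with kernel averaging and
# optional subtractive noise correction, a depth-resolved single-scattering
# attenuation estimator, and flow-signal binarization.

#' Compute the degree of polarization uniformity (DOPU)
#'
#' DOPU at a voxel is the degree of polarization of the kernel-averaged
#' Stokes vector:
#' \deqn{DOPU = \sqrt{\bar S_1^2 + \bar S_2^2 + \bar S_3^2} / \bar S_0}
#' where the bar denotes the mean over a small window around the voxel.
#' Uniformly polarized tissue gives DOPU near 1; melanin scrambles the
#' polarization state so the component means cancel and DOPU drops.
#'
#' The kernel is applied within each B-scan as (axial x lateral-fast); border
#' voxels use the kernel clipped at the volume edge (shrunken kernel). An
#' optional additive-noise correction subtracts \code{noiseVariance} from each
#' squared component mean and from the mean \eqn{\bar S_0} before the ratio.
#' Windows with no signal at all (\eqn{\sum S_0 = 0}) have no polarization
#' evidence; they are emitted as DOPU = 1 and flagged in
#' \code{\link{undefinedMask}}. The result is clipped to [0, 1].
#'
#' @param stokes a \linkS4class{StokesVolume}.
#' @param kernel odd integer pair, window extent (axial, lateral-fast);
#'   default 3 x 3.
#' @param noiseVariance non-negative scalar noise variance; default 0.
#' @return a \linkS4class{DopuVolume}.
#' @examples
#' s <- array(1, c(4, 4, 1))
#' sv <- StokesVolume(s, 0 * s, 0 * s, s)   # uniform circular state
#' range(dopu(computeDopu(sv)))             # exactly 1
#' @export
computeDopu <- function(stokes, kernel = c(3L, 3L), noiseVariance = 0) {
  stopifnot(is(stokes, "StokesVolume"))
  kernel <- as.integer(kernel)
  if (length(kernel) != 2L || any(kernel < 1L) || any(kernel %% 2L == 0L))
    stopf("kernel must be two odd integers >= 1, got (%s)",
          paste(kernel, collapse = ", "))
  if (length(noiseVariance) != 1L || noiseVariance < 0)
    stopf("noiseVariance must be a single non-negative number")

  d <- dim(stokes@s0)
  m0 <- m1 <- m2 <- m3 <- array(0, d)
  for (j in seq_len(d[3])) {            # per B-scan processing
    m0[, , j] <- boxMean2d(stokes@s0[, , j], kernel[1], kernel[2])$mean
    m1[, , j] <- boxMean2d(stokes@s1[, , j], kernel[1], kernel[2])$mean
    m2[, , j] <- boxMean2d(stokes@s2[, , j], kernel[1], kernel[2])$mean
    m3[, , j] <- boxMean2d(stokes@s3[, , j], kernel[1], kernel[2])$mean
  }
  undef <- m0 <= 0
  num <- sqrt(pmax(m1^2 - noiseVariance, 0) +
              pmax(m2^2 - noiseVariance, 0) +
              pmax(m3^2 - noiseVariance, 0))
  den <- m0 - noiseVariance
  dp <- array(1, d)                      # undefined -> 1 (no depolarization evidence)
  ok <- !undef & den > 0
  dp[ok] <- num[ok] / den[ok]
  dp <- clip01(dp)
  dp[dp >= 1 - 1e-12] <- 1               # snap fully polarized states to exactly 1
  DopuVolume(dp, kernel = kernel, noiseVariance = noiseVariance,
             undefined = undef)
}

#' Depth-resolved attenuation coefficient
#'
#' Single-scattering depth-resolved estimator: for each A-line,
#' \deqn{\mu(z) = I(z) / \left(2 \Delta \left[\sum_{z' > z} I(z') + I(z)/2\right]\right)}
#' with \eqn{\Delta} the axial pitch in mm. The denominator is the
#' trapezoidal estimate of the integrated signal below depth z, which keeps
#' the discretization bias second order in \eqn{\mu\Delta} (for a pure
#' exponential the estimate is \eqn{\tanh(\mu\Delta)/\Delta}). The estimator
#' attributes the signal at a depth to local backscatter relative to the
#' energy still arriving below it; under an exponentially decaying
#' single-layer model it recovers the true attenuation away from the tail of
#' the A-line. Depths whose below-voxel tail carries no signal cannot be
#' attributed and are emitted as \eqn{\mu = 0} and flagged.
#'
#' \code{muNorm} rescales to [0, 1] as \code{clip(mu / muRefMmInv, 0, 1)} so
#' the F_RPE index is bounded and its fixed threshold meaningful.
#'
#' @param intensity non-negative numeric 3-D array (depth x fast x slow).
#' @param axialPitchUm axial pitch in micrometres.
#' @param muRefMmInv normalization reference, mm^-1 (default 10).
#' @return an \linkS4class{AttenuationVolume}.
#' @export
computeAttenuation <- function(intensity, axialPitchUm, muRefMmInv = 10) {
  if (!is.array(intensity) || length(dim(intensity)) != 3L)
    stopf("intensity must be a 3-D array")
  if (any(intensity < 0)) stopf("intensity must be non-negative")
  if (axialPitchUm <= 0) stopf("axialPitchUm must be positive")
  if (muRefMmInv <= 0) stopf("muRefMmInv must be positive")

  d <- dim(intensity)
  nz <- d[1]
  deltaMm <- axialPitchUm / 1000
  m <- matrix(intensity, nrow = nz)           # columns are A-lines
  # below-voxel tail by bottom-up accumulation (a top-down cumsum subtracted
  # from the total cancels catastrophically where the tail is tiny)
  if (nz == 1L) {
    tail <- matrix(0, 1L, ncol(m))
  } else {
    csRev <- apply(m[nz:1, , drop = FALSE], 2, cumsum)
    tail <- rbind(csRev[(nz - 1):1, , drop = FALSE],
                  matrix(0, 1L, ncol(m)))     # sum over z' > z
  }
  muv <- matrix(0, nz, ncol(m))
  ok <- tail > 0
  muv[ok] <- m[ok] / (2 * deltaMm * (tail[ok] + m[ok] / 2))
  muArr <- array(muv, d)
  new("AttenuationVolume", mu = muArr,
      muNorm = clip01(muArr / muRefMmInv), muRefMmInv = muRefMmInv,
      axialPitchUm = axialPitchUm, undefined = array(!ok, d))
}

#' Binarize the OCT-angiography signal
#'
#' @param flow finite numeric 3-D array (normalized decorrelation-like signal).
#' @param threshold scalar in (0, 1); voxels with \code{flow >= threshold}
#'   are marked as flow. Default 0.5.
#' @return a \linkS4class{FlowMask}.
#' @export
binarizeOcta <- function(flow, threshold = 0.5) {
  if (!is.array(flow) || length(dim(flow)) != 3L)
    stopf("flow must be a 3-D array")
  if (any(!is.finite(flow))) stopf("flow must be finite")
  if (length(threshold) != 1L || threshold <= 0 || threshold >= 1)
    stopf("threshold must lie strictly inside (0, 1)")
  new("FlowMask", mask = array(as.numeric(flow >= threshold), dim(flow)),
      threshold = threshold)
}
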