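## Closed-loop study routines: reusable experiments that exercise the whole
## toolkit and return summary numbers.

#' Spectral-ratio study: empirical S_VV/S_UU against the model |H|^2
#'
#' For each medium, blurs one noiseless speckle ensemble with the medium's
#' impulse response and compares the radial-profile ratio of the output and
#' input PSD estimates against the model spectral ratio (the PSD-weighted
#' annulus average of |H(k)|^2 from the same photon records). Returns the
#' largest in-band relative deviation per medium.
#'
#' @param records [PathlengthRecords-class].
#' @param geometry [OpticalGeometry-class].
#' @param media list of [TurbidMedium-class] (or data.frame with muA,
#'   muSPrime, g columns).
#' @param N realizations in the input ensemble.
#' @param baseSeed ensemble seed.
#' @return data.frame with columns muA, muSPrime, maxDeviation (largest
#'   in-band |empirical/model - 1|).
#' @export
spectralRatioStudy <- function(records, geometry, media, N = 10L,
                               baseSeed = 1L) {
  if (is.data.frame(media))
    media <- lapply(seq_len(nrow(media)), function(i)
      turbidMedium(media$muA[i], media$muSPrime[i],
                   if ("g" %in% names(media)) media$g[i] else records@g))
  ens <- synthesizeEnsemble(geometry, N = N, baseSeed = baseSeed)
  dims <- dim(ens@images)[1:2]
  scale <- ens@pixelScale
  binWidth <- 1.0000001 / min(dims * scale)
  psdU <- estimatePSD(estimateACF(ens, circular = TRUE), window = "none")
  sUU <- radialAverage(psdU, binWidth = binWidth)
  kc <- min(apertureCutoff(geometry))
  out <- data.frame(muA = NA_real_, muSPrime = NA_real_,
                    maxDeviation = NA_real_)[rep(1L, length(media)), ]
  rownames(out) <- NULL
  for (i in seq_along(media)) {
    m <- media[[i]]
    h <- mediumImpulseResponse(records, m, dims, scale)
    v <- applyMedium(ens, h)
    sVV <- ensembleRadialPSD(v, circular = TRUE, window = "none",
                             binWidth = binWidth)
    mod <- modelSpectralRatio(records, m, psdU, binWidth = binWidth,
                              kMax = max(attr(sUU, "edges")))
    inb <- which(sUU$k <= kc)
    dev <- abs((sVV$S[inb] / sUU$S[inb]) / mod$ratio[inb] - 1)
    out$muA[i] <- m@muA
    out$muSPrime[i] <- m@muSPrime
    out$maxDeviation[i] <- max(dev)
  }
  out
}

#' Fixed-pattern impact study
#'
#' Quantifies why the pair-subtraction autocorrelation estimator exists:
#' over repeated trials, a deterministic edge-artefact pattern (amplitude a
#' given fraction of the signal's bright level) is injected into the imaging
#' chain, and the resulting change of the in-band radial PSD is measured for
#' the fixed-pattern-cancelling estimator and for the naive averaged
#' autocorrelation. The subtraction estimator is nearly transparent to the
#' pattern (the residual comes from auto-exposure, quantization and noise
#' interacting with it), while the naive estimator absorbs the pattern's
#' full spectral power.
#'
#' @param geometry [OpticalGeometry-class] for the speckle inputs.
#' @param sensor [SensorModel-class].
#' @param nTrials independent trials averaged.
#' @param N frames per ensemble.
#' @param amplitudeFraction pattern amplitude as a fraction of the ideal
#'   field's auto-exposure reference level (default 0.2).
#' @param baseSeed master seed.
#' @return list with `pairSubtractChangePct` and `naiveChangePct`: mean in-band
#'   relative PSD change, percent.
#' @export
fixedPatternImpactStudy <- function(geometry, sensor = sensorModel(),
                                    nTrials = 50L, N = 10L,
                                    amplitudeFraction = 0.2,
                                    baseSeed = 1L) {
  dims <- geometry@sensorShape
  scale <- rep(geometry@targetPixelScale, 2L)
  binWidth <- 1.0000001 / min(dims * scale)
  kc <- min(apertureCutoff(geometry))
  bandMean <- function(ens, pairSubtract) {
    p <- ensembleRadialPSD(ens, removeFixedPattern = pairSubtract, circular = TRUE,
                           window = "none", binWidth = binWidth)
    mean(p$S[p$k <= kc])
  }
  d4 <- dn <- numeric(nTrials)
  for (t in seq_len(nTrials)) {
    ens <- synthesizeEnsemble(geometry, N = N,
                              baseSeed = deriveSeed(baseSeed, t, 1L))
    ref <- quantile(ens@images,
                    sensor@autoExposurePercentile / 100, names = FALSE)
    fp <- makeFixedPattern(dims, amplitudeFraction * ref,
                           seed = deriveSeed(baseSeed, t, 2L))
    noiseSeed <- deriveSeed(baseSeed, t, 3L)
    clean <- correctExposure(observeEnsemble(ens, sensor,
                                             seed = noiseSeed))
    dirty <- correctExposure(observeEnsemble(ens, sensor,
                                             fixedPattern = fp,
                                             seed = noiseSeed))
    d4[t] <- abs(bandMean(dirty, TRUE) / bandMean(clean, TRUE) - 1)
    dn[t] <- abs(bandMean(dirty, FALSE) / bandMean(clean, FALSE) - 1)
  }
  list(pairSubtractChangePct = 100 * mean(d4), naiveChangePct = 100 * mean(dn))
}
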