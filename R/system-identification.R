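## Reduction of input and output image ensembles to the two response
## parameters. The medium acts as a linear spatially invariant filter, so
## the output PSD is |H(k_r)|^2 times the input PSD. Rather than fitting a
## full response curve to noisy spectra, the estimated radial PSDs are
## reduced to H_DC (low-frequency power ratio, approximately |H(0)|^2) and
## H_AC (DC-normalized in-band signal power retained by the backscatter).

#' Radial PSD profile of an image ensemble
#'
#' Convenience chain: fixed-pattern-cancelling autocorrelation, lag-windowed
#' Wiener-Khinchin spectrum, annulus average.
#'
#' @param x an ensemble.
#' @param removeFixedPattern,maxLag,circular passed to [estimateACF()].
#' @param window,nfft passed to [estimatePSD()].
#' @param nBins,binWidth,kMax passed to [radialAverage()].
#' @return the radial profile data.frame of [radialAverage()].
#' @export
ensembleRadialPSD <- function(x, removeFixedPattern = TRUE, maxLag = NULL,
                              circular = FALSE,
                              window = c("hann", "none"), nfft = NULL,
                              nBins = NULL, binWidth = NULL, kMax = NULL) {
  acf <- estimateACF(x, removeFixedPattern = removeFixedPattern,
                     maxLag = maxLag, circular = circular)
  psd <- estimatePSD(acf, window = match.arg(window), nfft = nfft)
  radialAverage(psd, nBins = nBins, binWidth = binWidth, kMax = kMax)
}

checkProfilePair <- function(sUU, sVV) {
  if (nrow(sUU) != nrow(sVV) || max(abs(sUU$k - sVV$k)) > 1e-9)
    stop("input and output radial profiles must share one frequency grid")
}

#' DC response from radial PSD profiles
#'
#' The ratio of band-averaged low-frequency PSD values,
#' S_VV(k_r -> 0) / S_UU(k_r -> 0), approximating |H(0)|^2. The k_r -> 0
#' limit is operationalized as the average over the `dcBins` lowest non-DC
#' radial bins, weighted by the cell count of each annulus (equivalent to
#' pooling all frequency cells of those bins, which minimizes the estimator
#' variance for a given band).
#'
#' @param sUU,sVV radial profiles from [radialAverage()] on one k grid.
#' @param dcBins number of lowest bins averaged (default 3).
#' @return the DC response (dimensionless).
#' @export
estimateHDC <- function(sUU, sVV, dcBins = 3L) {
  checkProfilePair(sUU, sVV)
  idx <- seq_len(min(dcBins, nrow(sUU)))
  w <- if (!is.null(sUU$n)) sUU$n[idx] else rep(1, length(idx))
  denom <- sum(w * sUU$S[idx])
  if (!is.finite(denom) || denom <= 1e-12 * max(sUU$S) * sum(w))
    stop("input PSD has no power in the DC band; ",
         "the DC response is ill-conditioned")
  sum(w * sVV$S[idx]) / denom
}

#' AC response from radial PSD profiles
#'
#' The in-band signal power retained by the backscatter, normalized to unit
#' DC response:
#' [S_UU(k->0)/S_VV(k->0)] * [int S_VV 2 pi k dk / int S_UU 2 pi k dk],
#' with the integrals taken over `band` by annulus-weighted summation.
#'
#' @param sUU,sVV radial profiles on one k grid.
#' @param band numeric(2), integration band [k_low, k_high] in 1/mm.
#' @param dcBins bins used for the k_r -> 0 average.
#' @return the AC response (dimensionless).
#' @export
estimateHAC <- function(sUU, sVV, band, dcBins = 3L) {
  checkProfilePair(sUU, sVV)
  idx <- which(sUU$k >= band[1] & sUU$k <= band[2])
  if (length(idx) < 2L)
    stop("integration band [", band[1], ", ", band[2],
         "] covers fewer than 2 radial bins")
  den <- radialIntegral(sUU, idx)
  if (den <= 1e-12 * max(sUU$S))
    stop("input PSD has no power in the integration band")
  hdc <- estimateHDC(sUU, sVV, dcBins)
  (1 / hdc) * radialIntegral(sVV, idx) / den
}

# internal: radial profile straight from a spectra cache (jackknife path)
radialFromCache <- function(cache, lagScale, subset = NULL, pairSubtract = TRUE,
                            normalization = "unbiased", window = "hann",
                            nfft = NULL, binWidth = NULL, nBins = NULL,
                            kMax = NULL) {
  C <- correlationSpectrum(cache, pairSubtract = pairSubtract, subset = subset)
  a <- acfFromSpectrum(C, cache, normalization = normalization)
  acf <- new("AcfEstimate", acf = a$acf, lagScale = lagScale,
             zeroLagIndex = a$zeroLagIndex, fixedPatternRemoved = pairSubtract,
             nUsed = if (is.null(subset)) cache$N else length(subset),
             normalization = a$normalization)
  psd <- estimatePSD(acf, window = window, nfft = nfft)
  radialAverage(psd, nBins = nBins, binWidth = binWidth, kMax = kMax)
}

#' Reduce an input/output ensemble pair to response parameters
#'
#' Runs the full identification chain on an exposure-corrected reference
#' input ensemble and a backscatter output ensemble: fixed-pattern
#' cancelling autocorrelation, PSD, radial average, then the DC and AC
#' response ratios. Uncertainties are leave-one-realization-out jackknife
#' standard errors, combined over the input and output ensembles.
#'
#' The input ensemble follows the reference-measurement convention: it is
#' typically captured once (a diffusing screen in place of the sample) and
#' reused for every sample measured under the same projection optics.
#'
#' @param input reference input ensemble ([SpeckleEnsemble-class],
#'   corrected [BackscatterEnsemble-class], or 3D array).
#' @param output backscatter ensemble (exposure-corrected).
#' @param band numeric(2) [k_low, k_high] in 1/mm; when NULL it is derived
#'   from `geometry` as [3rd radial bin edge, min per-axis aperture cutoff].
#' @param geometry optional [OpticalGeometry-class] used to derive the band.
#' @param dcBins bins for the k_r -> 0 average (default 3).
#' @param circular,window,maxLag,nfft,binWidth,nBins estimator settings, see
#'   [estimateACF()], [estimatePSD()], [radialAverage()].
#' @param jackknife "both" (default), "output" or "none": which ensembles to
#'   jackknife for standard errors. With a shared reference input measured
#'   once, its sampling error is a common systematic across samples (and is
#'   absorbed by calibration), so "output" is appropriate there. Logical
#'   TRUE/FALSE map to "both"/"none".
#' @return A [ResponseParameters-class]. Values outside [0, 1] are flagged
#'   (with a warning), never clipped.
#' @export
analyzeExperiment <- function(input, output, band = NULL, geometry = NULL,
                              dcBins = 3L, circular = TRUE,
                              window = c("hann", "none"), maxLag = NULL,
                              nfft = NULL, binWidth = NULL, nBins = NULL,
                              jackknife = c("both", "output", "none")) {
  if (is.logical(jackknife)) jackknife <- if (jackknife) "both" else "none"
  jackknife <- match.arg(jackknife)
  window <- match.arg(window)
  if (is(output, "BackscatterEnsemble") && !output@corrected)
    stop("output ensemble must be exposure-corrected first")
  arrU <- ensembleArray(input)
  arrV <- ensembleArray(output)
  if (!identical(dim(arrU)[1:2], dim(arrV)[1:2]))
    stop("input and output images must share one shape")
  scale <- ensemblePixelScale(input)

  cacheU <- spectraCache(arrU, maxLag = maxLag, circular = circular)
  cacheV <- spectraCache(arrV, maxLag = maxLag, circular = circular)
  prof <- function(cache, subset = NULL)
    radialFromCache(cache, scale, subset = subset, window = window,
                    nfft = nfft, binWidth = binWidth, nBins = nBins)
  sUU <- prof(cacheU)
  sVV <- prof(cacheV)

  if (is.null(band)) {
    edges <- attr(sUU, "edges")
    kHigh <- if (!is.null(geometry)) min(apertureCutoff(geometry))
             else max(sUU$k)
    band <- c(edges[min(3L, length(edges) - 1L)], kHigh)
  }

  hdc <- estimateHDC(sUU, sVV, dcBins)
  hac <- estimateHAC(sUU, sVV, band, dcBins)

  se <- c(dc = NA_real_, ac = NA_real_)
  if (jackknife != "none") {
    jk <- function(cache, fixedProf, dropOutput) {
      n <- cache$N
      th <- matrix(0, n, 2)
      for (i in seq_len(n)) {
        p <- prof(cache, subset = setdiff(seq_len(n), i))
        if (dropOutput) {
          th[i, 1] <- estimateHDC(fixedProf, p, dcBins)
          th[i, 2] <- estimateHAC(fixedProf, p, band, dcBins)
        } else {
          th[i, 1] <- estimateHDC(p, fixedProf, dcBins)
          th[i, 2] <- estimateHAC(p, fixedProf, band, dcBins)
        }
      }
      apply(th, 2, function(v) sqrt((n - 1) / n * sum((v - mean(v))^2)))
    }
    seOut <- jk(cacheV, sUU, dropOutput = TRUE)
    seIn <- if (jackknife == "both") jk(cacheU, sVV, dropOutput = FALSE)
            else c(0, 0)
    se <- sqrt(seOut^2 + seIn^2)
    names(se) <- c("dc", "ac")
  }

  oor <- hdc > 1 || hac > 1
  if (oor)
    warning(sprintf(
      "response parameters outside [0, 1] (H_DC = %.3g, H_AC = %.3g); ",
      hdc, hac), "check noise levels and calibration")
  new("ResponseParameters",
      hDC = hdc, hAC = hac, band = as.numeric(band),
      dcBins = as.numeric(dcBins),
      nIn = dim(arrU)[3], nOut = dim(arrV)[3],
      se = se, outOfRange = oor)
}

#' Model-side response parameters for a medium
#'
#' Evaluates the model counterparts of the DC and AC response ratios from
#' White Monte Carlo records and a measured input radial PSD: the same
#' functionals the estimators apply to data, with the model |H(k_r)|^2 in
#' place of the spectral ratio.
#'
#' @param records [PathlengthRecords-class].
#' @param medium [TurbidMedium-class].
#' @param sUU input radial profile (data.frame k, S from
#'   [radialAverage()]).
#' @param band numeric(2) integration band, 1/mm.
#' @param dcBins bins in the k_r -> 0 average.
#' @param dcMode "band" evaluates the DC ratio over the same low-frequency
#'   band as the estimator (the default, consistent with data); "dc0" uses
#'   the idealized |H(0)|^2 = R_d^2.
#' @return list(hDC, hAC).
#' @export
modelResponseParameters <- function(records, medium, sUU, band,
                                    dcBins = 3L,
                                    dcMode = c("band", "dc0")) {
  dcMode <- match.arg(dcMode)
  fr <- frequencyResponse(records, medium, k = c(0, sUU$k))
  H2 <- fr@H[-1]^2
  H0sq <- fr@H[1]^2
  idxDC <- seq_len(min(dcBins, nrow(sUU)))
  wDC <- if (!is.null(sUU$n)) sUU$n[idxDC] else rep(1, length(idxDC))
  hdc <- if (dcMode == "dc0") H0sq
         else sum(wDC * H2[idxDC] * sUU$S[idxDC]) /
              sum(wDC * sUU$S[idxDC])
  idx <- which(sUU$k >= band[1] & sUU$k <= band[2])
  wk <- sUU$S[idx] * 2 * pi * sUU$k[idx]
  hac <- (1 / hdc) * sum(H2[idx] * wk) / sum(wk)
  list(hDC = hdc, hAC = hac)
}

#' Model spectral ratio on the estimator's radial bins
#'
#' The model counterpart of the empirical S_VV/S_UU radial-profile ratio:
#' |H(k)|^2 evaluated at every 2D frequency cell of the input spectrum,
#' weighted by the input PSD, and annulus-averaged with the same binning as
#' [radialAverage()]. Because each annulus mixes cells at different |k|,
#' this PSD-weighted average -- not |H|^2 at the nominal bin centre -- is
#' what the empirical ratio estimates.
#'
#' @param records [PathlengthRecords-class].
#' @param medium [TurbidMedium-class].
#' @param psdUU input [PsdEstimate-class] (2D).
#' @param nBins,binWidth,kMax binning, as in [radialAverage()].
#' @return data.frame with columns `k` (bin centres) and `ratio` (model
#'   |H|^2 per bin).
#' @export
modelSpectralRatio <- function(records, medium, psdUU, nBins = NULL,
                               binWidth = NULL, kMax = NULL) {
  stopifnot(is(psdUU, "PsdEstimate"))
  kx <- psdUU@kx; ky <- psdUU@ky
  if (is.null(kMax)) kMax <- min(max(abs(kx)), max(abs(ky)))
  if (!is.null(nBins)) binWidth <- kMax / nBins
  else if (is.null(binWidth)) binWidth <- max(abs(kx)) / 64
  edges <- seq(0, kMax + binWidth * 1e-9, by = binWidth)
  kr <- sqrt(outer(kx^2, ky^2, "+"))
  fr <- frequencyResponse(records, medium,
                          k = seq(0, kMax + binWidth, by = binWidth / 8))
  H2 <- matrix(evalFrequencyResponse(fr, kr)^2, nrow(kr))
  sel <- kr < edges[length(edges)] & kr > 0
  bin <- factor(findInterval(kr[sel], edges, rightmost.closed = TRUE),
                levels = seq_len(length(edges) - 1L))
  num <- as.numeric(tapply(H2[sel] * psdUU@psd[sel], bin, sum))
  den <- as.numeric(tapply(psdUU@psd[sel], bin, sum))
  data.frame(k = (edges[-1] + edges[-length(edges)]) / 2,
             ratio = num / den)
}

#' @export
setMethod("responseParameters", "ResponseParameters", function(object)
  c(hDC = object@hDC, hAC = object@hAC))

setMethod("show", "ResponseParameters", function(object) {
  cat(sprintf(
    "ResponseParameters: H_DC = %.4g (se %.2g), H_AC = %.4g (se %.2g)\n",
    object@hDC, object@se["dc"], object@hAC, object@se["ac"]),
    sprintf("  band [%.3g, %.3g] 1/mm, %g DC bins, N_in = %d, N_out = %d%s\n",
            object@band[1], object@band[2], object@dcBins, object@nIn,
            object@nOut,
            if (object@outOfRange) " [OUT OF RANGE]" else ""))
})
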