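## First- and second-order statistics of image ensembles.
##
## Correlations are computed in the frequency domain. The fixed-pattern
## cancelling estimator subtracts the average cross-correlation over the
## N(N-1) distinct image pairs from the average autocorrelation of the N
## images; any additive deterministic component common to all realizations
## (including the process mean) cancels in expectation. The pair sums are
## folded through sum-image algebra so only N + 1 transforms are needed.

# Per-ensemble FFT cache. circular = TRUE treats images as periodic (exact
# for fields synthesized by a full-grid DFT); otherwise images are
# zero-padded so linear correlations are free of circular wrap.
spectraCache <- function(arr, maxLag = NULL, circular = FALSE) {
  d <- dim(arr)[1:2]
  N <- dim(arr)[3]
  if (circular) {
    pad <- d
    maxLag <- floor(d / 2)
  } else {
    if (is.null(maxLag)) maxLag <- floor(min(d) / 4)
    maxLag <- rep(as.integer(maxLag), length.out = 2L)
    if (any(maxLag >= d))
      stop("maxLag must be smaller than the image dimensions")
    pad <- vapply(d + maxLag + 1L, stats::nextn, 1L)
  }
  A <- array(complex(real = 0), dim = c(pad, N))
  buf <- matrix(0, pad[1], pad[2])
  for (i in seq_len(N)) {
    buf[] <- 0
    buf[seq_len(d[1]), seq_len(d[2])] <- arr[, , i]
    A[, , i] <- fft2(buf)
  }
  sumA <- apply(A, c(1, 2), sum)
  sumP <- apply(Mod(A)^2, c(1, 2), sum)
  list(A = A, sumA = sumA, sumP = sumP, dims = d, pad = pad,
       maxLag = maxLag, N = N, circular = circular)
}

# Correlation spectrum for a subset of realizations.
# pair subtraction: (1/n) sum_{i=j} |A_i|^2 - 1/(n(n-1)) * (|sum A_i|^2 - sum |A_i|^2)
correlationSpectrum <- function(cache, pairSubtract = TRUE, subset = NULL) {
  if (is.null(subset)) {
    sumA <- cache$sumA; sumP <- cache$sumP; n <- cache$N
  } else {
    n <- length(subset)
    sumA <- apply(cache$A[, , subset, drop = FALSE], c(1, 2), sum)
    sumP <- apply(Mod(cache$A[, , subset, drop = FALSE])^2, c(1, 2), sum)
  }
  if (pairSubtract) {
    if (n < 2L)
      stop("fixed-pattern removal needs at least N = 2 realizations")
    sumP / n - (Mod(sumA)^2 - sumP) / (n * (n - 1))
  } else {
    sumP / n
  }
}

# Centered lag-domain ACF from a correlation spectrum.
acfFromSpectrum <- function(C, cache,
                            normalization = c("unbiased", "biased")) {
  d <- cache$dims
  L <- cache$maxLag
  r <- Re(fft2(C, inverse = TRUE)) / prod(cache$pad)
  if (cache$circular) {
    acf <- fftshift2(r) / prod(d)
    z <- floor(d / 2) + 1L
    return(list(acf = acf, zeroLagIndex = as.integer(z),
                normalization = "circular"))
  }
  normalization <- match.arg(normalization)
  # crop wrap-ordered lags 0..L and -L..-1 into a centred (2L+1) block
  idx1 <- c(cache$pad[1] - L[1] + seq_len(L[1]), seq_len(L[1] + 1L))
  idx2 <- c(cache$pad[2] - L[2] + seq_len(L[2]), seq_len(L[2] + 1L))
  acf <- r[idx1, idx2, drop = FALSE]
  if (normalization == "unbiased") {
    counts <- outer(d[1] - abs(seq.int(-L[1], L[1])),
                    d[2] - abs(seq.int(-L[2], L[2])))
    acf <- acf / counts
  } else {
    acf <- acf / prod(d)
  }
  list(acf = acf, zeroLagIndex = as.integer(L + 1L),
       normalization = normalization)
}

#' Ensemble autocorrelation with optional fixed-pattern cancellation
#'
#' Estimates the autocorrelation function of the 2D random process behind an
#' image ensemble. With `removeFixedPattern = TRUE` (default) the average
#' cross-correlation over all distinct image pairs is subtracted from the
#' average autocorrelation, cancelling in expectation any additive
#' deterministic component shared by every realization -- glare edges,
#' scratches, and the process mean itself. With the flag off the plain
#' average autocorrelation is returned.
#'
#' @param x a [SpeckleEnsemble-class], [BackscatterEnsemble-class], 3D array
#'   (realization index last) or list of same-shape matrices.
#' @param removeFixedPattern logical; apply the pair-subtraction estimator.
#' @param maxLag largest lag retained, per axis (default: a quarter of the
#'   smaller image dimension). Ignored when `circular = TRUE`.
#' @param normalization "unbiased" divides each lag by its overlap count;
#'   "biased" divides by the pixel count (the Fourier pair of the averaged
#'   periodogram).
#' @param circular treat images as periodic and skip zero padding; exact for
#'   fields generated by full-grid Fourier synthesis.
#' @param ... unused.
#' @return An [AcfEstimate-class].
#' @export
setMethod("estimateACF", "ANY",
  function(x, removeFixedPattern = TRUE, maxLag = NULL,
           normalization = c("unbiased", "biased"), circular = FALSE, ...) {
    arr <- ensembleArray(x)
    if (dim(arr)[3] < 2L && removeFixedPattern)
      stop("fixed-pattern removal needs at least N = 2 realizations")
    normalization <- match.arg(normalization)
    cache <- spectraCache(arr, maxLag = maxLag, circular = circular)
    C <- correlationSpectrum(cache, pairSubtract = removeFixedPattern)
    a <- acfFromSpectrum(C, cache, normalization = normalization)
    new("AcfEstimate",
        acf = a$acf,
        lagScale = ensemblePixelScale(x),
        zeroLagIndex = a$zeroLagIndex,
        fixedPatternRemoved = removeFixedPattern,
        nUsed = dim(arr)[3],
        normalization = a$normalization)
  })

# Separable Hann lag window, unity at zero lag (preserves total power).
lagWindow <- function(dims, zeroLag, window) {
  if (window == "none") return(matrix(1, dims[1], dims[2]))
  l1 <- seq_len(dims[1]) - zeroLag[1]
  l2 <- seq_len(dims[2]) - zeroLag[2]
  L1 <- max(abs(l1), 1L); L2 <- max(abs(l2), 1L)
  w1 <- 0.5 * (1 + cos(pi * pmin(abs(l1) / L1, 1)))
  w2 <- 0.5 * (1 + cos(pi * pmin(abs(l2) / L2, 1)))
  outer(w1, w2)
}

#' Power spectral density from an autocorrelation estimate
#'
#' Applies a lag window to the autocorrelation and Fourier transforms it
#' (Wiener-Khinchin). The spectrum integrates (sum times the frequency cell
#' area) exactly to the windowed zero-lag value before clipping; negative
#' numerical residues are clipped to zero and their total magnitude (as a 2D
#' integral, so the Parseval identity can be audited after clipping) is
#' reported in the `clippedPower` slot.
#'
#' @param x an [AcfEstimate-class].
#' @param window "hann" (default) or "none". The Hann lag window is unity at
#'   zero lag, so total power is preserved.
#' @param nfft transform size per axis; defaults to the ACF size for
#'   circular estimates and to twice the lag extent (rounded up to a highly
#'   composite size) otherwise, which refines the frequency sampling.
#' @param ... unused.
#' @return A [PsdEstimate-class] with axes in 1/mm.
#' @export
setMethod("estimatePSD", "AcfEstimate",
  function(x, window = c("hann", "none"), nfft = NULL, ...) {
    window <- match.arg(window)
    a <- x@acf
    if (any(!is.finite(a))) stop("ACF contains non-finite values")
    d <- dim(a)
    z <- x@zeroLagIndex
    if (is.null(nfft)) {
      nfft <- if (x@normalization == "circular") d
              else vapply(2L * d, stats::nextn, 1L)
    }
    nfft <- rep(as.integer(nfft), length.out = 2L)
    if (any(nfft < d)) stop("nfft must be at least the ACF size")
    aw <- a * lagWindow(d, z, window)
    # embed so zero lag sits at [1, 1] with negative lags wrapped
    buf <- matrix(0, nfft[1], nfft[2])
    ii <- ((seq_len(d[1]) - z[1]) %% nfft[1]) + 1L
    jj <- ((seq_len(d[2]) - z[2]) %% nfft[2]) + 1L
    buf[ii, jj] <- aw
    cell <- prod(x@lagScale)
    psd <- Re(fft2(buf)) * cell
    dk <- 1 / (nfft * x@lagScale)
    clipped <- -sum(psd[psd < 0]) * prod(dk)  # clipped 2D integral
    psd[psd < 0] <- 0
    psd <- fftshift2(psd)
    new("PsdEstimate",
        psd = psd,
        kx = fftFreq(nfft[1], x@lagScale[1]),
        ky = fftFreq(nfft[2], x@lagScale[2]),
        window = window,
        nUsed = x@nUsed,
        clippedPower = clipped)
  })

#' Power spectral density straight from an image ensemble
#'
#' Convenience method: runs [estimateACF()] with the supplied (or default)
#' estimator settings, then the Wiener-Khinchin transform.
#'
#' @param x an ensemble (see [estimateACF()]).
#' @param window,nfft as in the [AcfEstimate-class] method.
#' @param removeFixedPattern,maxLag,normalization,circular passed to
#'   [estimateACF()].
#' @param ... unused.
#' @export
setMethod("estimatePSD", "ANY",
  function(x, window = c("hann", "none"), nfft = NULL,
           removeFixedPattern = TRUE, maxLag = NULL,
           normalization = c("unbiased", "biased"),
           circular = FALSE, ...) {
    acf <- estimateACF(x, removeFixedPattern = removeFixedPattern,
                       maxLag = maxLag,
                       normalization = match.arg(normalization),
                       circular = circular)
    estimatePSD(acf, window = match.arg(window), nfft = nfft)
  })

#' Radial (annulus) average of a 2D power spectrum
#'
#' Averages the spectrum over annuli of |k|. The zero-frequency cell is
#' excluded: the fixed-pattern-cancelling estimator removes the mean only in
#' expectation, and residual DC is estimator noise.
#'
#' @param x a [PsdEstimate-class].
#' @param nBins number of annuli; overrides `binWidth`.
#' @param binWidth annulus width in 1/mm; default Nyquist/64.
#' @param kMax outer radius (default: the largest radius fully inside the
#'   rectangular frequency support).
#' @param ... unused.
#' @return data.frame with columns `k` (bin centres, 1/mm), `S` (annulus
#'   means) and `n` (cells per annulus), with attributes `edges`,
#'   `binWidth`, and `total2D` (the 2D integral over the averaged region,
#'   for closure checks).
#' @export
setMethod("radialAverage", "PsdEstimate",
  function(x, nBins = NULL, binWidth = NULL, kMax = NULL, ...) {
    kx <- x@kx; ky <- x@ky
    if (is.null(kMax)) kMax <- min(max(abs(kx)), max(abs(ky)))
    if (!is.null(nBins)) {
      if (nBins < 4L) stop("at least 4 radial bins are required")
      binWidth <- kMax / nBins
    } else if (is.null(binWidth)) {
      # Nyquist/64 unless that under-resolves the frequency grid itself
      nyquist <- max(abs(kx))
      binWidth <- max(nyquist / 64,
                      1.0000001 * max(kx[2] - kx[1], ky[2] - ky[1]))
    }
    edges <- seq(0, kMax + binWidth * 1e-9, by = binWidth)
    if (length(edges) < 5L)
      stop("fewer than 4 annuli fit below kMax; reduce binWidth")
    kr <- sqrt(outer(kx^2, ky^2, "+"))
    sel <- kr < edges[length(edges)] & kr > 0  # exclude the DC cell
    bin <- findInterval(kr[sel], edges, rightmost.closed = TRUE)
    v <- x@psd[sel]
    nb <- length(edges) - 1L
    cnt <- tabulate(bin, nbins = nb)
    if (any(cnt == 0L))
      stop("empty annuli at the requested resolution; ",
           "reduce the number of bins or enlarge nfft")
    S <- as.numeric(tapply(v, factor(bin, levels = seq_len(nb)), mean))
    out <- data.frame(k = (edges[-1] + edges[-length(edges)]) / 2,
                      S = S, n = cnt)
    dkx <- kx[2] - kx[1]; dky <- ky[2] - ky[1]
    attr(out, "edges") <- edges
    attr(out, "binWidth") <- binWidth
    attr(out, "total2D") <- sum(v) * dkx * dky
    out
  })

# band-weighted integral sum(S * 2*pi*k * dk) over profile rows `idx`
radialIntegral <- function(profile, idx = seq_len(nrow(profile))) {
  bw <- attr(profile, "binWidth")
  sum(profile$S[idx] * 2 * pi * profile$k[idx] * bw)
}

#' Stationarity and ergodicity diagnostics
#'
#' Three checks that an ensemble behaves as independent realizations of one
#' wide-sense-stationary, mean-ergodic process: (i) pairwise
#' cross-correlation peaks are small relative to the autocorrelation peak
#' (independence); (ii) pixelwise means across realizations scatter around
#' the global mean no more than their sampling error predicts (mean
#' ergodicity); (iii) the autocorrelation decays well below its peak within
#' the available lag range. Degenerate ensembles produce fail verdicts, not
#' errors.
#'
#' @param x an ensemble (N >= 3).
#' @param thresholds named numeric: `crossAuto` (max cross/auto peak ratio),
#'   `ergodicMeanSE` (allowed scatter in SE units), `acfDecay` (allowed ACF
#'   magnitude at the largest lag, relative to peak).
#' @param maxLag passed to the ACF decay check.
#' @param ... unused.
#' @return A [StationarityReport-class].
#' @export
setMethod("stationarityReport", "ANY",
  function(x, thresholds = c(crossAuto = 0.1, ergodicMeanSE = 3,
                             acfDecay = 0.1),
           maxLag = NULL, ...) {
    arr <- ensembleArray(x)
    d <- dim(arr)[1:2]
    N <- dim(arr)[3]
    if (N < 3L) stop("stationarity diagnostics need N >= 3 realizations")

    # (i) independence: centred cross-correlation peaks vs auto peaks
    ctr <- arr
    for (i in seq_len(N)) ctr[, , i] <- arr[, , i] - mean(arr[, , i])
    pad <- vapply(2L * d, stats::nextn, 1L)
    A <- array(complex(real = 0), dim = c(pad, N))
    buf <- matrix(0, pad[1], pad[2])
    for (i in seq_len(N)) {
      buf[] <- 0
      buf[seq_len(d[1]), seq_len(d[2])] <- ctr[, , i]
      A[, , i] <- fft2(buf)
    }
    autoPeak <- mean(vapply(seq_len(N),
                            function(i) sum(ctr[, , i]^2), 1.0))
    crossMax <- 0
    if (autoPeak > 0) {
      for (i in seq_len(N - 1L)) for (j in seq.int(i + 1L, N)) {
        r <- Re(fft2(A[, , i] * Conj(A[, , j]), inverse = TRUE)) / prod(pad)
        crossMax <- max(crossMax, max(abs(r)))
      }
      crossRatio <- crossMax / autoPeak
    } else crossRatio <- Inf

    # (ii) mean ergodicity: pixelwise ensemble means vs sampling error
    pixMean <- apply(arr, c(1, 2), mean)
    pixVar <- apply(arr, c(1, 2), var)
    num <- mean((pixMean - mean(pixMean))^2)
    den <- mean(pixVar) / N
    ergodicSE <- if (den > 0) sqrt(num / den) else Inf

    # (iii) ACF decay within the field of view
    acf <- estimateACF(arr, removeFixedPattern = TRUE, maxLag = maxLag)
    a <- acf@acf
    z <- acf@zeroLagIndex
    peak <- abs(a[z[1], z[2]])
    edge <- c(a[1, ], a[nrow(a), ], a[, 1], a[, ncol(a)])
    decay <- if (peak > 0) max(abs(edge)) / peak else Inf

    vals <- c(crossAuto = crossRatio, ergodicMeanSE = ergodicSE,
              acfDecay = decay)
    new("StationarityReport",
        crossAutoRatio = crossRatio,
        meanDiscrepancySE = ergodicSE,
        acfDecayRatio = decay,
        thresholds = thresholds,
        pass = vals < thresholds[names(vals)])
  })

setMethod("show", "StationarityReport", function(object) {
  cat("StationarityReport\n",
      sprintf("  cross/auto peak ratio: %.4g (< %g: %s)\n",
              object@crossAutoRatio, object@thresholds["crossAuto"],
              object@pass["crossAuto"]),
      sprintf("  ergodic-mean discrepancy: %.3g SE (< %g: %s)\n",
              object@meanDiscrepancySE, object@thresholds["ergodicMeanSE"],
              object@pass["ergodicMeanSE"]),
      sprintf("  ACF edge/peak ratio: %.4g (< %g: %s)\n",
              object@acfDecayRatio, object@thresholds["acfDecay"],
              object@pass["acfDecay"]), sep = "")
})

setMethod("show", "AcfEstimate", function(object) {
  z <- object@zeroLagIndex
  cat(sprintf(
    "AcfEstimate %d x %d lags (%s%s), zero-lag %.4g, N = %d\n",
    nrow(object@acf), ncol(object@acf), object@normalization,
    if (object@fixedPatternRemoved) ", fixed pattern removed" else "",
    object@acf[z[1], z[2]], object@nUsed))
})

setMethod("show", "PsdEstimate", function(object) {
  cat(sprintf(
    "PsdEstimate %d x %d bins, window %s, clipped %.3g, N = %d\n",
    nrow(object@psd), ncol(object@psd), object@window,
    object@clippedPower, object@nUsed))
})
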