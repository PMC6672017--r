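## The imaging-chain forward model: convolution of the speckle input with
## the medium's radial impulse response, then sensor effects (auto exposure,
## shot/read noise, 8-bit quantization) and an optional additive fixed
## pattern standing in for cuvette edge artefacts.

#' Rasterize a radial impulse response onto a pixel grid
#'
#' Lays h(r) out for circular convolution: linear interpolation of the
#' radial profile onto the grid, periodized by summing image shifts so that
#' a diffuse halo wider than the field of view wraps the way a periodic
#' medium response would (periodization in space samples the continuous
#' frequency response exactly at the DFT frequencies). The wrap order is
#' chosen automatically from the halo extent; if the response still carries
#' appreciable mass beyond the covered radius, rasterization fails with
#' guidance. The kernel mass is renormalized to R_d, preserving the H(0)
#' contract exactly.
#'
#' @param h a [RadialImpulseResponse-class].
#' @param dims grid dimensions (pixels).
#' @param pixelScale numeric(2), mm/px.
#' @param massTolerance largest acceptable fraction of R_d beyond the
#'   periodization radius (default 0.005).
#' @param maxWrap largest periodization order (image shifts per side).
#' @return matrix with zero displacement at [1, 1] (DFT-ready layout).
#' @export
rasterizeKernel <- function(h, dims, pixelScale, massTolerance = 0.005,
                            maxWrap = 16L) {
  stopifnot(is(h, "RadialImpulseResponse"))
  dims <- as.integer(rep(dims, length.out = 2L))
  pixelScale <- rep(pixelScale, length.out = 2L)
  centers <- (h@binEdges[-1] + h@binEdges[-length(h@binEdges)]) / 2
  extent <- dims * pixelScale
  mass <- h@h * pi * diff(h@binEdges^2)
  beyondMass <- function(radius)
    sum(mass[centers > radius]) + h@outOfRange
  # smallest wrap order whose covered radius holds all but massTolerance
  wrap <- 1L
  while (wrap < maxWrap &&
         h@Rd > 0 &&
         beyondMass(wrap * min(extent)) / h@Rd > massTolerance)
    wrap <- wrap + 1L
  if (h@Rd > 0 &&
      beyondMass(wrap * min(extent)) / h@Rd > massTolerance)
    stop(sprintf(
      paste0("impulse response carries %.2g%% of its mass beyond the ",
             "largest representable radius %.3g mm; enlarge the image or ",
             "coarsen the pixel scale"),
      100 * beyondMass(wrap * min(extent)) / h@Rd, wrap * min(extent)))
  ax <- (seq_len(dims[1]) - 1L) * pixelScale[1]
  ay <- (seq_len(dims[2]) - 1L) * pixelScale[2]
  K <- matrix(0, dims[1], dims[2])
  xg <- c(0, centers)
  yg <- c(h@h[1], h@h)
  for (m1 in seq.int(-wrap, wrap)) for (m2 in seq.int(-wrap, wrap)) {
    r <- sqrt(outer((ax - m1 * extent[1])^2, (ay - m2 * extent[2])^2, "+"))
    if (min(r) > max(h@binEdges)) next
    K <- K + approx(x = xg, y = yg, xout = r,
                    yleft = h@h[1], yright = 0)$y
  }
  # h varies on sub-pixel scales near the origin; midpoint sampling there
  # biases the kernel's spectrum by a near-constant offset. Replace the
  # central block with pixel-area averages (oversampled quadrature).
  ns <- 3L  # half-width of the corrected block, pixels
  sub <- 8L
  off <- (seq_len(sub) - (sub + 1) / 2) / sub
  for (i in seq.int(-ns, ns)) for (j in seq.int(-ns, ns)) {
    px <- (i + off) * pixelScale[1]
    py <- (j + off) * pixelScale[2]
    rr <- sqrt(outer(px^2, py^2, "+"))
    val <- mean(approx(x = xg, y = yg, xout = rr,
                       yleft = h@h[1], yright = 0)$y)
    K[(i %% dims[1]) + 1L, (j %% dims[2]) + 1L] <- val
  }
  tot <- sum(K) * prod(pixelScale)
  if (tot <= 0) stop("rasterized kernel has no mass")
  K * (h@Rd / tot)
}

#' Blur a speckle input with a medium's impulse response
#'
#' Computes the ideal diffuse backscatter v = h * u by frequency-domain
#' multiplication with the rotationally rasterized kernel. Synthesized
#' speckle fields are DFT-periodic, so circular convolution is exact for
#' them; the kernel mass equals R_d, hence mean(v) = R_d * mean(u).
#'
#' @param x a [SpeckleField-class], matrix, or [SpeckleEnsemble-class].
#' @param h a [RadialImpulseResponse-class].
#' @param pixelScale required when `x` is a bare matrix.
#' @param ... unused.
#' @return same shape as the input: a blurred field, matrix, or ensemble.
#' @export
setMethod("applyMedium", "matrix", function(x, h, pixelScale, ...) {
  K <- rasterizeKernel(h, dim(x), pixelScale)
  Re(fft2(fft2(x) * fft2(K), inverse = TRUE)) / length(x) *
    prod(rep(pixelScale, length.out = 2L))
})

#' @export
setMethod("applyMedium", "SpeckleField", function(x, h, ...) {
  x@intensity <- applyMedium(x@intensity, h, pixelScale = x@pixelScale)
  x
})

#' @export
setMethod("applyMedium", "SpeckleEnsemble", function(x, h, ...) {
  d <- dim(x@images)
  K <- rasterizeKernel(h, d[1:2], x@pixelScale)
  FK <- fft2(K)
  cell <- prod(x@pixelScale)
  for (i in seq_len(d[3])) {
    x@images[, , i] <-
      Re(fft2(fft2(x@images[, , i]) * FK, inverse = TRUE)) /
      prod(d[1:2]) * cell
  }
  x
})

#' Construct a sensor model
#'
#' @param bitDepth bits per pixel; maxCount = 2^bitDepth - 1.
#' @param readNoise Gaussian read noise, counts RMS.
#' @param shotNoise apply Poisson shot noise to the pre-read-out signal.
#' @param autoExposurePercentile,targetCount auto exposure maps this
#'   percentile of the ideal field to this count, making best use of the
#'   dynamic range with minimal clipping.
#' @return A [SensorModel-class].
#' @export
sensorModel <- function(bitDepth = 8, readNoise = 1, shotNoise = TRUE,
                        autoExposurePercentile = 99.5, targetCount = 250) {
  new("SensorModel", bitDepth = bitDepth, maxCount = 2^bitDepth - 1,
      readNoise = readNoise, shotNoise = shotNoise,
      autoExposurePercentile = autoExposurePercentile,
      targetCount = targetCount)
}

#' Synthetic cuvette edge artefact
#'
#' A bright border frame plus random scratch segments, used as the default
#' additive fixed pattern. It mimics glare from edges and scratches on a
#' glass window without claiming realism; being identical across frames, it
#' is exactly the class of artefact the pair-subtraction autocorrelation
#' estimator cancels.
#'
#' @param dims image dimensions (pixels).
#' @param amplitude peak pattern value, in the units of the field it will be
#'   added to.
#' @param frameWidth border width in pixels.
#' @param nScratches number of random line segments.
#' @param seed RNG seed.
#' @return matrix of the given dimensions.
#' @export
makeFixedPattern <- function(dims, amplitude, frameWidth = 3L,
                             nScratches = 8L, seed = 1L) {
  dims <- as.integer(rep(dims, length.out = 2L))
  withSeed(seed, {
    fp <- matrix(0, dims[1], dims[2])
    fw <- min(frameWidth, floor(min(dims) / 4))
    if (fw > 0) {
      fp[c(seq_len(fw), dims[1] - seq_len(fw) + 1L), ] <- amplitude
      fp[, c(seq_len(fw), dims[2] - seq_len(fw) + 1L)] <- amplitude
    }
    for (s in seq_len(nScratches)) {
      p0 <- runif(2) * (dims - 1) + 1
      ang <- runif(1, 0, pi)
      len <- runif(1, 0.2, 0.6) * min(dims)
      t <- seq(0, len, by = 0.5)
      ii <- round(p0[1] + t * cos(ang))
      jj <- round(p0[2] + t * sin(ang))
      ok <- ii >= 1 & ii <= dims[1] & jj >= 1 & jj <= dims[2]
      amp <- amplitude * runif(1, 0.4, 1)
      fp[cbind(ii[ok], jj[ok])] <- amp
    }
    fp
  })
}

#' Image an ideal field through the sensor model
#'
#' Auto exposure picks the exposure time that maps the configured percentile
#' of (field + fixed pattern) to the target count; Poisson shot noise (if
#' enabled) and Gaussian read noise are applied, and the result is rounded
#' and clipped to [0, maxCount].
#'
#' @param field non-negative matrix (ideal intensity) or
#'   [SpeckleField-class].
#' @param sensor a [SensorModel-class].
#' @param fixedPattern optional additive matrix in field units.
#' @param seed optional RNG seed for the noise draws.
#' @return list(counts = integer matrix, exposure = exposure time).
#' @export
imageWithSensor <- function(field, sensor, fixedPattern = NULL,
                            seed = NULL) {
  if (is(field, "SpeckleField")) field <- field@intensity
  if (any(field < 0)) stop("ideal field must be non-negative")
  ideal <- field
  if (!is.null(fixedPattern)) {
    if (!identical(dim(fixedPattern), dim(field)))
      stop("fixed pattern dimensions must match the field")
    ideal <- ideal + fixedPattern
  }
  ref <- quantile(ideal, sensor@autoExposurePercentile / 100, names = FALSE)
  if (ref <= 0) stop("cannot set exposure for an all-zero field")
  exposure <- sensor@targetCount / ref
  signal <- exposure * ideal
  counts <- withSeed(seed, {
    out <- if (sensor@shotNoise)
      matrix(rpois(length(signal), signal), nrow(signal))
    else signal
    if (sensor@readNoise > 0)
      out <- out + rnorm(length(out), 0, sensor@readNoise)
    out
  })
  counts <- pmin(pmax(round(counts), 0), sensor@maxCount)
  list(counts = matrix(as.integer(counts), nrow(signal)),
       exposure = exposure)
}

#' Image an ensemble of ideal fields
#'
#' Applies [imageWithSensor()] frame by frame with derived per-frame seeds,
#' returning raw counts plus exposure metadata.
#'
#' @param x a [SpeckleEnsemble-class] (possibly blurred by
#'   [applyMedium()]) or 3D array.
#' @param sensor a [SensorModel-class].
#' @param fixedPattern optional additive matrix, identical for all frames.
#' @param seed base seed for the per-frame noise.
#' @param medium optional [TurbidMedium-class] recorded for provenance.
#' @return A [BackscatterEnsemble-class] holding integer counts
#'   (`corrected = FALSE`).
#' @export
observeEnsemble <- function(x, sensor, fixedPattern = NULL, seed = 1L,
                            medium = NULL) {
  arr <- ensembleArray(x)
  N <- dim(arr)[3]
  counts <- array(0, dim = dim(arr))
  expo <- numeric(N)
  seeds <- vapply(seq_len(N), function(i) deriveSeed(seed, i, 7L), 1L)
  for (i in seq_len(N)) {
    fr <- imageWithSensor(arr[, , i], sensor, fixedPattern = fixedPattern,
                          seed = seeds[i])
    counts[, , i] <- fr$counts
    expo[i] <- fr$exposure
  }
  new("BackscatterEnsemble",
      images = counts,
      pixelScale = ensemblePixelScale(x),
      seeds = as.numeric(seeds),
      exposureTimes = expo,
      corrected = FALSE,
      medium = medium,
      fixedPattern = fixedPattern)
}

#' Divide frames by their exposure times
#'
#' Equalizes gain across frames that were captured with auto exposure, so
#' ensembles of bright and dim backscatter share one intensity scale.
#'
#' @param object a [BackscatterEnsemble-class] with raw counts.
#' @param ... unused.
#' @return the ensemble with real-valued exposure-normalized frames
#'   (`corrected = TRUE`).
#' @export
setMethod("correctExposure", "BackscatterEnsemble", function(object, ...) {
  if (object@corrected) return(object)
  if (!length(object@exposureTimes) || any(!is.finite(object@exposureTimes)))
    stop("exposure metadata is missing or invalid")
  for (i in seq_len(dim(object@images)[3]))
    object@images[, , i] <- object@images[, , i] / object@exposureTimes[i]
  object@corrected <- TRUE
  object
})
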