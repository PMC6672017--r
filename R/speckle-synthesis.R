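## Fourier-optics synthesis of objective speckle patterns.
##
## The scattering surface is modelled as a random phase screen: inside the
## elliptical illuminated spot the field has unit amplitude and i.i.d. phase
## uniform on [0, 2pi) (the ideal-white-noise surface limit); outside it is
## zero. The far-field intensity on the target plane is the squared modulus
## of the discrete Fourier transform of the masked screen. The screen pitch
## is solved from lambda*D/(M*delta) = target pixel scale so the transform
## lands exactly on the requested sampling grid.

# Solve the screen sampling for a geometry and grid, with feasibility checks.
screenSpec <- function(geometry, gridShape) {
  p <- geometry@targetPixelScale
  lam <- lambdaMm(geometry)
  D <- geometry@distance
  delta <- lam * D / (gridShape * p)     # mm per screen cell, per axis
  extent <- gridShape * delta            # = lam*D/p, independent of M
  semi <- effectiveApertureSemiAxes(geometry)
  if (any(2 * semi > extent)) {
    stop("aperture (", paste(signif(2 * semi, 3), collapse = " x "),
         " mm) exceeds the phase-screen physical extent (",
         paste(signif(extent, 3), collapse = " x "),
         " mm = lambda*D / pixel scale); increase the target pixel scale ",
         "or the distance D")
  }
  list(delta = delta, extent = extent, semi = semi)
}

defaultGridShape <- function(sensorShape) {
  pmax(nextPow2(ceiling(1.25 * max(sensorShape))), 64)
}

#' Synthesize one objective speckle pattern
#'
#' Simulates coherent scattering from a rough surface through a finite
#' elliptical aperture: a unit-amplitude random phase screen is masked by the
#' aperture, Fourier transformed, and squared. The result is sampled on the
#' sensor grid at the geometry's target pixel scale and normalized to unit
#' spatial mean. Deterministic given (geometry, seed).
#'
#' With a large aperture the pattern is fully developed: pointwise intensity
#' follows the 2-dof chi-squared (exponential) law with unit contrast. A
#' small aperture yields partially developed speckle with grain scale of
#' order lambda*D/d and a power spectrum bandlimited to d/(lambda*D).
#'
#' @param geometry an [OpticalGeometry-class].
#' @param seed integer RNG seed.
#' @param gridShape phase-screen grid (power of two recommended); defaults
#'   to the smallest power of two at least 1.25x the larger sensor axis.
#'   Scalar values are recycled to both axes.
#' @param roughness "uniform" for i.i.d. uniform random phases (speckle) or
#'   "none" for a flat screen (a single Airy-like diffraction lobe; used as a
#'   degenerate control).
#' @param realizationIndex stored in the result.
#' @return A [SpeckleField-class].
#' @export
synthesizeSpeckle <- function(geometry, seed,
                              gridShape = NULL,
                              roughness = c("uniform", "none"),
                              realizationIndex = 1L) {
  stopifnot(is(geometry, "OpticalGeometry"))
  validObject(geometry)
  roughness <- match.arg(roughness)
  shape <- geometry@sensorShape
  if (is.null(gridShape)) gridShape <- defaultGridShape(shape)
  if (length(gridShape) == 1L) gridShape <- rep(gridShape, 2L)
  gridShape <- as.integer(gridShape)
  if (any(gridShape < shape))
    stop("phase-screen grid (", paste(gridShape, collapse = "x"),
         ") is too small to hold the requested sensor shape (",
         paste(shape, collapse = "x"), ")")
  spec <- screenSpec(geometry, gridShape)

  # elliptical binary mask on the screen, centred
  x <- (seq_len(gridShape[1]) - (floor(gridShape[1] / 2) + 1)) * spec$delta[1]
  y <- (seq_len(gridShape[2]) - (floor(gridShape[2] / 2) + 1)) * spec$delta[2]
  mask <- outer((x / spec$semi[1])^2, (y / spec$semi[2])^2, "+") <= 1

  phase <- withSeed(seed, {
    if (roughness == "uniform")
      matrix(runif(prod(gridShape), 0, 2 * pi), gridShape[1], gridShape[2])
    else matrix(0, gridShape[1], gridShape[2])
  })
  field <- mask * exp(1i * phase)
  u <- Mod(fft2(field))^2
  u <- fftshift2(u)

  # central crop to the sensor
  r0 <- floor((gridShape[1] - shape[1]) / 2)
  c0 <- floor((gridShape[2] - shape[2]) / 2)
  u <- u[r0 + seq_len(shape[1]), c0 + seq_len(shape[2]), drop = FALSE]
  u <- u / mean(u)

  new("SpeckleField",
      intensity = u,
      pixelScale = rep(geometry@targetPixelScale, 2L),
      realizationIndex = as.integer(realizationIndex),
      seed = as.numeric(seed))
}

#' Synthesize an ensemble of independent speckle realizations
#'
#' Each realization uses a fresh independent phase screen (emulating a new
#' rough-surface patch), with per-realization seeds derived from `baseSeed`
#' by a counter scheme, so the ensemble is reproducible and extensible.
#'
#' @param geometry an [OpticalGeometry-class].
#' @param N number of realizations, >= 2.
#' @param baseSeed ensemble base seed.
#' @param ... passed to [synthesizeSpeckle()].
#' @return A [SpeckleEnsemble-class].
#' @export
synthesizeEnsemble <- function(geometry, N = 10L, baseSeed = 1L, ...) {
  N <- as.integer(N)
  if (N < 2L) stop("an ensemble needs N >= 2 realizations")
  seeds <- vapply(seq_len(N), function(i) deriveSeed(baseSeed, i), 1L)
  fields <- lapply(seq_len(N), function(i)
    synthesizeSpeckle(geometry, seed = seeds[i], realizationIndex = i, ...))
  arr <- array(0, dim = c(dim(fields[[1]]@intensity), N))
  for (i in seq_len(N)) arr[, , i] <- fields[[i]]@intensity
  new("SpeckleEnsemble",
      images = arr,
      pixelScale = fields[[1]]@pixelScale,
      seeds = as.numeric(seeds),
      geometry = geometry,
      baseSeed = as.numeric(baseSeed))
}

## Accessors and show methods -------------------------------------------

#' @describeIn SpeckleField intensity matrix
#' @param object a SpeckleField
#' @export
setMethod("intensity", "SpeckleField", function(object) object@intensity)

#' @export
setMethod("images", "ImageEnsemble", function(object) object@images)

#' @export
setMethod("pixelScale", "ImageEnsemble", function(object) object@pixelScale)

#' @export
setMethod("pixelScale", "SpeckleField", function(object) object@pixelScale)

#' @export
setMethod("nRealizations", "ImageEnsemble", function(object)
  dim(object@images)[3])

#' @export
setMethod("exposureTimes", "BackscatterEnsemble", function(object)
  object@exposureTimes)

setMethod("show", "SpeckleField", function(object) {
  d <- dim(object@intensity)
  cat(sprintf(
    "SpeckleField %d x %d px (%.4g x %.4g mm/px), mean %.4g, contrast %.3f\n",
    d[1], d[2], object@pixelScale[1], object@pixelScale[2],
    mean(object@intensity),
    sd(object@intensity) / mean(object@intensity)))
})

setMethod("show", "SpeckleEnsemble", function(object) {
  d <- dim(object@images)
  cat(sprintf(
    "SpeckleEnsemble: N = %d realizations of %d x %d px (base seed %g)\n",
    d[3], d[1], d[2], object@baseSeed))
})

setMethod("show", "BackscatterEnsemble", function(object) {
  d <- dim(object@images)
  cat(sprintf(
    "BackscatterEnsemble: N = %d frames of %d x %d px (%s)\n",
    d[3], d[1], d[2],
    if (object@corrected) "exposure-corrected" else "raw counts"))
})
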