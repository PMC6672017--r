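## S4 classes for the speckle / photon-transport toolkit.

#' Projection and imaging geometry
#'
#' Holds the optical parameters that govern speckle bandwidth and sampling:
#' the laser wavelength, the distance D between the scattering surface and the
#' target plane, the semi-diameters of the elliptical illuminated spot on the
#' scatterer, the incidence angle of the projection on the target, the image
#' sensor pixel pitch and shape, and the pixel scale in the target (sample)
#' plane. The speckle grain scale along each axis is of order lambda*D/d where
#' d is the full aperture extent along that axis; the intensity power spectrum
#' is bandlimited to d/(lambda*D) per axis.
#'
#' @slot wavelength laser wavelength in nm.
#' @slot distance scatterer-to-target distance D in mm.
#' @slot apertureSemiAxes numeric(2); semi-diameters (d_x, d_y) of the
#'   elliptical illuminated spot, in mm.
#' @slot incidenceAngle projection incidence angle on the target, degrees.
#'   Oblique incidence stretches the projected pattern along one axis by
#'   1/cos(theta); it is modelled as a cos(theta) shrink of the effective
#'   aperture along that axis.
#' @slot pixelPitch physical sensor pixel pitch in micrometres.
#' @slot sensorShape integer(2); image dimensions in pixels.
#' @slot targetPixelScale length per pixel in the target plane, mm/px. For
#'   speckle observed directly on the sensor this equals pixelPitch/1000.
#' @export
setClass("OpticalGeometry",
  representation(
    wavelength = "numeric",
    distance = "numeric",
    apertureSemiAxes = "numeric",
    incidenceAngle = "numeric",
    pixelPitch = "numeric",
    sensorShape = "integer",
    targetPixelScale = "numeric"
  )
)

setValidity("OpticalGeometry", function(object) {
  msg <- character()
  if (length(object@wavelength) != 1L || !is.finite(object@wavelength) ||
      object@wavelength <= 0)
    msg <- c(msg, "wavelength must be a single positive number (nm)")
  if (length(object@distance) != 1L || object@distance <= 0)
    msg <- c(msg, "distance must be positive (mm)")
  if (length(object@apertureSemiAxes) != 2L ||
      any(!is.finite(object@apertureSemiAxes)) ||
      any(object@apertureSemiAxes <= 0))
    msg <- c(msg, "apertureSemiAxes must be two positive lengths (mm)")
  if (object@incidenceAngle < 0 || object@incidenceAngle >= 60)
    msg <- c(msg, "incidenceAngle must lie in [0, 60) degrees")
  if (object@pixelPitch <= 0)
    msg <- c(msg, "pixelPitch must be positive (micrometres)")
  if (length(object@sensorShape) != 2L || any(object@sensorShape < 16L))
    msg <- c(msg, "sensorShape must be two pixel counts >= 16")
  if (length(object@targetPixelScale) != 1L || object@targetPixelScale <= 0)
    msg <- c(msg, "targetPixelScale must be positive (mm/px)")
  if (length(msg)) msg else TRUE
})

#' Speckle intensity field
#'
#' A single realization u(x, y) of the projected speckle intensity process,
#' normalized to unit spatial mean at synthesis time.
#'
#' @slot intensity non-negative real matrix.
#' @slot pixelScale numeric(2); mm per pixel along each image axis.
#' @slot realizationIndex integer index within its ensemble.
#' @slot seed RNG seed used for this realization.
#' @export
setClass("SpeckleField",
  representation(
    intensity = "matrix",
    pixelScale = "numeric",
    realizationIndex = "integer",
    seed = "numeric"
  )
)

setValidity("SpeckleField", function(object) {
  u <- object@intensity
  msg <- character()
  if (!is.numeric(u) || any(!is.finite(u)))
    msg <- c(msg, "intensity must be finite and numeric")
  else {
    if (any(u < 0)) msg <- c(msg, "intensity must be non-negative")
    if (!any(u > 0)) msg <- c(msg, "intensity must have a positive value")
  }
  if (length(object@pixelScale) != 2L || any(object@pixelScale <= 0))
    msg <- c(msg, "pixelScale must be two positive lengths (mm/px)")
  if (length(msg)) msg else TRUE
})

#' Ensemble of images treated as realizations of one 2D random process
#'
#' Virtual parent of [SpeckleEnsemble-class] and
#' [BackscatterEnsemble-class]. Images are stored as a 3D array with the
#' realization index last.
#'
#' @slot images numeric 3D array, dim = c(nx, ny, N).
#' @slot pixelScale numeric(2), mm/px.
#' @slot seeds per-realization RNG seeds.
#' @export
setClass("ImageEnsemble",
  representation(
    images = "array",
    pixelScale = "numeric",
    seeds = "numeric",
    "VIRTUAL"
  )
)

#' Speckle input ensemble
#'
#' N independent speckle realizations of the same stationary random process,
#' as produced by [synthesizeEnsemble()].
#'
#' @slot geometry the [OpticalGeometry-class] that generated the ensemble
#'   (may be NULL for ensembles read from disk).
#' @slot baseSeed the ensemble base seed; per-realization seeds are derived
#'   from it by a counter scheme.
#' @export
setClass("SpeckleEnsemble",
  contains = "ImageEnsemble",
  representation(geometry = "ANY", baseSeed = "numeric")
)

setValidity("SpeckleEnsemble", function(object) {
  d <- dim(object@images)
  msg <- character()
  if (length(d) != 3L) msg <- c(msg, "images must be a 3D array")
  else if (d[3] < 2L) msg <- c(msg, "an ensemble needs N >= 2 realizations")
  if (length(object@seeds) && anyDuplicated(object@seeds))
    msg <- c(msg, "realization seeds must be pairwise distinct")
  if (length(object@pixelScale) != 2L || any(object@pixelScale <= 0))
    msg <- c(msg, "pixelScale must be two positive lengths")
  if (length(msg)) msg else TRUE
})

#' Observed backscatter ensemble
#'
#' Frames imaged through the sensor model. Before exposure correction the
#' images hold integer counts in [0, maxCount]; after [correctExposure()]
#' they hold real exposure-normalized values.
#'
#' @slot exposureTimes per-frame auto-exposure times (arbitrary units).
#' @slot corrected logical; TRUE once divided by exposure time.
#' @slot medium the [TurbidMedium-class] that produced the frames, or NULL.
#' @slot fixedPattern the additive fixed pattern injected at imaging time
#'   (matrix), or NULL.
#' @export
setClass("BackscatterEnsemble",
  contains = "ImageEnsemble",
  representation(
    exposureTimes = "numeric",
    corrected = "logical",
    medium = "ANY",
    fixedPattern = "ANY"
  )
)

setValidity("BackscatterEnsemble", function(object) {
  d <- dim(object@images)
  msg <- character()
  if (length(d) != 3L) msg <- c(msg, "images must be a 3D array")
  if (length(object@exposureTimes) != d[3])
    msg <- c(msg, "one exposure time per frame is required")
  else if (any(object@exposureTimes <= 0))
    msg <- c(msg, "exposure times must be positive")
  if (length(msg)) msg else TRUE
})

#' Homogeneous turbid medium
#'
#' The (mu_a, mu_s', g) triple of the sample under test. The scattering
#' coefficient mu_s = mu_s'/(1 - g) and the photon mean free path
#' 1/(mu_a + mu_s') are derived via [muS()] and [meanFreePath()].
#'
#' @slot muA absorption coefficient, 1/mm, >= 0.
#' @slot muSPrime reduced scattering coefficient, 1/mm, > 0.
#' @slot g scattering anisotropy (mean cosine), in [0, 1).
#' @export
setClass("TurbidMedium",
  representation(muA = "numeric", muSPrime = "numeric", g = "numeric")
)

setValidity("TurbidMedium", function(object) {
  msg <- character()
  if (length(object@muA) != 1L || object@muA < 0)
    msg <- c(msg, "muA must be a single value >= 0")
  if (length(object@muSPrime) != 1L || object@muSPrime <= 0)
    msg <- c(msg, "muSPrime must be a single value > 0")
  if (length(object@g) != 1L || object@g < 0 || object@g >= 1)
    msg <- c(msg, "g must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Dimensionless White Monte Carlo exit records
#'
#' Per-escaped-photon exit radius rho and total path Lambda, both in units of
#' one scattering mean free path (1/mu_s). Because the walk is simulated with
#' unit scattering and zero absorption, one simulation at fixed anisotropy g
#' serves every (mu_a, mu_s') pair: physical radius is rho/mu_s and absorption
#' enters as the weight exp(-mu_a * Lambda / mu_s).
#'
#' @slot rho dimensionless exit radii.
#' @slot path dimensionless total path lengths.
#' @slot g anisotropy used in the walk.
#' @slot nLaunched,nTruncated photon accounting; escaped = length(rho).
#' @slot maxPath truncation threshold in scattering lengths.
#' @slot boundary "matched" or "fresnel".
#' @slot nRel relative refractive index (used when boundary == "fresnel").
#' @slot seed RNG seed of the simulation.
#' @export
setClass("PathlengthRecords",
  representation(
    rho = "numeric", path = "numeric", g = "numeric",
    nLaunched = "numeric", nTruncated = "numeric", maxPath = "numeric",
    boundary = "character", nRel = "numeric", seed = "numeric"
  )
)

setValidity("PathlengthRecords", function(object) {
  msg <- character()
  if (length(object@rho) != length(object@path))
    msg <- c(msg, "rho and path must have equal length")
  if (any(object@rho < 0)) msg <- c(msg, "rho must be >= 0")
  if (length(object@path) && any(object@path <= 0))
    msg <- c(msg, "path must be > 0")
  if (length(object@rho) + object@nTruncated > object@nLaunched)
    msg <- c(msg, "escaped + truncated cannot exceed launched")
  if (length(msg)) msg else TRUE
})

#' Radial diffuse-backscatter impulse response h(r)
#'
#' Diffuse backscattered power per unit area per unit incident power, binned
#' over radius, for a pencil beam on a semi-infinite medium.
#'
#' @slot binEdges radial bin edges in mm.
#' @slot h response values, 1/mm^2, one per bin.
#' @slot Rd total diffuse reflectance (all escaped weight / launched).
#' @slot outOfRange escaped weight falling beyond the last bin edge,
#'   normalized by photons launched.
#' @slot medium the [TurbidMedium-class] described.
#' @export
setClass("RadialImpulseResponse",
  representation(
    binEdges = "numeric", h = "numeric", Rd = "numeric",
    outOfRange = "numeric", medium = "ANY"
  )
)

setValidity("RadialImpulseResponse", function(object) {
  msg <- character()
  if (length(object@h) != length(object@binEdges) - 1L)
    msg <- c(msg, "h must have one value per bin")
  if (any(object@h < 0)) msg <- c(msg, "h must be non-negative")
  if (object@Rd < 0 || object@Rd > 1 + 1e-9)
    msg <- c(msg, "Rd must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Spatial frequency response H(k_r)
#'
#' Zeroth-order Hankel transform of the impulse response, computed directly
#' from photon records; H(0) equals the diffuse reflectance R_d by
#' construction and |H(k)| <= H(0) (low-pass character).
#'
#' @slot k radial spatial frequency grid, 1/mm.
#' @slot H response values, dimensionless.
#' @slot medium the [TurbidMedium-class] described.
#' @export
setClass("FrequencyResponse",
  representation(k = "numeric", H = "numeric", medium = "ANY")
)

setValidity("FrequencyResponse", function(object) {
  if (length(object@k) != length(object@H))
    return("k and H must have equal length")
  TRUE
})

#' Camera sensor model
#'
#' 8-bit quantizing sensor with percentile-based auto exposure, optional
#' Poisson shot noise and Gaussian read noise.
#'
#' @slot bitDepth bits per pixel (8 by default).
#' @slot maxCount full-well count, 2^bitDepth - 1.
#' @slot readNoise read noise, counts RMS.
#' @slot shotNoise logical; apply Poisson shot noise.
#' @slot autoExposurePercentile percentile of the ideal field mapped to
#'   targetCount by auto exposure.
#' @slot targetCount count value the percentile is mapped to.
#' @export
setClass("SensorModel",
  representation(
    bitDepth = "numeric", maxCount = "numeric", readNoise = "numeric",
    shotNoise = "logical", autoExposurePercentile = "numeric",
    targetCount = "numeric"
  )
)

setValidity("SensorModel", function(object) {
  msg <- character()
  if (object@targetCount > object@maxCount)
    msg <- c(msg, "targetCount must not exceed maxCount")
  if (object@readNoise < 0) msg <- c(msg, "readNoise must be >= 0")
  if (object@autoExposurePercentile <= 0 ||
      object@autoExposurePercentile > 100)
    msg <- c(msg, "autoExposurePercentile must lie in (0, 100]")
  if (length(msg)) msg else TRUE
})

#' Ensemble autocorrelation estimate
#'
#' 2D autocorrelation over spatial lags, centered on zero lag. With
#' fixed-pattern removal on, the estimate subtracts the average
#' cross-correlation of the N(N-1) distinct image pairs from the average
#' autocorrelation of the N images, cancelling (in expectation) any additive
#' deterministic component shared by all realizations, including the process
#' mean.
#'
#' @slot acf real matrix over lags; zero lag at `zeroLagIndex`.
#' @slot lagScale numeric(2), mm per lag step.
#' @slot zeroLagIndex integer(2), position of zero lag in `acf`.
#' @slot fixedPatternRemoved logical flag.
#' @slot nUsed number of realizations used.
#' @slot normalization "unbiased" (per-lag overlap counts), "biased"
#'   (1/n normalization) or "circular" (periodic images, no padding).
#' @export
setClass("AcfEstimate",
  representation(
    acf = "matrix", lagScale = "numeric", zeroLagIndex = "integer",
    fixedPatternRemoved = "logical", nUsed = "numeric",
    normalization = "character"
  )
)

setValidity("AcfEstimate", function(object) {
  z <- object@zeroLagIndex
  if (length(z) != 2L || any(z < 1L) || any(z > dim(object@acf)))
    return("zeroLagIndex out of range")
  peak <- abs(object@acf[z[1], z[2]])
  if (peak + 1e-12 < max(abs(object@acf)) * (1 - 1e-9))
    return("zero-lag value must be the maximum in magnitude")
  TRUE
})

#' Power spectral density estimate
#'
#' Non-negative 2D spectrum over spatial frequencies, obtained from an
#' [AcfEstimate-class] via the Wiener-Khinchin theorem (discrete Fourier
#' transform of the lag-windowed autocorrelation).
#'
#' @slot psd non-negative real matrix (clipped; see `clippedPower`).
#' @slot kx,ky frequency axes in 1/mm, ascending, zero included.
#' @slot window lag window used ("hann" or "none").
#' @slot nUsed realizations behind the source ACF.
#' @slot clippedPower total magnitude of negative numerical residues that
#'   were clipped to zero.
#' @export
setClass("PsdEstimate",
  representation(
    psd = "matrix", kx = "numeric", ky = "numeric", window = "character",
    nUsed = "numeric", clippedPower = "numeric"
  )
)

setValidity("PsdEstimate", function(object) {
  msg <- character()
  if (any(object@psd < 0)) msg <- c(msg, "psd must be non-negative")
  if (length(object@kx) != nrow(object@psd) ||
      length(object@ky) != ncol(object@psd))
    msg <- c(msg, "frequency axes must match psd dimensions")
  if (length(msg)) msg else TRUE
})

#' Stationarity and ergodicity diagnostics for an image ensemble
#'
#' @slot crossAutoRatio max pairwise cross-correlation peak relative to the
#'   autocorrelation peak (independence check).
#' @slot meanDiscrepancySE pixelwise ensemble-mean scatter relative to its
#'   sampling error under ergodicity, in standard-error units.
#' @slot acfDecayRatio autocorrelation magnitude at the largest available lag
#'   relative to its peak.
#' @slot thresholds named numeric(3) of pass thresholds.
#' @slot pass named logical(3) verdicts.
#' @export
setClass("StationarityReport",
  representation(
    crossAutoRatio = "numeric", meanDiscrepancySE = "numeric",
    acfDecayRatio = "numeric", thresholds = "numeric", pass = "logical"
  )
)

#' DC and AC response parameters
#'
#' The two-number summary of the medium's spatial frequency response: H_DC,
#' the low-frequency power ratio of output to input (approximately
#' |H(0)|^2), and H_AC, the DC-normalized fraction of in-band signal power
#' retained by the backscatter. Both are ratios of output to input and are
#' expected in [0, 1]; values outside that range are flagged, not clipped.
#'
#' @slot hDC,hAC the response parameters.
#' @slot band numeric(2), the [k_low, k_high] integration band in 1/mm.
#' @slot dcBins number of lowest non-DC radial bins averaged for the
#'   k_r -> 0 limit.
#' @slot nIn,nOut ensemble sizes used.
#' @slot se named numeric(2): jackknife standard errors of (hDC, hAC).
#' @slot outOfRange logical; TRUE when either parameter fell outside [0, 1].
#' @export
setClass("ResponseParameters",
  representation(
    hDC = "numeric", hAC = "numeric", band = "numeric", dcBins = "numeric",
    nIn = "numeric", nOut = "numeric", se = "numeric", outOfRange = "logical"
  )
)

setValidity("ResponseParameters", function(object) {
  msg <- character()
  if (!is.finite(object@hDC) || !is.finite(object@hAC))
    msg <- c(msg, "response parameters must be finite")
  if (object@hDC < 0 || object@hAC < 0)
    msg <- c(msg, "response parameters must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Forward lookup table (mu_a, mu_s') -> (H_DC, H_AC)
#'
#' Model response parameters evaluated on a grid of media from one set of
#' White Monte Carlo records, against a fixed input spectrum.
#'
#' @slot muAGrid,muSPrimeGrid strictly increasing grids, 1/mm.
#' @slot g anisotropy of the records used.
#' @slot hDC,hAC matrices, dim = c(length(muAGrid), length(muSPrimeGrid)).
#' @slot band numeric(2) integration band, 1/mm.
#' @slot dcBins bins used for the k_r -> 0 average.
#' @slot sUU list(k, S): the input radial PSD profile the table was built
#'   against.
#' @slot provenance list (records seed, photon count, dcMode, ...).
#' @export
setClass("ForwardLookupTable",
  representation(
    muAGrid = "numeric", muSPrimeGrid = "numeric", g = "numeric",
    hDC = "matrix", hAC = "matrix", band = "numeric", dcBins = "numeric",
    sUU = "list", provenance = "list"
  )
)

setValidity("ForwardLookupTable", function(object) {
  msg <- character()
  if (is.unsorted(object@muAGrid, strictly = TRUE) ||
      is.unsorted(object@muSPrimeGrid, strictly = TRUE))
    msg <- c(msg, "grids must be strictly increasing")
  if (any(!is.finite(object@hDC)) || any(!is.finite(object@hAC)) ||
      any(object@hDC < 0) || any(object@hAC < 0))
    msg <- c(msg, "H values must be finite and >= 0")
  dd <- c(length(object@muAGrid), length(object@muSPrimeGrid))
  if (!identical(dim(object@hDC), dd) || !identical(dim(object@hAC), dd))
    msg <- c(msg, "hDC/hAC dimensions must match the grids")
  if (length(msg)) msg else TRUE
})

#' Per-axis affine calibration of observed response parameters
#'
#' Least-squares scale and offset mapping observed H_DC and H_AC onto their
#' model values, fitted on reference samples with known optical properties.
#'
#' @slot scale,offset named numeric(2) ("dc", "ac").
#' @slot residuals list of per-axis fit residuals.
#' @slot references data.frame of the reference samples used.
#' @export
setClass("CalibrationModel",
  representation(
    scale = "numeric", offset = "numeric", residuals = "list",
    references = "data.frame"
  )
)

setValidity("CalibrationModel", function(object) {
  if (any(object@scale <= 0)) return("calibration scales must be > 0")
  TRUE
})

#' Named grid of synthetic tissue phantoms
#'
#' A letter-by-number grid of media (letter = mu_s' level, number = mu_a
#' level) plus one undiluted high-scattering 'IL' entry, emulating a liquid
#' phantom dilution series. Values are synthetic.
#'
#' @slot table data.frame with columns name, muA, muSPrime, g, seed.
#' @slot config generation parameters.
#' @export
setClass("PhantomSet",
  representation(table = "data.frame", config = "list")
)

setValidity("PhantomSet", function(object) {
  tb <- object@table
  need <- c("name", "muA", "muSPrime", "g", "seed")
  if (!all(need %in% names(tb)))
    return("table must have columns name, muA, muSPrime, g, seed")
  if (anyDuplicated(tb$name)) return("phantom names must be unique")
  TRUE
})
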