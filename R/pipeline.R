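## End-to-end closed-loop pipeline: White MC -> lookup table -> synthetic
## observations -> system identification -> calibration -> inversion.

#' Default projection geometry for sample measurements
#'
#' The projection arm used for closed-loop simulations: 635 nm illumination,
#' the smallest aperture setting (1.5 mm x 0.8 mm spot) at a projection
#' distance long enough to put the speckle band (cutoff about 1.1-1.4 1/mm)
#' inside both the imaging Nyquist limit and the frequency range where
#' tissue-like media show contrast, with 45 degree incidence to avoid
#' specular glare. The target is imaged at the 34 mm -> 673 px scale of an
#' f/4 camera viewing a cuvette face.
#'
#' @param sensorShape analysed image size in pixels (default 320 x 320, a
#'   desk-scale crop of the full face).
#' @return An [OpticalGeometry-class].
#' @export
methodGeometry <- function(sensorShape = c(320L, 320L)) {
  opticalGeometry(
    wavelength = 635, distance = 1200,
    apertureSemiAxes = c(0.75, 0.4), incidenceAngle = 45,
    pixelPitch = 4.8, sensorShape = sensorShape,
    targetPixelScale = 34 / 673)
}

#' Breadboard geometry for direct speckle observation
#'
#' Speckle observed directly on the sensor (no imaging optics): 635 nm,
#' scatterer-to-sensor distance 86 mm, 4.8 um pixels. The full sensor is
#' 1280 x 1024 px (a 6.1 x 4.9 mm window); smaller crops keep simulations
#' light.
#'
#' @param sensorShape image size in pixels.
#' @param apertureSemiAxes spot semi-axes in mm; the three canonical
#'   settings are c(1.75, 0.95), c(1.25, 0.65) and c(0.75, 0.4)
#'   (3.5 x 1.9, 2.5 x 1.3, 1.5 x 0.8 mm spots).
#' @return An [OpticalGeometry-class].
#' @export
breadboardGeometry <- function(sensorShape = c(1280L, 1024L),
                               apertureSemiAxes = c(1.75, 0.95)) {
  opticalGeometry(
    wavelength = 635, distance = 86,
    apertureSemiAxes = apertureSemiAxes, incidenceAngle = 0,
    pixelPitch = 4.8, sensorShape = sensorShape)
}

#' Run the full closed-loop recovery pipeline
#'
#' Simulates the complete experiment and analysis: a White Monte Carlo
#' record set; a reference speckle ensemble (the diffusing-screen input
#' measurement); a forward lookup table; noisy backscatter observations for
#' calibration and test phantoms (fresh input realizations per observation,
#' shared additive fixed pattern); reduction of every observation to
#' (H_DC, H_AC); per-axis affine calibration on the reference phantoms; and
#' inversion of the test phantoms back to (mu_a, mu_s').
#'
#' @param seed master seed; every stage derives its own seed from it.
#' @param preset "study" (N = 10, 3 replicates, 6 interior test media) or
#'   "demo" (smaller, for a quick smoke run). Explicit arguments override
#'   the preset.
#' @param geometry,sensor optical and sensor models.
#' @param nPhotons photons for the White MC stage.
#' @param N frames per ensemble.
#' @param replicates independent observation sets per phantom.
#' @param testPhantoms,calibrationPhantoms phantom names (see
#'   [makePhantomSet()]).
#' @param fixedPatternAmplitude edge-artefact amplitude relative to unit
#'   input mean.
#' @param noise sensor shot noise on/off.
#' @param window spectral lag window. Default "none": the pair-subtraction
#'   estimator already cancels the mean, and in circular estimation there is
#'   no leakage for a taper to suppress, while a lag window would smooth the
#'   steep low-frequency response in a way the model side does not share.
#' @param dcBins lowest non-DC radial bins averaged for the k_r -> 0 limit.
#'   Default: enough annuli for the DC band to span one third of the
#'   aperture cutoff (at least 3). A DC band tied to the illumination
#'   bandwidth rather than to the image's frequency resolution keeps the
#'   estimator variance (set by the number of pooled frequency cells) from
#'   growing as images get larger, at a negligible cost in absorption
#'   sensitivity.
#' @param outDir optional directory; results and models are written as JSON.
#' @return list with elements `records`, `sUU`, `band`, `lut`,
#'   `calibration`, `responses` (every analyzed observation), `results`
#'   (per-replicate test-phantom inversions with true values and relative
#'   errors), `resultsByPhantom` (inversion of replicate-averaged response
#'   parameters, one row per test phantom) and `summary` (median absolute
#'   relative errors of the replicate-averaged estimates).
#' @export
runPipeline <- function(seed = 1L, preset = c("study", "demo"),
                        geometry = NULL, sensor = sensorModel(),
                        nPhotons = NULL, N = NULL, replicates = NULL,
                        testPhantoms = NULL, calibrationPhantoms = NULL,
                        fixedPatternAmplitude = 0.25, noise = TRUE,
                        window = "none", dcBins = NULL, outDir = NULL) {
  preset <- match.arg(preset)
  demo <- preset == "demo"
  # study images match the pixel budget of a full 673 x 495 cuvette-face
  # image at a transform-friendly size
  if (is.null(geometry))
    geometry <- methodGeometry(if (demo) c(192L, 192L) else c(512L, 512L))
  if (is.null(nPhotons)) nPhotons <- if (demo) 3e4 else 1e5
  if (is.null(N)) N <- if (demo) 6L else 10L
  if (is.null(replicates)) replicates <- if (demo) 1L else 3L
  if (is.null(testPhantoms))
    testPhantoms <- if (demo) c("C4", "E3")
                    else c("B3", "C6", "D4", "E2", "F5", "E7")
  if (is.null(calibrationPhantoms))
    calibrationPhantoms <- if (demo) c("A1", "A8", "G1", "G8")
                           else c("A1", "A8", "G1", "G8",
                                  "D1", "D8", "B6", "F2")
  if (!noise) sensor@shotNoise <- FALSE

  dims <- geometry@sensorShape
  scale <- rep(geometry@targetPixelScale, 2L)
  binWidth <- 1.0000001 / min(dims * scale)

  records <- runWhiteMC(g = 0.7, nPhotons = nPhotons,
                        seed = deriveSeed(seed, 9L))

  # reference input measurement (diffusing screen in place of the sample)
  refInput <- synthesizeEnsemble(geometry, N = N,
                                 baseSeed = deriveSeed(seed, 0L))
  refObs <- correctExposure(observeEnsemble(
    refInput, sensor, seed = deriveSeed(seed, 0L, 2L)))
  psdUU <- estimatePSD(estimateACF(refObs, circular = TRUE),
                       window = window)
  sUU <- radialAverage(psdUU, binWidth = binWidth)
  kc <- min(apertureCutoff(geometry))
  band <- c(attr(sUU, "edges")[3], kc)
  if (is.null(dcBins))
    dcBins <- max(3L, as.integer(ceiling(kc / 3 / binWidth)))

  lut <- buildLUT(records, sUU = sUU, psdUU = psdUU, band = band,
                  dcBins = dcBins)

  phantoms <- makePhantomSet(seed = deriveSeed(seed, 1L))
  tb <- phantomTable(phantoms)
  wanted <- unique(c(calibrationPhantoms, testPhantoms))
  missing <- setdiff(wanted, tb$name)
  if (length(missing))
    stop("unknown phantom name(s): ", paste(missing, collapse = ", "))

  fp <- if (fixedPatternAmplitude > 0)
    makeFixedPattern(dims, fixedPatternAmplitude,
                     seed = deriveSeed(seed, 77L))
  else NULL

  responses <- list()
  for (name in wanted) {
    row <- tb[tb$name == name, ]
    medium <- turbidMedium(row$muA, row$muSPrime, row$g)
    h <- mediumImpulseResponse(records, medium, dims, scale)
    K <- rasterizeKernel(h, dims, scale)
    FK <- fft2(K)
    cell <- prod(scale)
    for (r in seq_len(replicates)) {
      input <- synthesizeEnsemble(geometry, N = N,
                                  baseSeed = deriveSeed(row$seed, r, 1L))
      ideal <- input
      for (i in seq_len(N))
        ideal@images[, , i] <-
          Re(fft2(fft2(input@images[, , i]) * FK, inverse = TRUE)) /
          prod(dims) * cell
      obs <- correctExposure(observeEnsemble(
        ideal, sensor, fixedPattern = fp,
        seed = deriveSeed(row$seed, r, 2L), medium = medium))
      # jackknife errors are consumed downstream only for test phantoms
      rp <- analyzeExperiment(refObs, obs, band = band, dcBins = dcBins,
                              circular = TRUE, window = window,
                              binWidth = binWidth,
                              jackknife = if (name %in% testPhantoms)
                                "output" else "none")
      responses[[length(responses) + 1L]] <- data.frame(
        name = name, replicate = r, muA = row$muA,
        muSPrime = row$muSPrime, hDC = rp@hDC, hAC = rp@hAC,
        seHDC = rp@se["dc"], seHAC = rp@se["ac"],
        stringsAsFactors = FALSE)
    }
  }
  responses <- do.call(rbind, responses)
  rownames(responses) <- NULL

  # calibration on replicate-averaged reference observations
  calRows <- responses[responses$name %in% calibrationPhantoms, ]
  calAgg <- do.call(rbind, lapply(split(calRows, calRows$name), function(d)
    data.frame(muA = d$muA[1], muSPrime = d$muSPrime[1],
               hDC = mean(d$hDC), hAC = mean(d$hAC))))
  calibration <- fitCalibration(calAgg, lut)

  testRows <- responses[responses$name %in% testPhantoms, ]
  inv <- invertResponse(
    data.frame(hDC = testRows$hDC, hAC = testRows$hAC,
               seHDC = testRows$seHDC, seHAC = testRows$seHAC),
    lut, calibration)
  results <- cbind(testRows[, c("name", "replicate")],
                   trueMuA = testRows$muA,
                   trueMuSPrime = testRows$muSPrime,
                   inv)
  results$relErrMuA <- abs(results$muA - results$trueMuA) / results$trueMuA
  results$relErrMuSPrime <-
    abs(results$muSPrime - results$trueMuSPrime) / results$trueMuSPrime
  rownames(results) <- NULL

  # one estimate per phantom from the replicate-averaged response pair
  # (the replicates are repeated observations of one sample)
  testAgg <- do.call(rbind, lapply(split(testRows, testRows$name),
    function(d) data.frame(
      name = d$name[1], trueMuA = d$muA[1], trueMuSPrime = d$muSPrime[1],
      hDC = mean(d$hDC), hAC = mean(d$hAC),
      seHDC = mean(d$seHDC) / sqrt(nrow(d)),
      seHAC = mean(d$seHAC) / sqrt(nrow(d)))))
  invAgg <- invertResponse(testAgg, lut, calibration)
  resultsByPhantom <- cbind(testAgg[, c("name", "trueMuA", "trueMuSPrime")],
                            invAgg[, c("muA", "muSPrime", "seMuA",
                                       "seMuSPrime", "outOfRange")])
  resultsByPhantom$relErrMuA <-
    abs(resultsByPhantom$muA - resultsByPhantom$trueMuA) /
    resultsByPhantom$trueMuA
  resultsByPhantom$relErrMuSPrime <-
    abs(resultsByPhantom$muSPrime - resultsByPhantom$trueMuSPrime) /
    resultsByPhantom$trueMuSPrime
  rownames(resultsByPhantom) <- NULL

  summary <- c(medianRelErrMuA = median(resultsByPhantom$relErrMuA),
               medianRelErrMuSPrime =
                 median(resultsByPhantom$relErrMuSPrime))

  out <- list(records = records, sUU = sUU, band = band, lut = lut,
              calibration = calibration, responses = responses,
              results = results, resultsByPhantom = resultsByPhantom,
              summary = summary)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeModelJSON(lut, file.path(outDir, "lut.json"))
    writeModelJSON(calibration, file.path(outDir, "calibration.json"))
    jsonlite::write_json(results, file.path(outDir, "results.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  out
}
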