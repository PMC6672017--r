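## Synthetic stand-in for a liquid tissue-phantom dilution series: a
## letter-by-number grid of media (letter = mu_s' level from the emulsion
## concentration, number = mu_a level from the dye concentration) plus an
## undiluted high-scattering 'IL' entry. Values are synthetic; downstream
## code only consumes the (mu_a, mu_s', g) triples.

#' Create a named synthetic phantom set
#'
#' @param nMuspLevels letters (mu_s' levels), default 7 (A..G).
#' @param nMuaLevels numbers (mu_a levels), default 8 (1..8), giving the
#'   56 + IL = 57 entries of a full dilution series.
#' @param muaRange,muspRange log-spaced grid ranges, 1/mm. Defaults span
#'   skin-like media: mu_a in [0.003, 0.4], mu_s' in [0.5, 4].
#' @param g shared anisotropy.
#' @param seed base seed; per-phantom seeds are derived from it.
#' @param includeIL add the undiluted entry (mu_s' above the lettered grid,
#'   minimal mu_a).
#' @return A [PhantomSet-class].
#' @examples
#' ps <- makePhantomSet()
#' nrow(phantomTable(ps))  # 57
#' @export
makePhantomSet <- function(nMuspLevels = 7L, nMuaLevels = 8L,
                           muaRange = c(0.003, 0.4),
                           muspRange = c(0.5, 4), g = 0.7, seed = 1L,
                           includeIL = TRUE) {
  if (nMuspLevels < 1L || nMuaLevels < 1L)
    stop("grid must have at least one level per axis")
  if (nMuspLevels > 26L) stop("at most 26 mu_s' levels (letters)")
  musp <- if (nMuspLevels == 1L) muspRange[1]
          else exp(seq(log(muspRange[1]), log(muspRange[2]),
                       length.out = nMuspLevels))
  mua <- if (nMuaLevels == 1L) muaRange[1]
         else exp(seq(log(muaRange[1]), log(muaRange[2]),
                      length.out = nMuaLevels))
  grid <- expand.grid(number = seq_len(nMuaLevels),
                      letter = seq_len(nMuspLevels))
  tb <- data.frame(
    name = paste0(LETTERS[grid$letter], grid$number),
    muA = mua[grid$number],
    muSPrime = musp[grid$letter],
    g = g,
    stringsAsFactors = FALSE)
  if (includeIL) {
    tb <- rbind(tb, data.frame(
      name = "IL", muA = muaRange[1],
      muSPrime = 1.3 * max(muspRange), g = g))
  }
  rownames(tb) <- NULL
  tb$seed <- vapply(seq_len(nrow(tb)),
                    function(i) deriveSeed(seed, 1000L + i), 1L)
  new("PhantomSet", table = tb,
      config = list(nMuspLevels = nMuspLevels, nMuaLevels = nMuaLevels,
                    muaRange = muaRange, muspRange = muspRange, g = g,
                    seed = seed, includeIL = includeIL))
}

#' @describeIn makePhantomSet the phantom table
#' @param object a PhantomSet
#' @export
setMethod("phantomTable", "PhantomSet", function(object) object@table)

setMethod("show", "PhantomSet", function(object) {
  tb <- object@table
  cat(sprintf(
    "PhantomSet: %d media (%d x %d grid%s), g = %g\n",
    nrow(tb), object@config$nMuspLevels, object@config$nMuaLevels,
    if (object@config$includeIL) " + IL" else "", object@config$g))
})

phantomMedium <- function(phantomSet, name) {
  tb <- phantomTable(phantomSet)
  row <- tb[tb$name == name, ]
  if (!nrow(row)) stop("unknown phantom '", name, "'")
  turbidMedium(row$muA, row$muSPrime, row$g)
}

# impulse response sized for a given image: fine radial bins out to the
# radius enclosing all but a sliver of the escaped weight
mediumImpulseResponse <- function(records, medium, dims, pixelScale) {
  sr <- scaledRecords(records, medium)
  ord <- order(sr$r)
  cw <- cumsum(sr$w[ord])
  rNeed <- sr$r[ord][findInterval(0.9995 * cw[length(cw)], cw) + 1L]
  rNeed <- max(rNeed * 1.05, min(dims * rep(pixelScale, length.out = 2L)))
  step <- min(pixelScale) / 2
  impulseResponse(records, medium,
                  binEdges = seq(0, rNeed + step, by = step))
}

#' Simulate a complete backscatter observation
#'
#' The full forward model for one medium: blur the speckle input ensemble
#' with the medium's impulse response, add the fixed pattern, image through
#' the sensor, and (optionally) exposure-correct.
#'
#' @param input a [SpeckleEnsemble-class].
#' @param medium a [TurbidMedium-class].
#' @param records [PathlengthRecords-class] at the medium's g.
#' @param sensor a [SensorModel-class].
#' @param fixedPattern optional additive matrix (input-intensity units).
#' @param seed noise seed.
#' @param correct exposure-correct the result (default TRUE).
#' @return A [BackscatterEnsemble-class].
#' @export
simulateBackscatter <- function(input, medium, records, sensor,
                                fixedPattern = NULL, seed = 1L,
                                correct = TRUE) {
  d <- dim(input@images)[1:2]
  h <- mediumImpulseResponse(records, medium, d, input@pixelScale)
  ideal <- applyMedium(input, h)
  obs <- observeEnsemble(ideal, sensor, fixedPattern = fixedPattern,
                         seed = seed, medium = medium)
  if (correct) correctExposure(obs) else obs
}

#' Generate an on-disk synthetic experiment bundle
#'
#' Writes a reference input ensemble (the diffusing-screen stand-in: the
#' speckle ensemble imaged directly by the sensor) and, for every phantom
#' and replicate, a backscatter ensemble through the full forward model.
#' Every ensemble gets fresh input realizations of the same speckle process,
#' with seeds derived from `baseSeed`; a manifest records files, seeds and
#' true parameters, so every artefact is reproducible.
#'
#' @param phantomSet a [PhantomSet-class].
#' @param geometry an [OpticalGeometry-class].
#' @param sensor a [SensorModel-class].
#' @param records [PathlengthRecords-class].
#' @param outDir output directory (created if needed).
#' @param N frames per ensemble.
#' @param replicates independent observation sets per phantom.
#' @param baseSeed master seed.
#' @param fixedPatternAmplitude edge-artefact amplitude relative to the unit
#'   input mean (0 disables the pattern).
#' @param noise logical; sensor shot noise (read noise stays as configured
#'   in `sensor`).
#' @return (invisibly) the manifest list; written as manifest.json.
#' @export
makeExperimentBundle <- function(phantomSet, geometry, sensor, records,
                                 outDir, N = 10L, replicates = 1L,
                                 baseSeed = 1L,
                                 fixedPatternAmplitude = 0.25,
                                 noise = TRUE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory ", outDir)
  if (!noise) sensor@shotNoise <- FALSE
  tb <- phantomTable(phantomSet)
  fp <- if (fixedPatternAmplitude > 0)
    makeFixedPattern(geometry@sensorShape, fixedPatternAmplitude,
                     seed = deriveSeed(baseSeed, 77L))
  else NULL

  refDir <- file.path(outDir, "reference")
  refSeed <- deriveSeed(baseSeed, 0L)
  refInput <- synthesizeEnsemble(geometry, N = N, baseSeed = refSeed)
  refObs <- observeEnsemble(refInput, sensor,
                            seed = deriveSeed(baseSeed, 0L, 2L))
  writeImageEnsemble(refObs, refDir)

  phantomEntries <- vector("list", nrow(tb))
  for (p in seq_len(nrow(tb))) {
    medium <- turbidMedium(tb$muA[p], tb$muSPrime[p], tb$g[p])
    reps <- vector("list", replicates)
    for (r in seq_len(replicates)) {
      sIn <- deriveSeed(tb$seed[p], r, 1L)
      sNoise <- deriveSeed(tb$seed[p], r, 2L)
      input <- synthesizeEnsemble(geometry, N = N, baseSeed = sIn)
      obs <- simulateBackscatter(input, medium, records, sensor,
                                 fixedPattern = fp, seed = sNoise,
                                 correct = FALSE)
      dirP <- file.path(outDir, tb$name[p], sprintf("rep%02d", r))
      writeImageEnsemble(obs, dirP)
      reps[[r]] <- list(dir = file.path(tb$name[p], sprintf("rep%02d", r)),
                        inputSeed = sIn, noiseSeed = sNoise)
    }
    phantomEntries[[p]] <- list(
      name = tb$name[p], muA = tb$muA[p], muSPrime = tb$muSPrime[p],
      g = tb$g[p], seed = tb$seed[p], replicates = reps)
  }
  manifest <- list(
    synthetic = TRUE,
    note = paste("fully synthetic phantom bundle; optical properties are",
                 "generated stand-ins, not measured reference values"),
    baseSeed = baseSeed, N = N, replicates = replicates,
    noise = noise, fixedPatternAmplitude = fixedPatternAmplitude,
    geometry = geometryToList(geometry),
    sensor = list(bitDepth = sensor@bitDepth, readNoise = sensor@readNoise,
                  shotNoise = sensor@shotNoise,
                  autoExposurePercentile = sensor@autoExposurePercentile,
                  targetCount = sensor@targetCount),
    records = list(g = records@g, nPhotons = records@nLaunched,
                   seed = records@seed, maxPath = records@maxPath,
                   boundary = records@boundary),
    reference = list(dir = "reference", inputSeed = refSeed),
    phantoms = phantomEntries)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

geometryToList <- function(geometry) {
  list(wavelength = geometry@wavelength, distance = geometry@distance,
       apertureSemiAxes = geometry@apertureSemiAxes,
       incidenceAngle = geometry@incidenceAngle,
       pixelPitch = geometry@pixelPitch,
       sensorShape = geometry@sensorShape,
       targetPixelScale = geometry@targetPixelScale)
}

geometryFromList <- function(x) {
  opticalGeometry(wavelength = x$wavelength, distance = x$distance,
                  apertureSemiAxes = unlist(x$apertureSemiAxes),
                  incidenceAngle = x$incidenceAngle,
                  pixelPitch = x$pixelPitch,
                  sensorShape = unlist(x$sensorShape),
                  targetPixelScale = x$targetPixelScale)
}
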