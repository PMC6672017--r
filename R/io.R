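## Image + JSON-sidecar I/O. Every frame is written as a grayscale TIFF next
## to a JSON sidecar carrying the metadata that image headers would lose
## (exposure time, seed, pixel scale, normalization), plus one meta.json per
## ensemble. Sidecars, not header tags, make the round trip bit-auditable
## across image libraries.

ensembleMetaName <- "meta.json"

#' Write an image ensemble as TIFF frames with JSON sidecars
#'
#' Raw-count ensembles (8- or 16-bit) round-trip exactly; real-valued
#' ensembles are scaled by a recorded normalization factor and quantized to
#' 16 bits.
#'
#' @param x a [BackscatterEnsemble-class] or [SpeckleEnsemble-class].
#' @param dir output directory (created if needed).
#' @param bitDepth 8 or 16; default 8 for integer count ensembles, 16
#'   otherwise.
#' @return (invisibly) the directory.
#' @export
writeImageEnsemble <- function(x, dir, bitDepth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  arr <- x@images
  N <- dim(arr)[3]
  isCounts <- is(x, "BackscatterEnsemble") && !x@corrected
  if (is.null(bitDepth)) bitDepth <- if (isCounts) 8L else 16L
  maxRaw <- 2^bitDepth - 1
  norm <- if (isCounts) 1 else max(arr) / maxRaw
  if (norm <= 0) norm <- 1
  expo <- if (is(x, "BackscatterEnsemble")) x@exposureTimes
          else rep(1, N)
  seeds <- if (length(x@seeds) == N) x@seeds else rep(NA_real_, N)
  for (i in seq_len(N)) {
    stem <- sprintf("img_%03d", i)
    img <- arr[, , i] / norm
    tiff::writeTIFF(pmin(pmax(img, 0), maxRaw) / maxRaw,
                    file.path(dir, paste0(stem, ".tiff")),
                    bits.per.sample = bitDepth)
    jsonlite::write_json(
      list(index = i, seed = seeds[i], exposure = expo[i],
           pixelScale = x@pixelScale, bitDepth = bitDepth,
           normalization = norm),
      file.path(dir, paste0(stem, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  meta <- list(class = class(x)[1], N = N, pixelScale = x@pixelScale,
               bitDepth = bitDepth, normalization = norm,
               corrected = if (is(x, "BackscatterEnsemble")) x@corrected
                           else NA)
  if (is(x, "SpeckleEnsemble")) {
    meta$baseSeed <- x@baseSeed
    if (is(x@geometry, "OpticalGeometry"))
      meta$geometry <- geometryToList(x@geometry)
  }
  if (is(x, "BackscatterEnsemble") && is(x@medium, "TurbidMedium"))
    meta$medium <- list(muA = x@medium@muA, muSPrime = x@medium@muSPrime,
                        g = x@medium@g)
  jsonlite::write_json(meta, file.path(dir, ensembleMetaName),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an image ensemble written by [writeImageEnsemble()]
#'
#' Frames are ordered by their sidecar indices; exposure times, pixel scale
#' and seeds are reattached. A frame without a sidecar, a corrupt image, or
#' mixed shapes/bit depths abort with the offending file named.
#'
#' @param dir the ensemble directory.
#' @return a [BackscatterEnsemble-class] (raw counts or corrected values,
#'   per the stored metadata) or [SpeckleEnsemble-class].
#' @export
readImageEnsemble <- function(dir) {
  if (!dir.exists(dir)) stop("no such ensemble directory: ", dir)
  metaPath <- file.path(dir, ensembleMetaName)
  if (!file.exists(metaPath))
    stop("missing ensemble metadata (", ensembleMetaName, ") in ", dir)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "\\.tiff?$", full.names = TRUE))
  if (!length(files)) stop("no TIFF images found in ", dir)
  frames <- vector("list", length(files))
  info <- vector("list", length(files))
  for (i in seq_along(files)) {
    sidecar <- sub("\\.tiff?$", ".json", files[i])
    if (!file.exists(sidecar))
      stop("missing sidecar for image ", basename(files[i]))
    info[[i]] <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    img <- tryCatch(tiff::readTIFF(files[i]),
                    error = function(e)
                      stop("corrupt image file ", basename(files[i]),
                           ": ", conditionMessage(e), call. = FALSE))
    if (is.array(img) && length(dim(img)) == 3L) img <- img[, , 1]
    frames[[i]] <- img
  }
  depths <- vapply(info, function(x) as.numeric(x$bitDepth), 1.0)
  if (length(unique(depths)) != 1L)
    stop("mixed bit depths in ", dir, " (",
         paste(unique(depths), collapse = ", "),
         "); ensembles must be homogeneous")
  shapes <- vapply(frames, function(f) paste(dim(f), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop("mixed image shapes in ", dir, ": ",
         paste(unique(shapes), collapse = " vs "))
  ord <- order(vapply(info, function(x) as.numeric(x$index), 1.0))
  frames <- frames[ord]; info <- info[ord]
  maxRaw <- 2^depths[1] - 1
  norm <- as.numeric(info[[1]]$normalization)
  arr <- array(0, dim = c(dim(frames[[1]]), length(frames)))
  for (i in seq_along(frames))
    arr[, , i] <- round(frames[[i]] * maxRaw) * norm
  pixelScale <- as.numeric(unlist(info[[1]]$pixelScale))
  seeds <- vapply(info, function(x) as.numeric(x$seed)[1], 1.0)
  expo <- vapply(info, function(x) as.numeric(x$exposure), 1.0)
  if (identical(meta$class, "SpeckleEnsemble")) {
    geom <- if (!is.null(meta$geometry)) geometryFromList(meta$geometry)
            else NULL
    new("SpeckleEnsemble", images = arr, pixelScale = pixelScale,
        seeds = seeds, geometry = geom,
        baseSeed = as.numeric(meta$baseSeed %||% NA_real_))
  } else {
    medium <- if (!is.null(meta$medium))
      turbidMedium(meta$medium$muA, meta$medium$muSPrime, meta$medium$g)
    else NULL
    corrected <- isTRUE(meta$corrected)
    new("BackscatterEnsemble", images = arr, pixelScale = pixelScale,
        seeds = seeds, exposureTimes = expo, corrected = corrected,
        medium = medium, fixedPattern = NULL)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a lookup table or calibration model as JSON
#' @param x a [ForwardLookupTable-class] or [CalibrationModel-class].
#' @param path output file.
#' @export
writeModelJSON <- function(x, path) {
  obj <- if (is(x, "ForwardLookupTable")) {
    list(type = "ForwardLookupTable", muAGrid = x@muAGrid,
         muSPrimeGrid = x@muSPrimeGrid, g = x@g,
         hDC = as.numeric(x@hDC), hAC = as.numeric(x@hAC),
         band = x@band, dcBins = x@dcBins, sUU = x@sUU,
         provenance = x@provenance)
  } else if (is(x, "CalibrationModel")) {
    list(type = "CalibrationModel", scale = as.list(x@scale),
         offset = as.list(x@offset))
  } else stop("unsupported object for JSON export")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
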