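#' Create a projection/imaging geometry
#'
#' @param wavelength laser wavelength, nm.
#' @param distance scatterer-to-target distance D, mm.
#' @param apertureSemiAxes semi-diameters (d_x, d_y) of the elliptical
#'   illuminated spot, mm; a scalar is recycled to a circular spot.
#' @param incidenceAngle projection incidence angle theta on the target,
#'   degrees (default 0). Only its geometric stretch of the projected pattern
#'   is modelled.
#' @param pixelPitch sensor pixel pitch, micrometres.
#' @param sensorShape image dimensions in pixels, length 2.
#' @param targetPixelScale mm per pixel in the target plane. Defaults to
#'   `pixelPitch/1000`, i.e. speckle observed directly on the sensor.
#'
#' @return An [OpticalGeometry-class] object.
#' @examples
#' g <- opticalGeometry(wavelength = 635, distance = 86,
#'                      apertureSemiAxes = c(0.75, 0.75),
#'                      pixelPitch = 4.8, sensorShape = c(256, 256))
#' grainScale(g) * 1e3  # expected grain scale, micrometres
#' @export
opticalGeometry <- function(wavelength, distance, apertureSemiAxes,
                            incidenceAngle = 0, pixelPitch,
                            sensorShape, targetPixelScale = NULL) {
  if (length(apertureSemiAxes) == 1L)
    apertureSemiAxes <- rep(apertureSemiAxes, 2L)
  if (is.null(targetPixelScale)) targetPixelScale <- pixelPitch / 1000
  new("OpticalGeometry",
      wavelength = as.numeric(wavelength),
      distance = as.numeric(distance),
      apertureSemiAxes = as.numeric(apertureSemiAxes),
      incidenceAngle = as.numeric(incidenceAngle),
      pixelPitch = as.numeric(pixelPitch),
      sensorShape = as.integer(sensorShape),
      targetPixelScale = as.numeric(targetPixelScale))
}

# wavelength in mm
lambdaMm <- function(geometry) geometry@wavelength * 1e-6

# cos(theta) shrink of the aperture x-axis models the oblique projection
effectiveApertureSemiAxes <- function(geometry) {
  a <- geometry@apertureSemiAxes
  c(a[1] * cos(geometry@incidenceAngle * pi / 180), a[2])
}

#' Nyquist frequency of the target-plane sampling
#'
#' `1 / (2 * targetPixelScale)`, the highest spatial frequency observable
#' without aliasing, in 1/mm.
#' @param object an [OpticalGeometry-class].
#' @param ... unused.
#' @export
setMethod("nyquistFrequency", "OpticalGeometry", function(object, ...) {
  1 / (2 * object@targetPixelScale)
})

#' Aperture-determined PSD cutoff, per axis
#'
#' The intensity power spectrum of the projected speckle is supported inside
#' an ellipse with per-axis cutoff d_eff/(lambda * D), where d_eff is the
#' full effective aperture extent along that axis. Returned in 1/mm as
#' c(kx, ky).
#' @param object an [OpticalGeometry-class].
#' @param ... unused.
#' @export
setMethod("apertureCutoff", "OpticalGeometry", function(object, ...) {
  2 * effectiveApertureSemiAxes(object) / (lambdaMm(object) * object@distance)
})

#' Physical sensor extent in mm, per axis
#' @param object an [OpticalGeometry-class].
#' @param ... unused.
#' @export
setMethod("sensorExtent", "OpticalGeometry", function(object, ...) {
  as.numeric(object@sensorShape) * object@pixelPitch * 1e-3
})

#' Expected speckle grain scale, per axis
#'
#' Of order lambda*D/d_eff (mm), larger along the axis of the smaller
#' aperture extent.
#' @param object an [OpticalGeometry-class].
#' @param ... unused.
#' @export
setMethod("grainScale", "OpticalGeometry", function(object, ...) {
  lambdaMm(object) * object@distance /
    (2 * effectiveApertureSemiAxes(object))
})

#' Convert a target-plane length to pixels
#'
#' @param geometry an [OpticalGeometry-class].
#' @param lengthMm length in the target plane, mm.
#' @return length in pixels at the geometry's target pixel scale.
#' @export
targetPixels <- function(geometry, lengthMm) {
  lengthMm / geometry@targetPixelScale
}

setMethod("show", "OpticalGeometry", function(object) {
  a <- object@apertureSemiAxes
  cat("OpticalGeometry\n",
      sprintf("  wavelength: %g nm, D: %g mm, theta: %g deg\n",
              object@wavelength, object@distance, object@incidenceAngle),
      sprintf("  aperture semi-axes: %g x %g mm\n", a[1], a[2]),
      sprintf("  sensor: %d x %d px @ %g um; target scale %g mm/px\n",
              object@sensorShape[1], object@sensorShape[2],
              object@pixelPitch, object@targetPixelScale),
      sprintf("  Nyquist: %.3g 1/mm; PSD cutoff: %.3g x %.3g 1/mm\n",
              nyquistFrequency(object), apertureCutoff(object)[1],
              apertureCutoff(object)[2]), sep = "")
})
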