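# Shared fixtures, memoized so expensive simulations run once per session.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache)) {
    assign(key, force(expr), envir = .fixtureCache)
  }
  get(key, envir = .fixtureCache)
}

# White MC records at the default anisotropy (shared across test files)
wmcRecords <- function(g = 0.7, nPhotons = 5e4, seed = 101) {
  cached(sprintf("wmc_%g_%g_%d", g, nPhotons, seed),
         runWhiteMC(g = g, nPhotons = nPhotons, seed = seed))
}

# small direct-observation geometry (speckle straight on the sensor)
smallBreadboard <- function(sensorShape = c(128L, 128L),
                            apertureSemiAxes = c(0.75, 0.75)) {
  opticalGeometry(wavelength = 635, distance = 86,
                  apertureSemiAxes = apertureSemiAxes,
                  incidenceAngle = 0, pixelPitch = 4.8,
                  sensorShape = sensorShape)
}

# small sample-measurement geometry (closed-loop pipeline conditions)
smallMethod <- function(sensorShape = c(128L, 128L)) {
  methodGeometry(sensorShape)
}

# ACF full width at half maximum along one axis, in lag units
acfFWHM <- function(acf, axis = 1L) {
  z <- acf@zeroLagIndex
  prof <- if (axis == 1L) acf@acf[, z[2]] else acf@acf[z[1], ]
  z0 <- z[axis]
  prof <- prof / prof[z0]
  half <- function(side) {
    i <- z0
    repeat {
      j <- i + side
      if (j < 1L || j > length(prof)) return(abs(i - z0))
      if (prof[j] < 0.5) {
        frac <- (prof[i] - 0.5) / (prof[i] - prof[j])
        return(abs(i - z0) + frac)
      }
      i <- j
    }
  }
  half(1L) + half(-1L)
}

# radial second moment of a PSD profile
psdSecondMoment <- function(profile) {
  sum(profile$k^2 * profile$S) / sum(profile$S)
}

# analytic input-PSD radial profile (triangular aperture-autocorrelation
# shape), used where a deterministic stand-in spectrum is enough
syntheticInputProfile <- function(kc = 1.05, binWidth = 0.06,
                                  kMax = 2) {
  edges <- seq(0, kMax, by = binWidth)
  k <- (edges[-1] + edges[-length(edges)]) / 2
  S <- pmax(1 - k / kc, 0) + 1e-6
  out <- data.frame(k = k, S = S, n = rep(8L, length(k)))
  attr(out, "edges") <- edges
  attr(out, "binWidth") <- binWidth
  out
}
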