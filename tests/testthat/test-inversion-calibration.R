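# a deterministic aperture-shaped input profile and matching band
lutFixture <- function(dcMode = "band") {
  rec <- wmcRecords()
  sUU <- syntheticInputProfile()
  band <- c(attr(sUU, "edges")[3], 1.05)
  lut <- cached(paste0("lut_", dcMode),
                buildLUT(rec, sUU = sUU, band = band, dcMode = dcMode))
  list(rec = rec, sUU = sUU, band = band, lut = lut)
}

test_that("the idealized DC mode recovers R_d^2 = 1 at zero absorption", {
  fx <- lutFixture()
  lut0 <- buildLUT(fx$rec, muAGrid = c(1e-9, 1e-6), muSPrimeGrid = 1,
                   sUU = fx$sUU, band = fx$band, dcMode = "dc0")
  expect_equal(lut0@hDC[1, 1], 1, tolerance = 0.02)
})

test_that("the lookup table reproduces the expected physical trends", {
  lut <- lutFixture()$lut
  # H_DC strictly decreasing in mu_a at every mu_s' (validity enforces it
  # too; assert directly on the grid)
  expect_true(all(apply(lut@hDC, 2, function(col) all(diff(col) < 0))))
  # H_AC strictly increasing in mu_a (absorption trims long, blurred paths)
  expect_true(all(apply(lut@hAC, 2, function(col) all(diff(col) > 0))))
  # H_AC increasing in mu_s' at fixed mu_a (higher cutoff frequency)
  expect_true(all(apply(lut@hAC, 1, function(row) all(diff(row) > 0))))
  # H_DC increasing in mu_s' at fixed mu_a (more backscatter)
  expect_true(all(apply(lut@hDC, 1, function(row) all(diff(row) > 0))))
  # absorption sensitivity of H_DC is larger at low mu_s'
  relChange <- function(col) (col[1] - col[length(col)]) / col[1]
  expect_gt(relChange(lut@hDC[, 1]), relChange(lut@hDC[, 8]))
})

test_that("LUT nodes are self-consistent under photon-count refinement", {
  fx <- lutFixture()
  recBig <- runWhiteMC(g = 0.7, nPhotons = 2e5, seed = 301)
  sub <- list(muA = c(0.01, 0.1), musp = c(0.8, 2.5))
  small <- buildLUT(fx$rec, muAGrid = sub$muA, muSPrimeGrid = sub$musp,
                    sUU = fx$sUU, band = fx$band)
  big <- buildLUT(recBig, muAGrid = sub$muA, muSPrimeGrid = sub$musp,
                  sUU = fx$sUU, band = fx$band)
  # Monte Carlo consistency between independent runs at different sizes
  expect_equal(small@hDC, big@hDC, tolerance = 0.02)
  expect_equal(small@hAC, big@hAC, tolerance = 0.02)
})

test_that("grid injectivity: distinct media stay distinct responses", {
  lut <- lutFixture()$lut
  expect_gt(lutMinSeparation(lut), 1e-3)
})

test_that("affine calibration is identifiable", {
  lut <- lutFixture()$lut
  refs <- data.frame(muA = c(0.004, 0.02, 0.1, 0.35),
                     muSPrime = c(0.6, 1.2, 2.2, 3.6))
  model <- t(vapply(seq_len(4), function(i)
    speckleTransport:::lutInterpolate(lut, refs$muA[i], refs$muSPrime[i]),
    c(hDC = 0, hAC = 0)))
  # observed = model exactly -> identity
  refs1 <- cbind(refs, hDC = model[, 1], hAC = model[, 2])
  cal1 <- fitCalibration(refs1, lut)
  expect_equal(unname(cal1@scale), c(1, 1), tolerance = 1e-9)
  expect_equal(unname(cal1@offset), c(0, 0), tolerance = 1e-9)

  # observed distorted by a known affine map -> exactly recovered
  refs2 <- cbind(refs, hDC = (model[, 1] - 0.05) / 0.8,
                 hAC = (model[, 2] - 0.02) / 1.1)
  cal2 <- fitCalibration(refs2, lut)
  expect_equal(unname(cal2@scale), c(0.8, 1.1), tolerance = 1e-6)
  expect_equal(unname(cal2@offset), c(0.05, 0.02), tolerance = 1e-6)

  # 5% multiplicative noise, 8 references -> scale within 10%
  set.seed(31)
  refs3 <- data.frame(muA = exp(runif(8, log(0.004), log(0.35))),
                      muSPrime = exp(runif(8, log(0.6), log(3.6))))
  m3 <- t(vapply(seq_len(8), function(i)
    speckleTransport:::lutInterpolate(lut, refs3$muA[i],
                                      refs3$muSPrime[i]),
    c(hDC = 0, hAC = 0)))
  refs3 <- cbind(refs3,
                 hDC = (m3[, 1] / 0.9) * exp(rnorm(8, 0, 0.05)),
                 hAC = (m3[, 2] / 1.05) * exp(rnorm(8, 0, 0.05)))
  cal3 <- fitCalibration(refs3, lut)
  expect_equal(unname(cal3@scale[1]), 0.9, tolerance = 0.1)
  expect_equal(unname(cal3@scale[2]), 1.05, tolerance = 0.15)

  # degenerate references
  refs4 <- refs1[c(1, 1), ]
  expect_error(fitCalibration(refs4, lut), "degenerate|spread")
})

test_that("inversion is exact at nodes and controlled between them", {
  lut <- lutFixture()$lut
  # every interior node round-trips exactly under identity calibration
  for (i in 2:(length(lut@muAGrid) - 1)) {
    for (j in 2:(length(lut@muSPrimeGrid) - 1)) {
      est <- invertResponse(data.frame(hDC = lut@hDC[i, j],
                                       hAC = lut@hAC[i, j]), lut)
      expect_equal(est$muA, lut@muAGrid[i], tolerance = 1e-9)
      expect_equal(est$muSPrime, lut@muSPrimeGrid[j], tolerance = 1e-9)
      expect_false(est$outOfRange)
    }
  }
  # a point between nodes: compare against a dense forward evaluation
  fx <- lutFixture()
  target <- c(muA = 0.02, muSPrime = 1.5)
  node <- buildLUT(fx$rec, muAGrid = target[1], muSPrimeGrid = target[2],
                   sUU = fx$sUU, band = fx$band)
  est <- invertResponse(data.frame(hDC = node@hDC[1, 1],
                                   hAC = node@hAC[1, 1]), lut)
  expect_equal(est$muA, unname(target[1]), tolerance = 0.1)
  expect_equal(est$muSPrime, unname(target[2]), tolerance = 0.05)

  # far outside the mapped region: flagged and clamped to the boundary
  out <- invertResponse(data.frame(hDC = 0.95, hAC = 0.95), lut)
  expect_true(out$outOfRange)
  expect_true(is.finite(out$muA) && is.finite(out$muSPrime))
})

test_that("uncertainties propagate through the local Jacobian", {
  lut <- lutFixture()$lut
  q <- data.frame(hDC = lut@hDC[3, 4] * 1.01, hAC = lut@hAC[3, 4] * 0.99,
                  seHDC = 0.02 * lut@hDC[3, 4],
                  seHAC = 0.02 * lut@hAC[3, 4])
  est <- invertResponse(q, lut)
  expect_true(est$seMuA > 0 && est$seMuSPrime > 0)
  # doubling the response errors doubles the propagated errors
  q2 <- q; q2$seHDC <- 2 * q$seHDC; q2$seHAC <- 2 * q$seHAC
  est2 <- invertResponse(q2, lut)
  expect_equal(est2$seMuA / est$seMuA, 2, tolerance = 1e-6)
})
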