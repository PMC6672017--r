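test_that("identity and pure-attenuation systems give the expected ratios", {
  g <- smallBreadboard(c(96L, 96L))
  ens <- synthesizeEnsemble(g, N = 6, baseSeed = 41)
  rp <- analyzeExperiment(ens, ens, band = c(2, 60), jackknife = "none")
  expect_equal(rp@hDC, 1, tolerance = 1e-9)
  expect_equal(rp@hAC, 1, tolerance = 1e-9)

  half <- ens
  half@images <- ens@images * 0.5
  expect_warning(
    rp2 <- analyzeExperiment(ens, half, band = c(2, 60),
                             jackknife = "none"),
    NA)
  expect_equal(rp2@hDC, 0.25, tolerance = 1e-9)
  expect_equal(rp2@hAC, 1, tolerance = 1e-9)
})

test_that("an ideal brick-wall low-pass gives the analytic AC response", {
  # flat input spectrum, |H|^2 = 1 below half-band and 0 above: H_AC is
  # the fraction of annulus-weighted power below the cutoff
  bw <- 0.05
  edges <- seq(0, 2, by = bw)
  k <- (edges[-1] + edges[-length(edges)]) / 2
  sUU <- data.frame(k = k, S = rep(2.5, length(k)), n = rep(10, length(k)))
  attr(sUU, "edges") <- edges; attr(sUU, "binWidth") <- bw
  kcut <- 1
  sVV <- sUU
  sVV$S <- sUU$S * as.numeric(k <= kcut)
  band <- c(0, 2)
  hdc <- estimateHDC(sUU, sVV)
  expect_equal(hdc, 1)
  hac <- estimateHAC(sUU, sVV, band)
  analytic <- sum(2 * pi * k[k <= kcut] * bw) / sum(2 * pi * k * bw)
  expect_equal(hac, analytic, tolerance = 1e-12)
})

test_that("profile mismatches and empty bands are rejected", {
  p1 <- syntheticInputProfile()
  p2 <- syntheticInputProfile(binWidth = 0.05)
  expect_error(estimateHDC(p1, p2), "share one frequency grid")
  dead <- p1; dead$S[1:3] <- 0  # no power in the DC band
  expect_error(estimateHDC(dead, p1), "ill-conditioned")
  expect_error(estimateHAC(p1, p1, band = c(1.9, 1.95)),
               "fewer than 2")
})

test_that("noiseless closed loop matches the model functionals", {
  g <- smallMethod(c(160L, 160L))
  ens <- synthesizeEnsemble(g, N = 10, baseSeed = 43)
  rec <- wmcRecords()
  dims <- dim(ens@images)[1:2]; scale <- ens@pixelScale
  bw <- 1.0000001 / min(dims * scale)
  psdU <- estimatePSD(estimateACF(ens, circular = TRUE), window = "none")
  sUU <- radialAverage(psdU, binWidth = bw)
  band <- c(attr(sUU, "edges")[3], min(apertureCutoff(g)))
  for (mm in list(c(0.03, 1), c(0.1, 2))) {
    m <- turbidMedium(mm[1], mm[2], 0.7)
    h <- speckleTransport:::mediumImpulseResponse(rec, m, dims, scale)
    v <- applyMedium(ens, h)
    rp <- analyzeExperiment(ens, v, band = band, circular = TRUE,
                            window = "none", binWidth = bw,
                            jackknife = "none")
    model <- buildLUT(rec, muAGrid = mm[1], muSPrimeGrid = mm[2],
                      sUU = sUU, psdUU = psdU, band = band)
    expect_equal(rp@hDC, model@hDC[1, 1], tolerance = 0.05)
    expect_equal(rp@hAC, model@hAC[1, 1], tolerance = 0.05)
  }
})

test_that("jackknife errors are calibrated and shrink as 1/sqrt(N)", {
  # white-noise process: the jackknife both tracks the true sampling
  # error and scales with ensemble size
  set.seed(52)
  d <- 48L
  ref <- array(rnorm(d * d * 20, mean = 5), dim = c(d, d, 20))
  sUU <- ensembleRadialPSD(ref, circular = TRUE, window = "none")
  band <- c(attr(sUU, "edges")[3], 0.4)
  run <- function(n, reps) {
    jk <- hdc <- numeric(reps)
    for (r in seq_len(reps)) {
      arr <- array(rnorm(d * d * n, mean = 5), dim = c(d, d, n))
      rp <- suppressWarnings(
        analyzeExperiment(ref, arr, band = band, circular = TRUE,
                          window = "none", jackknife = "output"))
      jk[r] <- rp@se["dc"]; hdc[r] <- rp@hDC
    }
    c(jk = mean(jk), emp = sd(hdc))
  }
  r5 <- run(5L, 15L); r10 <- run(10L, 15L); r20 <- run(20L, 15L)
  # calibration: jackknife mean within a factor ~1.5 of the true sd
  expect_gt(r5["jk"] / r5["emp"], 0.6); expect_lt(r5["jk"] / r5["emp"], 1.7)
  expect_gt(r20["jk"] / r20["emp"], 0.6); expect_lt(r20["jk"] / r20["emp"], 1.7)
  # scaling: monotone decrease, overall ratio near 2
  expect_true(r5["jk"] > r10["jk"] && r10["jk"] > r20["jk"])
  ratio <- unname(r5["jk"] / r20["jk"])
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 3)
})

test_that("estimates above the illumination bandlimit are distorted", {
  g <- smallMethod(c(128L, 128L))
  ens <- synthesizeEnsemble(g, N = 8, baseSeed = 46)
  rec <- wmcRecords()
  m <- turbidMedium(0.05, 1, 0.7)
  dims <- c(128L, 128L); scale <- ens@pixelScale
  h <- speckleTransport:::mediumImpulseResponse(rec, m, dims, scale)
  v0 <- applyMedium(ens, h)
  # mild sensor noise so out-of-band bins hold noise, not zeros
  sens <- sensorModel()
  v <- correctExposure(observeEnsemble(v0, sens, seed = 47))
  ref <- correctExposure(observeEnsemble(ens, sens, seed = 48))
  bw <- 1.0000001 / min(dims * scale)
  kc <- min(apertureCutoff(g))
  inBand <- analyzeExperiment(ref, v, band = c(3 * bw, kc),
                              circular = TRUE, window = "none",
                              binWidth = bw, jackknife = "output")
  beyond <- analyzeExperiment(ref, v, band = c(3 * bw, 6 * kc),
                              circular = TRUE, window = "none",
                              binWidth = bw, jackknife = "none")
  expect_gt(abs(beyond@hAC - inBand@hAC),
            max(inBand@se["ac"], 1e-6))
})

test_that("out-of-range response parameters warn but are preserved", {
  p <- syntheticInputProfile()
  boosted <- p; boosted$S <- p$S * 4
  g <- smallBreadboard(c(64L, 64L))
  ens <- synthesizeEnsemble(g, N = 4, baseSeed = 49)
  up <- ens; up@images <- ens@images * 2
  expect_warning(
    rp <- analyzeExperiment(ens, up, band = c(2, 60), jackknife = "none"),
    "outside")
  expect_equal(rp@hDC, 4, tolerance = 1e-9)
  expect_true(rp@outOfRange)
})
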