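# helper: radial impulse response with all mass in a delta-like first bin
deltaResponse <- function(mass, pixel = 0.05) {
  edges <- c(0, pixel / 4, pixel / 2)
  new("RadialImpulseResponse", binEdges = edges,
      h = c(mass / (pi * (pixel / 4)^2), 0), Rd = mass,
      outOfRange = 0, medium = NULL)
}

test_that("a delta kernel reproduces (or attenuates) the input exactly", {
  g <- smallBreadboard(c(64L, 64L))
  f <- synthesizeSpeckle(g, seed = 2)
  v1 <- applyMedium(f, deltaResponse(1, min(f@pixelScale)))
  expect_equal(v1@intensity, f@intensity, tolerance = 1e-10)
  v2 <- applyMedium(f, deltaResponse(0.5, min(f@pixelScale)))
  expect_equal(v2@intensity, 0.5 * f@intensity, tolerance = 1e-10)
})

test_that("frequency-domain convolution matches direct summation", {
  set.seed(21)
  n <- 32L
  u <- matrix(runif(n * n), n)
  px <- 0.05
  sig <- 0.08
  edges <- seq(0, 0.5, by = 0.01)
  ctr <- (edges[-1] + edges[-length(edges)]) / 2
  hv <- exp(-ctr^2 / (2 * sig^2))
  h <- new("RadialImpulseResponse", binEdges = edges, h = hv,
           Rd = sum(hv * pi * diff(edges^2)), outOfRange = 0,
           medium = NULL)
  K <- rasterizeKernel(h, c(n, n), c(px, px))
  vFFT <- applyMedium(u, h, pixelScale = c(px, px))
  # direct circular convolution
  vDir <- matrix(0, n, n)
  for (a in 0:(n - 1)) for (b in 0:(n - 1)) {
    if (K[a + 1, b + 1] == 0) next
    sh <- u[((seq_len(n) - 1 - a) %% n) + 1, ((seq_len(n) - 1 - b) %% n) + 1]
    vDir <- vDir + K[a + 1, b + 1] * sh
  }
  vDir <- vDir * px^2
  expect_lt(max(abs(vFFT - vDir)), 1e-8)
  # kernel mass = R_d makes the mean ratio exact
  expect_equal(mean(vFFT) / mean(u), h@Rd, tolerance = 1e-10)
})

test_that("blurring an ensemble preserves mean power through R_d", {
  g <- smallMethod(c(64L, 64L))
  ens <- synthesizeEnsemble(g, N = 3, baseSeed = 23)
  rec <- wmcRecords()
  m <- turbidMedium(0.03, 2, 0.7)
  h <- speckleTransport:::mediumImpulseResponse(rec, m, c(64, 64),
                                                ens@pixelScale)
  v <- applyMedium(ens, h)
  expect_equal(mean(images(v)) / mean(images(ens)), h@Rd,
               tolerance = 1e-6)
})

test_that("auto exposure maps the percentile to the target count", {
  sens <- sensorModel(shotNoise = FALSE, readNoise = 0)
  fieldA <- matrix(3, 40, 40)
  fieldB <- matrix(30, 40, 40)
  frA <- imageWithSensor(fieldA, sens)
  frB <- imageWithSensor(fieldB, sens)
  expect_true(all(frA$counts == 250L))
  # exposure invariance: a 10x brighter field gives the same frame
  expect_identical(frA$counts, frB$counts)
  expect_equal(frA$exposure / frB$exposure, 10)
  expect_error(imageWithSensor(matrix(0, 8, 8), sens), "all-zero")
  expect_error(imageWithSensor(matrix(-1, 8, 8), sens), "non-negative")
})

test_that("shot noise has Poisson variance", {
  sens <- sensorModel(shotNoise = TRUE, readNoise = 0,
                      autoExposurePercentile = 100, targetCount = 100)
  field <- matrix(1, 320, 320)  # 1e5 pixels at 100 counts
  fr <- imageWithSensor(field, sens, seed = 24)
  expect_equal(var(as.numeric(fr$counts)), 100, tolerance = 0.05 * 100)
  expect_equal(mean(fr$counts), 100, tolerance = 1)
})

test_that("exposure correction equalizes gain", {
  g <- smallBreadboard(c(48L, 48L))
  ens <- synthesizeEnsemble(g, N = 2, baseSeed = 25)
  sens <- sensorModel(shotNoise = FALSE, readNoise = 0)
  # counts [F, 2F] recorded at exposures [t, 2t] describe one scene:
  # identical frames after correction
  f <- round(100 * ens@images[, , 1])
  obs <- new("BackscatterEnsemble",
             images = array(c(f, 2 * f), dim = c(48, 48, 2)),
             pixelScale = ens@pixelScale, seeds = c(1, 2),
             exposureTimes = c(3, 6), corrected = FALSE,
             medium = NULL, fixedPattern = NULL)
  cor <- correctExposure(obs)
  expect_equal(cor@images[, , 1], cor@images[, , 2], tolerance = 1e-12)
  # auto-exposure halves the exposure time for a twice-brighter field
  arr <- array(c(ens@images[, , 1], 2 * ens@images[, , 1]),
               dim = c(48, 48, 2))
  obs2 <- observeEnsemble(arr, sens)
  expect_equal(obs2@exposureTimes[1] / obs2@exposureTimes[2], 2,
               tolerance = 1e-9)

  # noise-free round trip: away from the clipped highlights, the
  # corrected frame tracks the ideal field to within the quantization
  # step divided by the exposure time
  one <- imageWithSensor(ens@images[, , 1], sens)
  corrected <- one$counts / one$exposure
  keep <- one$counts < 255L
  expect_gt(mean(keep), 0.99)
  expect_lt(max(abs((corrected - ens@images[, , 1])[keep])),
            0.5 / one$exposure + 1e-12)

  bad <- obs
  bad@corrected <- FALSE
  bad@exposureTimes <- c(NA_real_, 1)
  expect_error(correctExposure(bad), "exposure metadata")
})

test_that("kernels too wide for the grid are rejected with guidance", {
  # a response whose mass sits far beyond what a tiny grid can periodize
  edges <- seq(0, 400, length.out = 2001)
  ctr <- (edges[-1] + edges[-length(edges)]) / 2
  hv <- exp(-ctr / 150) / ctr
  hv <- hv * 0.8 / sum(hv * pi * diff(edges^2))  # total mass 0.8
  h <- new("RadialImpulseResponse", binEdges = edges, h = hv,
           Rd = 0.8, outOfRange = 0, medium = NULL)
  expect_error(rasterizeKernel(h, c(32, 32), c(0.05, 0.05), maxWrap = 2L),
               "beyond the largest representable radius")
})

test_that("the fixed pattern is deterministic and bounded", {
  fp1 <- makeFixedPattern(c(64, 64), 2, seed = 5)
  fp2 <- makeFixedPattern(c(64, 64), 2, seed = 5)
  expect_identical(fp1, fp2)
  expect_true(all(fp1 >= 0 & fp1 <= 2))
  expect_gt(sum(fp1 > 0), 0)
})
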