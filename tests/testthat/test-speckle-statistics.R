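test_that("white-noise autocovariance: unit peak, vanishing off-lags", {
  set.seed(4)
  arr <- array(rnorm(48 * 48 * 30), dim = c(48, 48, 30))
  a <- estimateACF(arr, maxLag = 8)
  z <- a@zeroLagIndex
  expect_equal(a@acf[z[1], z[2]], 1, tolerance = 0.05)
  off <- a@acf
  off[z[1], z[2]] <- 0
  expect_lt(max(abs(off)), 0.05)
})

test_that("pair subtraction cancels an additive deterministic component", {
  set.seed(5)
  d <- 32L; N <- 20L
  ramp <- outer(seq_len(d), seq_len(d), function(i, j) 0.1 * i + 0.05 * j)
  clean <- array(rnorm(d * d * N), dim = c(d, d, N))
  dirty <- sweep(clean, c(1, 2), ramp, "+")
  aClean <- estimateACF(clean, maxLag = 6)
  aDirty <- estimateACF(dirty, maxLag = 6)
  aNaive <- estimateACF(dirty, removeFixedPattern = FALSE, maxLag = 6)
  # the pair-subtraction estimate is algebraically unchanged by the ramp
  expect_equal(aDirty@acf, aClean@acf, tolerance = 1e-10)
  # the naive average autocorrelation is visibly contaminated
  expect_gt(max(abs(aNaive@acf - aClean@acf)), 1)
})

test_that("two identical images give an exactly zero estimate", {
  img <- matrix(runif(32 * 32, 1, 2), 32)
  arr <- array(c(img, img), dim = c(32, 32, 2))
  a <- estimateACF(arr, maxLag = 8)
  expect_lt(max(abs(a@acf)), 1e-12)
})

test_that("the pair-subtraction estimator is unbiased for the random part", {
  # known process: white noise circularly smoothed by a 3x3 kernel, plus a
  # fixed pattern; the truth is the kernel's autocorrelation
  set.seed(6)
  d <- 24L; N <- 6L; reps <- 200L; L <- 4L
  kern <- matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1), 3) / 8
  # place kernel with its centre at [1,1] via circular shift
  Kc <- matrix(0, d, d)
  for (i in 1:3) for (j in 1:3)
    Kc[((i - 2) %% d) + 1, ((j - 2) %% d) + 1] <- kern[i, j]
  FK <- fft(Kc)
  trueAcv <- Re(fft(Mod(FK)^2, inverse = TRUE)) / (d * d)
  # centre the true autocovariance on a (2L+1)^2 window
  idx <- function(l) ((l %% d) + 1)
  truth <- outer(-L:L, -L:L, Vectorize(function(a, b) trueAcv[idx(a), idx(b)]))
  fixed <- matrix(5 * sin(seq_len(d) / 3), d, d)
  est <- array(0, dim = c(2 * L + 1, 2 * L + 1, reps))
  for (r in seq_len(reps)) {
    arr <- array(0, dim = c(d, d, N))
    for (i in seq_len(N)) {
      w <- matrix(rnorm(d * d), d)
      arr[, , i] <- Re(fft(fft(w) * FK, inverse = TRUE)) / (d * d) + fixed
    }
    est[, , r] <- estimateACF(arr, maxLag = L)@acf
  }
  m <- apply(est, c(1, 2), mean)
  s <- apply(est, c(1, 2), sd) / sqrt(reps)
  # unbiased overlap normalization on a circularly stationary process:
  # the mean estimate matches the truth within 3 SE at every lag
  expect_true(all(abs(m - truth) < 3 * s + 1e-6))
})

test_that("the ACF and periodogram routes agree to numerical precision", {
  set.seed(7)
  d <- 16L; N <- 5L
  arr <- array(rnorm(d * d * N, mean = 3), dim = c(d, d, N))
  nfft <- 32L
  a <- estimateACF(arr, maxLag = d - 1L, normalization = "biased")
  p1 <- estimatePSD(a, window = "none", nfft = nfft)
  # cross-periodogram construction on the same grid
  pad <- function(m) { b <- matrix(0, nfft, nfft); b[1:d, 1:d] <- m; b }
  Fs <- lapply(seq_len(N), function(i) fft(pad(arr[, , i])))
  sumP <- Reduce(`+`, lapply(Fs, function(f) Mod(f)^2))
  sumA <- Reduce(`+`, Fs)
  C <- sumP / N - (Mod(sumA)^2 - sumP) / (N * (N - 1))
  p2 <- speckleTransport:::fftshift2(Re(C)) / (d * d)
  expect_lt(max(abs(p1@psd - pmax(p2, 0))) / max(p1@psd), 1e-8)
})

test_that("spectra of elementary autocorrelations are as expected", {
  # discrete delta at zero lag -> flat spectrum
  a <- new("AcfEstimate", acf = {
    m <- matrix(0, 9, 9); m[5, 5] <- 2; m
  }, lagScale = c(1, 1), zeroLagIndex = c(5L, 5L),
  fixedPatternRemoved = FALSE, nUsed = 1, normalization = "unbiased")
  p <- estimatePSD(a, window = "none", nfft = 16)
  expect_lt(diff(range(p@psd)), 1e-10 * max(p@psd))

  # cosine of a single frequency -> two conjugate bins
  lags <- -8:8
  acfm <- outer(cos(2 * pi * lags * 4 / 17), rep(1, 17))
  a2 <- new("AcfEstimate", acf = acfm, lagScale = c(1, 1),
            zeroLagIndex = c(9L, 9L), fixedPatternRemoved = FALSE,
            nUsed = 1, normalization = "unbiased")
  p2 <- estimatePSD(a2, window = "none", nfft = 17)
  v <- sort(p2@psd, decreasing = TRUE)
  expect_gt(sum(v[1:2]), 0.99 * sum(v))
})

test_that("Parseval holds: the spectrum integrates to the zero-lag value", {
  set.seed(8)
  arr <- array(runif(32 * 32 * 4, 1, 2), dim = c(32, 32, 4))
  a <- estimateACF(arr, maxLag = 10)
  for (w in c("none", "hann")) {
    p <- estimatePSD(a, window = w)
    z <- a@zeroLagIndex
    # clipping raises the integral by the clipped magnitude; before
    # clipping the spectrum integrates exactly to the zero-lag value
    total <- sum(p@psd) * (p@kx[2] - p@kx[1]) * (p@ky[2] - p@ky[1]) -
      p@clippedPower
    expect_equal(total, a@acf[z[1], z[2]], tolerance = 1e-9)
  }
})

test_that("radial averaging closes the 2D integral and matches profiles", {
  # isotropic Gaussian spectrum on a fine grid
  n <- 128L
  k <- speckleTransport:::fftFreq(n, 1)
  kr <- sqrt(outer(k^2, k^2, "+"))
  sig <- 0.12
  psd <- new("PsdEstimate", psd = exp(-kr^2 / (2 * sig^2)), kx = k, ky = k,
             window = "none", nUsed = 1, clippedPower = 0)
  prof <- radialAverage(psd, nBins = 32)
  bw <- attr(prof, "binWidth")
  closure <- sum(prof$S * 2 * pi * prof$k * bw)
  expect_equal(closure, attr(prof, "total2D"), tolerance = 0.02)
  # profile matches the 1D cross-section of the isotropic shape
  expect_equal(prof$S, exp(-prof$k^2 / (2 * sig^2)), tolerance = 0.02)

  # spectrum confined to DC -> zero profile
  dc <- matrix(0, n, n)
  dc[which(k == 0), which(k == 0)] <- 7
  psd0 <- new("PsdEstimate", psd = dc, kx = k, ky = k, window = "none",
              nUsed = 1, clippedPower = 0)
  prof0 <- radialAverage(psd0, nBins = 16)
  expect_true(all(prof0$S == 0))

  # elliptical spectrum: radial profile lies between the axial sections
  ell <- exp(-outer((k / 0.3)^2, (k / 0.12)^2, "+"))
  psdE <- new("PsdEstimate", psd = ell, kx = k, ky = k, window = "none",
              nUsed = 1, clippedPower = 0)
  profE <- radialAverage(psdE, nBins = 24)
  lo <- pmin(exp(-(profE$k / 0.3)^2), exp(-(profE$k / 0.12)^2))
  hi <- pmax(exp(-(profE$k / 0.3)^2), exp(-(profE$k / 0.12)^2))
  expect_true(all(profE$S >= lo - 0.02 & profE$S <= hi + 0.02))
})

test_that("stationarity diagnostics separate healthy and broken ensembles", {
  g <- smallBreadboard(c(128L, 128L), apertureSemiAxes = c(1.5, 1.5))
  ens <- synthesizeEnsemble(g, N = 10, baseSeed = 31)
  rep1 <- stationarityReport(ens)
  expect_true(all(rep1@pass))

  # N copies of one image: cross/auto ratio ~ 1
  img <- images(ens)[, , 1]
  copies <- array(rep(img, 5), dim = c(dim(img), 5))
  rep2 <- stationarityReport(copies)
  expect_false(rep2@pass["crossAuto"])
  expect_gt(rep2@crossAutoRatio, 0.9)

  # a strong shared gradient breaks mean ergodicity
  ramp <- outer(seq_len(128) / 16, rep(1, 128))
  graded <- sweep(images(ens), c(1, 2), ramp, "+")
  rep3 <- stationarityReport(graded)
  expect_false(rep3@pass["ergodicMeanSE"])
})

test_that("input validation: shapes, N, finiteness", {
  expect_error(estimateACF(list(matrix(0, 4, 4), matrix(0, 5, 5))),
               "share one shape")
  expect_error(estimateACF(array(1, dim = c(8, 8, 1))), "N = 2")
  expect_error(radialAverage(new("PsdEstimate",
                                 psd = matrix(1, 8, 8),
                                 kx = speckleTransport:::fftFreq(8, 1),
                                 ky = speckleTransport:::fftFreq(8, 1),
                                 window = "none", nUsed = 1,
                                 clippedPower = 0), nBins = 2),
               "4 radial bins")
})
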