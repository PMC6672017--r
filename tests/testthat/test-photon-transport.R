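test_that("medium derivations and parameter validation", {
  m <- turbidMedium(0.03, 1, 0.7)
  expect_equal(muS(m), 1 / 0.3)
  expect_equal(meanFreePath(m), 1 / 1.03)
  expect_error(turbidMedium(0.1, -1), "muSPrime")
  expect_error(turbidMedium(-0.1, 1), "muA")
  expect_error(runWhiteMC(g = 1.2, nPhotons = 10), "g must")
  expect_error(runWhiteMC(boundary = "fresnel", nRel = 0.8,
                          nPhotons = 10), "nRel")
})

test_that("the walk is reproducible and conserves energy", {
  r1 <- runWhiteMC(g = 0.7, nPhotons = 2000, seed = 12)
  r2 <- runWhiteMC(g = 0.7, nPhotons = 2000, seed = 12)
  expect_identical(r1@rho, r2@rho)
  expect_identical(r1@path, r2@path)

  # non-absorbing semi-infinite medium returns essentially everything
  r0 <- runWhiteMC(g = 0, nPhotons = 2e4, seed = 13)
  expect_gte(length(r0@rho) / r0@nLaunched, 0.99)
  m0 <- turbidMedium(0, 1, 0)
  expect_equal(impulseResponse(r0, m0)@Rd, 1, tolerance = 0.01)
})

test_that("Henyey-Greenstein sampling reproduces the anisotropy", {
  cs <- sampleHGCosines(1e6, 0.7, seed = 14)
  expect_equal(mean(cs), 0.7, tolerance = 0.002)
  cs0 <- sampleHGCosines(2e5, 0, seed = 15)
  expect_equal(mean(cs0), 0, tolerance = 0.005)
  expect_true(all(abs(cs) <= 1))
})

test_that("absorption weighting: monotone R_d, diffusion-level accuracy", {
  rec <- wmcRecords()
  rd <- vapply(c(0.001, 0.01, 0.1, 0.5), function(mua)
    impulseResponse(rec, turbidMedium(mua, 1, 0.7))@Rd, 1.0)
  expect_true(all(diff(rd) < 0))

  # diffusion-approximation total reflectance for a matched boundary
  mua <- 0.01; musp <- 1
  mutr <- mua + musp
  x <- sqrt(3 * mua * mutr) / mutr
  rdDiff <- 1.5 * (musp / mutr) / ((x + 1) * (x + 1.5))
  expect_equal(impulseResponse(rec, turbidMedium(mua, musp, 0.7))@Rd,
               rdDiff, tolerance = 0.15)
})

test_that("frequency response: H(0) = R_d, low-pass, mu_s' ordering", {
  rec <- wmcRecords()
  grid <- expand.grid(mua = c(0.003, 0.03, 0.3),
                      musp = c(0.5, 1, 2, 4))
  for (i in seq_len(nrow(grid))) {
    m <- turbidMedium(grid$mua[i], grid$musp[i], 0.7)
    fr <- frequencyResponse(rec, m, k = seq(0, 2, by = 0.1))
    expect_equal(fr@H[1], impulseResponse(rec, m)@Rd, tolerance = 1e-12)
    expect_true(all(abs(fr@H) <= fr@H[1] + 1e-12))
  }
  # lower mu_s' lets photons diffuse farther: narrower frequency response
  normH <- function(musp) {
    fr <- frequencyResponse(rec, turbidMedium(0.03, musp, 0.7),
                            k = c(0, 0.5))
    fr@H[2] / fr@H[1]
  }
  expect_lt(normH(0.5), normH(2))
})

test_that("mu_a matters most where mu_s' is low", {
  rec <- wmcRecords()
  rel <- function(musp) {
    a <- impulseResponse(rec, turbidMedium(0.003, musp, 0.7))@Rd
    b <- impulseResponse(rec, turbidMedium(0.3, musp, 0.7))@Rd
    (a - b) / a
  }
  expect_gt(rel(0.5), rel(4))
})

test_that("White MC similarity: one record set serves scaled media", {
  rec <- wmcRecords()
  m1 <- turbidMedium(0.03, 1, 0.7)
  m2 <- turbidMedium(0.06, 2, 0.7)  # same mu_a/mu_s' ratio
  expect_equal(impulseResponse(rec, m1)@Rd, impulseResponse(rec, m2)@Rd,
               tolerance = 1e-12)
  k <- c(0.2, 0.5, 1)
  H1 <- frequencyResponse(rec, m1, k = k)@H
  H2 <- frequencyResponse(rec, m2, k = 2 * k)@H  # H2(2k) = H1(k)
  expect_equal(H2, H1, tolerance = 1e-10)
})

test_that("binned and record-level transforms agree in-band", {
  rec <- wmcRecords()
  m <- turbidMedium(0.03, 1, 0.7)
  k <- seq(0.1, 2, by = 0.1)
  direct <- frequencyResponse(rec, m, k = k)@H
  h <- impulseResponse(rec, m)
  ctr <- (h@binEdges[-1] + h@binEdges[-length(h@binEdges)]) / 2
  mass <- h@h * pi * diff(h@binEdges^2)
  binned <- vapply(k, function(q)
    sum(mass * besselJ(2 * pi * q * ctr, 0)) + h@outOfRange * 0, 1.0)
  expect_equal(binned, direct, tolerance = 0.02)
})

test_that("R_d is insensitive to g at matched mu_s'", {
  r5 <- runWhiteMC(g = 0.5, nPhotons = 3e4, seed = 16)
  r9 <- runWhiteMC(g = 0.9, nPhotons = 3e4, seed = 17)
  rd5 <- impulseResponse(r5, turbidMedium(0.03, 1, 0.5))@Rd
  rd9 <- impulseResponse(r9, turbidMedium(0.03, 1, 0.9))@Rd
  expect_lt(abs(rd5 - rd9) / rd5, 0.05)
})

test_that("a refractive-index mismatch traps light", {
  rMatch <- wmcRecords()
  rFres <- cached("wmc_fresnel", runWhiteMC(g = 0.7, nPhotons = 3e4,
                                            boundary = "fresnel",
                                            nRel = 1.4, seed = 18))
  m <- turbidMedium(0.03, 1, 0.7)
  expect_lt(impulseResponse(rFres, m)@Rd, impulseResponse(rMatch, m)@Rd)
})

test_that("empty records are rejected", {
  rec <- wmcRecords()
  empty <- new("PathlengthRecords", rho = numeric(), path = numeric(),
               g = 0.7, nLaunched = 10, nTruncated = 10, maxPath = 1,
               boundary = "matched", nRel = 1, seed = 1)
  expect_error(impulseResponse(empty, turbidMedium(0.1, 1, 0.7)),
               "no escaped")
  expect_error(frequencyResponse(empty, turbidMedium(0.1, 1, 0.7)),
               "no escaped")
})
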