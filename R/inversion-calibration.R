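## Forward lookup table (mu_a, mu_s') -> (H_DC, H_AC), affine calibration
## against reference samples, and inverse interpolation on the H_DC - H_AC
## plane. Interpolation in parameter space is linear in (log mu_a,
## log mu_s'), matching the log-spaced grids.

#' Build the forward lookup table
#'
#' Evaluates the model (H_DC, H_AC) pair on a grid of media from one set of
#' White Monte Carlo records and a fixed input radial PSD. One simulation at
#' the grid's anisotropy serves every node (the White Monte Carlo reuse).
#' The expected monotonicity -- H_DC strictly decreasing in mu_a at fixed
#' mu_s' -- is verified and the table is rejected on violation.
#'
#' @param records [PathlengthRecords-class].
#' @param muAGrid,muSPrimeGrid strictly increasing grids, 1/mm. Defaults:
#'   7 log-spaced mu_a levels over [0.003, 0.4] and 8 log-spaced mu_s'
#'   levels over [0.5, 4], spanning skin-like media.
#' @param sUU input radial PSD profile (data.frame k, S with a `binWidth`
#'   attribute, from [radialAverage()]). May be omitted when `psdUU` is
#'   given.
#' @param psdUU optional input [PsdEstimate-class] (2D). When supplied, the
#'   model |H|^2 is averaged over the actual frequency cells of each
#'   annulus, weighted by the input PSD -- the same functional the data
#'   estimator computes -- rather than evaluated at nominal bin centres.
#' @param band numeric(2) integration band, 1/mm.
#' @param dcBins,dcMode see [modelResponseParameters()].
#' @param g anisotropy recorded in the table (from records).
#' @return A [ForwardLookupTable-class].
#' @export
buildLUT <- function(records, muAGrid = NULL, muSPrimeGrid = NULL,
                     sUU = NULL, psdUU = NULL, band, dcBins = 3L,
                     dcMode = c("band", "dc0"), g = records@g) {
  dcMode <- match.arg(dcMode)
  if (is.null(muAGrid))
    muAGrid <- exp(seq(log(0.003), log(0.4), length.out = 7L))
  if (is.null(muSPrimeGrid))
    muSPrimeGrid <- exp(seq(log(0.5), log(4), length.out = 8L))
  nA <- length(muAGrid); nS <- length(muSPrimeGrid)
  hDC <- hAC <- matrix(0, nA, nS)

  if (is.null(sUU)) stop("sUU (the input radial profile) is required")
  k <- sUU$k
  bw <- attr(sUU, "binWidth")
  idxDC <- seq_len(min(dcBins, length(k)))
  idxB <- which(k >= band[1] & k <= band[2])
  maxBin <- max(c(idxDC, idxB))

  cellMap <- NULL
  if (!is.null(psdUU)) {
    stopifnot(is(psdUU, "PsdEstimate"))
    edges <- attr(sUU, "edges")
    kCap <- edges[maxBin + 1L]
    kr <- sqrt(outer(psdUU@kx^2, psdUU@ky^2, "+"))
    sel <- kr < kCap & kr > 0
    cellMap <- list(
      bin = factor(findInterval(kr[sel], edges, rightmost.closed = TRUE),
                   levels = seq_len(length(edges) - 1L)),
      kcell = kr[sel], w = psdUU@psd[sel])
  }
  kFine <- seq(0, k[maxBin] + bw, by = bw / 8)
  for (j in seq_len(nS)) {
    ms <- muSPrimeGrid[j] / (1 - g)
    r <- records@rho / ms
    lam <- records@path / ms
    kEval <- if (is.null(cellMap)) k else kFine
    # J0 kernel shared across the mu_a column
    J <- vapply(kEval, function(kk) besselJ(2 * pi * kk * r, 0),
                numeric(length(r)))
    for (i in seq_len(nA)) {
      w <- exp(-muAGrid[i] * lam)
      H <- as.numeric(crossprod(w, J)) / records@nLaunched
      H0 <- sum(w) / records@nLaunched
      if (is.null(cellMap)) {
        # bin-centre approximation from the radial profile alone
        H2 <- H^2
        Svv <- H2 * sUU$S
      } else {
        Hc <- approx(kEval, H, xout = cellMap$kcell, rule = 2)$y
        num <- as.numeric(tapply(Hc^2 * cellMap$w, cellMap$bin, sum))
        den <- as.numeric(tapply(cellMap$w, cellMap$bin, sum))
        Svv <- (num / den) * sUU$S
      }
      wDC <- if (!is.null(sUU$n)) sUU$n[idxDC] else rep(1, length(idxDC))
      hDC[i, j] <- if (dcMode == "dc0") H0^2
                   else sum(wDC * Svv[idxDC]) / sum(wDC * sUU$S[idxDC])
      wk <- 2 * pi * k[idxB]
      hAC[i, j] <- sum(Svv[idxB] * wk) /
                   (sum(sUU$S[idxB] * wk) * hDC[i, j])
    }
  }
  bad <- which(apply(hDC, 2, function(col) any(diff(col) >= 0)))
  if (length(bad))
    stop("lookup table rejected: H_DC is not strictly decreasing in mu_a ",
         "at mu_s' = ", paste(signif(muSPrimeGrid[bad], 3), collapse = ", "),
         " (increase the photon count or coarsen the grid)")
  new("ForwardLookupTable",
      muAGrid = as.numeric(muAGrid),
      muSPrimeGrid = as.numeric(muSPrimeGrid),
      g = g, hDC = hDC, hAC = hAC,
      band = as.numeric(band), dcBins = as.numeric(dcBins),
      sUU = list(k = sUU$k, S = sUU$S, binWidth = attr(sUU, "binWidth")),
      provenance = list(seed = records@seed,
                        nPhotons = records@nLaunched,
                        dcMode = dcMode))
}

# bilinear interpolation of the forward map at arbitrary (muA, muSPrime),
# linear in log-parameters
lutInterpolate <- function(lut, muA, muSPrime) {
  la <- log(muA); ls <- log(muSPrime)
  ga <- log(lut@muAGrid); gs <- log(lut@muSPrimeGrid)
  if (la < min(ga) - 1e-9 || la > max(ga) + 1e-9 ||
      ls < min(gs) - 1e-9 || ls > max(gs) + 1e-9)
    stop("(muA, muSPrime) = (", signif(muA, 3), ", ", signif(muSPrime, 3),
         ") lies outside the lookup-table envelope")
  i <- min(max(findInterval(la, ga), 1L), length(ga) - 1L)
  j <- min(max(findInterval(ls, gs), 1L), length(gs) - 1L)
  ta <- (la - ga[i]) / (ga[i + 1] - ga[i])
  ts <- (ls - gs[j]) / (gs[j + 1] - gs[j])
  bil <- function(M)
    (1 - ta) * (1 - ts) * M[i, j] + ta * (1 - ts) * M[i + 1, j] +
    (1 - ta) * ts * M[i, j + 1] + ta * ts * M[i + 1, j + 1]
  c(hDC = bil(lut@hDC), hAC = bil(lut@hAC))
}

#' Minimum node separation on the (H_DC, H_AC) plane
#'
#' The uniqueness requirement restated as a grid property: every medium on
#' the grid must map to a distinct response pair. Returns the smallest
#' pairwise Euclidean distance between node images.
#'
#' @param lut a [ForwardLookupTable-class].
#' @return smallest pairwise distance (dimensionless response units).
#' @export
lutMinSeparation <- function(lut) {
  pts <- cbind(as.numeric(lut@hDC), as.numeric(lut@hAC))
  min(dist(pts))
}

#' Fit the per-axis affine calibration
#'
#' Observed response parameters differ from model values by an
#' instrument-dependent scale and offset; both are corrected by calibrating
#' against standard samples with known optical properties. Fits, per axis
#' independently, the least-squares affine map from observed to model
#' values.
#'
#' @param references data.frame with columns `muA`, `muSPrime` (known
#'   properties), `hDC`, `hAC` (observed parameters); >= 2 rows spanning
#'   distinct model values on each axis.
#' @param lut the [ForwardLookupTable-class] providing model values.
#' @return A [CalibrationModel-class].
#' @export
fitCalibration <- function(references, lut) {
  need <- c("muA", "muSPrime", "hDC", "hAC")
  if (!all(need %in% names(references)))
    stop("references need columns ", paste(need, collapse = ", "))
  if (nrow(references) < 2L)
    stop("at least 2 reference samples are required")
  model <- t(vapply(seq_len(nrow(references)), function(i)
    lutInterpolate(lut, references$muA[i], references$muSPrime[i]),
    c(hDC = 0, hAC = 0)))
  fitAxis <- function(obs, mod, what) {
    if (diff(range(obs)) < 1e-12 || diff(range(mod)) < 1e-12)
      stop("degenerate references: no spread in ", what)
    f <- lm(mod ~ obs)
    list(scale = unname(coef(f)[2]), offset = unname(coef(f)[1]),
         residuals = unname(f$residuals))
  }
  fdc <- fitAxis(references$hDC, model[, "hDC"], "H_DC")
  fac <- fitAxis(references$hAC, model[, "hAC"], "H_AC")
  if (fdc$scale <= 0 || fac$scale <= 0)
    stop("calibration fit produced a non-positive scale; ",
         "references are inconsistent with the model")
  new("CalibrationModel",
      scale = c(dc = fdc$scale, ac = fac$scale),
      offset = c(dc = fdc$offset, ac = fac$offset),
      residuals = list(dc = fdc$residuals, ac = fac$residuals),
      references = cbind(references,
                         modelHDC = model[, "hDC"],
                         modelHAC = model[, "hAC"]))
}

#' Identity calibration (scale 1, offset 0)
#' @export
identityCalibration <- function() {
  new("CalibrationModel",
      scale = c(dc = 1, ac = 1), offset = c(dc = 0, ac = 0),
      residuals = list(), references = data.frame())
}

applyCalibration <- function(calibration, hDC, hAC) {
  c(hDC = calibration@scale["dc"] * hDC + calibration@offset["dc"],
    hAC = calibration@scale["ac"] * hAC + calibration@offset["ac"],
    use.names = FALSE)
}

# triangulation of the forward image of the grid: two triangles per cell,
# vertices in (hDC, hAC) with payload (log muA, log muSPrime)
lutTriangles <- function(lut) {
  nA <- length(lut@muAGrid); nS <- length(lut@muSPrimeGrid)
  idx <- function(i, j) (j - 1L) * nA + i
  tris <- list()
  n <- 0L
  for (j in seq_len(nS - 1L)) for (i in seq_len(nA - 1L)) {
    tris[[n + 1L]] <- c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
    tris[[n + 2L]] <- c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
    n <- n + 2L
  }
  list(tris = do.call(rbind, tris),
       px = as.numeric(lut@hDC), py = as.numeric(lut@hAC),
       la = log(rep(lut@muAGrid, times = nS)),
       ls = log(rep(lut@muSPrimeGrid, each = nA)))
}

# barycentric coordinates of point q in triangle (p1, p2, p3)
barycentric <- function(q, p1, p2, p3) {
  M <- cbind(p2 - p1, p3 - p1)
  d <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  if (abs(d) < 1e-300) return(c(-1, -1, -1))
  v <- q - p1
  l2 <- (v[1] * M[2, 2] - v[2] * M[1, 2]) / d
  l3 <- (-v[1] * M[2, 1] + v[2] * M[1, 1]) / d
  c(1 - l2 - l3, l2, l3)
}

#' Invert response parameters to optical properties
#'
#' Applies the affine calibration, then inverse-interpolates the observed
#' point on the (H_DC, H_AC) plane through a triangulation of the forward
#' image of the lookup-table grid (piecewise linear in log-parameters).
#' Points outside the mapped region are projected to the nearest point of
#' the region boundary and flagged. Uncertainties propagate the jackknife
#' errors of the response parameters through the local Jacobian of the
#' forward map.
#'
#' @param observed a [ResponseParameters-class], or a data.frame with
#'   columns `hDC`, `hAC` (optionally `seHDC`, `seHAC`) for batch
#'   inversion.
#' @param lut a [ForwardLookupTable-class].
#' @param calibration a [CalibrationModel-class] (default: identity).
#' @return data.frame with columns muA, muSPrime, seMuA, seMuSPrime, hDC,
#'   hAC, hDCCal, hACCal, outOfRange.
#' @export
invertResponse <- function(observed, lut, calibration = identityCalibration()) {
  if (is(observed, "ResponseParameters")) {
    observed <- data.frame(hDC = observed@hDC, hAC = observed@hAC,
                           seHDC = observed@se["dc"],
                           seHAC = observed@se["ac"])
  }
  if (!all(c("hDC", "hAC") %in% names(observed)))
    stop("observed must provide hDC and hAC")
  if (is.null(observed$seHDC)) observed$seHDC <- NA_real_
  if (is.null(observed$seHAC)) observed$seHAC <- NA_real_

  tri <- lutTriangles(lut)
  nT <- nrow(tri$tris)
  nObs <- nrow(observed)
  out <- data.frame(muA = rep(NA_real_, nObs), muSPrime = NA_real_,
                    seMuA = NA_real_, seMuSPrime = NA_real_,
                    hDC = observed$hDC, hAC = observed$hAC,
                    hDCCal = NA_real_, hACCal = NA_real_,
                    outOfRange = FALSE)
  rownames(out) <- rownames(observed)

  for (r in seq_len(nObs)) {
    q0 <- applyCalibration(calibration, observed$hDC[r], observed$hAC[r])
    out$hDCCal[r] <- q0[1]; out$hACCal[r] <- q0[2]
    q <- q0
    locate <- function(q) {
      for (t in seq_len(nT)) {
        v <- tri$tris[t, ]
        l <- barycentric(q, c(tri$px[v[1]], tri$py[v[1]]),
                         c(tri$px[v[2]], tri$py[v[2]]),
                         c(tri$px[v[3]], tri$py[v[3]]))
        if (all(l >= -1e-9)) return(list(t = t, l = l))
      }
      NULL
    }
    loc <- locate(q)
    if (is.null(loc)) {
      # project onto the nearest boundary segment of the mapped region
      q <- nearestBoundaryPoint(lut, q)
      out$outOfRange[r] <- TRUE
      loc <- locate(q)
      if (is.null(loc)) {
        # numeric edge case: snap to the nearest node
        d2 <- (tri$px - q[1])^2 + (tri$py - q[2])^2
        v <- which.min(d2)
        out$muA[r] <- exp(tri$la[v]); out$muSPrime[r] <- exp(tri$ls[v])
        next
      }
    }
    v <- tri$tris[loc$t, ]
    la <- sum(loc$l * tri$la[v])
    ls <- sum(loc$l * tri$ls[v])
    out$muA[r] <- exp(la)
    out$muSPrime[r] <- exp(ls)

    if (is.finite(observed$seHDC[r]) && is.finite(observed$seHAC[r])) {
      # forward Jacobian d(hDC, hAC)/d(log muA, log muSPrime) on the triangle
      P <- cbind(c(tri$px[v[2]] - tri$px[v[1]], tri$py[v[2]] - tri$py[v[1]]),
                 c(tri$px[v[3]] - tri$px[v[1]], tri$py[v[3]] - tri$py[v[1]]))
      Th <- cbind(c(tri$la[v[2]] - tri$la[v[1]], tri$ls[v[2]] - tri$ls[v[1]]),
                  c(tri$la[v[3]] - tri$la[v[1]], tri$ls[v[3]] - tri$ls[v[1]]))
      # d theta / d H = Th %*% P^{-1}, with calibration scale on the way in
      Jinv <- try(Th %*% solve(P), silent = TRUE)
      if (!inherits(Jinv, "try-error")) {
        sH <- c(calibration@scale["dc"] * observed$seHDC[r],
                calibration@scale["ac"] * observed$seHAC[r])
        cv <- Jinv %*% diag(sH^2) %*% t(Jinv)
        out$seMuA[r] <- out$muA[r] * sqrt(cv[1, 1])
        out$seMuSPrime[r] <- out$muSPrime[r] * sqrt(cv[2, 2])
      }
    }
  }
  out
}

# nearest point on the boundary polyline of the forward image of the grid
nearestBoundaryPoint <- function(lut, q) {
  nA <- nrow(lut@hDC); nS <- ncol(lut@hDC)
  ring <- rbind(
    cbind(lut@hDC[, 1], lut@hAC[, 1]),
    cbind(lut@hDC[nA, ], lut@hAC[nA, ]),
    cbind(rev(lut@hDC[, nS]), rev(lut@hAC[, nS])),
    cbind(rev(lut@hDC[1, ]), rev(lut@hAC[1, ])))
  best <- c(ring[1, 1], ring[1, 2]); bd <- Inf
  for (s in seq_len(nrow(ring) - 1L)) {
    a <- ring[s, ]; b <- ring[s + 1L, ]
    ab <- b - a
    t <- sum((q - a) * ab) / max(sum(ab^2), 1e-300)
    t <- min(max(t, 0), 1)
    p <- a + t * ab
    d <- sum((q - p)^2)
    if (d < bd) { bd <- d; best <- p }
  }
  best
}

setMethod("show", "ForwardLookupTable", function(object) {
  cat(sprintf(
    "ForwardLookupTable: %d muA x %d muS' nodes, g = %g\n",
    length(object@muAGrid), length(object@muSPrimeGrid), object@g),
    sprintf("  muA [%.3g, %.3g], muS' [%.3g, %.3g] 1/mm; band [%.3g, %.3g]\n",
            min(object@muAGrid), max(object@muAGrid),
            min(object@muSPrimeGrid), max(object@muSPrimeGrid),
            object@band[1], object@band[2]),
    sprintf("  H_DC range [%.3g, %.3g], H_AC range [%.3g, %.3g]\n",
            min(object@hDC), max(object@hDC),
            min(object@hAC), max(object@hAC)))
})

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf(
    "CalibrationModel: H_DC -> %.4g x + %.4g; H_AC -> %.4g x + %.4g (%d refs)\n",
    object@scale["dc"], object@offset["dc"],
    object@scale["ac"], object@offset["ac"], nrow(object@references)))
})
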