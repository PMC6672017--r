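## Internal helpers: seeded evaluation, seed derivation, FFT plumbing.

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Counter-based seed derivation: reproducible, extensible, stays < 2^31.
deriveSeed <- function(base, ...) {
  idx <- c(...)
  m <- 2147483629  # prime < 2^31
  s <- as.numeric(base) %% m
  for (i in seq_along(idx)) {
    s <- (s * 48271 + as.numeric(idx[i]) * 16807 + i * 104729) %% m
  }
  as.integer(s %% 2147483587L + 1L)
}

nextPow2 <- function(n) 2^ceiling(log2(pmax(n, 1)))

# 2D FFT helpers --------------------------------------------------------

fft2 <- function(x, inverse = FALSE) stats::fft(x, inverse = inverse)

ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Move zero frequency (at [1,1]) to the centre [floor(n/2)+1, ...].
fftshift2 <- function(x) {
  d <- dim(x)
  s <- floor(d / 2)
  x[c(seq_len(d[1])[-seq_len(d[1] - s[1])], seq_len(d[1] - s[1])),
    c(seq_len(d[2])[-seq_len(d[2] - s[2])], seq_len(d[2] - s[2]))]
}

ifftshift2 <- function(x) {
  d <- dim(x)
  s <- ceiling(d / 2)
  x[c(seq_len(d[1])[-seq_len(d[1] - s[1])], seq_len(d[1] - s[1])),
    c(seq_len(d[2])[-seq_len(d[2] - s[2])], seq_len(d[2] - s[2]))]
}

# DFT frequency axis (cycles per unit length), fftshifted to ascending order.
fftFreq <- function(n, delta) {
  k <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L))
  sort(k) / (n * delta)
}

# Extract a 3D array of images from ensemble-like inputs.
ensembleArray <- function(x) {
  if (is(x, "ImageEnsemble")) return(x@images)
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  if (is.list(x) && all(vapply(x, is.matrix, TRUE))) {
    d <- dim(x[[1]])
    if (!all(vapply(x, function(m) identical(dim(m), d), TRUE)))
      stop("images in an ensemble must share one shape")
    return(array(unlist(x, use.names = FALSE), dim = c(d, length(x))))
  }
  stop("cannot interpret 'x' as an image ensemble ",
       "(expected ImageEnsemble, 3D array, or list of matrices)")
}

ensemblePixelScale <- function(x, default = c(1, 1)) {
  if (is(x, "ImageEnsemble")) x@pixelScale else default
}
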