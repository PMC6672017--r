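---
title: "Measuring light transport properties with speckle structured illumination: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring light transport properties with speckle structured illumination: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Turbid media — skin, milk, lipid emulsions, paints — are characterized by
two light transport properties: the absorption coefficient $\mu_a$ and the
reduced scattering coefficient $\mu_s'$ (both mm$^{-1}$). When a spatial
intensity pattern $u(x, y)$ is projected onto such a medium, the diffusely
backscattered image $v(x, y)$ is a blurred, attenuated copy:
$v = h * u$, where $h(r)$ is the radially symmetric impulse response of the
semi-infinite medium. The medium thus acts as a linear, spatially invariant
low-pass filter whose frequency response $H(k_r)$ — the Hankel transform of
$h(r)$ — is set by $(\mu_a, \mu_s')$. Estimating $H$ from projected patterns
and backscatter images, and inverting it, yields the two properties without
contact.

Instead of projecting discrete sinusoids one spatial frequency at a time,
this toolkit works with *objective speckle patterns*: interference patterns
formed when coherent light scatters off a rough surface. Speckle is
spatially broadband, so a single frame probes an entire band of spatial
frequencies at once — the property that makes frame-by-frame analysis of
moving targets conceivable. The price is that the illumination is a random
process, so identification becomes a statistical estimation problem over an
ensemble of $N$ independent realizations.

The package closes the full loop synthetically: speckle synthesis, photon
transport, the imaging chain, spectral system identification, and inversion,
each testable against the others.

## Speckle synthesis

A rough scattering surface illuminated over an elliptical spot is modelled
as a *random phase screen*: unit amplitude and independent uniform phase on
$[0, 2\pi)$ inside the spot, zero outside. In the far field the intensity is
the squared modulus of the Fourier transform of the masked screen. The
screen pitch is solved from $\lambda D / (M \delta) = p$ (grid size $M$,
screen pitch $\delta$, target pixel scale $p$) so the transform lands
exactly on the requested sampling grid — no resampling is ever applied.

Key consequences, all verified by the test suite:

* With a spot much larger than the grain scale, the pattern is **fully
  developed**: pointwise intensity is exponential (a $\chi^2$ distribution
  with 2 degrees of freedom), so the contrast $\sigma/\mu$ is 1 and the
  moment-matched degrees-of-freedom estimate $2\bar{u}^2/s^2$ is 2.
* A finite spot of extent $d$ **bandlimits** the intensity spectrum to
  $k_c = d/(\lambda D)$ per axis and produces grains of scale
  $\lambda D / d$; halving the aperture broadens the autocorrelation and
  narrows the spectrum. This is the design dial that matches the projected
  band to the imaging Nyquist limit and to the frequency range where the
  media of interest actually differ.
* Oblique incidence at $\theta$ (used to keep specular glare out of the
  camera) only stretches the projected pattern along one axis; it is
  modelled as a $\cos\theta$ shrink of the effective aperture axis.

The uniform-phase screen is an idealization (the white-noise-surface
limit). Real card stock has unknown height statistics; no attempt is made to
reproduce measured first-order histograms, and the first-order statistics of
partially developed patterns here (higher-order $\chi^2$) should not be
read as predictions for any particular surface.

## Ensemble statistics

All second-order statistics flow through one estimator chain:
autocorrelation → Wiener–Khinchin spectrum → radial (annulus) average.

The autocorrelation estimator subtracts the average cross-correlation of the
$N(N-1)$ distinct image pairs from the average autocorrelation of the $N$
images. Any additive component common to every frame — glare edges,
scratches on a cuvette window, and the process mean itself — cancels
*algebraically*, not just in expectation; what survives noise-wise is the
interaction of the pattern with exposure, quantization and shot noise, which
the fixed-pattern impact study measures at a few tenths of a percent while
the naive averaged autocorrelation is corrupted at the tens-of-percent
level. This is why heterogeneous instrument artefacts do not need to be
modelled, only cancelled.

Numerical choices:

* Correlations are computed by FFT. For general images they are zero-padded
  (linear correlation) and normalized by per-lag overlap counts (unbiased).
  For fields generated by full-grid Fourier synthesis the `circular = TRUE`
  path is exact and keeps every frequency cell.
* The PSD is the transform of the lag-windowed autocorrelation. The Hann
  lag window (unity at zero lag, power preserving) is the general-purpose
  default; the closed-loop pipeline uses `window = "none"` because the pair
  subtraction already removes the mean — there is no DC leakage for a taper
  to suppress — and lag-windowing smooths the steep low-frequency part of
  $S_{VV}$ by 5–30% in a way the model side of the reduction does not share.
* Negative spectral residues are clipped to zero and their integral
  reported; the Parseval identity (2D spectral integral = zero-lag value) is
  exact before clipping and auditable after it.
* Radial profiles exclude the DC cell (residual mean power is estimator
  noise) and default to annuli of width Nyquist/64; the closed-loop pipeline
  uses one annulus per frequency-grid ring so the medium's response, which
  varies on the ~0.1 mm$^{-1}$ scale, is resolved.

Stationarity and mean-ergodicity — the assumptions that justify treating
spatial averages as process expectations — are checked by three diagnostics
(pairwise cross/auto correlation peaks, pixelwise-mean scatter in
standard-error units, autocorrelation decay), with configurable thresholds
and fail verdicts rather than errors on degenerate input.

## Photon transport

The medium model is a White Monte Carlo random walk in the half space:
unit scattering, zero absorption, Henyey–Greenstein deflections at fixed
anisotropy $g$, step lengths $-\ln \xi$. Each escaping packet contributes a
dimensionless exit radius $\rho$ and total path $\Lambda$ (both in units of
$1/\mu_s$). One simulation then serves *every* $(\mu_a, \mu_s')$ pair at
that $g$: physical radius $r = \rho/\mu_s$ and absorption weight
$e^{-\mu_a \Lambda / \mu_s}$. The frequency response is evaluated directly
on the records as $H(k) = n^{-1} \sum_i w_i J_0(2\pi k \rho_i/\mu_s)$, so
$H(0)$ equals the total diffuse reflectance $R_d$ identically.

Defaults and their reasons:

* `boundary = "matched"`: the simplest defensible boundary; a Fresnel
  boundary with relative index $n_{rel}$ is available and, as expected,
  traps light and lowers $R_d$.
* `maxDimensionlessPath = 1e5`: the first-passage tail of the walk decays
  like $s^{-1/2}$, so truncating at $10^4$ scattering lengths would leave
  1.5–3% of walks unresolved and visibly violate energy conservation at
  $\mu_a = 0$; at $10^5$ the unresolved fraction is ~0.5% (g = 0) to ~1%
  (g = 0.7) and is reported per run so the bias is auditable. For any
  absorbing medium of interest the truncated weight is negligible.
* Normal incidence for the impulse response (the response is radially
  symmetric; the projection angle only matters for glare, which is not
  modelled).
* $g = 0.7$ for tissue-like media; $R_d$ changes by under 5% between
  $g = 0.5$ and $g = 0.9$ at matched $\mu_s'$, which is why a single $g$ is
  acceptable.

Checked physics: $R_d \to 1$ for non-absorbing media; $R_d$ strictly
decreasing in $\mu_a$; agreement with the diffusion-approximation total
reflectance within 15%; the similarity relation (media with equal
$\mu_a/\mu_s'$ share $R_d$, and $H$ rescales in $k$) holds to numerical
precision — this is the core correctness property of the White Monte Carlo
reuse.

## The imaging chain

The forward model composes: circular convolution with the rasterized radial
kernel, an additive fixed pattern (a synthetic bright frame plus random
scratch segments, standing in for cuvette edge artefacts), percentile-based
auto-exposure (the 99.5th percentile maps to count 250 of 255), Poisson shot
noise, Gaussian read noise (1 count RMS), rounding and clipping to 8 bits.
Offline, frames are divided by their recorded exposure times, which
equalizes gain across bright and dim samples.

Two rasterization details matter numerically. First, for weakly absorbing,
weakly scattering media the diffuse halo is wider than any practical field
of view; the kernel is therefore *periodized* (summed over image shifts),
which makes circular convolution the exact discrete analogue — spatial
periodization samples the continuous $H$ exactly at the DFT frequencies.
The periodization order is chosen from the halo extent, and a response whose
mass cannot be represented errors out with guidance. Second, $h(r)$ varies
on sub-pixel scales near the origin, and midpoint sampling there biases the
kernel spectrum by a near-constant offset of order $10^{-3} R_d$; the
central pixels are therefore area-averaged by oversampled quadrature. After
these two corrections the kernel's DFT matches the record-level Hankel
transform within ~1% across the tissue-like media matrix, which is what
makes a 3% end-to-end spectral-transfer tolerance meaningful.

## System identification

With stationary random illumination, $S_{VV}(k_r) = |H(k_r)|^2
S_{UU}(k_r)$. Rather than fitting the full noisy ratio, the spectra are
reduced to two numbers:

* $H_{DC}$: the ratio of output to input power at low spatial frequency —
  the fraction of light returned (approximately $|H(0)|^2 = R_d^2$);
* $H_{AC}$: the in-band, DC-normalized retained signal power — a measure of
  how much contrast survives the diffusion blur (annulus-weighted integrals
  $\int S\, 2\pi k_r\, dk_r$ over the band).

Choices the source material leaves open, and how they were fixed here:

* **The $k_r \to 0$ limit** is operationalized as the average over the
  lowest non-DC annuli, weighted by the number of frequency cells in each
  annulus (equivalent to pooling the cells). The pooled weighting roughly
  halves the estimator variance relative to plain per-annulus averaging,
  because the innermost annulus holds only 4 cells. The general-purpose
  default is 3 annuli; the closed-loop pipeline widens the band to one
  third of the aperture cutoff, because a band tied to the image's
  frequency resolution starves the estimator of cells as images grow — a
  sensitivity-versus-variance analysis on the forward model shows the
  absorption uncertainty falls monotonically as the band widens toward
  $k_c/3$, the model side being evaluated over the identical band either
  way.
* **The integration band** runs from the third annulus edge to the
  aperture cutoff $k_c$ — the illumination band. Integrating beyond the
  bandlimit demonstrably distorts the estimate by more than its jackknife
  error, which is the quantitative reason the aperture is tuned to the
  narrowest band the application allows.
* **Model/estimator consistency.** $H(k_r)$ decays substantially across any
  finite low-frequency band for weakly scattering media, so the idealized
  $|H(0)|^2$ is *not* what the data estimator measures. The model side of
  the reduction (and the lookup table) therefore evaluates the identical
  functional — cell-weighted annulus averages of $|H|^2$ against the
  measured input spectrum (`dcMode = "band"`). The idealized
  `dcMode = "dc0"` ($R_d^2$) is kept for reference.
* **Uncertainties** are leave-one-frame-out jackknife standard errors. When
  one stored reference input serves all samples (the calibration protocol),
  its sampling error is a common systematic absorbed by calibration, so
  only the output ensemble is jackknifed. A caveat: on speckle ensembles the
  pair-subtraction estimator contains a mean-zero pair term whose variance
  falls as $1/N^2$; the delete-one jackknife does not see that component
  well, so at very small $N$ (about 5) the reported errors on strongly
  blurred ensembles are indicative rather than calibrated. At the
  operating point ($N = 10$, replicate-averaged) they are conservative.

Values outside $[0, 1]$ are flagged with a warning and preserved — they
diagnose noise or calibration faults and must not be silently clipped.

## Lookup table, calibration, inversion

The forward map is tabulated on a log-spaced grid of 7 $\mu_a$ levels over
$[0.003, 0.4]$ by 8 $\mu_s'$ levels over $[0.5, 4]$ mm$^{-1}$ — the
envelope of skin-like media — from one record set. The expected physics is
enforced: $H_{DC}$ strictly decreasing in $\mu_a$ (fold-over rejects the
table), increasing in $\mu_s'$; $H_{AC}$ increasing in both (absorption
trims long blurred paths, scattering raises the cutoff); $\mu_a$ sensitivity
strongest at low $\mu_s'$. Grid injectivity — no two media mapping to
nearly the same $(H_{DC}, H_{AC})$ point — is asserted as a minimum pairwise
separation.

Real instruments differ from the model by scale and offset on each
parameter; a per-axis affine calibration (4 parameters) is fitted by least
squares against reference samples with known properties, and recovered
exactly on noiseless synthetic distortions. Inversion triangulates the
forward image of the grid and inverse-interpolates linearly in
$(\log \mu_a, \log \mu_s')$; out-of-region points are projected to the
boundary and flagged. Uncertainties propagate the jackknife errors through
the local Jacobian of the containing triangle.

## The synthetic experiment and what it shows

`runPipeline()` reproduces the full protocol: one reference speckle
ensemble ($N = 10$ frames) measured through the sensor (the
diffusing-screen input measurement); noisy backscatter ensembles — fresh
input realizations per observation, a shared fixed pattern — for 8
calibration phantoms and 6 interior test media, 3 replicates each; reduction
of every observation to $(H_{DC}, H_{AC})$; calibration; inversion of the
replicate-averaged test responses.

Problem sizes: 512×512-pixel images at the 34 mm / 673 px target scale
(matching the pixel budget of a full cuvette-face image at a
transform-friendly size), $10^5$ photons in the shared White MC record set,
a 635 nm projection with the 1.5 × 0.8 mm aperture at 1.2 m so the
illumination band (cutoff ≈ 1.05–1.4 mm$^{-1}$) sits inside both the
Nyquist limit (≈ 10 mm$^{-1}$) and the range where tissue-like $H$ curves
differ.

What passing tests do and do not show. The generator emulates the
measurement's statistical structure — bandlimited stationary random
illumination, linear spatially invariant blur, auto-exposed 8-bit capture
with shot/read noise, shared deterministic artefacts — so closed-loop
recovery demonstrates that the estimator chain and inversion are consistent
and that the information content at these conditions supports ~10–25%
recovery of $\mu_a$ and a few percent of $\mu_s'$. It does not validate the
phase-screen idealization against a real rough surface, real cuvette
optics, lens point-spread functions, or refractive-index mismatch at a real
phantom surface — those enter a real instrument through the calibration
step, which is exactly why the method calibrates rather than trusting
absolute model values. A known physical limit shows up clearly in the
synthetic study too: at very low $\mu_a$ under strong scattering, the
response surface is nearly flat in $\mu_a$ and no estimator can recover it
precisely; the test-media set deliberately includes that corner, and its
uncertainty is reported rather than hidden.

## Known limitations

* Homogeneous, semi-infinite media only; spatially varying properties (the
  eventual dermatological target) break spatial invariance and are out of
  scope.
* Single wavelength; no spectroscopic inversion, and $g$ is fixed rather
  than estimated (the response is insensitive to it at matched $\mu_s'$).
* The fixed-pattern fixture is a stand-in; no claim is made that it matches
  any particular instrument's artefacts — only that the estimator cancels
  whatever is common across frames.
* Polarization, interferometric effects of oblique incidence, and the
  camera's own diffraction-limited point spread function are not modelled.
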