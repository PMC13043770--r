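---
title: "Mapping local dielectric permittivity with spectral phasors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping local dielectric permittivity with spectral phasors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dielmap)
```

## The measurement problem

Solvatochromic dyes such as ACDAN report on the polarity of their immediate
molecular environment: after excitation the dye's dipole moment increases,
the surrounding solvent dipoles reorient, and the emitted photon is
red-shifted by an amount that grows with the medium's relative dielectric
permittivity $\varepsilon$ (in units of $\varepsilon_0$). Hyperspectral
confocal imaging records a full emission spectrum at every pixel — on the
instrument geometry assumed throughout this package, 32 contiguous
detection windows of 9.75 nm bandwidth spanning 416–728 nm, 512 × 512
pixels per frame. `dielmap` turns such stacks into per-pixel maps of
$\varepsilon$, resolves coexisting dense (condensate) and depleted phases
of liquid–liquid phase-separated systems, and connects the resulting
*permittivity contrast* $\varepsilon_c - \varepsilon_d$ to
condensate–membrane wetting mechanics.

## Spectral readouts

Two readouts of the per-pixel spectrum are implemented.

**Spectral phasor.** The discrete Fourier coefficient of the normalized
spectrum,
$$G = \frac{\sum_c I(c)\cos(2\pi n c/N_c)}{\sum_c I(c)}, \qquad
  S = \frac{\sum_c I(c)\sin(2\pi n c/N_c)}{\sum_c I(c)},$$
with channel index $c = 0,\dots,N_c-1$ and harmonic $n$ (default 1; a
single-harmonic phasor is the standard choice for unimodal emission
spectra). The phase $\phi = \mathrm{atan2}(S, G)$, wrapped to $[0, 2\pi)$
so that it increases monotonically with redshift across the window, tracks
the spectral center of mass; the modulus $M = \sqrt{G^2+S^2} \le 1$ tracks
spectral sharpness. The transform is fit-free, linear in the spectrum
(mixtures map to convex combinations on the phasor plot, weighted by
integrated intensity), and exact analytic identities (delta-spectrum
angles $2\pi c/N_c$, uniform-spectrum null, shift covariance) make it
testable to machine precision.

**Skewed-Gaussian fit.** The emission profile is modeled as
$$I(\lambda) = I_0\,\psi\!\left(\tfrac{\lambda-\mu}{\sigma}\right)
  \Phi\!\left(\gamma\tfrac{\lambda-\mu}{\sigma}\right)$$
with $\psi$/$\Phi$ the standard normal density/CDF, fitted by least
squares on channel-center wavelengths (centers, not edges: at 9.75 nm
bandwidth the difference is material). The emission maximum
$\lambda_{\max}$ is the numerically located mode (coarse grid plus local
refinement; no closed form exists). Two numerical choices deserve note:

* *Initialization and multi-start.* $\mu$ starts at the intensity-weighted
  mean wavelength and $\sigma$ at the weighted standard deviation; because
  skewness trades off against location, the optimizer is restarted from a
  small ladder of trial skewnesses with method-of-moments rescaling, and a
  Gauss–Newton polish (`nls`, port algorithm) sharpens the best optimum.
* *Identifiability near $\gamma = 0$.* To first order a small skew is
  exactly a location shift, so $(\mu, \gamma)$ lie on a flat ridge: on
  noiseless symmetric data they are only recoverable to about $10^{-3}$
  while the mode itself is sharp to better than $10^{-4}$ nm. Downstream
  analysis therefore consumes $\lambda_{\max}$, never raw $(\mu,\gamma)$.

## Calibration

The emission maximum is linked to permittivity through the Lippert–Mataga
form
$$\frac{1}{\lambda_{\max}} = a\,f(\varepsilon) + b,$$
where $f$ is a generalized Debye (orientation-polarizability) function —
default $f(\varepsilon) = (\varepsilon-1)/(2\varepsilon+1)$, with the
refractive-index term of the classical orientation polarizability absorbed
into the intercept $b$; other variants can be plugged in and are recorded
in the model. The lumped slope $a$ (nm$^{-1}$) houses the dye's dipole
moments and molecular volume; a dye that red-shifts with permittivity has
$a < 0$. Fitting is done by exact linear least squares in
$1/\lambda_{\max}$ versus $f(\varepsilon)$ space (no iteration, no
convergence concerns), and strict monotonicity of
$\lambda_{\max}(\varepsilon)$ over the calibrated range (default
$[2, 80]\,\varepsilon_0$) is verified so the map is invertible.

Phase readouts enter through the linear phase/wavelength relation
$$\lambda_{\max} = \frac{\phi\,(\lambda_f-\lambda_0)}{2\pi} + \lambda_0,
  \qquad \lambda_0 = 416\ \mathrm{nm},\ \lambda_f = 728\ \mathrm{nm},$$
so one fitting machinery serves both readout kinds; inversion is by
bracketed bisection on the monotone forward map, and readouts outside the
calibrated interval are clamped to the nearest endpoint and *flagged*,
never silently extrapolated (thresholding normally removes such pixels
first; clamping keeps maps renderable while preserving auditability).

Reference solutions of known permittivity anchor the fit. For binary
mixtures (e.g. ethanol–water) the package computes reference
permittivities with the Maxwell–Garnett effective-medium relation
$$\frac{\varepsilon_{\mathrm{eff}}-\varepsilon_h}
       {\varepsilon_{\mathrm{eff}}+2\varepsilon_h}
  = \delta\,\frac{\varepsilon_i-\varepsilon_h}{\varepsilon_i+2\varepsilon_h},$$
with the majority component as host; the shipped
`ethanol_water_mixtures.csv` table carries component permittivities (80.1
and 25.3 at room temperature) and volume fractions only — effective values
are always computed, never tabulated.

**One calibration per readout kind.** The phase of a broad, skewed,
edge-truncated spectrum tracks its center of mass, which sits a few nm
from its mode (half a channel of discretization offset, minus a
skew-dependent term). Because the calibration curve is flat at high
$\varepsilon$ (d$\lambda$/d$\varepsilon \approx 0.05$ nm per
$\varepsilon_0$ at $\varepsilon = 60$ for the default model), readouts
must be inverted through a calibration built from the *same* readout
pipeline: phase readouts through a phase-calibrated model, Gaussian-fit
modes through a mode-calibrated one. Mixing branches injects a systematic
offset that the flat region amplifies into tens of permittivity units.
This mirrors experimental practice, where each analysis branch is fitted
its own calibration curve.

## From stack to statistics

1. **Thresholding** operates on the mean-intensity image (averaged over
   the full spectral range). The default is a quantile threshold at 0.5 of
   the mean-intensity distribution (the exclusion level is always recorded
   for provenance); absolute and Otsu thresholds are alternatives.
2. **Permittivity map**: per included pixel, phasor → phase → wavelength →
   $\varepsilon$, with zero-intensity pixels flagged invalid (never NaN)
   and clamped pixels flagged.
3. **Segmentation** splits included pixels into condensate and depleted
   classes on the mean-intensity image (Otsu), *not* on $\varepsilon$, to
   avoid circularity with the measured quantity. The brighter class is the
   condensate by default (the dye partitions into the dense phase); a
   polarity switch covers dye-excluding condensates. Bimodality is
   accepted when the between-class variance fraction at the split exceeds
   0.8 (a unimodal normal/Poisson histogram yields ≈ 0.64, well-separated
   phases > 0.9); otherwise a single class is returned with a warning and
   the contrast is undefined. Connected condensate components
   (8-connectivity) support per-droplet statistics, with border-touching
   droplets kept but flagged.
4. **Statistics**: per phase, the *mean phase* is converted to
   $\varepsilon$ (mean-then-convert, the per-stack statistic), with the
   median and IQR of per-pixel $\varepsilon$ reported alongside for
   boxplot-style summaries; the contrast is
   $\varepsilon_c - \varepsilon_d$. For narrow phase distributions
   (sd < 0.05 rad) the two averaging orders agree within 2% — a tested
   property. Per-phase statistics pool pixels across droplets within a
   stack; per-droplet weighting is available via the component labels.

## The synthetic stated world

The generator renders 2D scenes of circular condensate droplets (default:
three droplets of $\varepsilon_c = 5$, expected peak counts 400) on a
depleted background ($\varepsilon_d = 60$, peak counts 100 — the regime
where per-channel counts of order $10^2$ make phasor coordinates
quasi-continuous), with channel-wise Poisson shot noise and a single
integer seed controlling all draws. Pixel spectra are skewed Gaussians
with fixed skewness $\gamma = 1$ and an affine width law $\sigma$: 45 nm
at $\varepsilon = 2$ down to 35 nm at $\varepsilon = 80$ — fixtures chosen
as plausible for a naphthalene-core dye, not measured claims, and recorded
in the stack metadata. The default synthetic calibration anchors the
emission maximum at 445 nm ($\varepsilon = 2$, oil-like) and 520 nm
($\varepsilon = 80$, water-like).

The generator *pins the phasor phase*: the spectrum's location is solved
so that its discrete phasor phase maps exactly (tolerance $10^{-10}$ rad)
onto the calibrated $\lambda_{\max}$ through the phase/wavelength
relation. The spectrum's mode then sits within about a third of a channel
of the calibrated value rather than exactly on it — the price of making
the phase pipeline exactly self-consistent (see the calibration section
for why the converse choice fails). Consequently noiseless scenes recover
their generating permittivities to the inversion tolerance, and noisy
recovery errors are attributable to shot noise alone.

"Sedimenting droplet" artifacts emulate condensates drifting into the
focal plane during sequential channel acquisition: their short-wavelength
(first-acquired) channels are zeroed. This strictly inflates the apparent
phase (red-weighted center of mass) — i.e. artificially elevated apparent
permittivity — while halving the droplet's mean intensity, so the default
quantile threshold removes exactly these pixels; both effects are asserted
on fixtures.

What a green synthetic test does *not* establish: the generator has no
optics (PSF, chromatic aberration), no detector read noise, no
photobleaching, no dye-partitioning thermodynamics, and its
width/skewness laws are stand-ins — so modulus-versus-permittivity trends
must not be validated quantitatively against it, and real-data accuracy
claims remain outside the package's scope.

## Wetting mechanics

For a condensate adhering to a vesicle membrane, the three apparent
contact angles $(\theta_i, \theta_e, \theta_c)$ facing the vesicle
interior, external phase and condensate close to 360° around the contact
line (tolerance: warn above 2°, error above 5° — measurement-level slack
for confocal cross-sections). Force balance of the condensate interfacial
tension $\Sigma_{ce}$ and the two membrane tensions gives the law-of-sines
ratios
$$\Sigma_{ie}/\Sigma_{ce} = \sin\theta_c/\sin\theta_i, \qquad
  \Sigma_{ic}/\Sigma_{ce} = \sin\theta_e/\sin\theta_i,$$
whose difference is the rescaled affinity contrast
$$W/\Sigma_{ce} = \cos\theta^{in}
  = \frac{\sin\theta_e - \sin\theta_c}{\sin\theta_i},$$
with $\theta^{in}$ the intrinsic contact angle — a scale-invariant
material parameter. $W < 0$ means the membrane prefers the condensate.
Angles are accepted in degrees (the community convention) and converted
internally; angle extraction from images is out of scope — tabulated
angles enter via CSV. The linear trend of $\theta^{in}$ against the
permittivity contrast is fitted by ordinary (or inverse-variance weighted)
least squares; with no published angle values to compare against, the
trend fit is validated on synthetic data only.

## Defaults at a glance

| Parameter | Default | Units | Why |
|---|---|---|---|
| Detection axis | 416–728, 32 ch | nm | instrument geometry assumed throughout |
| Harmonic $n$ | 1 | – | standard for unimodal spectra |
| Calibrated range | [2, 80] | $\varepsilon_0$ | oil-like to water-like span |
| Debye variant | $(\varepsilon-1)/(2\varepsilon+1)$ | – | reaction-field form; others pluggable |
| Threshold | quantile 0.5 | – | exclusion level not standardized; always logged |
| Bimodality gate | $\eta^2 \ge 0.8$ | – | normal histogram gives ≈ 0.64 |
| Closure tolerance | warn 2, error 5 | deg | confocal measurement slack |
| Generator $\sigma$ law | 45 → 35 | nm | fixture; recorded in metadata |
| Generator $\gamma$ | 1 | – | fixture; recorded in metadata |
| Peak counts | 400 / 100 | counts | dye partitions into the dense phase |

## Known limitations

* Stacks are interchanged as a self-describing plain-text table, not
  TIFF/OME-TIFF (no TIFF codec among the package's dependencies);
  converting instrument exports requires one external step.
* 2D only; no z-stacks, time-lapse, flat-field or spectral-response
  correction; no multi-harmonic decomposition or spectral unmixing.
* At the flat high-permittivity end of the calibration, tiny wavelength
  errors translate into large permittivity errors; this is intrinsic to
  the physics of the readout, and per-pixel IQRs there are accordingly
  wide even in clean synthetic data.
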