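# dielmap

Quantitative mapping of **local dielectric permittivity** from
hyperspectral fluorescence stacks of an environment-sensitive
(solvatochromic) dye such as ACDAN — for biophysicists studying
biomolecular condensates, membrane wetting, and the polarity of crowded
aqueous environments.

The emission of such a dye red-shifts with the relative permittivity ε of
its immediate surroundings. A hyperspectral confocal stack records a full
emission spectrum at every pixel (here: 32 channels of 9.75 nm spanning
416–728 nm); `dielmap` converts those spectra into per-pixel ε maps and
per-phase statistics:

* **Spectral phasor transform** — the first Fourier coefficient
  `G = Σ I(c)cos(2πnc/N)/ΣI(c)`, `S = Σ I(c)sin(2πnc/N)/ΣI(c)` of each
  normalized pixel spectrum; the phase φ tracks spectral redshift, the
  modulus M spectral sharpness.
* **Skewed-Gaussian fitting** — `I(λ) = I₀ ψ((λ−μ)/σ) Φ(γ(λ−μ)/σ)` as an
  alternative readout that extracts the emission maximum λmax.
* **Lippert–Mataga calibration** — `1/λmax = a·f(ε) + b` with
  `f(ε) = (ε−1)/(2ε+1)`, fitted to reference solutions by exact linear
  least squares and inverted by bracketed bisection; the phase enters via
  `λmax = φ(λf−λ0)/2π + λ0`. Maxwell–Garnett effective-medium
  permittivities are computed for binary reference mixtures.
* **Mapping and statistics** — intensity thresholding,
  condensate/depleted segmentation (Otsu on mean intensity), per-phase
  mean-phase ε, median/IQR and the permittivity contrast εc − εd.
* **Wetting mechanics** — intrinsic contact angle
  `cos θin = (sin θe − sin θc)/sin θi`, tension ratios, affinity contrast
  `W = cos θin · Σce`, and the linear θin-vs-Δε trend fit.
* **Synthetic generator** — two-phase droplet scenes with Poisson shot
  noise, known ground truth, and "sedimenting droplet" artifacts (missing
  short-wavelength channels), so the whole pipeline is testable offline.

## Worked example

Calibrate on a synthetic 21-solution dilution series, render a noisy
two-phase scene (three ε = 5 condensate droplets on an ε = 60 background),
and recover per-phase permittivities:

```r
library(dielmap)

fm   <- forward_model()                       # synthetic dye response
refs <- generate_reference_set(seq(2, 80, length.out = 21), fm,
                               readout_kind = "phase")
cal  <- fit_calibration(refs)
cal
#> <calibration_model> 1/lambda_max = a*f(eps) + b
#>   a = -0.00111501 nm^-1, b = 0.00247019 nm^-1, variant = debye
#>   eps in [2, 80] -> lambda_max in [445.00, 520.00] nm; axis 416-728 nm

sim  <- generate_stack(scene_spec(seed = 42L), fm)
mask <- threshold_mask(sim$stack)             # median-quantile exclusion
pmap <- permittivity_map(sim$stack, cal, mask)
seg  <- segment_phases(sim$stack, mask)
phase_statistics(pmap, seg)
#>       label    n mean_phase epsilon_mean_phase epsilon_median epsilon_iqr
#>  condensate 1851   1.376443           5.003937       5.005686   0.1289257
#>    depleted 6431   2.075923          60.158025      60.210989  25.1272590
#> permittivity contrast (condensate - depleted): -55.154
```

The mean phase of each segmented phase is converted through the
calibration: the condensate reads ε ≈ 5.00 (truth 5), the depleted phase
ε ≈ 60.2 (truth 60), contrast ≈ −55. The wide depleted-phase IQR is the
flat high-ε end of the calibration amplifying per-pixel shot noise — the
per-stack mean-phase statistic is the robust quantity.

Wetting mechanics from an apparent contact-angle triple:

```r
intrinsic_contact_angle(wetting_geometry(120, 150, 90, sigma_ce = 0.5))
#> <wetting_result> theta_in = 125.26 deg (cos = -0.5774)
#>   W/Sigma_ce = -0.5774, W = -0.2887
#>   Sigma_ie/Sigma_ce = 1.1547, Sigma_ic/Sigma_ce = 0.5774
```

θin > 90° (W < 0): the membrane prefers the condensate over the external
phase.

## Command line

```sh
Rscript inst/scripts/dielmap simulate  --out sim --seed 4
Rscript inst/scripts/dielmap calibrate --references refs.csv --out cal.json
Rscript inst/scripts/dielmap stats     --stack sim/stack.tsv --calibration cal.json --out out
Rscript inst/scripts/dielmap wetting   --table angles.csv --out wetting.csv --trend trend.json
```

Each subcommand writes its outputs plus a machine-readable
`run_log.json` (config echo, seed, thresholds, version). Stacks travel as
a self-describing plain-text table (`write_stack`/`read_stack`); channel
0 is the bluest window (416–425.75 nm).

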