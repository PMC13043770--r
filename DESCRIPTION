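Package: dielmap
Title: Dielectric Permittivity Mapping from Hyperspectral Fluorescence
    Stacks by Spectral Phasor Analysis
Version: 0.1.0
Authors@R:
    person("dielmap", "developers", email = "dielmap@example.org",
           role = c("aut", "cre"))
Description: Quantitative mapping of local dielectric permittivity from
    hyperspectral image stacks of an environment-sensitive solvatochromic
    fluorophore (such as ACDAN). Implements the discrete spectral phasor
    transform with per-pixel phase and modulus, skewed-Gaussian fitting of
    emission spectra to extract the emission maximum, a Lippert-Mataga
    calibration linking spectral readouts to relative permittivity
    (including Maxwell-Garnett effective-medium permittivities for
    reference mixtures), intensity thresholding and two-phase
    condensate/depleted segmentation with permittivity-contrast statistics,
    membrane-wetting mechanics (intrinsic contact angle, tension ratios and
    affinity contrast from apparent contact-angle triples), a synthetic
    hyperspectral stack generator with known ground truth and Poisson shot
    noise, and a small command-line interface tying the pipeline together.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
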