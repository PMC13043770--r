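# Synthetic-data generator: hyperspectral stacks of two-phase
# condensate/depleted scenes with known ground truth, and synthetic
# calibration reference sets. Everything downstream is testable against
# these without any instrument data.

#' Default synthetic calibration (stand-in dye response)
#'
#' A redshift-with-permittivity calibration anchored so that the emission
#' maximum moves from 445 nm at eps = 2 (oil-like) to 520 nm at eps = 80
#' (water-like) — a realistic span for a naphthalene-core solvatochromic
#' dye inside a 416-728 nm detection window. The lumped `(a, b)` are solved
#' from those two anchors; this is a generator fixture, not a measured
#' instrument calibration.
#'
#' @param lambda_blue,lambda_red Emission maxima (nm) at the ends of
#'   `epsilon_range`.
#' @param epsilon_range Calibrated permittivity interval.
#' @param axis Detection endpoints `c(lambda0, lambdaf)` in nm.
#' @return A [calibration_model()].
#' @export
default_calibration <- function(lambda_blue = 445, lambda_red = 520,
                                epsilon_range = c(2, 80),
                                axis = c(416, 728)) {
  f_lo <- debye_f(epsilon_range[1])
  f_hi <- debye_f(epsilon_range[2])
  a <- (1 / lambda_red - 1 / lambda_blue) / (f_hi - f_lo)
  b <- 1 / lambda_blue - a * f_lo
  calibration_model(a, b, epsilon_range = epsilon_range, axis = axis)
}

#' Forward spectral model for the synthetic generator
#'
#' Couples a calibration (peak position vs permittivity) with a spectral
#' shape law: a skewed Gaussian of fixed skewness `gamma` whose width
#' follows an affine trend `sigma(eps)`, narrowing slightly from low- to
#' high-permittivity environments (default 45 nm at eps = 2 down to 35 nm
#' at eps = 80). The width law and skewness are generator fixtures.
#'
#' @param calibration A [calibration_model()] (default
#'   [default_calibration()]).
#' @param sigma_at_range Spectral widths (nm) at the two ends of the
#'   calibration's `epsilon_range`.
#' @param gamma Fixed skewness of the emission profile.
#' @return Object of class `forward_model`.
#' @export
forward_model <- function(calibration = default_calibration(),
                          sigma_at_range = c(45, 35), gamma = 1) {
  stopifnot(inherits(calibration, "calibration_model"),
            length(sigma_at_range) == 2L, all(sigma_at_range > 0))
  structure(list(calibration = calibration,
                 sigma_at_range = as.numeric(sigma_at_range),
                 gamma = gamma),
            class = "forward_model")
}

#' Spectral width at a given permittivity under a forward model
#' @param epsilon Relative permittivity, vectorized.
#' @param model A [forward_model()].
#' @return Width(s) sigma in nm.
#' @export
sigma_law <- function(epsilon, model) {
  er <- model$calibration$epsilon_range
  s <- model$sigma_at_range
  s[1] + (s[2] - s[1]) * (epsilon - er[1]) / (er[2] - er[1])
}

#' Noiseless forward spectrum at a prescribed permittivity
#'
#' Generates the expected emission spectrum of a pixel at permittivity
#' `epsilon`: a skewed Gaussian sampled at channel-center wavelengths and
#' scaled so the continuous profile peaks at `peak_counts`.
#'
#' The location parameter is chosen (by root-finding, tolerance 1e-10 rad)
#' so that the *discrete phasor phase* of the noiseless spectrum maps
#' exactly onto the calibrated emission maximum through the
#' phase/wavelength relation of the calibration axis. This makes the
#' phasor pipeline exactly self-consistent: for broad, skewed, partially
#' truncated spectra the phase tracks the spectral center of mass, not the
#' mode, so a generator that placed the mode at the calibrated wavelength
#' would introduce a systematic phase offset that the steep high-eps end
#' of the calibration amplifies into tens of permittivity units. The mode
#' of the generated spectrum consequently sits within about half a channel
#' bandwidth of the calibrated emission maximum rather than exactly on it;
#' the Gaussian-fit readout branch is calibrated on its own mode readouts
#' (see [generate_reference_set()]), mirroring the practice of fitting
#' each readout kind its own calibration curve.
#'
#' @param epsilon Relative permittivity, inside the model's range.
#' @param model A [forward_model()].
#' @param axis A [spectral_axis()].
#' @param peak_counts Peak expected photon count (default 100, the regime in
#'   which per-channel counts make phasor coordinates quasi-continuous).
#' @return A [spectrum()] of expected (noise-free) counts.
#' @export
forward_spectrum <- function(epsilon, model, axis = spectral_axis(),
                             peak_counts = 100) {
  stopifnot(inherits(model, "forward_model"),
            inherits(axis, "spectral_axis"), peak_counts >= 0)
  er <- model$calibration$epsilon_range
  if (!is.finite(epsilon) || epsilon < er[1] || epsilon > er[2])
    stop(sprintf("forward_spectrum: epsilon %g outside model range [%g, %g]",
                 epsilon, er[1], er[2]))
  lam_max <- lippert_mataga_lambda_max(epsilon, model$calibration)
  target_phase <- lambda_max_to_phase(lam_max, model$calibration$axis)
  sg <- sigma_law(epsilon, model)
  x0 <- if (model$gamma == 0) 0 else .skew_mode_std(model$gamma)
  peak_val <- stats::dnorm(x0) * stats::pnorm(model$gamma * x0)
  I0 <- peak_counts / peak_val
  lam <- channel_centers(axis)
  phase_of_mu <- function(mu)
    phasor_transform(skew_gaussian(lam, 1, mu, sg, model$gamma))$phase
  # phase is monotone in the location over the detection window
  ctr <- lam_max - sg * x0
  lo <- ctr - 4 * sg
  hi <- ctr + 2 * sg
  mu <- stats::uniroot(function(m) phase_of_mu(m) - target_phase,
                       c(lo, hi), tol = 1e-10)$root
  spectrum(skew_gaussian(lam, I0, mu, sg, model$gamma), axis)
}

#' Specify a synthetic two-phase scene
#'
#' Circular condensate droplets on a depleted-phase background. The dye
#' partitions into the dense phase, so droplets default to higher peak
#' counts than the background. Optional "sedimenting droplet" artifacts
#' reproduce out-of-focus condensates entering the plane during sequential
#' channel acquisition: their short-wavelength channels (acquired first) are
#' missing, which inflates the apparent phase.
#'
#' @param rows,cols Image size in pixels (default 128 x 128).
#' @param droplets Data frame with columns `row`, `col`, `radius` (px),
#'   `epsilon`, `peak` (expected peak counts). Overlaps are resolved by draw
#'   order (later rows win).
#' @param background_epsilon Depleted-phase permittivity (default 60).
#' @param background_peak Depleted-phase expected peak counts (default 100).
#' @param noise `"poisson"` (default) or `"none"`.
#' @param artifact_droplets Optional data frame like `droplets` with an
#'   extra column `cutoff` (0-based channel index; channels below it are
#'   zeroed).
#' @param seed Integer seed controlling all stochastic draws.
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(rows = 128L, cols = 128L,
                       droplets = data.frame(
                         row = c(38, 90, 64), col = c(40, 44, 100),
                         radius = c(14, 12, 16),
                         epsilon = c(5, 5, 5), peak = c(400, 400, 400)),
                       background_epsilon = 60, background_peak = 100,
                       noise = c("poisson", "none"),
                       artifact_droplets = NULL, seed = 1L) {
  noise <- match.arg(noise)
  droplets <- as.data.frame(droplets)
  stopifnot(all(c("row", "col", "radius", "epsilon", "peak") %in%
                  names(droplets)),
            all(droplets$radius > 0), all(droplets$peak >= 0),
            background_peak >= 0, rows >= 1, cols >= 1)
  if (!is.null(artifact_droplets)) {
    artifact_droplets <- as.data.frame(artifact_droplets)
    stopifnot(all(c("row", "col", "radius", "epsilon", "peak", "cutoff") %in%
                    names(artifact_droplets)))
  }
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 droplets = droplets,
                 background_epsilon = background_epsilon,
                 background_peak = background_peak, noise = noise,
                 artifact_droplets = artifact_droplets,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# run code under a private RNG state seeded with `seed`
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic hyperspectral stack with ground truth
#'
#' Renders the scene pixel by pixel from [forward_spectrum()] at each
#' pixel's ground-truth permittivity, applies channel-wise Poisson shot
#' noise when enabled, then zeroes the sub-cutoff channels of artifact
#' droplets. Deterministic for a fixed scene seed.
#'
#' @param scene A [scene_spec()].
#' @param model A [forward_model()].
#' @param axis A [spectral_axis()].
#' @return List with components `stack` (a [hyperspectral_stack()]),
#'   `labels` (integer matrix: 0 depleted background, 1 condensate droplet,
#'   2 artifact droplet), and `truth` (data frame of per-region generating
#'   parameters).
#' @export
generate_stack <- function(scene, model = forward_model(),
                           axis = spectral_axis()) {
  stopifnot(inherits(scene, "scene_spec"), inherits(model, "forward_model"),
            inherits(axis, "spectral_axis"))
  nr <- scene$rows; ncl <- scene$cols; nc <- axis$n_channels
  eps_map <- matrix(scene$background_epsilon, nr, ncl)
  peak_map <- matrix(scene$background_peak, nr, ncl)
  labels <- matrix(0L, nr, ncl)
  cutoff_map <- matrix(0L, nr, ncl)  # channels strictly below are zeroed
  rr <- row(eps_map); cc <- col(eps_map)
  paint <- function(d, lab) {
    for (i in seq_len(nrow(d))) {
      inside <- (rr - d$row[i])^2 + (cc - d$col[i])^2 <= d$radius[i]^2
      eps_map[inside] <<- d$epsilon[i]
      peak_map[inside] <<- d$peak[i]
      labels[inside] <<- lab
      cutoff_map[inside] <<- if (lab == 2L) as.integer(d$cutoff[i]) else 0L
    }
  }
  paint(scene$droplets, 1L)
  if (!is.null(scene$artifact_droplets)) paint(scene$artifact_droplets, 2L)

  # expected spectra per unique (epsilon, peak) pair, then scatter into cube
  key <- paste(eps_map, peak_map)
  uk <- !duplicated(key)
  spec_tab <- vapply(which(uk), function(j)
    forward_spectrum(eps_map[j], model, axis, peak_map[j])$intensities,
    numeric(nc))
  expected <- t(spec_tab[, match(key, key[uk]), drop = FALSE])  # npix x nc

  counts <- if (scene$noise == "poisson") {
    .with_seed(scene$seed,
               matrix(stats::rpois(length(expected), lambda = expected),
                      nrow(expected), nc))
  } else expected
  # missing short-wavelength channels of sedimenting (artifact) droplets
  if (any(cutoff_map > 0L)) {
    ch0 <- matrix(rep(0:(nc - 1L), each = nr * ncl), nr * ncl, nc)
    counts[ch0 < as.vector(cutoff_map)] <- 0
  }
  stack <- hyperspectral_stack(
    array(counts, dim = c(nr, ncl, nc)), axis,
    metadata = list(generator = "dielmap::generate_stack",
                    seed = scene$seed, noise = scene$noise))
  truth <- data.frame(
    region = c("background",
               if (nrow(scene$droplets)) paste0("droplet_", seq_len(nrow(scene$droplets))),
               if (!is.null(scene$artifact_droplets))
                 paste0("artifact_", seq_len(nrow(scene$artifact_droplets)))),
    label = c(0L, rep(1L, nrow(scene$droplets)),
              if (!is.null(scene$artifact_droplets))
                rep(2L, nrow(scene$artifact_droplets))),
    epsilon = c(scene$background_epsilon, scene$droplets$epsilon,
                if (!is.null(scene$artifact_droplets))
                  scene$artifact_droplets$epsilon),
    peak = c(scene$background_peak, scene$droplets$peak,
             if (!is.null(scene$artifact_droplets))
               scene$artifact_droplets$peak))
  list(stack = stack, labels = labels, truth = truth)
}

#' Generate a synthetic calibration reference series
#'
#' Emulates a solvent dilution series: for each requested permittivity a
#' readout is produced and optionally perturbed with Gaussian noise,
#' yielding a reference table ready for [fit_calibration()]. Readout kinds:
#' \describe{
#'   \item{`"lambda_max"`}{the calibrated emission maximum itself (noise-free
#'     readouts recover the generating `(a, b)` exactly);}
#'   \item{`"phase"`}{the discrete phasor phase of the generated reference
#'     spectrum, measured with [phasor_transform()] on `axis` — the same
#'     pipeline later applied to image pixels;}
#'   \item{`"mode"`}{the emission maximum extracted by fitting the generated
#'     reference spectrum with [fit_skewed_gaussian()], reported as a
#'     `lambda_max` readout. Mode readouts carry a small systematic offset
#'     relative to the phase branch (discretization and skew), which is why
#'     each branch is calibrated on its own readouts.}
#' }
#' The generating `(a, b)` are attached as attributes for recovery checks.
#'
#' @param epsilons Permittivities of the reference solutions (>= 3).
#' @param model A [forward_model()].
#' @param noise_sd Gaussian readout noise sd (nm for wavelength kinds,
#'   radians for phase; default 0).
#' @param seed Optional integer seed for the noise draws.
#' @param readout_kind `"lambda_max"` (default), `"phase"` or `"mode"`.
#' @param axis [spectral_axis()] used to synthesize spectra for the
#'   `"phase"` and `"mode"` readout kinds.
#' @return Data frame with columns `name`, `epsilon`, `source`, `readout`,
#'   `readout_kind`, and attributes `true_a`, `true_b`.
#' @export
generate_reference_set <- function(epsilons, model = forward_model(),
                                   noise_sd = 0, seed = NULL,
                                   readout_kind = c("lambda_max", "phase",
                                                    "mode"),
                                   axis = spectral_axis()) {
  stopifnot(inherits(model, "forward_model"), length(epsilons) >= 3L,
            noise_sd >= 0)
  readout_kind <- match.arg(readout_kind)
  readout <- switch(readout_kind,
    lambda_max = lippert_mataga_lambda_max(epsilons, model$calibration),
    phase = vapply(epsilons, function(e)
      phasor_transform(forward_spectrum(e, model, axis))$phase, 0),
    mode = vapply(epsilons, function(e)
      fit_skewed_gaussian(forward_spectrum(e, model, axis))$lambda_max, 0))
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) stats::rnorm(length(readout), 0, noise_sd)
             else .with_seed(seed, stats::rnorm(length(readout), 0, noise_sd))
    readout <- readout + noise
  }
  refs <- data.frame(
    name = sprintf("synthetic_ref_%02d", seq_along(epsilons)),
    epsilon = epsilons, source = "synthetic",
    readout = readout,
    readout_kind = if (readout_kind == "mode") "lambda_max" else readout_kind)
  attr(refs, "true_a") <- model$calibration$a
  attr(refs, "true_b") <- model$calibration$b
  refs
}
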