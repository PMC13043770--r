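# Core spectral data types, the discrete spectral phasor transform, and the
# skewed-Gaussian spectral fit used to extract the emission maximum.

#' Discretized emission-wavelength axis
#'
#' Describes the spectral detection grid shared by all spectra in a
#' hyperspectral acquisition: `n_channels` contiguous detection windows of
#' equal bandwidth spanning `[lambda_start, lambda_end]`. Channel index `c`
#' runs from 0 to `n_channels - 1`, with channel 0 the bluest window.
#'
#' @param lambda_start Short-wavelength edge of the detection range (nm).
#' @param lambda_end Long-wavelength edge of the detection range (nm).
#' @param n_channels Number of detection windows (integer, >= 2).
#' @return An object of class `spectral_axis` with fields `lambda_start`,
#'   `lambda_end`, `n_channels` and the derived `bandwidth` (nm).
#' @examples
#' ax <- spectral_axis(416, 728, 32)
#' ax$bandwidth        # 9.75 nm
#' channel_centers(ax)[1]
#' @export
spectral_axis <- function(lambda_start = 416, lambda_end = 728,
                          n_channels = 32L) {
  stopifnot(is.numeric(lambda_start), is.numeric(lambda_end),
            length(lambda_start) == 1L, length(lambda_end) == 1L)
  n_channels <- as.integer(n_channels)
  if (!is.finite(lambda_start) || !is.finite(lambda_end) ||
      lambda_end <= lambda_start)
    stop("spectral_axis: lambda_end must exceed lambda_start")
  if (is.na(n_channels) || n_channels < 2L)
    stop("spectral_axis: n_channels must be an integer >= 2")
  structure(
    list(lambda_start = lambda_start,
         lambda_end   = lambda_end,
         n_channels   = n_channels,
         bandwidth    = (lambda_end - lambda_start) / n_channels),
    class = "spectral_axis")
}

#' @export
print.spectral_axis <- function(x, ...) {
  cat(sprintf("<spectral_axis> %g-%g nm, %d channels (bandwidth %.4g nm)\n",
              x$lambda_start, x$lambda_end, x$n_channels, x$bandwidth))
  invisible(x)
}

#' Channel-center wavelengths of a spectral axis
#'
#' Channel `c` (0-based) covers
#' `[lambda_start + c*bw, lambda_start + (c+1)*bw]`; its center is
#' `lambda_start + (c + 0.5)*bw`. Centers, not edges, are used as the
#' wavelength grid for spectral fitting.
#'
#' @param axis A [spectral_axis()].
#' @return Numeric vector of `n_channels` wavelengths (nm).
#' @export
channel_centers <- function(axis) {
  stopifnot(inherits(axis, "spectral_axis"))
  axis$lambda_start + (seq_len(axis$n_channels) - 0.5) * axis$bandwidth
}

#' Single emission spectrum on a spectral axis
#'
#' @param intensities Nonnegative intensity per channel (arbitrary units).
#' @param axis A [spectral_axis()] whose channel count matches
#'   `length(intensities)`.
#' @return An object of class `dm_spectrum`.
#' @export
spectrum <- function(intensities, axis) {
  stopifnot(inherits(axis, "spectral_axis"), is.numeric(intensities))
  if (length(intensities) != axis$n_channels)
    stop(sprintf("spectrum: %d intensities for a %d-channel axis",
                 length(intensities), axis$n_channels))
  if (anyNA(intensities) || any(intensities < 0))
    stop("spectrum: intensities must be finite and nonnegative")
  structure(list(intensities = as.numeric(intensities), axis = axis),
            class = "dm_spectrum")
}

#' Hyperspectral image stack
#'
#' A pixel-by-channel intensity cube: a full emission spectrum is recorded at
#' every pixel. The cube is a 3D array indexed `(row, col, channel)` whose
#' channel dimension must match the axis.
#'
#' @param cube Nonnegative numeric array `(rows, cols, n_channels)`.
#' @param axis A [spectral_axis()].
#' @param pixel_size Optional pixel edge length (nm).
#' @param metadata Optional named list of free-form metadata.
#' @return An object of class `hyperspectral_stack`.
#' @export
hyperspectral_stack <- function(cube, axis, pixel_size = NULL,
                                metadata = list()) {
  stopifnot(inherits(axis, "spectral_axis"))
  if (!is.array(cube) || length(dim(cube)) != 3L)
    stop("hyperspectral_stack: cube must be a 3D array (row, col, channel)")
  if (dim(cube)[3] != axis$n_channels)
    stop(sprintf(
      "hyperspectral_stack: cube has %d channels but axis declares %d",
      dim(cube)[3], axis$n_channels))
  if (anyNA(cube) || any(cube < 0))
    stop("hyperspectral_stack: intensities must be finite and nonnegative")
  structure(list(cube = cube, axis = axis, pixel_size = pixel_size,
                 metadata = metadata),
            class = "hyperspectral_stack")
}

#' @export
print.hyperspectral_stack <- function(x, ...) {
  d <- dim(x$cube)
  cat(sprintf("<hyperspectral_stack> %d x %d px, %d channels (%g-%g nm)\n",
              d[1], d[2], d[3], x$axis$lambda_start, x$axis$lambda_end))
  invisible(x)
}

#' Mean-intensity image of a stack
#'
#' Per-pixel intensity averaged over the entire detected spectral range; the
#' image on which thresholding and phase segmentation operate.
#'
#' @param stack A [hyperspectral_stack()].
#' @return Numeric matrix `(rows, cols)`.
#' @export
mean_intensity <- function(stack) {
  stopifnot(inherits(stack, "hyperspectral_stack"))
  d <- dim(stack$cube)
  matrix(rowMeans(matrix(stack$cube, d[1] * d[2], d[3])), d[1], d[2])
}

#' Phase and modulus from phasor coordinates
#'
#' The phase is the quadrant-aware arctangent of (S, G) wrapped to
#' `[0, 2*pi)` so that phase increases monotonically with emission redshift
#' across the detection window; the modulus is `sqrt(G^2 + S^2)`.
#'
#' @param G,S Real phasor coordinates (vectorized).
#' @return List with numeric `phase` (radians, `NA` where `G = S = 0`) and
#'   `modulus`.
#' @examples
#' phase_modulus(0, 1)    # phase pi/2, modulus 1
#' phase_modulus(-1, 0)   # phase pi (not 0: quadrant-aware)
#' @export
phase_modulus <- function(G, S) {
  stopifnot(is.numeric(G), is.numeric(S), length(G) == length(S))
  modulus <- sqrt(G^2 + S^2)
  phase <- atan2(S, G) %% (2 * pi)
  undef <- modulus == 0
  if (any(undef, na.rm = TRUE)) phase[undef] <- NA_real_
  list(phase = phase, modulus = modulus)
}

#' Discrete spectral phasor transform of one spectrum
#'
#' Computes the first (or `harmonic`-th) Fourier coefficient of the
#' normalized spectrum:
#' \deqn{G = \sum_c I(c)\cos(2\pi n c/N_c) / \sum_c I(c), \qquad
#'       S = \sum_c I(c)\sin(2\pi n c/N_c) / \sum_c I(c),}
#' with channel index `c = 0, ..., Nc-1`, so that a spectrum concentrated in
#' the bluest channel has phase 0. The phase tracks the spectral center of
#' mass (redshift); the modulus tracks spectral sharpness.
#'
#' @param x A [spectrum()] or a nonnegative numeric intensity vector.
#' @param harmonic Positive integer number of trigonometric cycles spanning
#'   the detection window (default 1).
#' @return Object of class `phasor_point`: fields `G`, `S`, `phase`
#'   (radians in `[0, 2*pi)`), `modulus`, `harmonic`.
#' @export
phasor_transform <- function(x, harmonic = 1L) {
  intens <- if (inherits(x, "dm_spectrum")) x$intensities else as.numeric(x)
  harmonic <- as.integer(harmonic)
  if (is.na(harmonic) || harmonic < 1L)
    stop("phasor_transform: harmonic must be a positive integer")
  if (anyNA(intens) || any(intens < 0))
    stop("phasor_transform: intensities must be finite and nonnegative")
  tot <- sum(intens)
  if (tot <= 0)
    stop(errorCondition("phasor_transform: empty spectrum (zero total intensity)",
                        class = c("dielmap_empty_spectrum", "error", "condition")))
  nc <- length(intens)
  ang <- 2 * pi * harmonic * (seq_len(nc) - 1L) / nc
  G <- sum(intens * cos(ang)) / tot
  S <- sum(intens * sin(ang)) / tot
  pm <- phase_modulus(G, S)
  structure(list(G = G, S = S, phase = pm$phase, modulus = pm$modulus,
                 harmonic = harmonic),
            class = "phasor_point")
}

#' @export
print.phasor_point <- function(x, ...) {
  cat(sprintf("<phasor_point> G=%.4f S=%.4f phase=%.4f rad modulus=%.4f (n=%d)\n",
              x$G, x$S, x$phase, x$modulus, x$harmonic))
  invisible(x)
}

#' Per-pixel phasor transform of a hyperspectral stack
#'
#' Applies [phasor_transform()] at every pixel; pixels with zero total
#' intensity are flagged invalid (never `NaN`). The set of per-pixel phasors
#' forms the pixel cloud of the phasor plot.
#'
#' @param stack A [hyperspectral_stack()].
#' @param harmonic Positive integer harmonic (default 1).
#' @return Object of class `phasor_image` with matrices `G`, `S`, `phase`,
#'   `modulus`, logical `valid`, plus `harmonic` and the stack `axis`.
#' @export
phasor_image <- function(stack, harmonic = 1L) {
  stopifnot(inherits(stack, "hyperspectral_stack"))
  harmonic <- as.integer(harmonic)
  if (is.na(harmonic) || harmonic < 1L)
    stop("phasor_image: harmonic must be a positive integer")
  d <- dim(stack$cube)
  nc <- d[3]
  m <- matrix(stack$cube, d[1] * d[2], nc)
  tot <- rowSums(m)
  valid <- tot > 0
  ang <- 2 * pi * harmonic * (seq_len(nc) - 1L) / nc
  G <- as.vector(m %*% cos(ang))
  S <- as.vector(m %*% sin(ang))
  G[valid] <- G[valid] / tot[valid]
  S[valid] <- S[valid] / tot[valid]
  G[!valid] <- NA_real_
  S[!valid] <- NA_real_
  pm <- phase_modulus(ifelse(valid, G, 0), ifelse(valid, S, 0))
  phase <- ifelse(valid, pm$phase, NA_real_)
  modulus <- ifelse(valid, pm$modulus, NA_real_)
  shape <- function(v) matrix(v, d[1], d[2])
  structure(list(G = shape(G), S = shape(S), phase = shape(phase),
                 modulus = shape(modulus), valid = shape(valid),
                 harmonic = harmonic, axis = stack$axis),
            class = "phasor_image")
}

#' @export
print.phasor_image <- function(x, ...) {
  cat(sprintf("<phasor_image> %d x %d px, %d valid, harmonic %d\n",
              nrow(x$G), ncol(x$G), sum(x$valid), x$harmonic))
  invisible(x)
}

#' Phasor-plot scatter of a phasor image
#'
#' Draws the per-pixel (G, S) cloud inside the unit circle.
#'
#' @param x A [phasor_image()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.phasor_image <- function(x, ...) {
  graphics::plot(x$G[x$valid], x$S[x$valid], pch = ".", asp = 1,
                 xlim = c(-1, 1), ylim = c(-1, 1),
                 xlab = "G", ylab = "S", ...)
  th <- seq(0, 2 * pi, length.out = 361)
  graphics::lines(cos(th), sin(th), col = "grey60")
  invisible(x)
}

# Skewed-Gaussian emission model ---------------------------------------------

#' Skewed-Gaussian emission profile
#'
#' Evaluates
#' \deqn{I(\lambda) = I_0\, \psi\!\left(\frac{\lambda-\mu}{\sigma}\right)
#'       \Phi\!\left(\gamma \frac{\lambda-\mu}{\sigma}\right),}
#' where \eqn{\psi} is the standard normal density and \eqn{\Phi} the
#' standard normal cumulative distribution. `gamma = 0` reduces to a
#' symmetric Gaussian with mode `mu`.
#'
#' @param lambda Wavelengths (nm), vectorized.
#' @param I0 Intensity scale (> 0).
#' @param mu Location (nm).
#' @param sigma Width (nm, > 0).
#' @param gamma Skewness (dimensionless).
#' @return Intensities at `lambda`.
#' @export
skew_gaussian <- function(lambda, I0, mu, sigma, gamma) {
  x <- (lambda - mu) / sigma
  I0 * stats::dnorm(x) * stats::pnorm(gamma * x)
}

# Mode of the standardized profile dnorm(x) * pnorm(gamma * x): coarse grid
# then golden-section refinement. The mode has no closed form.
.skew_mode_std <- function(gamma, tol = 1e-10) {
  f <- function(x) stats::dnorm(x) * stats::pnorm(gamma * x)
  grid <- seq(-1.2, 1.2, by = 0.02)  # standardized mode always falls inside
  i <- which.max(f(grid))
  lo <- grid[max(1L, i - 2L)]
  hi <- grid[min(length(grid), i + 2L)]
  stats::optimize(f, c(lo, hi), maximum = TRUE, tol = tol)$maximum
}

#' Emission maximum (mode) of a skewed-Gaussian fit
#'
#' The mode of the skewed Gaussian has no closed form; it is located by a
#' coarse grid search on the standardized profile followed by local
#' refinement (tolerance 1e-10 in standardized units, well below 1e-6 nm for
#' typical widths). For `gamma = 0` the mode equals `mu`; flipping the sign
#' of `gamma` mirrors the mode about `mu`.
#'
#' @param fit A `skew_gaussian_fit` (from [fit_skewed_gaussian()]) or a list
#'   with fields `mu`, `sigma`, `gamma`.
#' @return The emission-maximum wavelength (nm).
#' @export
mode_of_skew_gaussian <- function(fit) {
  stopifnot(is.list(fit), !is.null(fit$mu), !is.null(fit$sigma))
  if (!is.finite(fit$mu) || !is.finite(fit$sigma) || fit$sigma <= 0)
    stop("mode_of_skew_gaussian: invalid parameters")
  g <- if (is.null(fit$gamma)) 0 else fit$gamma
  if (g == 0) return(fit$mu)
  fit$mu + fit$sigma * .skew_mode_std(g)
}

#' Fit a skewed Gaussian to an emission spectrum
#'
#' Least-squares fit of the skewed-Gaussian profile (see [skew_gaussian()])
#' to intensities at channel-center wavelengths. Initialization: `mu` at the
#' intensity-weighted mean wavelength, `sigma` at the weighted standard
#' deviation, `gamma = 0`, and `I0` scaled to the observed peak; `I0` and
#' `sigma` are kept positive via log-parameterization. The emission maximum
#' `lambda_max` is then located with [mode_of_skew_gaussian()].
#'
#' @param spec A [spectrum()].
#' @param init Optional list with starting values `I0`, `mu`, `sigma`,
#'   `gamma`.
#' @return Object of class `skew_gaussian_fit`: `I0`, `mu`, `sigma`,
#'   `gamma`, derived `lambda_max` (nm), `residual_norm` and a `converged`
#'   flag with optimizer `message`.
#' @export
fit_skewed_gaussian <- function(spec, init = NULL) {
  stopifnot(inherits(spec, "dm_spectrum"))
  y <- spec$intensities
  lam <- channel_centers(spec$axis)
  if (sum(y > 0) < 5L)
    stop(errorCondition(
      "fit_skewed_gaussian: need >= 5 channels with positive intensity",
      class = c("dielmap_insufficient_data", "error", "condition")))
  if (diff(range(y)) <= 0)
    stop(errorCondition("fit_skewed_gaussian: degenerate spectrum (flat)",
                        class = c("dielmap_degenerate_spectrum", "error",
                                  "condition")))
  w <- y / sum(y)
  mu0 <- sum(w * lam)
  sd0 <- sqrt(max(sum(w * (lam - mu0)^2), spec$axis$bandwidth^2))
  obj <- function(p) {
    r <- y - skew_gaussian(lam, exp(p[1]), p[2], exp(p[3]), p[4])
    sum(r * r)
  }
  # The profile is a scaled skew-normal, so skewness trades off against
  # location and a single symmetric start can stall in a local optimum.
  # Multi-start over trial skewness with method-of-moments location/scale
  # (delta = g/sqrt(1+g^2); mean offset delta*sqrt(2/pi), variance shrink
  # 1 - 2*delta^2/pi), keeping the best least-squares solution.
  starts <- if (is.null(init)) {
    lapply(c(0, 1, -1, 3, -3), function(g) {
      delta <- g / sqrt(1 + g^2)
      sg <- sd0 / sqrt(1 - 2 * delta^2 / pi)
      mu <- mu0 - sg * delta * sqrt(2 / pi)
      x0 <- if (g == 0) 0 else .skew_mode_std(g)
      I0 <- max(y) / (stats::dnorm(x0) * stats::pnorm(g * x0))
      c(log(I0), mu, log(sg), g)
    })
  } else {
    list(c(log(init$I0), init$mu, log(init$sigma), init$gamma))
  }
  opt <- NULL
  for (p0 in starts) {
    o <- stats::optim(p0, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
    # second pass guards against premature BFGS stops
    o2 <- stats::optim(o$par, obj, method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-14))
    if (o2$value < o$value) o <- o2
    if (is.null(opt) || o$value < opt$value) opt <- o
  }
  # Gauss-Newton polish: BFGS can stall on the correlated mu/gamma ridge;
  # nls (port, zero-residual-safe scaleOffset) sharpens the optimum.
  polished <- tryCatch({
    nf <- stats::nls(
      y ~ skew_gaussian(lam, I0, mu, sigma, gamma),
      start = list(I0 = exp(opt$par[1]), mu = opt$par[2],
                   sigma = exp(opt$par[3]), gamma = opt$par[4]),
      algorithm = "port",
      lower = c(I0 = 1e-12, mu = -Inf, sigma = 1e-6, gamma = -Inf),
      control = stats::nls.control(maxiter = 200, scaleOffset = 1,
                                   warnOnly = TRUE))
    cf <- stats::coef(nf)
    list(par = c(log(cf[["I0"]]), cf[["mu"]], log(cf[["sigma"]]),
                 cf[["gamma"]]),
         value = sum(stats::residuals(nf)^2),
         convergence = opt$convergence, message = opt$message)
  }, error = function(e) NULL)
  if (!is.null(polished) && polished$value <= opt$value)
    opt[c("par", "value")] <- polished[c("par", "value")]
  p <- opt$par
  fit <- structure(
    list(I0 = exp(p[1]), mu = p[2], sigma = exp(p[3]), gamma = p[4],
         lambda_max = NA_real_, residual_norm = sqrt(opt$value),
         converged = opt$convergence == 0,
         message = if (opt$convergence == 0) "converged"
                   else sprintf("optim convergence code %d: %s",
                                opt$convergence,
                                if (is.null(opt$message)) "" else opt$message)),
    class = "skew_gaussian_fit")
  if (!fit$converged)
    warning(sprintf("fit_skewed_gaussian: %s", fit$message))
  fit$lambda_max <- mode_of_skew_gaussian(fit)
  fit
}

#' @export
print.skew_gaussian_fit <- function(x, ...) {
  cat(sprintf(
    "<skew_gaussian_fit> I0=%.4g mu=%.2f nm sigma=%.2f nm gamma=%.3f\n",
    x$I0, x$mu, x$sigma, x$gamma))
  cat(sprintf("  lambda_max=%.3f nm  residual_norm=%.4g  %s\n",
              x$lambda_max, x$residual_norm, x$message))
  invisible(x)
}
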