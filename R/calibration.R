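# Lippert-Mataga calibration: the bijective mapping between the dye's
# spectral readout (emission maximum or phasor phase) and relative dielectric
# permittivity, plus Maxwell-Garnett mixture permittivities used when
# building reference solutions.

#' Generalized Debye / orientation-polarizability function
#'
#' Default variant is the Onsager reaction-field form
#' `f(eps) = (eps - 1) / (2*eps + 1)`, strictly increasing in `eps`, 0 at
#' `eps = 1` and approaching 1/2 as `eps` grows. The refractive-index term
#' of the classic orientation polarizability is absorbed into the
#' calibration intercept. A custom variant may be supplied as a function.
#'
#' @param epsilon Relative permittivity (>= 1), vectorized.
#' @param variant `"debye"` (default) or a function of `epsilon`.
#' @return Dimensionless polarity function value(s).
#' @examples
#' debye_f(2)   # 1/5
#' @export
debye_f <- function(epsilon, variant = "debye") {
  if (any(!is.finite(epsilon)) || any(epsilon < 1))
    stop("debye_f: epsilon must be finite and >= 1")
  if (is.function(variant)) return(variant(epsilon))
  switch(variant,
         debye = (epsilon - 1) / (2 * epsilon + 1),
         stop(sprintf("debye_f: unknown variant '%s'", variant)))
}

#' Construct a calibration model
#'
#' The forward model is linear in the polarity function:
#' `1/lambda_max = a * f(eps) + b`, with lumped slope `a` (nm^-1) housing
#' the dipole-moment and molecular-volume prefactor and lumped intercept
#' `b` (nm^-1). A redshift-with-permittivity dye has `a < 0`. Strict
#' monotonicity of `lambda_max(eps)` over `epsilon_range` (required for a
#' unique inversion) is verified on construction.
#'
#' @param a Lumped slope (nm^-1).
#' @param b Lumped intercept (nm^-1).
#' @param debye_variant Polarity-function variant (see [debye_f()]).
#' @param epsilon_range Calibrated permittivity interval (default `c(2, 80)`).
#' @param axis Detection-window endpoints `c(lambda0, lambdaf)` in nm used by
#'   the phase/wavelength relation (default `c(416, 728)`).
#' @param diagnostics Optional fit diagnostics (stored verbatim).
#' @return Object of class `calibration_model`.
#' @export
calibration_model <- function(a, b, debye_variant = "debye",
                              epsilon_range = c(2, 80),
                              axis = c(416, 728), diagnostics = NULL) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1L, length(b) == 1L,
            length(epsilon_range) == 2L, length(axis) == 2L,
            epsilon_range[1] < epsilon_range[2], axis[1] < axis[2])
  model <- structure(
    list(a = a, b = b, debye_variant = debye_variant,
         epsilon_range = as.numeric(epsilon_range), axis = as.numeric(axis),
         diagnostics = diagnostics, monotone = NA),
    class = "calibration_model")
  eg <- seq(epsilon_range[1], epsilon_range[2], length.out = 257)
  lg <- lippert_mataga_lambda_max(eg, model)
  dl <- diff(lg)
  model$monotone <- all(dl > 0) || all(dl < 0)
  if (!model$monotone)
    warning("calibration_model: lambda_max(epsilon) is not strictly monotone over epsilon_range; inversion is ill-defined")
  model
}

#' @export
print.calibration_model <- function(x, ...) {
  lm_lo <- lippert_mataga_lambda_max(x$epsilon_range[1], x)
  lm_hi <- lippert_mataga_lambda_max(x$epsilon_range[2], x)
  cat(sprintf("<calibration_model> 1/lambda_max = a*f(eps) + b\n"))
  cat(sprintf("  a = %.6g nm^-1, b = %.6g nm^-1, variant = %s\n", x$a, x$b,
              if (is.function(x$debye_variant)) "<function>" else x$debye_variant))
  cat(sprintf("  eps in [%g, %g] -> lambda_max in [%.2f, %.2f] nm; axis %g-%g nm\n",
              x$epsilon_range[1], x$epsilon_range[2], lm_lo, lm_hi,
              x$axis[1], x$axis[2]))
  invisible(x)
}

#' Forward calibration: emission maximum at a given permittivity
#'
#' Evaluates `lambda_max = 1 / (a * f(eps) + b)`.
#'
#' @param epsilon Relative permittivity, vectorized.
#' @param model A [calibration_model()].
#' @return Emission-maximum wavelength(s) in nm.
#' @export
lippert_mataga_lambda_max <- function(epsilon, model) {
  stopifnot(inherits(model, "calibration_model"))
  inv <- model$a * debye_f(epsilon, model$debye_variant) + model$b
  if (any(inv <= 0))
    stop("lippert_mataga_lambda_max: nonphysical model (a*f(eps) + b <= 0)")
  1 / inv
}

#' Phasor phase to emission-maximum wavelength
#'
#' Linear relation mapping the phase across one full turn onto the detection
#' window: `lambda_max = phase * (lambdaf - lambda0) / (2*pi) + lambda0`,
#' so phase 0 maps to the blue edge and `2*pi` to the red edge.
#'
#' @param phase Phase in radians, in `[0, 2*pi]`, vectorized.
#' @param axis Detection endpoints `c(lambda0, lambdaf)` in nm.
#' @return Wavelength(s) in nm.
#' @export
phase_to_lambda_max <- function(phase, axis = c(416, 728)) {
  stopifnot(length(axis) == 2L, axis[1] < axis[2])
  if (any(!is.finite(phase)) || any(phase < 0 | phase > 2 * pi))
    stop("phase_to_lambda_max: phase must lie in [0, 2*pi]")
  phase * (axis[2] - axis[1]) / (2 * pi) + axis[1]
}

#' Emission-maximum wavelength to phasor phase
#'
#' Inverse of [phase_to_lambda_max()].
#'
#' @param lambda_max Wavelength(s) in nm, inside the detection window.
#' @param axis Detection endpoints `c(lambda0, lambdaf)` in nm.
#' @return Phase(s) in radians.
#' @export
lambda_max_to_phase <- function(lambda_max, axis = c(416, 728)) {
  stopifnot(length(axis) == 2L, axis[1] < axis[2])
  if (any(!is.finite(lambda_max)) ||
      any(lambda_max < axis[1] | lambda_max > axis[2]))
    stop("lambda_max_to_phase: wavelength outside detection window")
  (lambda_max - axis[1]) / (axis[2] - axis[1]) * 2 * pi
}

#' Fit a calibration model to reference solutions
#'
#' Linear least squares of `1/lambda_max` against `f(eps)` (the space in
#' which the forward model is exactly linear, so the fit needs no iteration).
#' Phase readouts are first converted to wavelengths through the axis
#' relation, so a single model serves both readout kinds. Monotonicity of
#' the fitted forward map is verified and reported.
#'
#' @param refs Data frame of reference solutions with columns `epsilon`,
#'   `readout` and `readout_kind` (`"lambda_max"` or `"phase"`); optional
#'   `name`, `source`.
#' @param debye_variant Polarity-function variant.
#' @param epsilon_range Calibrated interval for the resulting model.
#' @param axis Detection endpoints `c(lambda0, lambdaf)` in nm.
#' @return A [calibration_model()] whose `diagnostics` hold per-reference
#'   residuals (in `1/nm`) and the reference table.
#' @export
fit_calibration <- function(refs, debye_variant = "debye",
                            epsilon_range = c(2, 80), axis = c(416, 728)) {
  refs <- as.data.frame(refs)
  if (!all(c("epsilon", "readout") %in% names(refs)))
    stop("fit_calibration: refs needs columns 'epsilon' and 'readout'")
  if (is.null(refs$readout_kind)) refs$readout_kind <- "lambda_max"
  if (nrow(refs) < 3L)
    stop(errorCondition(
      sprintf("fit_calibration: insufficient references (%d < 3)", nrow(refs)),
      class = c("dielmap_insufficient_data", "error", "condition")))
  if (any(refs$epsilon <= 1))
    stop("fit_calibration: reference permittivities must exceed 1")
  if (diff(range(refs$epsilon)) <= 0)
    stop(errorCondition(
      "fit_calibration: degenerate permittivity range in references",
      class = c("dielmap_insufficient_data", "error", "condition")))
  lam <- refs$readout
  is_phase <- refs$readout_kind == "phase"
  if (any(is_phase))
    lam[is_phase] <- phase_to_lambda_max(refs$readout[is_phase], axis)
  fe <- debye_f(refs$epsilon, debye_variant)
  fit <- stats::lm.fit(cbind(f = fe, intercept = 1), 1 / lam)
  a <- unname(fit$coefficients["f"])
  b <- unname(fit$coefficients["intercept"])
  diag <- list(residuals = unname(fit$residuals),
               rms_residual = sqrt(mean(fit$residuals^2)),
               n_references = nrow(refs),
               references = refs)
  calibration_model(a, b, debye_variant = debye_variant,
                    epsilon_range = epsilon_range, axis = axis,
                    diagnostics = diag)
}

#' Invert a spectral readout to relative permittivity
#'
#' Solves the monotone forward map for `eps` by bracketed bisection on the
#' calibrated interval. Readouts mapping outside the calibrated
#' `lambda_max` interval are clamped to the nearest range endpoint and
#' flagged (attribute `"clamped"`), never silently extrapolated. Phase
#' readouts are converted via [phase_to_lambda_max()] first, so the two
#' readout kinds are exactly consistent.
#'
#' @param readout Emission maxima (nm) or phases (radians), vectorized.
#' @param model A [calibration_model()].
#' @param kind `"lambda_max"` (default) or `"phase"`.
#' @param tol Absolute tolerance on `eps` (default 1e-9).
#' @return Numeric permittivities with logical attribute `clamped`.
#' @export
invert_to_epsilon <- function(readout, model, kind = c("lambda_max", "phase"),
                              tol = 1e-9) {
  stopifnot(inherits(model, "calibration_model"))
  kind <- match.arg(kind)
  if (!model$monotone)
    stop("invert_to_epsilon: model is not monotone; inversion undefined")
  lam <- if (kind == "phase") phase_to_lambda_max(readout, model$axis)
         else readout
  if (any(!is.finite(lam)) ||
      any(lam < model$axis[1] | lam > model$axis[2]))
    stop("invert_to_epsilon: readout outside the detection window")
  e_lo <- model$epsilon_range[1]
  e_hi <- model$epsilon_range[2]
  l_lo <- lippert_mataga_lambda_max(e_lo, model)
  l_hi <- lippert_mataga_lambda_max(e_hi, model)
  increasing <- l_hi > l_lo
  lmin <- min(l_lo, l_hi); lmax <- max(l_lo, l_hi)
  clamped <- lam < lmin | lam > lmax
  target <- pmin(pmax(lam, lmin), lmax)
  # vectorized bisection on the monotone forward map
  lo <- rep(e_lo, length(target))
  hi <- rep(e_hi, length(target))
  n_iter <- ceiling(log2((e_hi - e_lo) / tol))
  for (i in seq_len(n_iter)) {
    mid <- (lo + hi) / 2
    lm_mid <- lippert_mataga_lambda_max(mid, model)
    go_up <- if (increasing) lm_mid < target else lm_mid > target
    lo <- ifelse(go_up, mid, lo)
    hi <- ifelse(go_up, hi, mid)
  }
  eps <- (lo + hi) / 2
  # snap exactly to the endpoints where the readout fell outside the range
  eps[clamped & target == lmin] <- if (increasing) e_lo else e_hi
  eps[clamped & target == lmax] <- if (increasing) e_hi else e_lo
  attr(eps, "clamped") <- clamped
  eps
}

#' Maxwell-Garnett effective permittivity of a two-component mixture
#'
#' Solves the Maxwell-Garnett effective-medium relation
#' \deqn{\frac{\varepsilon_{\mathrm{eff}}-\varepsilon_h}
#'            {\varepsilon_{\mathrm{eff}}+2\varepsilon_h}
#'       = \delta\,\frac{\varepsilon_i-\varepsilon_h}
#'                      {\varepsilon_i+2\varepsilon_h}}
#' for the effective permittivity of spherical inclusions (permittivity
#' `epsilon_inclusion`, volume fraction `delta`) in a host
#' (`epsilon_host`). Used to assign permittivities to binary reference
#' mixtures such as ethanol-water, with the majority component as host.
#'
#' @param epsilon_host Host relative permittivity (> 0).
#' @param epsilon_inclusion Inclusion relative permittivity (> 0).
#' @param volume_fraction Inclusion volume fraction `delta` in `[0, 1]`,
#'   vectorized.
#' @return Effective relative permittivity, between host and inclusion
#'   values and monotone in `delta`.
#' @export
maxwell_garnett <- function(epsilon_host, epsilon_inclusion, volume_fraction) {
  stopifnot(is.numeric(epsilon_host), is.numeric(epsilon_inclusion),
            epsilon_host > 0, epsilon_inclusion > 0)
  if (any(!is.finite(volume_fraction)) ||
      any(volume_fraction < 0 | volume_fraction > 1))
    stop("maxwell_garnett: volume_fraction must lie in [0, 1]")
  r <- (epsilon_inclusion - epsilon_host) / (epsilon_inclusion + 2 * epsilon_host)
  epsilon_host * (1 + 2 * volume_fraction * r) / (1 - volume_fraction * r)
}
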