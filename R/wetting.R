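# Membrane-wetting mechanics: intrinsic contact angle from apparent
# contact-angle triples, membrane tension ratios, affinity contrast, and the
# linear trend of intrinsic angle vs permittivity contrast.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Apparent contact-angle geometry of a vesicle-condensate pair
#'
#' The three apparent angles face the vesicle interior (`theta_i`), the
#' external depleted phase (`theta_e`) and the condensate (`theta_c`) in a
#' confocal cross-section; they must close to 360 degrees around the
#' contact line. Closure violations up to `warn_tol` degrees pass silently,
#' between `warn_tol` and `err_tol` they warn (measurement-level slack),
#' beyond `err_tol` they error.
#'
#' @param theta_i,theta_e,theta_c Apparent contact angles (degrees), each in
#'   (0, 360).
#' @param sigma_ce Optional condensate-buffer interfacial tension
#'   (force/length) enabling an absolute affinity contrast.
#' @param warn_tol,err_tol Closure tolerances (degrees; defaults 2 and 5).
#' @return Object of class `wetting_geometry`.
#' @export
wetting_geometry <- function(theta_i, theta_e, theta_c, sigma_ce = NULL,
                             warn_tol = 2, err_tol = 5) {
  ang <- c(theta_i, theta_e, theta_c)
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 360))
    stop("wetting_geometry: angles must lie in (0, 360) degrees")
  gap <- abs(sum(ang) - 360)
  if (gap > err_tol)
    stop(errorCondition(
      sprintf("wetting_geometry: angles sum to %.2f deg (|gap| %.2f > %g): inconsistent angle triple",
              sum(ang), gap, err_tol),
      class = c("dielmap_inconsistent_angles", "error", "condition")))
  if (gap > warn_tol)
    warning(sprintf("wetting_geometry: angle closure off by %.2f deg", gap))
  if (!is.null(sigma_ce) && (!is.finite(sigma_ce) || sigma_ce <= 0))
    stop("wetting_geometry: sigma_ce must be positive")
  if (abs(sin(.deg2rad(theta_i))) < 1e-12)
    stop("wetting_geometry: sin(theta_i) = 0, degenerate geometry")
  structure(list(theta_i = unname(theta_i), theta_e = unname(theta_e),
                 theta_c = unname(theta_c), sigma_ce = sigma_ce),
            class = "wetting_geometry")
}

#' Intrinsic contact angle and wetting mechanics from an angle triple
#'
#' Resolves the force balance of the three tensions pulling along the
#' contact line. The law of sines for the tension triangle gives the
#' membrane tension ratios
#' \deqn{\Sigma_{ie}/\Sigma_{ce} = \sin\theta_c / \sin\theta_i, \qquad
#'       \Sigma_{ic}/\Sigma_{ce} = \sin\theta_e / \sin\theta_i,}
#' and their difference yields the rescaled affinity contrast
#' \deqn{W/\Sigma_{ce} = \cos\theta^{in}
#'   = (\sin\theta_e - \sin\theta_c)/\sin\theta_i,}
#' where the intrinsic contact angle \eqn{\theta^{in}} is a scale-invariant
#' material parameter: it depends only on the angle triple, not on vesicle
#' or condensate size. `W` is negative when the membrane prefers the
#' condensate phase over the external buffer and positive otherwise.
#'
#' @param geom A [wetting_geometry()].
#' @return Object of class `wetting_result`: `theta_in` (degrees),
#'   `cos_theta_in`, `W_over_sigma` (equal to `cos_theta_in`), `W`
#'   (force/length, `NA` without `sigma_ce`), `tension_ratio_ie`,
#'   `tension_ratio_ic`.
#' @export
intrinsic_contact_angle <- function(geom) {
  stopifnot(inherits(geom, "wetting_geometry"))
  si <- sin(.deg2rad(geom$theta_i))
  se <- sin(.deg2rad(geom$theta_e))
  sc <- sin(.deg2rad(geom$theta_c))
  ct <- (se - sc) / si
  if (abs(ct) > 1 + 1e-9)
    stop(errorCondition(
      sprintf("intrinsic_contact_angle: inconsistent angle triple, |cos theta_in| = %.6f > 1",
              abs(ct)),
      class = c("dielmap_inconsistent_angles", "error", "condition")))
  ct <- min(max(ct, -1), 1)
  structure(list(
    theta_in = .rad2deg(acos(ct)),
    cos_theta_in = ct,
    W_over_sigma = ct,
    W = if (is.null(geom$sigma_ce)) NA_real_ else ct * geom$sigma_ce,
    tension_ratio_ie = sc / si,
    tension_ratio_ic = se / si),
    class = "wetting_result")
}

#' @export
print.wetting_result <- function(x, ...) {
  cat(sprintf("<wetting_result> theta_in = %.2f deg (cos = %.4f)\n",
              x$theta_in, x$cos_theta_in))
  cat(sprintf("  W/Sigma_ce = %.4f%s\n", x$W_over_sigma,
              if (is.na(x$W)) "" else sprintf(", W = %.4g", x$W)))
  cat(sprintf("  Sigma_ie/Sigma_ce = %.4f, Sigma_ic/Sigma_ce = %.4f\n",
              x$tension_ratio_ie, x$tension_ratio_ic))
  invisible(x)
}

#' Affinity contrast from the intrinsic contact angle
#'
#' `W = cos(theta_in) * sigma_ce`: the difference in membrane adhesion free
#' energy per unit area between condensate and depleted phase, in units of
#' the condensate interfacial tension.
#'
#' @param theta_in Intrinsic contact angle (degrees, in `[0, 180]`).
#' @param sigma_ce Condensate-buffer interfacial tension (> 0).
#' @return Affinity contrast `W` (same units as `sigma_ce`).
#' @export
affinity_contrast <- function(theta_in, sigma_ce) {
  if (any(!is.finite(theta_in)) || any(theta_in < 0 | theta_in > 180))
    stop("affinity_contrast: theta_in must lie in [0, 180] degrees")
  if (any(!is.finite(sigma_ce)) || any(sigma_ce <= 0))
    stop("affinity_contrast: sigma_ce must be positive")
  cos(.deg2rad(theta_in)) * sigma_ce
}

#' Linear trend of intrinsic contact angle vs permittivity contrast
#'
#' Ordinary (or, with uncertainties, inverse-variance weighted) least
#' squares of `theta_in = slope * delta_epsilon + intercept`.
#'
#' @param delta_epsilon Permittivity contrasts (condensate minus depleted).
#' @param theta_in Intrinsic contact angles (degrees).
#' @param uncertainties Optional per-point standard deviations of
#'   `theta_in` (degrees); weights are `1/uncertainty^2`.
#' @return Object of class `trend_fit`: `slope` (deg per permittivity
#'   unit), `intercept` (deg), standard errors `slope_se`, `intercept_se`,
#'   `residuals`, `fitted`, `n`.
#' @export
fit_wetting_trend <- function(delta_epsilon, theta_in, uncertainties = NULL) {
  stopifnot(is.numeric(delta_epsilon), is.numeric(theta_in),
            length(delta_epsilon) == length(theta_in))
  n <- length(theta_in)
  if (n < 3L)
    stop(errorCondition(
      sprintf("fit_wetting_trend: insufficient data (%d < 3 points)", n),
      class = c("dielmap_insufficient_data", "error", "condition")))
  if (stats::var(delta_epsilon) <= 0)
    stop("fit_wetting_trend: zero variance in delta_epsilon, singular fit")
  w <- if (is.null(uncertainties)) NULL else {
    stopifnot(length(uncertainties) == n, all(uncertainties > 0))
    1 / uncertainties^2
  }
  df <- data.frame(x = delta_epsilon, y = theta_in)
  fit <- if (is.null(w)) stats::lm(y ~ x, data = df)
         else stats::lm(y ~ x, data = df, weights = w)
  cf <- suppressWarnings(summary(fit))$coefficients  # exact fits warn
  structure(list(slope = unname(cf["x", "Estimate"]),
                 intercept = unname(cf["(Intercept)", "Estimate"]),
                 slope_se = unname(cf["x", "Std. Error"]),
                 intercept_se = unname(cf["(Intercept)", "Std. Error"]),
                 residuals = unname(stats::residuals(fit)),
                 fitted = unname(stats::fitted(fit)), n = n),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "<trend_fit> theta_in = %.4g * delta_eps + %.4g (SE %.3g, %.3g; n = %d)\n",
    x$slope, x$intercept, x$slope_se, x$intercept_se, x$n))
  invisible(x)
}

#' Process a table of measured contact-angle triples
#'
#' Row-wise application of [wetting_geometry()] + [intrinsic_contact_angle()].
#' Rows with inconsistent angle triples are flagged (`ok = FALSE`, reason
#' recorded) rather than aborting the batch; a warning summarizes them.
#'
#' @param tab Data frame with columns `theta_i_deg`, `theta_e_deg`,
#'   `theta_c_deg` and optional `condition_id`, `sigma_ce`,
#'   `delta_epsilon`.
#' @return Input table augmented with `theta_in_deg`, `cos_theta_in`, `W`,
#'   `tension_ratio_ie`, `tension_ratio_ic`, `ok`, `note`.
#' @export
process_wetting_table <- function(tab) {
  tab <- as.data.frame(tab)
  need <- c("theta_i_deg", "theta_e_deg", "theta_c_deg")
  if (!all(need %in% names(tab)))
    stop(sprintf("process_wetting_table: missing columns: %s",
                 paste(setdiff(need, names(tab)), collapse = ", ")))
  out <- tab
  out$theta_in_deg <- out$cos_theta_in <- out$W <-
    out$tension_ratio_ie <- out$tension_ratio_ic <- NA_real_
  out$ok <- FALSE
  out$note <- ""
  for (i in seq_len(nrow(tab))) {
    res <- tryCatch({
      g <- withCallingHandlers(
        wetting_geometry(tab$theta_i_deg[i], tab$theta_e_deg[i],
                         tab$theta_c_deg[i],
                         sigma_ce = if ("sigma_ce" %in% names(tab) &&
                                        is.finite(tab$sigma_ce[i]))
                           tab$sigma_ce[i] else NULL),
        warning = function(w) invokeRestart("muffleWarning"))
      intrinsic_contact_angle(g)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$note[i] <- conditionMessage(res)
    } else {
      out$theta_in_deg[i] <- res$theta_in
      out$cos_theta_in[i] <- res$cos_theta_in
      out$W[i] <- res$W
      out$tension_ratio_ie[i] <- res$tension_ratio_ie
      out$tension_ratio_ic[i] <- res$tension_ratio_ic
      out$ok[i] <- TRUE
    }
  }
  if (any(!out$ok))
    warning(sprintf("process_wetting_table: %d of %d rows flagged inconsistent",
                    sum(!out$ok), nrow(out)))
  out
}
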