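# From a hyperspectral stack to permittivity maps and per-phase statistics:
# intensity thresholding, per-pixel phasor -> permittivity conversion,
# condensate/depleted segmentation, permittivity contrast.

# Otsu's threshold on a numeric vector (maximizes between-class variance on
# a 256-bin histogram). Returns a value strictly inside the data range.
otsu_threshold <- function(v, n_bins = 256L) {
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) <= 0) return(rng[1])
  h <- graphics::hist(v, breaks = seq(rng[1], rng[2], length.out = n_bins + 1L),
                      plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w1 <- cumsum(p)
  m1 <- cumsum(p * mids)
  mt <- m1[length(m1)]
  bcv <- (mt * w1 - m1)^2 / (w1 * (1 - w1))
  bcv[!is.finite(bcv)] <- -Inf
  k <- which.max(bcv)
  (mids[k] + mids[min(k + 1L, length(mids))]) / 2
}

#' Intensity-based pixel exclusion mask
#'
#' Computes an inclusion mask on the mean-intensity image (per-pixel mean
#' over the full spectral range). Low-signal pixels — background junk and
#' sedimenting droplets with missing short-wavelength channels — fall below
#' the threshold and are excluded from all downstream analysis. The method
#' and effective threshold are recorded for provenance.
#'
#' @param stack A [hyperspectral_stack()].
#' @param method `"quantile"` (default; `value` is the quantile of the
#'   mean-intensity distribution, default 0.5), `"absolute"` (`value` is an
#'   intensity in a.u.), or `"otsu"` (value ignored).
#' @param value Threshold parameter, per `method`.
#' @return Object of class `pixel_mask`: logical matrix `include`, the
#'   effective `threshold_value` (a.u.) and `method`.
#' @export
threshold_mask <- function(stack, method = c("quantile", "absolute", "otsu"),
                           value = 0.5) {
  stopifnot(inherits(stack, "hyperspectral_stack"))
  method <- match.arg(method)
  mi <- mean_intensity(stack)
  thr <- switch(method,
    quantile = {
      if (!is.finite(value) || value <= 0 || value >= 1)
        stop("threshold_mask: quantile value must lie in (0, 1)")
      stats::quantile(mi, value, names = FALSE)
    },
    absolute = value,
    otsu = otsu_threshold(mi))
  include <- mi >= thr
  if (!any(include))
    warning("threshold_mask: threshold excludes every pixel")
  structure(list(include = include, threshold_value = thr, method = method),
            class = "pixel_mask")
}

#' @export
print.pixel_mask <- function(x, ...) {
  cat(sprintf("<pixel_mask> %d/%d pixels included (%s threshold %.4g a.u.)\n",
              sum(x$include), length(x$include), x$method, x$threshold_value))
  invisible(x)
}

#' Per-pixel permittivity map
#'
#' The full pixel pipeline: phasor transform, phase, phase-to-wavelength,
#' calibration inversion. Pixels outside the mask or with zero signal carry
#' no permittivity value; pixels whose readout falls outside the calibrated
#' range are clamped to the range endpoint and flagged.
#'
#' @param stack A [hyperspectral_stack()].
#' @param model A [calibration_model()].
#' @param mask Optional [threshold_mask()]; default includes all pixels.
#' @param harmonic Phasor harmonic (default 1).
#' @return Object of class `permittivity_map`: matrices `epsilon` (NA where
#'   invalid/excluded), logical `clamped` and `valid`, the `model`, the
#'   `phasor` image, and the `mask` used.
#' @export
permittivity_map <- function(stack, model, mask = NULL, harmonic = 1L) {
  stopifnot(inherits(stack, "hyperspectral_stack"),
            inherits(model, "calibration_model"))
  d <- dim(stack$cube)
  if (is.null(mask)) {
    mask <- structure(list(include = matrix(TRUE, d[1], d[2]),
                           threshold_value = -Inf, method = "absolute"),
                      class = "pixel_mask")
  }
  stopifnot(inherits(mask, "pixel_mask"),
            all(dim(mask$include) == d[1:2]))
  ph <- phasor_image(stack, harmonic)
  valid <- ph$valid & mask$include
  eps <- matrix(NA_real_, d[1], d[2])
  clamped <- matrix(FALSE, d[1], d[2])
  if (!any(valid)) {
    warning("permittivity_map: no valid included pixels")
  } else {
    e <- invert_to_epsilon(ph$phase[valid], model, kind = "phase")
    eps[valid] <- e
    clamped[valid] <- attr(e, "clamped")
  }
  structure(list(epsilon = eps, clamped = clamped, valid = valid,
                 model = model, phasor = ph, mask = mask),
            class = "permittivity_map")
}

#' @export
print.permittivity_map <- function(x, ...) {
  cat(sprintf("<permittivity_map> %d x %d px, %d valid (%d clamped)\n",
              nrow(x$epsilon), ncol(x$epsilon), sum(x$valid),
              sum(x$clamped)))
  if (any(x$valid))
    cat(sprintf("  epsilon: median %.2f, IQR [%.2f, %.2f]\n",
                stats::median(x$epsilon[x$valid]),
                stats::quantile(x$epsilon[x$valid], 0.25),
                stats::quantile(x$epsilon[x$valid], 0.75)))
  invisible(x)
}

#' Permittivity map as image
#' @param x A [permittivity_map()].
#' @param ... Passed to [graphics::image()].
#' @export
plot.permittivity_map <- function(x, ...) {
  graphics::image(t(x$epsilon)[, nrow(x$epsilon):1], useRaster = TRUE,
                  col = grDevices::hcl.colors(64, "viridis"),
                  axes = FALSE, ...)
  invisible(x)
}

#' Two-phase segmentation of included pixels
#'
#' Splits the included pixels into condensate and depleted classes on the
#' mean-intensity image (Otsu's bimodal histogram split). Because the dye
#' partitions into the dense phase, the brighter class is labeled
#' condensate by default; `polarity = "dim"` inverts the assignment for
#' systems where the dye is excluded from the condensate. Segmentation uses
#' intensity, not permittivity, to avoid circularity with the quantity
#' being measured.
#'
#' If the included-intensity distribution shows no usable bimodality
#' (between-class variance fraction below 0.8 at the Otsu split, or an
#' empty class) all included pixels are assigned to a single class with a
#' warning; the permittivity contrast is then undefined.
#'
#' @param stack A [hyperspectral_stack()].
#' @param mask A [threshold_mask()] (non-empty).
#' @param polarity `"bright"` (default: condensate = brighter class) or
#'   `"dim"`.
#' @return Object of class `phase_segmentation`: integer matrix `labels`
#'   (0 excluded, 1 depleted, 2 condensate), per-label `counts`, the class
#'   `split_value`, `polarity`, and logical `bimodal`.
#' @export
segment_phases <- function(stack, mask, polarity = c("bright", "dim")) {
  stopifnot(inherits(stack, "hyperspectral_stack"),
            inherits(mask, "pixel_mask"))
  polarity <- match.arg(polarity)
  if (!any(mask$include))
    stop("segment_phases: mask excludes every pixel")
  mi <- mean_intensity(stack)
  v <- mi[mask$include]
  labels <- matrix(0L, nrow(mi), ncol(mi))
  bimodal <- diff(range(v)) > 0
  split <- NA_real_
  if (bimodal) {
    split <- otsu_threshold(v)
    hi <- v >= split
    n_hi <- sum(hi); n_lo <- sum(!hi)
    if (n_hi == 0L || n_lo == 0L) {
      bimodal <- FALSE
    } else {
      # between-class variance fraction at the Otsu split: ~0.64 for a
      # unimodal normal/Poisson histogram, > 0.9 for separated phases
      w1 <- n_lo / length(v)
      eta2 <- w1 * (1 - w1) * (mean(v[hi]) - mean(v[!hi]))^2 / stats::var(v)
      if (!is.finite(eta2) || eta2 < 0.8) bimodal <- FALSE
    }
  }
  if (!bimodal) {
    warning("segment_phases: included intensities are not bimodal; single-class result, contrast undefined")
    labels[mask$include] <- if (polarity == "bright") 2L else 1L
  } else {
    bright <- mask$include & (mi >= split)
    dim_px <- mask$include & (mi < split)
    if (polarity == "bright") {
      labels[bright] <- 2L; labels[dim_px] <- 1L
    } else {
      labels[bright] <- 1L; labels[dim_px] <- 2L
    }
  }
  structure(list(labels = labels,
                 counts = c(excluded = sum(labels == 0L),
                            depleted = sum(labels == 1L),
                            condensate = sum(labels == 2L)),
                 split_value = split, polarity = polarity,
                 bimodal = bimodal),
            class = "phase_segmentation")
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat(sprintf(
    "<phase_segmentation> condensate %d px, depleted %d px, excluded %d px\n",
    x$counts["condensate"], x$counts["depleted"], x$counts["excluded"]))
  if (!x$bimodal) cat("  (single-class: no usable bimodality)\n")
  invisible(x)
}

#' Connected condensate components
#'
#' Labels 8-connected components of the condensate class, for per-droplet
#' statistics. Components touching the image border are kept but flagged.
#'
#' @param seg A [segment_phases()] result.
#' @return List with integer matrix `component` (0 = not condensate) and a
#'   data frame `components` (id, n_pixels, touches_border).
#' @export
condensate_components <- function(seg) {
  stopifnot(inherits(seg, "phase_segmentation"))
  m <- seg$labels == 2L
  nr <- nrow(m); ncl <- ncol(m)
  comp <- matrix(0L, nr, ncl)
  nxt <- 0L
  idx <- which(m)
  for (start in idx) {
    if (comp[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    comp[start] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      r0 <- (p - 1L) %% nr + 1L; c0 <- (p - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        r <- r0 + dr; c <- c0 + dc
        if (r < 1L || r > nr || c < 1L || c > ncl) next
        q <- (c - 1L) * nr + r
        if (m[q] && comp[q] == 0L) { comp[q] <- nxt; queue <- c(queue, q) }
      }
    }
  }
  info <- if (nxt > 0L) {
    do.call(rbind, lapply(seq_len(nxt), function(k) {
      px <- which(comp == k)
      r <- (px - 1L) %% nr + 1L; c <- (px - 1L) %/% nr + 1L
      data.frame(id = k, n_pixels = length(px),
                 touches_border = any(r == 1L | r == nr | c == 1L | c == ncl))
    }))
  } else data.frame(id = integer(), n_pixels = integer(),
                    touches_border = logical())
  list(component = comp, components = info)
}

#' Per-phase permittivity statistics and contrast
#'
#' For each phase label: the mean phasor phase over its pixels, the
#' permittivity obtained by converting that mean phase through the
#' calibration (mean-then-convert, the per-stack statistic), plus the
#' median and interquartile range of per-pixel permittivities for
#' boxplot-style reporting. The permittivity contrast is the condensate
#' minus depleted value of the mean-phase permittivity, defined only when
#' both phases are present.
#'
#' @param pmap A [permittivity_map()] (carries the calibration model and
#'   phasor image).
#' @param seg A [segment_phases()] result of matching dimensions.
#' @return Object of class `phase_stats`: data frame `per_label` (label, n,
#'   mean_phase, epsilon_mean_phase, epsilon_median, epsilon_iqr) and
#'   scalar `contrast` (`NA` when undefined).
#' @export
phase_statistics <- function(pmap, seg) {
  stopifnot(inherits(pmap, "permittivity_map"),
            inherits(seg, "phase_segmentation"),
            all(dim(pmap$epsilon) == dim(seg$labels)))
  one <- function(lab_code, lab_name) {
    sel <- seg$labels == lab_code & pmap$valid
    if (!any(sel)) return(NULL)
    mp <- mean(pmap$phasor$phase[sel])
    e_mp <- as.numeric(invert_to_epsilon(mp, pmap$model, kind = "phase"))
    e_px <- pmap$epsilon[sel]
    data.frame(label = lab_name, n = sum(sel), mean_phase = mp,
               epsilon_mean_phase = e_mp,
               epsilon_median = stats::median(e_px),
               epsilon_iqr = stats::IQR(e_px))
  }
  per_label <- rbind(one(2L, "condensate"), one(1L, "depleted"))
  contrast <- NA_real_
  if (!is.null(per_label) && nrow(per_label) == 2L)
    contrast <- per_label$epsilon_mean_phase[per_label$label == "condensate"] -
      per_label$epsilon_mean_phase[per_label$label == "depleted"]
  structure(list(per_label = per_label, contrast = contrast),
            class = "phase_stats")
}

#' @export
print.phase_stats <- function(x, ...) {
  print(x$per_label, row.names = FALSE)
  cat(sprintf("permittivity contrast (condensate - depleted): %s\n",
              if (is.na(x$contrast)) "undefined"
              else sprintf("%.3f", x$contrast)))
  invisible(x)
}
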