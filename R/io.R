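# Readers/writers. Hyperspectral stacks are interchanged as a plain-text
# channel-column table with a small self-describing header (no binary TIFF
# dependency is assumed); reference tables, stats and wetting tables are
# CSV; calibration models and trend fits are JSON.

#' Write a hyperspectral stack to a plain-text file
#'
#' Format: header lines `#dielmap-stack v1`, `#lambda_start=`,
#' `#lambda_end=`, `#n_channels=`, `#rows=`, `#cols=`, `#pixel_size=`,
#' followed by a tab-separated table with one row per pixel (R column-major
#' pixel order) and one column per channel, channel 0 (the bluest window,
#' e.g. 416-425.75 nm on the default axis) first. Integer count data
#' round-trips exactly.
#'
#' @param stack A [hyperspectral_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "hyperspectral_stack"))
  d <- dim(stack$cube)
  ax <- stack$axis
  header <- c("#dielmap-stack v1",
              sprintf("#lambda_start=%.10g", ax$lambda_start),
              sprintf("#lambda_end=%.10g", ax$lambda_end),
              sprintf("#n_channels=%d", ax$n_channels),
              sprintf("#rows=%d", d[1]),
              sprintf("#cols=%d", d[2]),
              sprintf("#pixel_size=%s",
                      if (is.null(stack$pixel_size)) "NA"
                      else sprintf("%.10g", stack$pixel_size)))
  writeLines(header, path)
  m <- matrix(stack$cube, d[1] * d[2], d[3])
  colnames(m) <- sprintf("ch%02d", 0:(d[3] - 1L))
  data.table::fwrite(data.table::as.data.table(m), path, sep = "\t",
                     append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a hyperspectral stack written by [write_stack()]
#'
#' @param path Input file path.
#' @param n_channels Optional expected channel count; a mismatch is a
#'   structural error naming both counts.
#' @return A [hyperspectral_stack()].
#' @export
read_stack <- function(path, n_channels = NULL) {
  if (!file.exists(path)) stop(sprintf("read_stack: no such file: %s", path))
  head_lines <- readLines(path, n = 8L)
  if (!length(head_lines) || head_lines[1] != "#dielmap-stack v1")
    stop(sprintf("read_stack: %s is not a dielmap stack file", path))
  hdr <- head_lines[startsWith(head_lines, "#") & grepl("=", head_lines)]
  kv <- do.call(rbind, strsplit(sub("^#", "", hdr), "=", fixed = TRUE))
  vals <- stats::setNames(kv[, 2], kv[, 1])
  nc <- as.integer(vals["n_channels"])
  if (!is.null(n_channels) && nc != as.integer(n_channels))
    stop(sprintf("read_stack: file has %d channels but %d expected",
                 nc, as.integer(n_channels)))
  rows <- as.integer(vals["rows"]); cols <- as.integer(vals["cols"])
  m <- as.matrix(data.table::fread(path, skip = length(hdr) + 1L,
                                   header = TRUE, sep = "\t"))
  if (ncol(m) != nc || nrow(m) != rows * cols)
    stop(sprintf("read_stack: table is %d x %d, header declares %d x %d pixels x %d channels",
                 nrow(m), ncol(m), rows, cols, nc))
  ps <- vals["pixel_size"]
  hyperspectral_stack(
    array(m, dim = c(rows, cols, nc)),
    spectral_axis(as.numeric(vals["lambda_start"]),
                  as.numeric(vals["lambda_end"]), nc),
    pixel_size = if (identical(unname(ps), "NA")) NULL else as.numeric(ps))
}

#' Write a spectrum as two-column CSV (wavelength_nm, intensity)
#' @param spec A [spectrum()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "dm_spectrum"))
  utils::write.csv(data.frame(wavelength_nm = channel_centers(spec$axis),
                              intensity = spec$intensities),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a reference-solution table from CSV
#'
#' Expected columns: `name`, `epsilon`, `source`, `readout`,
#' `readout_kind` (`"lambda_max"` or `"phase"`).
#'
#' @param path CSV path.
#' @return Data frame of references.
#' @export
read_references <- function(path) {
  if (!file.exists(path))
    stop(sprintf("read_references: no such file: %s", path))
  refs <- as.data.frame(data.table::fread(path))
  if (!all(c("epsilon", "readout") %in% names(refs)))
    stop("read_references: need at least columns 'epsilon' and 'readout'")
  refs
}

#' Serialize a calibration model to JSON
#' @param model A [calibration_model()] (built-in variant only).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  if (is.function(model$debye_variant))
    stop("write_calibration: function variants are not serializable")
  jsonlite::write_json(
    list(format = "dielmap-calibration-v1",
         a = model$a, b = model$b, debye_variant = model$debye_variant,
         epsilon_range = model$epsilon_range, axis = model$axis,
         diagnostics = model$diagnostics[c("residuals", "rms_residual",
                                           "n_references")]),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a calibration model from JSON
#' @param path JSON path written by [write_calibration()].
#' @return A [calibration_model()].
#' @export
read_calibration <- function(path) {
  if (!file.exists(path))
    stop(sprintf("read_calibration: no such file: %s", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$format, "dielmap-calibration-v1"))
    stop(sprintf("read_calibration: %s is not a dielmap calibration file",
                 path))
  calibration_model(j$a, j$b, debye_variant = j$debye_variant,
                    epsilon_range = j$epsilon_range, axis = j$axis,
                    diagnostics = j$diagnostics)
}

#' Read a contact-angle table from CSV
#'
#' Expected columns: `condition_id`, `theta_i_deg`, `theta_e_deg`,
#' `theta_c_deg`, optional `sigma_ce`, `delta_epsilon`.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_wetting_table <- function(path) {
  if (!file.exists(path))
    stop(sprintf("read_wetting_table: no such file: %s", path))
  as.data.frame(data.table::fread(path))
}

#' Write a trend fit to JSON
#' @param fit A `trend_fit` from [fit_wetting_trend()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_trend_fit <- function(fit, path) {
  stopifnot(inherits(fit, "trend_fit"))
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
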