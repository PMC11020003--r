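#' Resample spectra onto the fixed analysis grid
#'
#' Linear interpolation between neighbouring native samples; no
#' extrapolation -- every spectrum must cover the full grid span.
#'
#' @param set A `drs_set` (typically calibrated reflectance).
#' @param grid Target [wavelength_grid()] (default 450--1000 nm, 1922
#'   points).
#' @return A `drs_set` on the grid axis.
#' @export
resample_to_grid <- function(set, grid = wavelength_grid()) {
  stopifnot(inherits(set, "drs_set"), inherits(grid, "wavelength_grid"))
  wl_in <- set$wavelengths
  if (min(wl_in) > grid$start + 1e-9 || max(wl_in) < grid$stop - 1e-9) {
    abort(
      sprintf(
        "spectrum span [%.2f, %.2f] nm does not cover the grid [%g, %g] nm; missing %s",
        min(wl_in), max(wl_in), grid$start, grid$stop,
        paste(c(
          if (min(wl_in) > grid$start) sprintf("[%g, %.2f]", grid$start, min(wl_in)),
          if (max(wl_in) < grid$stop) sprintf("[%.2f, %g]", max(wl_in), grid$stop)
        ), collapse = " and ")
      ),
      class = "drspec_coverage_error"
    )
  }
  wl_out <- grid_points(grid)
  if (length(wl_in) == length(wl_out) && isTRUE(all.equal(wl_in, wl_out))) {
    out <- set$intensities
  } else {
    out <- t(apply(set$intensities, 1, function(v) {
      approx(wl_in, v, xout = wl_out, method = "linear", rule = 1)$y
    }))
  }
  drs_set(wl_out, out, set$meta, snv_applied = set$snv_applied,
          calibrated = set$calibrated)
}

#' Standard normal variate (SNV) normalisation
#'
#' Each spectrum is centred to mean zero and scaled to unit sample standard
#' deviation (divisor n-1). The calibrated reflectance values are kept on
#' the returned set (field `reflectance`) because haemoglobin-saturation
#' unmixing needs a physical reflectance scale.
#'
#' @param set A `drs_set`.
#' @return The SNV-normalised `drs_set` (`snv_applied = TRUE`).
#' @export
snv_normalize <- function(set) {
  stopifnot(inherits(set, "drs_set"))
  m <- rowMeans(set$intensities)
  s <- apply(set$intensities, 1, sd)
  if (any(s <= 0)) {
    abort(sprintf("zero-variance spectrum (index %d) cannot be SNV-normalised",
                  which(s <= 0)[1]),
          class = "drspec_degenerate_error")
  }
  vals <- sweep(sweep(set$intensities, 1, m, `-`), 1, s, `/`)
  drs_set(set$wavelengths, vals, set$meta, snv_applied = TRUE,
          calibrated = FALSE,
          reflectance = if (set$calibrated) set$intensities else set$reflectance)
}

#' Robust outlier detection across a spectrum set
#'
#' Each spectrum is summarised by one residual -- its mean intensity over
#' the shared axis -- so the rule removes whole aberrant acquisitions (air
#' gaps, detector saturation) rather than single wavelengths. A spectrum is
#' flagged when its residual lies strictly more than `threshold_factor`
#' times the (unscaled) median absolute deviation away from the median of
#' the residuals. The 25th and 75th residual percentiles are reported for
#' diagnostics; they play no part in the flagging rule.
#'
#' @param set A `drs_set` with at least 3 spectra.
#' @param threshold_factor MAD multiplier (default 1.5).
#' @return An `outlier_report`: a tibble with `spectrum`, `residual`,
#'   `outlier`, plus attributes `median_residual`, `mad`, `q25`, `q75`,
#'   `threshold_factor`.
#' @export
detect_outliers <- function(set, threshold_factor = 1.5) {
  stopifnot(inherits(set, "drs_set"))
  if (n_spectra(set) < 3) {
    abort("outlier detection needs at least 3 spectra", class = "drspec_argument_error")
  }
  res <- rowMeans(set$intensities)
  med <- median(res)
  mad_raw <- median(abs(res - med))
  flags <- abs(res - med) > threshold_factor * mad_raw
  out <- tibble(spectrum = seq_along(res), residual = res, outlier = flags)
  attr(out, "median_residual") <- med
  attr(out, "mad") <- mad_raw
  attr(out, "q25") <- unname(quantile(res, 0.25))
  attr(out, "q75") <- unname(quantile(res, 0.75))
  attr(out, "threshold_factor") <- threshold_factor
  class(out) <- c("outlier_report", class(out))
  out
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf(
    "<outlier_report> %d spectra, %d flagged | median %.4g, MAD %.4g, q25 %.4g, q75 %.4g, factor %.2g\n",
    nrow(x), sum(x$outlier), attr(x, "median_residual"), attr(x, "mad"),
    attr(x, "q25"), attr(x, "q75"), attr(x, "threshold_factor")
  ))
  NextMethod()
}

#' Full preprocessing pipeline for one spectrum set
#'
#' Composition, in order: white/dark calibration, resampling to the
#' analysis grid, MAD outlier removal, SNV normalisation. Outliers are
#' judged on physical reflectance, before SNV erases scale.
#'
#' Outlier rejection operates within each acquisition group (patient x
#' label by default), since the artefacts it targets -- air gaps, probe
#' lift-off, detector saturation -- corrupt individual acquisitions within
#' a session; pooling across patients would instead flag legitimate
#' inter-patient variability. Groups smaller than 3 spectra are kept
#' unfiltered.
#'
#' @param set A `drs_set` of raw counts (with attached or supplied
#'   references) or already-calibrated reflectance.
#' @param refs Optional [reference_set()].
#' @param grid Target [wavelength_grid()].
#' @param mad_factor MAD multiplier for outlier removal.
#' @param group_by Metadata columns defining acquisition groups for
#'   outlier detection; `NULL` treats the whole set as one group.
#' @return SNV-normalised `drs_set` of the surviving spectra, with the
#'   outlier report attached as attribute `outlier_report`.
#' @export
preprocess_set <- function(set, refs = NULL, grid = wavelength_grid(),
                           mad_factor = 1.5,
                           group_by = c("patient_id", "label")) {
  stopifnot(inherits(set, "drs_set"))
  if (n_spectra(set) == 0) {
    abort("empty spectrum set", class = "drspec_argument_error")
  }
  if (!set$calibrated) {
    set <- compute_reflectance(set, refs %||% set$refs)
  }
  set <- resample_to_grid(set, grid)
  grp <- if (is.null(group_by)) {
    rep("all", n_spectra(set))
  } else {
    do.call(paste, c(set$meta[group_by], sep = "\r"))
  }
  reports <- lapply(unique(grp), function(g) {
    idx <- which(grp == g)
    if (length(idx) < 3) {
      return(tibble(spectrum = idx,
                    residual = rowMeans(set$intensities[idx, , drop = FALSE]),
                    outlier = FALSE))
    }
    r <- detect_outliers(set[idx], mad_factor)
    r$spectrum <- idx
    r
  })
  report <- bind_rows(lapply(reports, as_tibble))
  report <- report[order(report$spectrum), ]
  attr(report, "threshold_factor") <- mad_factor
  keep <- report$spectrum[!report$outlier]
  if (length(keep) == 0) {
    abort("all spectra flagged as outliers", class = "drspec_degenerate_error")
  }
  out <- snv_normalize(set[keep])
  attr(out, "outlier_report") <- report
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
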