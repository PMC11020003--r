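#' Construct a spectrum set
#'
#' A `drs_set` is the package's container for a collection of spectra that
#' share one wavelength axis: an `n_spectra x n_wavelengths` intensity
#' matrix behind a tabular metadata surface (one tibble row per spectrum
#' with `patient_id`, `label`, `acquisition_index`). Labels are restricted
#' to `"normal"`, `"tumour"` and `"unknown"`.
#'
#' @param wavelengths Strictly ascending numeric vector (nm).
#' @param intensities Numeric matrix, one row per spectrum, `ncol ==
#'   length(wavelengths)`. A single spectrum may be given as a vector.
#' @param meta Tibble/data frame with columns `patient_id`, `label`,
#'   `acquisition_index`; defaults are filled in when omitted.
#' @param snv_applied Logical flag: values are SNV-normalised.
#' @param calibrated Logical flag: values are calibrated reflectance.
#' @param refs Optional [reference_set()] carried with raw instrument counts.
#' @param reflectance Optional matrix of calibrated reflectance kept
#'   alongside SNV-normalised values (used by saturation unmixing).
#' @return A `drs_set`.
#' @export
drs_set <- function(wavelengths, intensities, meta = NULL,
                    snv_applied = FALSE, calibrated = FALSE,
                    refs = NULL, reflectance = NULL) {
  wavelengths <- as.numeric(wavelengths)
  if (is.null(dim(intensities))) intensities <- matrix(intensities, nrow = 1)
  intensities <- as.matrix(intensities)
  if (length(wavelengths) < 2) {
    abort("need at least 2 wavelengths", class = "drspec_argument_error")
  }
  if (any(diff(wavelengths) <= 0)) {
    abort("wavelengths must be strictly ascending", class = "drspec_format_error")
  }
  if (ncol(intensities) != length(wavelengths)) {
    abort("intensity columns must match wavelength count", class = "drspec_argument_error")
  }
  if (any(!is.finite(intensities))) {
    abort("intensities must be finite", class = "drspec_argument_error")
  }
  n <- nrow(intensities)
  if (is.null(meta)) {
    meta <- tibble(
      patient_id = rep("unknown", n),
      label = rep("unknown", n),
      acquisition_index = seq_len(n)
    )
  }
  meta <- as_tibble(meta)
  if (nrow(meta) != n) {
    abort("meta rows must match spectrum count", class = "drspec_argument_error")
  }
  bad <- setdiff(unique(meta$label), c("normal", "tumour", "unknown"))
  if (length(bad) > 0) {
    abort(
      sprintf(
        "unknown label token(s): %s; accepted tokens are 'normal', 'tumour', 'unknown'",
        paste(bad, collapse = ", ")
      ),
      class = "drspec_format_error"
    )
  }
  structure(
    list(
      wavelengths = wavelengths, intensities = intensities, meta = meta,
      snv_applied = isTRUE(snv_applied), calibrated = isTRUE(calibrated),
      refs = refs, reflectance = reflectance
    ),
    class = "drs_set"
  )
}

#' Number of spectra in a set
#' @param set A `drs_set`.
#' @export
n_spectra <- function(set) {
  stopifnot(inherits(set, "drs_set"))
  nrow(set$intensities)
}

#' Subset a spectrum set by spectrum index
#' @param x A `drs_set`.
#' @param i Spectrum indices (rows).
#' @param ... Unused.
#' @export
`[.drs_set` <- function(x, i, ...) {
  drs_set(
    x$wavelengths, x$intensities[i, , drop = FALSE], x$meta[i, , drop = FALSE],
    snv_applied = x$snv_applied, calibrated = x$calibrated, refs = x$refs,
    reflectance = if (!is.null(x$reflectance)) x$reflectance[i, , drop = FALSE]
  )
}

#' @export
print.drs_set <- function(x, ...) {
  cat(sprintf(
    "<drs_set> %d spectra x %d wavelengths (%.1f-%.1f nm)%s%s\n",
    nrow(x$intensities), length(x$wavelengths),
    min(x$wavelengths), max(x$wavelengths),
    if (x$calibrated) ", calibrated" else "",
    if (x$snv_applied) ", SNV" else ""
  ))
  lab <- table(x$meta$label)
  cat("  labels:", paste(names(lab), lab, sep = "=", collapse = " "),
      "| patients:", length(unique(x$meta$patient_id)), "\n")
  invisible(x)
}

#' Long-format view of a spectrum set
#'
#' One row per (spectrum, wavelength) pair, carrying the spectrum metadata.
#'
#' @param x A `drs_set`.
#' @param ... Unused.
#' @return A tibble with columns `spectrum`, `patient_id`, `label`,
#'   `acquisition_index`, `wavelength`, `value`.
#' @export
tidy.drs_set <- function(x, ...) {
  n <- nrow(x$intensities)
  tibble(
    spectrum = rep(seq_len(n), each = length(x$wavelengths)),
    patient_id = rep(x$meta$patient_id, each = length(x$wavelengths)),
    label = rep(x$meta$label, each = length(x$wavelengths)),
    acquisition_index = rep(x$meta$acquisition_index, each = length(x$wavelengths)),
    wavelength = rep(x$wavelengths, times = n),
    value = as.vector(t(x$intensities))
  )
}

#' @export
glance.drs_set <- function(x, ...) {
  tibble(
    n_spectra = nrow(x$intensities),
    n_wavelengths = length(x$wavelengths),
    n_patients = length(unique(x$meta$patient_id)),
    n_tumour = sum(x$meta$label == "tumour"),
    n_normal = sum(x$meta$label == "normal"),
    snv_applied = x$snv_applied,
    calibrated = x$calibrated
  )
}

#' Spectra overview plot
#'
#' Per-class mean spectrum with a thin line per individual spectrum
#' (down-sampled to at most `max_spectra` lines).
#'
#' @param object A `drs_set`.
#' @param max_spectra Maximum individual spectra drawn.
#' @param ... Unused.
#' @export
autoplot.drs_set <- function(object, max_spectra = 50, ...) {
  long <- tidy(object)
  keep <- unique(long$spectrum)
  if (length(keep) > max_spectra) {
    keep <- keep[seq(1, length(keep), length.out = max_spectra)]
  }
  means <- long %>%
    group_by(.data$label, .data$wavelength) %>%
    summarise(value = mean(.data$value), .groups = "drop")
  ggplot(mapping = aes(x = .data$wavelength, y = .data$value, colour = .data$label)) +
    geom_line(
      data = filter(long, .data$spectrum %in% keep),
      aes(group = .data$spectrum), alpha = 0.15, linewidth = 0.2
    ) +
    geom_line(data = means, linewidth = 1) +
    labs(x = "wavelength (nm)", y = "intensity", colour = "tissue") +
    theme_minimal()
}
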