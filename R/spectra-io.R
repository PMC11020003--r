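#' White/dark reference pair for reflectance calibration
#'
#' @param white One-spectrum `drs_set` (or numeric vector) measured on a
#'   white reflectance standard.
#' @param dark One-spectrum `drs_set` (or numeric vector) of the dark field.
#' @return A `reference_set`.
#' @export
reference_set <- function(white, dark) {
  as_vec <- function(x, axis = NULL) {
    if (inherits(x, "drs_set")) {
      if (nrow(x$intensities) != 1) {
        abort("reference must be a single spectrum", class = "drspec_argument_error")
      }
      list(wl = x$wavelengths, v = as.numeric(x$intensities[1, ]))
    } else {
      list(wl = axis, v = as.numeric(x))
    }
  }
  w <- as_vec(white)
  d <- as_vec(dark, w$wl)
  if (length(w$v) != length(d$v) ||
      (!is.null(w$wl) && !is.null(d$wl) && !isTRUE(all.equal(w$wl, d$wl)))) {
    abort("white and dark must share one wavelength axis", class = "drspec_argument_error")
  }
  if (any(w$v - d$v <= 0)) {
    abort("white - dark must be positive at every wavelength",
          class = "drspec_calibration_error")
  }
  structure(list(wavelengths = w$wl, white = w$v, dark = d$v),
            class = "reference_set")
}

#' Calibrate raw counts to reflectance
#'
#' Standard white/dark calibration: at every wavelength,
#' `R = (I - D) / (W - D)`. Values outside \[0, 1\] produced by noise are
#' kept, not clipped (SNV later removes scale and offset; clipping would
#' bias shape features).
#'
#' @param set A `drs_set` of raw counts sharing the references' axis. If
#'   `refs` is omitted, references attached to the set are used.
#' @param refs A [reference_set()].
#' @return The calibrated `drs_set` (flag `calibrated = TRUE`).
#' @export
compute_reflectance <- function(set, refs = set$refs) {
  stopifnot(inherits(set, "drs_set"))
  if (is.null(refs)) {
    abort("no reference_set supplied or attached", class = "drspec_argument_error")
  }
  stopifnot(inherits(refs, "reference_set"))
  if (length(refs$white) != length(set$wavelengths) ||
      (!is.null(refs$wavelengths) &&
       !isTRUE(all.equal(refs$wavelengths, set$wavelengths)))) {
    abort("sample and reference wavelength axes differ", class = "drspec_argument_error")
  }
  denom <- refs$white - refs$dark
  refl <- sweep(sweep(set$intensities, 2, refs$dark, `-`), 2, denom, `/`)
  drs_set(set$wavelengths, refl, set$meta, calibrated = TRUE)
}

#' Write / read spectrum sets in the DRSSPEC/1 columnar text format
#'
#' Plain-text, diff-able format: a `# DRSSPEC/1` magic line, one comment
#' line per spectrum carrying its metadata, a tab-separated header
#' (`wavelength_nm`, `s1`, `s2`, ...), then one row per wavelength. Flags
#' (`snv_applied`, `calibrated`) travel in a `# flags` comment.
#'
#' @param set A `drs_set`.
#' @param path Output / input file path.
#' @return `write_spectra` returns `path` invisibly; `read_spectra` a
#'   `drs_set`.
#' @export
write_spectra <- function(set, path) {
  stopifnot(inherits(set, "drs_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# DRSSPEC/1", con)
  writeLines(sprintf("# flags\tsnv_applied=%d\tcalibrated=%d",
                     as.integer(set$snv_applied), as.integer(set$calibrated)), con)
  for (i in seq_len(nrow(set$intensities))) {
    writeLines(sprintf(
      "# spectrum\t%d\tpatient_id=%s\tlabel=%s\tacquisition_index=%d",
      i, set$meta$patient_id[i], set$meta$label[i],
      as.integer(set$meta$acquisition_index[i])
    ), con)
  }
  writeLines(paste(c("wavelength_nm", paste0("s", seq_len(nrow(set$intensities)))),
                   collapse = "\t"), con)
  body <- cbind(set$wavelengths, t(set$intensities))
  writeLines(apply(format(body, digits = 12, trim = TRUE, scientific = FALSE),
                   1, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || lines[1] != "# DRSSPEC/1") {
    abort("not a DRSSPEC/1 file (missing magic header)", class = "drspec_format_error")
  }
  is_comment <- startsWith(lines, "#")
  comments <- lines[is_comment]
  flags <- c(snv_applied = FALSE, calibrated = FALSE)
  fl <- grep("^# flags", comments, value = TRUE)
  if (length(fl) == 1) {
    flags["snv_applied"] <- grepl("snv_applied=1", fl)
    flags["calibrated"] <- grepl("calibrated=1", fl)
  }
  spec_lines <- grep("^# spectrum\t", comments, value = TRUE)
  parse_kv <- function(line, key) sub(sprintf(".*%s=([^\t]*).*", key), "\\1", line)
  meta <- tibble(
    patient_id = vapply(spec_lines, parse_kv, "", key = "patient_id", USE.NAMES = FALSE),
    label = vapply(spec_lines, parse_kv, "", key = "label", USE.NAMES = FALSE),
    acquisition_index = as.integer(
      vapply(spec_lines, parse_kv, "", key = "acquisition_index", USE.NAMES = FALSE)
    )
  )
  body <- lines[!is_comment]
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "wavelength_nm") {
    abort("missing wavelength_nm header column", class = "drspec_format_error")
  }
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  widths <- lengths(rows)
  if (any(widths != length(header))) {
    abort(sprintf("ragged row at line %d: expected %d fields, found %d",
                  which(!is_comment)[1 + which(widths != length(header))[1]],
                  length(header), widths[widths != length(header)][1]),
          class = "drspec_format_error")
  }
  num <- matrix(as.numeric(unlist(rows)), ncol = length(header), byrow = TRUE)
  if (any(is.na(num))) {
    abort("non-numeric value in data block", class = "drspec_format_error")
  }
  wl <- num[, 1]
  if (any(diff(wl) <= 0)) {
    abort(sprintf("wavelength column not strictly ascending (first violation after line %d)",
                  which(!is_comment)[1] + which(diff(wl) <= 0)[1]),
          class = "drspec_format_error")
  }
  if (nrow(meta) != length(header) - 1) {
    abort("spectrum metadata count does not match data columns",
          class = "drspec_format_error")
  }
  drs_set(wl, t(num[, -1, drop = FALSE]), meta,
          snv_applied = flags[["snv_applied"]], calibrated = flags[["calibrated"]])
}
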