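#' Shape-based spectral features
#'
#' Extracts, per spectrum: intensity and wavelength of the greatest peak,
#' intensity and wavelength of the secondary peak, mean intensity in the
#' 480--550, 580--700 and 450--720 nm regions, and the haemoglobin
#' saturation coefficient -- nine features in total.
#'
#' Peaks are local maxima (strictly greater than both neighbours) of the
#' spectrum after a light moving-average smooth (`smooth_window` grid
#' points, ~4.3 nm at the default grid) that suppresses per-point noise;
#' reported intensities are read from the unsmoothed values at the detected
#' positions. The secondary peak is the best local maximum at least
#' `min_separation_nm` away from the primary one, so a single haemoglobin
#' lobe is not counted twice. When a spectrum has no local maximum at all
#' (e.g. constant or monotone), peak fields fall back to the global maximum
#' and `peak_degenerate` is set.
#'
#' Saturation is estimated from the calibrated reflectance carried on an
#' SNV set (see [snv_normalize()]); when no reflectance-scale values are
#' available it is returned as `NA` with `hb_sat_undefined = TRUE`.
#'
#' @param set A `drs_set` on the analysis grid (typically SNV-normalised).
#' @param smooth_window Moving-average window (grid points) for peak
#'   detection; odd values recommended.
#' @param min_separation_nm Exclusion window around the primary peak.
#' @return A tibble, one row per spectrum: `patient_id`, `label`,
#'   `peak1_intensity`, `peak1_wavelength`, `peak2_intensity`,
#'   `peak2_wavelength`, `band_mean_480_550`, `band_mean_580_700`,
#'   `band_mean_450_720`, `hb_saturation`, `peak_degenerate`,
#'   `hb_sat_undefined`.
#' @export
extract_features <- function(set, smooth_window = 15, min_separation_nm = 20) {
  stopifnot(inherits(set, "drs_set"))
  wl <- set$wavelengths
  in_band <- function(lo, hi) wl >= lo & wl <= hi
  b1 <- in_band(480, 550); b2 <- in_band(580, 700); b3 <- in_band(450, 720)
  refl <- set$reflectance
  if (is.null(refl) && set$calibrated) refl <- set$intensities
  n <- n_spectra(set)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    v <- set$intensities[i, ]
    sm <- moving_average(v, smooth_window)
    pk <- local_maxima(sm)
    degenerate <- length(pk) == 0
    if (degenerate) {
      p1 <- which.max(v)
      p2 <- p1
    } else {
      p1 <- pk[which.max(sm[pk])]
      far <- pk[abs(wl[pk] - wl[p1]) >= min_separation_nm]
      p2 <- if (length(far) == 0) p1 else far[which.max(sm[far])]
    }
    sat <- if (is.null(refl)) NA_real_ else {
      estimate_hb_saturation(refl[i, ], wl)
    }
    rows[[i]] <- tibble(
      peak1_intensity = v[p1], peak1_wavelength = wl[p1],
      peak2_intensity = v[p2], peak2_wavelength = wl[p2],
      band_mean_480_550 = mean(v[b1]),
      band_mean_580_700 = mean(v[b2]),
      band_mean_450_720 = mean(v[b3]),
      hb_saturation = sat,
      peak_degenerate = degenerate,
      hb_sat_undefined = is.na(sat)
    )
  }
  bind_cols(
    set$meta[, c("patient_id", "label")],
    bind_rows(rows)
  )
}

# centred moving average; window clipped at the edges
moving_average <- function(v, window) {
  if (window <= 1) return(v)
  half <- floor(window / 2)
  cs <- cumsum(c(0, v))
  n <- length(v)
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# indices of strict local maxima (greater than both neighbours beyond a
# relative tolerance, so float jitter in a flat signal is not a peak)
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  tol <- 1e-10 * max(1, max(abs(v)))
  idx <- 2:(n - 1)
  idx[v[idx] > v[idx - 1] + tol & v[idx] > v[idx + 1] + tol]
}

#' Haemoglobin saturation by spectral unmixing
#'
#' Closed-form approximation of the saturation coefficient: the attenuation
#' `-log(R)` over 500--600 nm is decomposed by non-negative least squares
#' into oxy- and deoxy-haemoglobin extinction contributions plus an
#' unconstrained constant + linear-slope scattering nuisance term (the
#' nuisance coefficients are split into positive and negative parts so only
#' the pigment loadings are sign-constrained). Saturation is
#' `cHbO2 / (cHbO2 + cHb)`; when the total pigment loading falls below
#' `floor` the estimate is undefined (`NA`), which is the expected outcome
#' for a bloodless, flat spectrum.
#'
#' @param reflectance Numeric vector of calibrated reflectance values (or a
#'   one-spectrum calibrated `drs_set`).
#' @param wavelengths Wavelength axis (nm); taken from the set when one is
#'   given. Must cover 500--600 nm.
#' @param floor Minimum total pigment loading below which the estimate is
#'   `NA`.
#' @return Saturation in \[0, 1\], or `NA` when undefined.
#' @export
estimate_hb_saturation <- function(reflectance, wavelengths = NULL,
                                   floor = 1e-3) {
  if (inherits(reflectance, "drs_set")) {
    wavelengths <- reflectance$wavelengths
    reflectance <- as.numeric(reflectance$intensities[1, ])
  }
  stopifnot(is.numeric(reflectance), is.numeric(wavelengths),
            length(reflectance) == length(wavelengths))
  if (min(wavelengths) > 500 || max(wavelengths) < 600) {
    abort("saturation unmixing needs 500-600 nm coverage",
          class = "drspec_coverage_error")
  }
  sel <- wavelengths >= 500 & wavelengths <= 600
  wl <- wavelengths[sel]
  r <- reflectance[sel]
  r <- pmax(r, 1e-12)  # guard against noise-driven non-positive reflectance
  d <- -log(r)
  ext <- hb_extinction_synthetic(wl)
  slope <- (wl - 550) / 100
  A <- cbind(ext$hbo2, ext$hb, 1, -1, slope, -slope)
  fit <- pracma::lsqnonneg(A, d)
  c_oxy <- fit$x[1]
  c_deoxy <- fit$x[2]
  total <- c_oxy + c_deoxy
  if (!is.finite(total) || total < floor) return(NA_real_)
  c_oxy / total
}
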