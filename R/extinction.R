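#' Synthetic haemoglobin extinction spectra
#'
#' Returns effective extinction coefficients for oxy- and deoxy-haemoglobin
#' over 440--1010 nm (the 450--1000 nm analysis range plus margin for
#' native instrument axes). The curves are a smooth closed-form *synthetic
#' approximation* (sums of Gaussians on an exponentially decaying base), not
#' digitised laboratory tables: they reproduce the canonical qualitative
#' features that drive visible-range tissue contrast -- the oxyhaemoglobin
#' alpha/beta doublet at 542 and 577 nm, the single broad deoxyhaemoglobin
#' peak near 555 nm and its 760 nm band, an isosbestic-like crossing near
#' 800 nm, and a steep fall-off towards the red. Units are effective
#' attenuation per mm path per unit blood-volume fraction, so that
#' `exp(-bvf * path * eps)` yields physiologically plausible optical
#' densities.
#'
#' Both the synthetic spectrum generator and the saturation unmixing
#' estimator consume these same curves, which makes parameter-recovery
#' checks self-consistent.
#'
#' @param wavelengths Numeric vector of wavelengths in nm. Must lie within
#'   the supported 450--1000 nm range.
#' @return A tibble with columns `wavelength`, `hbo2`, `hb`.
#' @export
#' @examples
#' ext <- hb_extinction_synthetic(seq(450, 1000, by = 10))
#' head(ext)
hb_extinction_synthetic <- function(wavelengths) {
  stopifnot(is.numeric(wavelengths), length(wavelengths) >= 1)
  if (any(!is.finite(wavelengths))) {
    abort("wavelengths must be finite", class = "drspec_range_error")
  }
  if (any(wavelengths < 440 - 1e-9) || any(wavelengths > 1010 + 1e-9)) {
    abort(
      sprintf(
        "wavelengths outside the supported extinction range [440, 1010] nm (got %.1f-%.1f)",
        min(wavelengths), max(wavelengths)
      ),
      class = "drspec_range_error"
    )
  }
  g <- function(l, mu, sigma, a) a * exp(-0.5 * ((l - mu) / sigma)^2)
  l <- wavelengths
  # common steep blue-green base (Soret tail) decaying into the red
  base <- 90 * exp(-(l - 450) / 28)
  hbo2 <- base +
    g(l, 542, 11, 38) +  # beta band
    g(l, 577, 10, 40) +  # alpha band
    g(l, 930, 60, 2.2) + # NIR rise of HbO2
    0.45
  hb <- 0.8 * base +
    g(l, 555, 22, 46) +  # single broad visible peak
    g(l, 760, 22, 4.0) + # deoxy NIR band
    g(l, 630, 35, 6.0) + # red-edge shoulder (Hb > HbO2 in 600-700 nm)
    0.9
  tibble(wavelength = l, hbo2 = hbo2, hb = hb)
}
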