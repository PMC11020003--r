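#' Tissue optical parameters for the synthetic spectrum generator
#'
#' The generative reflectance model is a scattering power law attenuated by
#' haemoglobin absorption (a Beer-Lambert-style approximation of diffuse
#' reflectance):
#' \deqn{R(\lambda) = A (\lambda/500)^{-b}
#'   \exp\{-BVF \cdot L [s\,\epsilon_{HbO_2}(\lambda) +
#'   (1-s)\,\epsilon_{Hb}(\lambda)]\} + \mathcal{N}(0, \sigma^2)}
#' where `A` = `scatter_amplitude`, `b` = `scatter_power`, `BVF` =
#' `blood_volume_fraction`, `L` = `path_length` (mm), `s` = `hb_saturation`
#' and `sigma` = `noise_sd`.
#'
#' @param blood_volume_fraction Fraction of tissue volume occupied by blood,
#'   in \[0, 1\].
#' @param hb_saturation Oxygenated fraction of haemoglobin, in \[0, 1\].
#' @param scatter_amplitude Reflectance at 500 nm absent absorption, > 0.
#' @param scatter_power Scattering wavelength exponent, >= 0.
#' @param path_length Effective photon path length in mm, > 0.
#' @param noise_sd Additive Gaussian noise standard deviation, >= 0.
#' @return A `tissue_optics` parameter list.
#' @export
tissue_optics <- function(blood_volume_fraction = 0.02, hb_saturation = 0.8,
                          scatter_amplitude = 0.65, scatter_power = 1.1,
                          path_length = 1.0, noise_sd = 0.01) {
  p <- list(
    blood_volume_fraction = blood_volume_fraction, hb_saturation = hb_saturation,
    scatter_amplitude = scatter_amplitude, scatter_power = scatter_power,
    path_length = path_length, noise_sd = noise_sd
  )
  if (any(!vapply(p, is.numeric, TRUE)) || any(!is.finite(unlist(p)))) {
    abort("all tissue_optics fields must be finite numbers", class = "drspec_argument_error")
  }
  if (blood_volume_fraction < 0 || blood_volume_fraction > 1 ||
      hb_saturation < 0 || hb_saturation > 1) {
    abort("fractions must lie in [0, 1]", class = "drspec_argument_error")
  }
  if (scatter_amplitude <= 0 || scatter_power < 0 || path_length <= 0 || noise_sd < 0) {
    abort("scatter_amplitude, path_length > 0 and scatter_power, noise_sd >= 0 required",
          class = "drspec_argument_error")
  }
  structure(p, class = "tissue_optics")
}

#' Default class parameters for the two tissue types
#'
#' Tumour tissue is modelled with a higher blood-volume fraction and lower
#' haemoglobin saturation than normal tissue, plus slightly stronger
#' scattering -- the contrast DRS exploits. These are package defaults for
#' synthetic data, not measured values.
#'
#' @return Named list with `normal` and `tumour` [tissue_optics()] entries.
#' @export
default_class_params <- function() {
  list(
    normal = tissue_optics(
      blood_volume_fraction = 0.015, hb_saturation = 0.85,
      scatter_amplitude = 0.65, scatter_power = 1.0
    ),
    tumour = tissue_optics(
      blood_volume_fraction = 0.04, hb_saturation = 0.60,
      scatter_amplitude = 0.75, scatter_power = 1.3
    )
  )
}

# deterministic closed-form part of the generative model
reflectance_model <- function(params, wavelengths) {
  ext <- hb_extinction_synthetic(wavelengths)
  mu_a <- params$blood_volume_fraction * params$path_length *
    (params$hb_saturation * ext$hbo2 + (1 - params$hb_saturation) * ext$hb)
  params$scatter_amplitude * (wavelengths / 500)^(-params$scatter_power) * exp(-mu_a)
}

#' Generate one synthetic reflectance spectrum
#'
#' @param params A [tissue_optics()] parameter set.
#' @param grid A [wavelength_grid()] (or numeric wavelength vector) within
#'   the 450--1000 nm extinction-table support.
#' @param label,patient_id,acquisition_index Metadata for the spectrum.
#' @return A one-spectrum `drs_set` of noiseless-model-plus-noise
#'   reflectance values. Draws from the current RNG stream; seed outside
#'   for reproducibility.
#' @export
#' @examples
#' set.seed(1)
#' s <- generate_spectrum(tissue_optics(noise_sd = 0), wavelength_grid())
generate_spectrum <- function(params, grid = wavelength_grid(),
                              label = "unknown", patient_id = "synthetic",
                              acquisition_index = 1L) {
  stopifnot(inherits(params, "tissue_optics"))
  wl <- if (inherits(grid, "wavelength_grid")) grid_points(grid) else as.numeric(grid)
  r <- reflectance_model(params, wl)
  if (params$noise_sd > 0) r <- r + rnorm(length(wl), 0, params$noise_sd)
  drs_set(
    wl, matrix(r, nrow = 1),
    tibble(patient_id = patient_id, label = label,
           acquisition_index = as.integer(acquisition_index)),
    calibrated = TRUE
  )
}

#' Specification of a synthetic patient cohort
#'
#' @param n_patients Number of patients, >= 1.
#' @param spectra_per_class_per_patient Spectra per tissue class per patient
#'   (default 200, emulating a typical acquisition session).
#' @param class_params Named list of [tissue_optics()] per label; defaults
#'   to [default_class_params()].
#' @param patient_jitter_sdlog Log-normal per-patient multiplicative jitter
#'   applied once per patient to blood volume and scatter amplitude, so that
#'   spectra cluster by patient and patient-wise cross-validation is a
#'   meaningful test.
#' @param seed Integer seed making the cohort reproducible.
#' @return A `synthetic_dataset_spec`.
#' @export
synthetic_dataset_spec <- function(n_patients = 20,
                                   spectra_per_class_per_patient = 200,
                                   class_params = default_class_params(),
                                   patient_jitter_sdlog = 0.2,
                                   seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 1) {
    abort("n_patients must be >= 1", class = "drspec_argument_error")
  }
  if (!is.numeric(spectra_per_class_per_patient) || spectra_per_class_per_patient < 1) {
    abort("spectra_per_class_per_patient must be >= 1", class = "drspec_argument_error")
  }
  stopifnot(all(vapply(class_params, inherits, TRUE, "tissue_optics")))
  structure(
    list(
      n_patients = as.integer(n_patients),
      spectra_per_class_per_patient = as.integer(spectra_per_class_per_patient),
      class_params = class_params,
      patient_jitter_sdlog = patient_jitter_sdlog,
      seed = as.integer(seed)
    ),
    class = "synthetic_dataset_spec"
  )
}

#' Generate a synthetic patient cohort of raw instrument spectra
#'
#' Emulates an acquisition session: the model reflectance of each spectrum
#' is folded through a smooth synthetic lamp spectrum and dark level to give
#' raw detector counts, and the matching white/dark reference spectra are
#' attached to the returned set, so downstream calibration is exercised for
#' real. Spectra are generated on a native instrument axis slightly wider
#' than the 450--1000 nm analysis grid so that resampling is non-trivial.
#'
#' @param spec A [synthetic_dataset_spec()].
#' @param as_counts If `FALSE`, return calibrated reflectance directly
#'   (no lamp folding, no references).
#' @return A `drs_set` of raw counts with a `refs` [reference_set()]
#'   attached (or calibrated reflectance when `as_counts = FALSE`).
#' @export
generate_dataset <- function(spec, as_counts = TRUE) {
  stopifnot(inherits(spec, "synthetic_dataset_spec"))
  set.seed(spec$seed)
  # native instrument axis: 2048 unevenly listed but ascending points
  wl <- seq(448, 1002, length.out = 2048)
  labels <- names(spec$class_params)
  n_per <- spec$spectra_per_class_per_patient
  rows <- list()
  meta <- list()
  for (p in seq_len(spec$n_patients)) {
    pid <- sprintf("P%03d", p)
    jit_bvf <- exp(rnorm(1, 0, spec$patient_jitter_sdlog))
    jit_amp <- exp(rnorm(1, 0, spec$patient_jitter_sdlog))
    for (lab in labels) {
      base <- spec$class_params[[lab]]
      params <- tissue_optics(
        blood_volume_fraction = min(1, base$blood_volume_fraction * jit_bvf),
        hb_saturation = base$hb_saturation,
        scatter_amplitude = base$scatter_amplitude * jit_amp,
        scatter_power = base$scatter_power,
        path_length = base$path_length,
        noise_sd = base$noise_sd
      )
      clean <- reflectance_model(params, wl)
      noise <- matrix(rnorm(n_per * length(wl), 0, params$noise_sd), nrow = n_per)
      rows[[length(rows) + 1]] <- sweep(noise, 2, clean, `+`)
      meta[[length(meta) + 1]] <- tibble(
        patient_id = pid, label = lab, acquisition_index = seq_len(n_per)
      )
    }
  }
  refl <- do.call(rbind, rows)
  meta <- bind_rows(meta)
  if (!as_counts) {
    return(drs_set(wl, refl, meta, calibrated = TRUE))
  }
  # synthetic tungsten-like lamp and dark level shared by the session
  white_counts <- 3.2e4 * exp(-0.5 * ((wl - 880) / 260)^2) + 1500
  dark_counts <- 420 + 0.05 * (wl - 450)
  counts <- sweep(refl, 2, white_counts - dark_counts, `*`)
  counts <- sweep(counts, 2, dark_counts, `+`)
  refs <- reference_set(
    white = drs_set(wl, matrix(white_counts, nrow = 1)),
    dark = drs_set(wl, matrix(dark_counts, nrow = 1))
  )
  drs_set(wl, counts, meta, refs = refs)
}
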