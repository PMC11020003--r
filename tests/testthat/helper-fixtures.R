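# Independent brute-force oracles and tiny fixtures used across tests.

# MAD outlier rule by explicit enumeration (no shared code with the
# implementation): median and MAD from sorted copies, one flag per value.
brute_force_outlier_flags <- function(residuals, factor = 1.5) {
  med_of <- function(v) {
    s <- sort(v)
    n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  med <- med_of(residuals)
  devs <- numeric(length(residuals))
  for (i in seq_along(residuals)) devs[i] <- abs(residuals[i] - med)
  mad_val <- med_of(devs)
  flags <- logical(length(residuals))
  for (i in seq_along(residuals)) {
    flags[i] <- abs(residuals[i] - med) > factor * mad_val
  }
  flags
}

# AUC as exhaustive pairwise concordance probability, ties counted 1/2.
brute_force_auc <- function(scores, labels, positive = "tumour") {
  pos <- which(labels == positive)
  neg <- which(labels != positive)
  tot <- 0
  for (i in pos) {
    for (j in neg) {
      tot <- tot + if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0
    }
  }
  tot / (length(pos) * length(neg))
}

# A drs_set with prescribed per-spectrum residual means: constant spectra
# at the given levels on a short axis.
set_with_residuals <- function(levels_vec, wl = seq(500, 600, by = 10)) {
  drs_set(
    wl,
    matrix(rep(levels_vec, times = length(wl)), nrow = length(levels_vec)),
    calibrated = TRUE
  )
}

# Small calibrated synthetic cohort on the default grid.
small_cohort <- function(n_patients = 4, n_per = 6, seed = 1, noise_sd = 0.01) {
  cp <- default_class_params()
  cp$normal$noise_sd <- noise_sd
  cp$tumour$noise_sd <- noise_sd
  spec <- synthetic_dataset_spec(
    n_patients = n_patients, spectra_per_class_per_patient = n_per,
    class_params = cp, seed = seed
  )
  generate_dataset(spec, as_counts = FALSE)
}
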