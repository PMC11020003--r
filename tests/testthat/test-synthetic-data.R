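test_that("noise-free spectrum with no blood equals the scattering baseline", {
  p <- tissue_optics(blood_volume_fraction = 0, noise_sd = 0,
                     scatter_amplitude = 0.7, scatter_power = 1.2)
  g <- wavelength_grid(450, 1000, 200)
  s <- generate_spectrum(p, g)
  wl <- grid_points(g)
  expect_equal(as.numeric(s$intensities[1, ]), 0.7 * (wl / 500)^(-1.2))
})

test_that("spectrum generation is deterministic under a fixed seed", {
  p <- tissue_optics(noise_sd = 0.02)
  g <- wavelength_grid(450, 1000, 100)
  set.seed(99); a <- generate_spectrum(p, g)
  set.seed(99); b <- generate_spectrum(p, g)
  expect_identical(a$intensities, b$intensities)
})

test_that("reflectance at 560 nm decreases as blood volume increases", {
  g <- 560
  r_at <- function(bvf) {
    p <- tissue_optics(blood_volume_fraction = bvf, noise_sd = 0)
    generate_spectrum(p, c(559, 560, 561))$intensities[1, 2]
  }
  bvfs <- c(0.005, 0.01, 0.02, 0.05, 0.1)
  vals <- vapply(bvfs, r_at, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_lt(r_at(0.05), r_at(0.01))
})

test_that("generated cohorts have the specified size, labels and patients", {
  spec <- synthetic_dataset_spec(n_patients = 4, spectra_per_class_per_patient = 10,
                                 seed = 5)
  ds <- generate_dataset(spec)
  expect_equal(n_spectra(ds), 80)
  expect_equal(length(unique(ds$meta$patient_id)), 4)
  expect_equal(unname(table(ds$meta$label)), c(40, 40), ignore_attr = TRUE)
  # determinism
  ds2 <- generate_dataset(spec)
  expect_identical(ds$intensities, ds2$intensities)
  expect_identical(ds$meta, ds2$meta)
})

test_that("default class parameters produce distinct mean spectra", {
  cp <- default_class_params()
  cp$normal$noise_sd <- 0; cp$tumour$noise_sd <- 0
  expect_gt(cp$tumour$blood_volume_fraction, cp$normal$blood_volume_fraction)
  expect_lt(cp$tumour$hb_saturation, cp$normal$hb_saturation)
  spec <- synthetic_dataset_spec(n_patients = 2, spectra_per_class_per_patient = 3,
                                 class_params = cp, patient_jitter_sdlog = 0, seed = 1)
  ds <- generate_dataset(spec, as_counts = FALSE)
  mu_t <- colMeans(ds$intensities[ds$meta$label == "tumour", ])
  mu_n <- colMeans(ds$intensities[ds$meta$label == "normal", ])
  expect_gt(max(abs(mu_t - mu_n)), 0)
})

test_that("cohort spec rejects invalid counts", {
  expect_error(synthetic_dataset_spec(n_patients = 0), class = "drspec_argument_error")
  expect_error(synthetic_dataset_spec(spectra_per_class_per_patient = 0),
               class = "drspec_argument_error")
})

test_that("marker frames match the ground-truth trajectory and hue band", {
  spec <- marker_scene_spec(n_frames = 30, trajectory = "linear",
                            start = c(50, 50), velocity = c(3, 2), seed = 4)
  vid <- generate_marker_frames(spec)
  expect_length(vid$frames, 30)
  expect_equal(nrow(vid$trajectory), 30)
  # pixels inside the disk convert to HSV hue within the default green band
  fr <- vid$frames[[1]]
  cx <- vid$trajectory$x[1]; cy <- vid$trajectory$y[1]
  rng <- hsv_range()
  for (dx in c(-3, 0, 3)) {
    px <- fr[round(cy), round(cx) + dx, ]
    hue <- grDevices::rgb2hsv(matrix(px, 3))[1] * 360
    expect_gte(hue, rng$hue_min)
    expect_lte(hue, rng$hue_max)
  }
  # determinism
  vid2 <- generate_marker_frames(spec)
  expect_identical(vid$frames, vid2$frames)
})

test_that("oversized markers are rejected", {
  expect_error(
    marker_scene_spec(frame_width = 40, frame_height = 40, marker_radius = 25),
    class = "drspec_argument_error"
  )
})
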