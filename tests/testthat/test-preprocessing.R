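test_that("default grid has 1922 points at ~0.28631 nm spacing", {
  g <- wavelength_grid()
  pts <- grid_points(g)
  expect_length(pts, 1922)
  expect_equal(diff(pts)[1], 550 / 1921, tolerance = 1e-12)
  expect_equal(pts[1], 450)
  expect_equal(pts[1922], 1000)
})

test_that("resampling interpolates linearly and preserves constants", {
  wl <- seq(440, 1010, length.out = 300)
  g <- wavelength_grid()
  const <- drs_set(wl, matrix(3.7, 1, 300), calibrated = TRUE)
  out <- resample_to_grid(const, g)
  expect_equal(n_spectra(out), 1)
  expect_length(out$intensities[1, ], 1922)
  expect_true(all(abs(out$intensities - 3.7) < 1e-12))
  # identity when input is already on the target grid
  on_grid <- drs_set(grid_points(g), matrix(rnorm(1922), 1), calibrated = TRUE)
  expect_equal(resample_to_grid(on_grid, g)$intensities, on_grid$intensities)
  # insufficient span
  short <- drs_set(seq(500, 900, length.out = 50), matrix(1, 1, 50))
  err <- expect_error(resample_to_grid(short, g), class = "drspec_coverage_error")
  expect_match(conditionMessage(err), "missing")
})

test_that("SNV yields zero mean and unit sample sd", {
  ds <- drs_set(c(500, 600, 700), matrix(c(1, 2, 3), 1))
  out <- snv_normalize(ds)
  expect_equal(as.numeric(out$intensities), c(-1, 0, 1))
  expect_true(out$snv_applied)
  set.seed(11)
  rand <- drs_set(seq(450, 1000, length.out = 80), matrix(rnorm(5 * 80, 2, 3), 5))
  sn <- snv_normalize(rand)
  expect_true(all(abs(rowMeans(sn$intensities)) < 1e-9))
  expect_true(all(abs(apply(sn$intensities, 1, sd) - 1) < 1e-9))
  # constant spectrum is degenerate
  expect_error(snv_normalize(drs_set(c(1, 2, 3) + 500, matrix(2, 1, 3))),
               class = "drspec_degenerate_error")
})

test_that("SNV is invariant to positive affine transforms", {
  set.seed(21)
  wl <- seq(450, 1000, length.out = 60)
  for (i in 1:20) {
    x <- rnorm(60)
    a <- runif(1, 0.1, 10); b <- rnorm(1, 0, 5)
    s1 <- snv_normalize(drs_set(wl, matrix(x, 1)))$intensities
    s2 <- snv_normalize(drs_set(wl, matrix(a * x + b, 1)))$intensities
    expect_equal(s2, s1, tolerance = 1e-9)
  }
})

test_that("MAD outlier rule matches hand-derived cases", {
  # residuals (1, 2, 3, 100): median 2.5, MAD 1.0, band (1.0, 4.0];
  # 1 sits exactly on the boundary and the strict inequality keeps it
  rep1 <- detect_outliers(set_with_residuals(c(1, 2, 3, 100)))
  expect_identical(rep1$outlier, c(FALSE, FALSE, FALSE, TRUE))
  expect_identical(rep1$outlier, brute_force_outlier_flags(c(1, 2, 3, 100)))
  # all equal: MAD 0, 0 > 0 is false, nothing flagged
  rep2 <- detect_outliers(set_with_residuals(rep(5, 6)))
  expect_false(any(rep2$outlier))
  # residuals 10..14: MAD 1, threshold 1.5; deviations 2 > 1.5 flag the ends
  r3 <- c(10, 11, 12, 13, 14)
  rep3 <- detect_outliers(set_with_residuals(r3))
  expect_identical(rep3$outlier, brute_force_outlier_flags(r3))
  expect_identical(rep3$outlier, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  # diagnostics are reported
  expect_equal(attr(rep3, "median_residual"), 12)
  expect_equal(attr(rep3, "mad"), 1)
  expect_equal(attr(rep3, "q25"), 11)
  expect_equal(attr(rep3, "q75"), 13)
  expect_error(detect_outliers(set_with_residuals(c(1, 2))),
               class = "drspec_argument_error")
})

test_that("MAD flags agree with brute-force enumeration on random sets", {
  set.seed(17)
  for (trial in 1:300) {
    n <- sample(3:12, 1)
    res <- round(rnorm(n, 10, 3), sample(0:2, 1))
    fac <- sample(c(1, 1.5, 2, 3), 1)
    got <- detect_outliers(set_with_residuals(res), fac)$outlier
    expect_identical(got, brute_force_outlier_flags(res, fac))
  }
})

test_that("preprocess_set removes an injected aberrant spectrum", {
  ds <- small_cohort(n_patients = 1, n_per = 25, noise_sd = 0)
  sat <- ds
  sat$intensities[3, ] <- 5  # saturated acquisition, far off the cluster
  out <- preprocess_set(sat, grid = wavelength_grid(455, 995, 200))
  rep <- attr(out, "outlier_report")
  expect_true(rep$outlier[rep$spectrum == 3])
  expect_equal(n_spectra(out), n_spectra(ds) - 1)
  expect_true(out$snv_applied)
  # empty set errors
  expect_error(preprocess_set(ds[integer(0)]), class = "drspec_argument_error")
})

test_that("outlier rejection is idempotent on well-clustered survivors", {
  # noise-free acquisitions are identical within a patient/class group, so
  # after the aberrant ones are removed a second pass has MAD 0 and flags
  # nothing new
  ds <- small_cohort(n_patients = 2, n_per = 10, noise_sd = 0)
  ds$intensities[c(2, 15), ] <- ds$intensities[c(2, 15), ] + 2
  cleaned <- preprocess_set(ds, grid = wavelength_grid(455, 995, 150))
  expect_equal(n_spectra(cleaned), 38)
  refl <- drs_set(cleaned$wavelengths, cleaned$reflectance, cleaned$meta,
                  calibrated = TRUE)
  grp <- paste(refl$meta$patient_id, refl$meta$label)
  for (g in unique(grp)) {
    second <- detect_outliers(refl[grp == g])
    expect_false(any(second$outlier))
  }
})
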