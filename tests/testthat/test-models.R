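fold_meta <- function(n_patients, n_per = 10, balanced = TRUE, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    patient_id = rep(sprintf("P%02d", seq_len(n_patients)), each = n_per),
    label = if (balanced) {
      rep(rep(c("normal", "tumour"), each = n_per / 2), n_patients)
    } else {
      sample(c("normal", "tumour"), n_patients * n_per, replace = TRUE)
    }
  )
}

test_that("patient-wise folds partition patients without overlap", {
  meta <- fold_meta(10)
  folds <- make_patient_folds(meta, k = 5, seed = 3)
  pf <- attr(folds, "patient_folds")
  expect_equal(sort(unique(folds$fold)), 1:5)
  expect_equal(unname(table(pf$fold)), rep(2L, 5), ignore_attr = TRUE)
  # every spectrum assigned exactly once; patient sets pairwise disjoint
  expect_equal(nrow(folds), nrow(meta))
  by_fold <- split(folds$patient_id, folds$fold)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_length(intersect(by_fold[[i]], by_fold[[j]]), 0)
  }
  expect_error(make_patient_folds(fold_meta(4), k = 5),
               class = "drspec_argument_error")
})

test_that("greedy stratification keeps fold class fractions near global", {
  meta <- fold_meta(20, n_per = 20)
  folds <- make_patient_folds(meta, k = 5, seed = 2)
  global <- mean(meta$label == "tumour")
  for (f in 1:5) {
    frac <- mean(folds$label[folds$fold == f] == "tumour")
    expect_lt(abs(frac - global), 0.1 * max(global, 1e-9) + 1e-9)
  }
})

test_that("AUC equals hand-derived and brute-force concordance values", {
  expect_equal(
    compute_auc(c(0.1, 0.4, 0.35, 0.8), c("normal", "normal", "tumour", "tumour")),
    0.75
  )
  expect_equal(compute_auc(c(0.1, 0.2, 0.8, 0.9),
                           c("normal", "normal", "tumour", "tumour")), 1.0)
  expect_error(compute_auc(1:3, rep("tumour", 3)), class = "drspec_degenerate_error")
  set.seed(31)
  for (trial in 1:200) {
    n <- sample(4:30, 1)
    labels <- c("normal", "tumour",
                sample(c("normal", "tumour"), n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    expect_equal(compute_auc(scores, labels), brute_force_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("confusion metrics follow their definitions at threshold 0.5", {
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.55, 0.4, 0.3, 0.2, 0.1, 0.45)
  y <- c(rep("tumour", 5), rep("normal", 4), "tumour")  # 9 of 10 correct
  m <- metrics_from_scores(scores, y)
  expect_equal(m$accuracy, 0.9)
  expect_equal(m$sensitivity, m$tp / (m$tp + m$fn))
  expect_equal(m$specificity, m$tn / (m$tn + m$fp))
  expect_equal(m$tp + m$tn + m$fp + m$fn, 10)
  expect_true(all(unlist(m[, c("accuracy", "sensitivity", "specificity", "auc")]) >= 0 &
                  unlist(m[, c("accuracy", "sensitivity", "specificity", "auc")]) <= 1))
  # single-class test set: AUC undefined, other metrics still returned
  m1 <- metrics_from_scores(c(0.9, 0.2), c("tumour", "tumour"))
  expect_true(is.na(m1$auc))
  expect_equal(m1$accuracy, 0.5)
})

test_that("AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  for (trial in 1:20) {
    n <- sample(10:40, 1)
    scores <- runif(n)
    labels <- c("normal", "tumour", sample(c("normal", "tumour"), n - 2, TRUE))
    ours <- compute_auc(scores, labels)
    theirs <- as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = scores, levels = c("normal", "tumour"),
      direction = "<", quiet = TRUE
    )))
    expect_equal(ours, theirs, tolerance = 1e-10)
  }
})

test_that("classifier front-end validates kinds and classes", {
  x <- matrix(rnorm(40), 20, 2)
  y <- rep(c("normal", "tumour"), 10)
  expect_error(train_classifier(x, y, kind = "cnn2d"), class = "drspec_argument_error")
  expect_error(train_classifier(x, y, kind = "lgbm"), class = "drspec_argument_error")
  expect_error(train_classifier(x, rep("tumour", 20), kind = "rf"),
               class = "drspec_argument_error")
})

test_that("baseline classifiers are deterministic given a seed", {
  set.seed(6)
  x <- matrix(rnorm(200 * 5), 200, 5)
  y <- ifelse(x[, 1] + rnorm(200, 0, 0.5) > 0, "tumour", "normal")
  for (kind in c("rf", "xgb", "mlp")) {
    m1 <- train_classifier(x, y, kind = kind, seed = 11)
    m2 <- train_classifier(x, y, kind = kind, seed = 11)
    expect_identical(predict_proba(m1, x), predict_proba(m2, x), label = kind)
  }
  # each learns the signal
  for (kind in c("rf", "xgb", "svm", "mlp")) {
    m <- train_classifier(x, y, kind = kind, seed = 11)
    auc <- compute_auc(predict_proba(m, x), y)
    expect_gt(auc, 0.9)
  }
})

test_that("cross-validation never leaks a test patient into training", {
  ds <- small_cohort(n_patients = 6, n_per = 5, seed = 13)
  proc <- snv_normalize(resample_to_grid(ds, wavelength_grid(455, 995, 120)))
  f <- extract_features(proc)
  x <- as.matrix(f[, c("peak1_intensity", "peak1_wavelength", "band_mean_480_550",
                       "band_mean_580_700", "band_mean_450_720", "hb_saturation")])
  x[is.na(x)] <- 0.5
  cv <- cross_validate(x, proc$meta, kind = "rf", k = 3, seed = 5)
  fp <- attr(cv, "fold_patients")
  all_p <- unique(proc$meta$patient_id)
  expect_equal(sort(unlist(fp)), sort(all_p))
  for (i in seq_along(fp)) {
    expect_length(intersect(fp[[i]], unlist(fp[-i])), 0)
  }
  s <- tidy(cv)
  expect_identical(s$metric, c("accuracy", "sensitivity", "specificity", "auc"))
  expect_true(all(s$ci_lo <= s$ci_hi))
})
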