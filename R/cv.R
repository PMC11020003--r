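#' Patient-wise stratified fold assignment
#'
#' Every patient's spectra are allocated to exactly one fold, so no
#' patient's data can appear in both the training and test side of any
#' split. Stratification is approximate: patients are taken in descending
#' order of spectrum count and each is assigned to the fold that minimises
#' the resulting per-class count imbalance (total count as tie-break).
#'
#' @param set A `drs_set`, or a tibble with `patient_id` and `label`
#'   columns.
#' @param k Number of folds (default 5).
#' @param seed Integer seed (shuffles patients before the greedy pass so
#'   ties break differently across seeds).
#' @return A `fold_assignment`: tibble with one row per spectrum
#'   (`patient_id`, `label`, `fold`), plus attribute `patient_folds`.
#' @export
make_patient_folds <- function(set, k = 5, seed = 1L) {
  meta <- if (inherits(set, "drs_set")) set$meta else as_tibble(set)
  stopifnot(all(c("patient_id", "label") %in% names(meta)))
  k <- as.integer(k)
  patients <- unique(meta$patient_id)
  if (length(patients) < k) {
    abort(sprintf("%d patients cannot fill %d folds", length(patients), k),
          class = "drspec_argument_error")
  }
  set.seed(seed)
  counts <- meta %>%
    count(.data$patient_id, .data$label) %>%
    pivot_wider_counts()
  counts <- counts[sample.int(nrow(counts)), , drop = FALSE]
  counts <- counts[order(-counts$total), , drop = FALSE]
  classes <- setdiff(names(counts), c("patient_id", "total"))
  fold_tot <- matrix(0, k, length(classes), dimnames = list(NULL, classes))
  assign <- setNames(integer(nrow(counts)), counts$patient_id)
  for (i in seq_len(nrow(counts))) {
    add <- as.numeric(counts[i, classes])
    # imbalance after hypothetical assignment: spread of per-class totals
    score <- vapply(seq_len(k), function(f) {
      tmp <- fold_tot
      tmp[f, ] <- tmp[f, ] + add
      sum(apply(tmp, 2, function(cc) max(cc) - min(cc))) +
        1e-6 * sum(tmp[f, ])
    }, numeric(1))
    f <- which.min(score)
    fold_tot[f, ] <- fold_tot[f, ] + add
    assign[counts$patient_id[i]] <- f
  }
  out <- tibble(
    patient_id = meta$patient_id,
    label = meta$label,
    fold = unname(assign[meta$patient_id])
  )
  attr(out, "patient_folds") <- tibble(
    patient_id = names(assign), fold = unname(assign)
  )
  attr(out, "k") <- k
  class(out) <- c("fold_assignment", class(out))
  out
}

# wide per-patient label counts without depending on tidyr::pivot_wider dots
pivot_wider_counts <- function(counted) {
  wide <- tidyr::pivot_wider(counted, names_from = "label", values_from = "n",
                             values_fill = 0)
  wide$total <- rowSums(wide[, setdiff(names(wide), "patient_id"), drop = FALSE])
  wide
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of the empirical ROC; equal to the pairwise
#' concordance probability with ties counted one half.
#'
#' @param scores Numeric scores (higher = more tumour-like).
#' @param labels Binary labels; `positive` names the positive class.
#' @param positive Positive class label (default `"tumour"`).
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(scores, labels, positive = "tumour") {
  stopifnot(length(scores) == length(labels))
  pos <- labels == positive
  if (!any(pos) || all(pos)) {
    abort("AUC undefined: both classes must be present", class = "drspec_degenerate_error")
  }
  roc <- roc_points(scores, labels, positive)
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' ROC curve points
#'
#' @inheritParams compute_auc
#' @return Tibble of (`fpr`, `tpr`) pairs from (0,0) to (1,1), one step per
#'   distinct score threshold.
#' @export
roc_points <- function(scores, labels, positive = "tumour") {
  pos <- labels == positive
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # group tied scores into single threshold steps
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(grp, fromLast = TRUE)
  tibble(
    fpr = c(0, fp[last] / sum(!pos)),
    tpr = c(0, tp[last] / sum(pos))
  )
}

#' Evaluate a fitted classifier on a test set
#'
#' Confusion counts at probability threshold 0.5 with `tumour` as the
#' positive class: sensitivity is tumour recall, specificity normal
#' recall, accuracy the proportion of correctly identified spectra. AUC by
#' trapezoidal ROC integration (undefined, `NA`, when the test set has one
#' class).
#'
#' @param model A `drs_model`.
#' @param x Test predictor matrix.
#' @param y Test labels.
#' @param positive Positive class (default `"tumour"`).
#' @param threshold Probability threshold (default 0.5).
#' @return A `metrics_report` tibble (one row) with confusion counts,
#'   accuracy, sensitivity, specificity, auc; ROC points as attribute
#'   `roc`.
#' @export
evaluate_model <- function(model, x, y, positive = "tumour", threshold = 0.5) {
  if (length(y) == 0) abort("empty test set", class = "drspec_argument_error")
  p <- predict_proba(model, x)
  metrics_from_scores(p, y, positive, threshold)
}

#' Metrics from scores and labels
#' @inheritParams evaluate_model
#' @param scores Predicted positive-class probabilities.
#' @export
metrics_from_scores <- function(scores, y, positive = "tumour", threshold = 0.5) {
  truth_pos <- y == positive
  pred_pos <- scores >= threshold
  tp <- sum(pred_pos & truth_pos); fn <- sum(!pred_pos & truth_pos)
  tn <- sum(!pred_pos & !truth_pos); fp <- sum(pred_pos & !truth_pos)
  auc <- if (any(truth_pos) && any(!truth_pos)) {
    compute_auc(scores, y, positive)
  } else NA_real_
  out <- tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = (tp + tn) / length(y),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    auc = auc
  )
  attr(out, "roc") <- if (!is.na(auc)) roc_points(scores, y, positive)
  class(out) <- c("metrics_report", class(out))
  out
}

#' Patient-wise stratified k-fold cross-validation
#'
#' For each fold: fit on the other k-1 folds, evaluate on the held-out
#' fold. No spectrum of any test patient is ever seen in training (the
#' patient-wise fold construction guarantees it; the per-fold patient sets
#' are returned so the property is assertable).
#'
#' @param x Predictor matrix (rows aligned with `meta`).
#' @param meta Tibble with `patient_id` and `label` per row of `x`.
#' @param kind Classifier kind, see [train_classifier()].
#' @param k Number of folds (default 5).
#' @param seed Integer seed (folds and fits).
#' @param config Optional [specnet_config()].
#' @param ... Passed to [train_classifier()].
#' @return A `cv_result`: per-fold metrics tibble with attributes
#'   `summary` (mean and 95% t-interval per metric) and `fold_patients`.
#' @export
cross_validate <- function(x, meta, kind = "rf", k = 5, seed = 1L,
                           config = NULL, ...) {
  x <- as.matrix(x)
  meta <- as_tibble(meta)
  stopifnot(nrow(x) == nrow(meta))
  folds <- make_patient_folds(meta, k = k, seed = seed)
  per_fold <- vector("list", k)
  fold_patients <- vector("list", k)
  for (f in seq_len(k)) {
    te <- which(folds$fold == f)
    tr <- which(folds$fold != f)
    stopifnot(length(intersect(meta$patient_id[tr], meta$patient_id[te])) == 0)
    fold_patients[[f]] <- unique(meta$patient_id[te])
    model <- train_classifier(x[tr, , drop = FALSE], meta$label[tr],
                              kind = kind, seed = seed + f, config = config, ...)
    m <- evaluate_model(model, x[te, , drop = FALSE], meta$label[te])
    per_fold[[f]] <- mutate(m, fold = f)
  }
  out <- bind_rows(per_fold)
  metrics <- c("accuracy", "sensitivity", "specificity", "auc")
  summ <- purrr::map_dfr(metrics, function(mn) {
    vals <- out[[mn]]
    vals <- vals[!is.na(vals)]
    se <- sd(vals) / sqrt(length(vals))
    tq <- qt(0.975, df = length(vals) - 1)
    tibble(metric = mn, mean = mean(vals),
           ci_lo = mean(vals) - tq * se, ci_hi = mean(vals) + tq * se)
  })
  attr(out, "summary") <- summ
  attr(out, "fold_patients") <- fold_patients
  attr(out, "kind") <- kind
  class(out) <- c("cv_result", class(out))
  out
}

#' @export
tidy.cv_result <- function(x, ...) attr(x, "summary")

#' @export
glance.cv_result <- function(x, ...) {
  s <- attr(x, "summary")
  as_tibble(setNames(as.list(s$mean), paste0("mean_", s$metric))) %>%
    mutate(k = nrow(x), kind = attr(x, "kind"))
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d folds\n", attr(x, "kind"), nrow(x)))
  print(attr(x, "summary"))
  invisible(x)
}

#' ROC plot for a metrics report
#' @param object A `metrics_report` carrying ROC points.
#' @param ... Unused.
#' @export
autoplot.metrics_report <- function(object, ...) {
  roc <- attr(object, "roc")
  if (is.null(roc)) abort("no ROC points on this report", class = "drspec_argument_error")
  ggplot(roc, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    geom_path(colour = "#C2185B", linewidth = 0.9) +
    labs(x = "false positive rate", y = "true positive rate",
         title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    theme_minimal()
}
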