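#' Boruta all-relevant feature selection
#'
#' From-scratch implementation of the Boruta procedure. Each iteration
#' appends a "shadow" copy of every feature with its values independently
#' permuted, fits a random forest on the extended matrix, and scores a hit
#' for every real feature whose importance exceeds the best shadow
#' importance of that iteration. Importance is the scaled (z-score)
#' out-of-bag permutation importance: unlike in-sample impurity gain, it
#' does not systematically reward features a deep forest has merely
#' overfitted, which keeps the null behaviour of the procedure calibrated.
#' After `n_iterations` rounds a two-sided binomial test against chance
#' (p = 0.5), Bonferroni-adjusted across features when `mc_adjust` is
#' set, classifies each feature: significantly more hits than chance ->
#' `confirmed`, significantly fewer -> `rejected`, otherwise `tentative`.
#'
#' @param features Numeric matrix or data frame, one row per sample.
#' @param labels Binary labels (factor or character), both classes present.
#' @param n_iterations Number of shadow rounds (default 100).
#' @param p_threshold Two-sided significance threshold (default 0.01).
#' @param n_trees Trees per random forest (default 300).
#' @param mc_adjust Bonferroni-adjust the binomial test across features
#'   (default `TRUE`).
#' @param seed Integer seed.
#' @return A `boruta_result`: tibble with `feature`, `hits`, `p_value`,
#'   `decision`; attributes `n_iterations`, `p_threshold`.
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), 50, 4)
#' y <- ifelse(x[, 1] > 0, "tumour", "normal")
#' boruta_select(x, y, n_iterations = 20, seed = 1)
boruta_select <- function(features, labels, n_iterations = 100,
                          p_threshold = 0.01, n_trees = 300,
                          mc_adjust = TRUE, seed = 1L) {
  x <- as.matrix(features)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (ncol(x) < 2) abort("need at least 2 features", class = "drspec_argument_error")
  y <- factor(labels)
  if (nlevels(y) < 2) {
    abort("labels must contain both classes", class = "drspec_argument_error")
  }
  if (nrow(x) != length(y)) abort("row/label mismatch", class = "drspec_argument_error")
  p <- ncol(x)
  hits <- setNames(integer(p), colnames(x))
  set.seed(seed)
  for (it in seq_len(max(0, n_iterations))) {
    shadow <- apply(x, 2, sample)
    colnames(shadow) <- paste0("shadow_", colnames(x))
    dat <- data.frame(cbind(x, shadow), check.names = FALSE)
    dat$.y <- y
    fit <- ranger::ranger(
      dependent.variable.name = ".y", data = dat,
      num.trees = n_trees, importance = "permutation",
      scale.permutation.importance = TRUE,
      seed = seed + it, num.threads = 1
    )
    imp <- fit$variable.importance
    best_shadow <- max(imp[startsWith(names(imp), "shadow_")])
    hits <- hits + as.integer(imp[colnames(x)] > best_shadow)
  }
  n_it <- max(0, n_iterations)
  if (n_it == 0) {
    pv <- rep(1, p)
  } else {
    # two-sided exact binomial p-value against p = 0.5
    pv <- vapply(hits, function(h) {
      lo <- pbinom(h, n_it, 0.5)
      hi <- pbinom(h - 1, n_it, 0.5, lower.tail = FALSE)
      min(1, 2 * min(lo, hi))
    }, numeric(1))
  }
  thr <- if (mc_adjust) p_threshold / p else p_threshold
  decision <- ifelse(
    pv < thr & hits > n_it / 2, "confirmed",
    ifelse(pv < thr & hits < n_it / 2, "rejected", "tentative")
  )
  out <- tibble(
    feature = colnames(x), hits = as.integer(hits), p_value = pv,
    decision = decision
  )
  attr(out, "n_iterations") <- n_it
  attr(out, "p_threshold") <- p_threshold
  class(out) <- c("boruta_result", class(out))
  out
}

#' @export
print.boruta_result <- function(x, ...) {
  cat(sprintf("<boruta_result> %d features over %d iterations (p < %g): %d confirmed, %d tentative, %d rejected\n",
              nrow(x), attr(x, "n_iterations"), attr(x, "p_threshold"),
              sum(x$decision == "confirmed"), sum(x$decision == "tentative"),
              sum(x$decision == "rejected")))
  NextMethod()
}

#' @export
glance.boruta_result <- function(x, ...) {
  tibble(
    n_features = nrow(x),
    n_confirmed = sum(x$decision == "confirmed"),
    n_tentative = sum(x$decision == "tentative"),
    n_rejected = sum(x$decision == "rejected"),
    n_iterations = attr(x, "n_iterations"),
    p_threshold = attr(x, "p_threshold")
  )
}
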