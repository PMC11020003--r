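#' Train a tissue classifier
#'
#' Unified front-end over the supported model families. All fits are
#' deterministic given `seed` and support [predict_proba()].
#'
#' Kinds: `"specnet"` (the package's 1D CNN, consumes the full spectral
#' sequence), `"rf"` (random forest via ranger), `"xgb"` (gradient
#' boosting via xgboost), `"svm"` (linear support vector machine via
#' e1071), `"mlp"` (single-hidden-layer perceptron via nnet). A LightGBM
#' backend is not available in R, so kind `"lgbm"` raises an informative
#' error.
#'
#' @param x Numeric matrix of predictors (spectra for specnet, feature
#'   columns and/or intensities for the baselines).
#' @param y Binary labels; `"tumour"` is the positive class.
#' @param kind One of `"specnet"`, `"rf"`, `"xgb"`, `"svm"`, `"mlp"`.
#' @param seed Integer seed.
#' @param config Optional [specnet_config()] (specnet only).
#' @param ... Passed to the backing fit function.
#' @return A `drs_model` handle.
#' @export
train_classifier <- function(x, y, kind, seed = 1L, config = NULL, ...) {
  kinds <- c("specnet", "rf", "xgb", "svm", "mlp", "lgbm")
  if (!is.character(kind) || length(kind) != 1 || !(kind %in% kinds)) {
    abort(sprintf("unknown classifier kind '%s'; supported: %s",
                  as.character(kind)[1], paste(kinds, collapse = ", ")),
          class = "drspec_argument_error")
  }
  if (kind == "lgbm") {
    abort("kind 'lgbm' has no available backend in this package; use 'xgb' for gradient boosting",
          class = "drspec_argument_error")
  }
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- factor(y)
  if (nlevels(y) < 2) {
    abort("training data must contain both classes", class = "drspec_argument_error")
  }
  fit <- switch(kind,
    specnet = {
      cfg <- config %||% specnet_config(n1 = ncol(x), seed = seed)
      cfg$seed <- as.integer(seed)
      specnet_train(x, y, cfg)
    },
    rf = ranger::ranger(
      x = x, y = y, probability = TRUE, num.trees = 300,
      seed = seed, num.threads = 1, ...
    ),
    xgb = {
      dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = 0.3, max_depth = 6,
                      nthread = 1, seed = seed),
        data = dtrain, nrounds = 50, verbose = 0, ...
      )
    },
    svm = {
      set.seed(seed)
      e1071::svm(x = x, y = y, kernel = "linear", probability = TRUE,
                 scale = TRUE, ...)
    },
    mlp = {
      set.seed(seed)
      nnet::nnet(x = x, y = stats::model.matrix(~ y - 1)[, 2],
                 size = 16, decay = 1e-3, maxit = 200, trace = FALSE,
                 entropy = TRUE, MaxNWts = 200000, ...)
    }
  )
  structure(
    list(kind = kind, fit = fit, levels = levels(y), features = colnames(x)),
    class = "drs_model"
  )
}

#' Predicted tumour probability
#'
#' @param model A `drs_model` from [train_classifier()].
#' @param newdata Predictor matrix with the training columns.
#' @return Numeric vector of probabilities of the positive (`tumour`,
#'   i.e. second-level) class.
#' @export
predict_proba <- function(model, newdata) {
  stopifnot(inherits(model, "drs_model"))
  x <- as.matrix(newdata)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  pos <- model$levels[2]
  switch(model$kind,
    specnet = predict(model$fit, x)[, pos],
    rf = predict(model$fit, data = x, num.threads = 1)$predictions[, pos],
    xgb = as.numeric(predict(model$fit, xgboost::xgb.DMatrix(x))),
    svm = {
      p <- attr(predict(model$fit, x, probability = TRUE), "probabilities")
      as.numeric(p[, pos])
    },
    mlp = as.numeric(predict(model$fit, x))
  )
}

#' @export
print.drs_model <- function(x, ...) {
  cat(sprintf("<drs_model> kind=%s, %d predictors, classes: %s\n",
              x$kind, length(x$features), paste(x$levels, collapse = "/")))
  invisible(x)
}
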