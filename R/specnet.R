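#' SpecNet configuration
#'
#' SpecNet is a five-layer 1D convolutional network for spectral
#' classification: input of `n1` bands -> convolutional layer C1 with 20
#' kernels of length `k1` (valid convolution, stride 1, so `n2 = n1 - k1 +
#' 1`) -> max-pooling layer M2 of kernel `k2` (`n3 = floor(n2 / k2)`) ->
#' fully connected layer F3 of width `n4` -> output layer of `n5 = 2`
#' nodes with softmax. Trainable parameters per block: `20 * (k1 + 1)` for
#' C1, `(20 * n3 + 1) * n4` for F3 and `(n4 + 1) * n5` for the output
#' layer.
#'
#' Kernel sizes and the fully connected width are tunable; ReLU
#' activations, cross-entropy loss and an Adam optimiser are fixed
#' implementation choices.
#'
#' @param n1 Number of spectral bands (default 1922).
#' @param k1 Convolution kernel length (default 11), `k1 < n1`.
#' @param k2 Max-pooling kernel length (default 2).
#' @param n4 Fully connected width (default 64).
#' @param epochs Maximum training epochs (default 100).
#' @param batch_size Mini-batch size (default 32).
#' @param learning_rate Adam step size (default 1e-3).
#' @param val_fraction Fraction of training data held out for early
#'   stopping (default 0.1; set 0 to disable).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param seed Integer seed controlling initialisation and batching.
#' @return A `specnet_config`.
#' @export
specnet_config <- function(n1 = 1922L, k1 = 11L, k2 = 2L, n4 = 64L,
                           epochs = 100L, batch_size = 32L,
                           learning_rate = 1e-3, val_fraction = 0.1,
                           patience = 10L, seed = 1L) {
  n1 <- as.integer(n1); k1 <- as.integer(k1); k2 <- as.integer(k2)
  n4 <- as.integer(n4)
  if (k1 >= n1) abort("k1 must be smaller than n1", class = "drspec_argument_error")
  if (k1 < 1 || k2 < 1 || n4 < 1) {
    abort("k1, k2, n4 must be positive", class = "drspec_argument_error")
  }
  n2 <- n1 - k1 + 1L
  n3 <- n2 %/% k2
  if (n3 < 1) abort("pooling kernel too large for n2", class = "drspec_argument_error")
  structure(
    list(
      n1 = n1, k1 = k1, n2 = n2, k2 = k2, n3 = n3, n4 = n4, n5 = 2L,
      conv_filters = 20L,
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      learning_rate = learning_rate, val_fraction = val_fraction,
      patience = as.integer(patience), seed = as.integer(seed)
    ),
    class = "specnet_config"
  )
}

#' SpecNet architecture descriptor
#'
#' Lists the layers in order with their output shapes and closed-form
#' trainable-parameter counts.
#'
#' @param config A [specnet_config()].
#' @return A `specnet_descriptor`: tibble with `layer`, `type`,
#'   `output_length`, `channels`, `trainable_params`.
#' @export
#' @examples
#' build_specnet(specnet_config(k1 = 11, k2 = 2, n4 = 64))
build_specnet <- function(config) {
  stopifnot(inherits(config, "specnet_config"))
  f <- config$conv_filters
  out <- tibble(
    layer = c("input", "C1", "M2", "F3", "output"),
    type = c("input", "conv1d", "maxpool", "dense", "dense_softmax"),
    output_length = c(config$n1, config$n2, config$n3, config$n4, config$n5),
    channels = c(1L, f, f, 1L, 1L),
    trainable_params = c(
      0L,
      f * (config$k1 + 1L),
      0L,
      (f * config$n3 + 1L) * config$n4,
      (config$n4 + 1L) * config$n5
    )
  )
  attr(out, "config") <- config
  class(out) <- c("specnet_descriptor", class(out))
  out
}

#' @export
print.specnet_descriptor <- function(x, ...) {
  cat(sprintf("<specnet> 5-layer 1D CNN, %d trainable parameters\n",
              sum(x$trainable_params)))
  NextMethod()
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# column-wise sliding windows: row (t-1)*B + b holds X[b, t:(t+k-1)]
im2col <- function(X, n2, k) {
  out <- matrix(0, nrow(X) * n2, k)
  for (j in seq_len(k)) out[, j] <- as.vector(X[, j:(j + n2 - 1)])
  out
}

specnet_forward <- function(w, X, cfg, keep = FALSE) {
  B <- nrow(X)
  Xc <- im2col(X, cfg$n2, cfg$k1)
  Z1 <- sweep(Xc %*% t(w$W1), 2, w$b1, `+`)
  A1 <- relu(Z1)
  Aarr <- array(A1, c(B, cfg$n2, cfg$conv_filters))
  idx0 <- seq(1, by = cfg$k2, length.out = cfg$n3)
  P <- Aarr[, idx0, , drop = FALSE]
  if (cfg$k2 > 1) {
    for (j in 2:cfg$k2) {
      P <- pmax(P, Aarr[, idx0 + (j - 1), , drop = FALSE])
    }
  }
  # flatten (filter-major): column (f-1)*n3 + u
  Xf <- matrix(aperm(P, c(1, 2, 3)), B, cfg$n3 * cfg$conv_filters)
  H <- relu(sweep(Xf %*% w$W2, 2, w$b2, `+`))
  O <- sweep(H %*% w$W3, 2, w$b3, `+`)
  Om <- O - apply(O, 1, max)
  S <- exp(Om) / rowSums(exp(Om))
  if (!keep) return(list(probs = S))
  list(probs = S, Xc = Xc, Z1 = Z1, Aarr = Aarr, P = P, Xf = Xf, H = H)
}

specnet_backward <- function(w, fwd, Y, cfg) {
  B <- nrow(Y)
  dO <- (fwd$probs - Y) / B
  dW3 <- t(fwd$H) %*% dO
  db3 <- colSums(dO)
  dH <- dO %*% t(w$W3)
  dH[fwd$H <= 0] <- 0
  dW2 <- t(fwd$Xf) %*% dH
  db2 <- colSums(dH)
  dXf <- dH %*% t(w$W2)
  dP <- array(dXf, c(B, cfg$n3, cfg$conv_filters))
  dA <- array(0, c(B, cfg$n2, cfg$conv_filters))
  idx0 <- seq(1, by = cfg$k2, length.out = cfg$n3)
  assigned <- array(FALSE, c(B, cfg$n3, cfg$conv_filters))
  for (j in seq_len(cfg$k2)) {
    sl <- fwd$Aarr[, idx0 + (j - 1), , drop = FALSE]
    hit <- (sl == fwd$P) & !assigned
    dA[, idx0 + (j - 1), ] <- dA[, idx0 + (j - 1), , drop = FALSE] + dP * hit
    assigned <- assigned | hit
  }
  dA1 <- matrix(dA, B * cfg$n2, cfg$conv_filters)
  dA1[fwd$Z1 <= 0] <- 0
  dW1 <- t(dA1) %*% fwd$Xc
  db1 <- colSums(dA1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
}

#' Train SpecNet
#'
#' Mini-batch Adam optimisation of the five-layer network on a spectra
#' matrix. Training is deterministic given the config seed. When
#' `val_fraction > 0` a tail fraction of the (shuffled) data is held out
#' and training stops early once validation loss has not improved for
#' `patience` epochs.
#'
#' @param x Numeric matrix, one spectrum per row, `ncol == config$n1`.
#' @param y Labels (factor/character); the second level (alphabetically,
#'   `"tumour"` for the standard labels) is the positive class.
#' @param config A [specnet_config()].
#' @return A `specnet_fit` with weights, config, class levels and the
#'   per-epoch loss trace.
#' @export
specnet_train <- function(x, y, config = specnet_config()) {
  stopifnot(inherits(config, "specnet_config"))
  x <- as.matrix(x)
  if (ncol(x) != config$n1) {
    abort(sprintf("spectra have %d bands but config$n1 = %d", ncol(x), config$n1),
          class = "drspec_argument_error")
  }
  y <- factor(y)
  if (nlevels(y) != 2) {
    abort("SpecNet needs exactly two classes in the training data",
          class = "drspec_argument_error")
  }
  set.seed(config$seed)
  f <- config$conv_filters
  D <- f * config$n3
  w <- list(
    W1 = matrix(rnorm(f * config$k1, 0, sqrt(2 / config$k1)), f, config$k1),
    b1 = rep(0, f),
    W2 = matrix(rnorm(D * config$n4, 0, sqrt(2 / D)), D, config$n4),
    b2 = rep(0, config$n4),
    W3 = matrix(rnorm(config$n4 * config$n5, 0, sqrt(2 / config$n4)),
                config$n4, config$n5),
    b3 = rep(0, config$n5)
  )
  m <- lapply(w, function(p) p * 0)
  v <- lapply(w, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  n <- nrow(x)
  ord <- sample.int(n)
  n_val <- if (config$val_fraction > 0) max(0L, floor(config$val_fraction * n)) else 0L
  val_idx <- if (n_val >= 2) ord[seq_len(n_val)] else integer(0)
  tr_idx <- setdiff(ord, val_idx)
  Y_all <- matrix(0, n, 2)
  Y_all[cbind(seq_len(n), as.integer(y))] <- 1
  xent <- function(probs, Y) -mean(rowSums(Y * log(pmax(probs, 1e-12))))
  best_val <- Inf; best_w <- w; stall <- 0L; step <- 0L
  trace <- numeric(0)
  for (epoch in seq_len(config$epochs)) {
    idx <- sample(tr_idx)
    losses <- numeric(0)
    for (start in seq(1, length(idx), by = config$batch_size)) {
      b <- idx[start:min(start + config$batch_size - 1, length(idx))]
      if (length(b) < 2) next
      fwd <- specnet_forward(w, x[b, , drop = FALSE], config, keep = TRUE)
      losses <- c(losses, xent(fwd$probs, Y_all[b, , drop = FALSE]))
      g <- specnet_backward(w, fwd, Y_all[b, , drop = FALSE], config)
      step <- step + 1L
      for (nm in names(w)) {
        m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g[[nm]]
        v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g[[nm]]^2
        mhat <- m[[nm]] / (1 - beta1^step)
        vhat <- v[[nm]] / (1 - beta2^step)
        w[[nm]] <- w[[nm]] - config$learning_rate * mhat / (sqrt(vhat) + eps)
      }
    }
    trace <- c(trace, mean(losses))
    if (length(val_idx) > 0) {
      vloss <- xent(
        specnet_forward(w, x[val_idx, , drop = FALSE], config)$probs,
        Y_all[val_idx, , drop = FALSE]
      )
      if (vloss < best_val - 1e-6) {
        best_val <- vloss; best_w <- w; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
  }
  if (length(val_idx) > 0) w <- best_w
  structure(
    list(weights = w, config = config, levels = levels(y), loss_trace = trace),
    class = "specnet_fit"
  )
}

#' @export
predict.specnet_fit <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  probs <- specnet_forward(object$weights, x, object$config)$probs
  colnames(probs) <- object$levels
  if (type == "class") {
    factor(object$levels[max.col(probs)], levels = object$levels)
  } else {
    probs
  }
}

#' Count the actual trainable parameters held by a fit
#' @param fit A `specnet_fit`.
#' @return Named integer vector of per-block counts (`C1`, `F3`, `output`).
#' @export
specnet_parameter_counts <- function(fit) {
  stopifnot(inherits(fit, "specnet_fit"))
  w <- fit$weights
  c(
    C1 = length(w$W1) + length(w$b1),
    F3 = length(w$W2) + length(w$b2),
    output = length(w$W3) + length(w$b3)
  )
}

#' @export
glance.specnet_fit <- function(x, ...) {
  tibble(
    n_params = sum(specnet_parameter_counts(x)),
    epochs_run = length(x$loss_trace),
    final_loss = x$loss_trace[length(x$loss_trace)]
  )
}
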