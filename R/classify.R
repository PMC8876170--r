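#' Mean squared error
#'
#' `(1/n) * sum((X - Y)^2)` over all entries, the training objective of the
#' perceptron classifiers.
#'
#' @param actual,predicted numeric vectors or matrices of equal shape.
#' @return nonnegative scalar.
#' @export
mse <- function(actual, predicted) {
  if (length(actual) == 0) stop("mse: empty input")
  if (!all(dim(as.matrix(actual)) == dim(as.matrix(predicted))))
    stop("mse: shape mismatch")
  mean((as.numeric(actual) - as.numeric(predicted))^2)
}

#' Training configuration for the perceptron classifiers
#'
#' Training runs full gradient descent on the configured objective and stops
#' at `max_epochs` or after `max_validation_failures` consecutive epochs
#' without improvement of the validation loss; the returned model is the
#' checkpoint from the best validation epoch. The two named presets differ
#' only in objective: `ann` minimizes the mean squared error between target
#' and softmax output, `ffnn` the cross-entropy.
#'
#' @param max_epochs cap on epochs (default 1000).
#' @param max_validation_failures early-stopping patience (default 6).
#' @param learning_rate gradient step (default 0.5).
#' @param batch_size mini-batch size; `Inf` (default) = full batch.
#' @param seed integer seed for weight initialization and batch order.
#' @param objective `"mse"` or `"cross_entropy"`.
#' @param hidden integer vector of hidden-layer widths (default 10, one
#'   hidden layer of 10 units; a 10-layer stack is available as
#'   `rep(10, 10)`).
#' @return list of class `train_config`.
#' @export
train_config <- function(max_epochs = 1000L, max_validation_failures = 6L,
                         learning_rate = 0.5, batch_size = Inf, seed = 0L,
                         objective = c("mse", "cross_entropy"),
                         hidden = 10L) {
  objective <- match.arg(objective)
  if (max_validation_failures < 1) stop("max_validation_failures must be >= 1")
  if (max_epochs < 1) stop("max_epochs must be >= 1")
  structure(list(max_epochs = as.integer(max_epochs),
                 max_validation_failures = as.integer(max_validation_failures),
                 learning_rate = learning_rate, batch_size = batch_size,
                 seed = as.integer(seed), objective = objective,
                 hidden = as.integer(hidden)),
            class = "train_config")
}

fit_scaler <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  list(mean = mu, sd = sdv)
}

apply_scaler <- function(scaler, X) {
  sweep(sweep(X, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}

label_targets <- function(labels) {
  f <- factor(labels, levels = c("normal", "leukemia"))
  if (any(is.na(f))) stop("labels must be 'normal' or 'leukemia'")
  T <- matrix(0, length(f), 2)
  T[cbind(seq_along(f), as.integer(f))] <- 1
  colnames(T) <- levels(f)
  T
}

mlp_init <- function(sizes, seed) {
  set.seed(seed)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1)) {
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1], 0, 1 / sqrt(sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(W = W, b = b)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

mlp_forward <- function(par, X) {
  L <- length(par$W)
  A <- list(X)
  for (l in seq_len(L - 1)) {
    Z <- sweep(A[[l]] %*% par$W[[l]], 2, par$b[[l]], "+")
    A[[l + 1]] <- sigmoid(Z)
  }
  Zout <- sweep(A[[L]] %*% par$W[[L]], 2, par$b[[L]], "+")
  P <- softmax_rows(Zout)
  list(A = A, P = P)
}

mlp_loss <- function(P, T, objective) {
  if (objective == "mse") mean((T - P)^2)
  else -mean(rowSums(T * log(pmax(P, 1e-12))))
}

mlp_backward <- function(par, fw, T, objective) {
  n <- nrow(T); L <- length(par$W)
  P <- fw$P
  if (objective == "cross_entropy") {
    dZ <- (P - T) / n
  } else {
    # d(mse)/dP through the softmax Jacobian
    dP <- 2 * (P - T) / length(T)
    dZ <- P * (dP - rowSums(dP * P))
  }
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in L:1) {
    gW[[l]] <- t(fw$A[[l]]) %*% dZ
    gb[[l]] <- colSums(dZ)
    if (l > 1) {
      dA <- dZ %*% t(par$W[[l]])
      dZ <- dA * fw$A[[l]] * (1 - fw$A[[l]])
    }
  }
  list(W = gW, b = gb)
}

grad_norm <- function(g) {
  sqrt(sum(vapply(g$W, function(m) sum(m^2), 0)) +
         sum(vapply(g$b, function(v) sum(v^2), 0)))
}

#' Train a multilayer perceptron classifier
#'
#' Standardizes features with training-partition statistics, then runs
#' gradient descent on the configured objective (mean squared error or
#' cross-entropy between the one-hot targets and the softmax output) with
#' validation-based early stopping: training halts at `max_epochs` or after
#' `max_validation_failures` consecutive epochs without a new validation-loss
#' minimum, and the returned weights are the best-validation checkpoint. The
#' per-epoch trace records train/validation/test loss, the gradient norm and
#' the failure counter.
#'
#' @param features numeric matrix, one row per sample.
#' @param labels `"leukemia"` / `"normal"` per row.
#' @param partition `"train"`, `"validation"` or `"test"` per row (rows with
#'   other values are ignored). Validation defaults to the training rows
#'   when absent.
#' @param config a [train_config()].
#' @return list of class `mlp_model` with the weights, scaler, trace and
#'   `best_epoch`.
#' @export
train_mlp <- function(features, labels, partition = NULL,
                      config = train_config()) {
  X <- as.matrix(features)
  if (!all(is.finite(X))) stop("train_mlp: features must be finite")
  if (is.null(partition)) partition <- rep("train", nrow(X))
  tr <- partition == "train"
  va <- partition == "validation"
  te <- partition == "test"
  if (!any(va)) va <- tr
  T <- label_targets(labels)
  if (length(unique(labels[tr])) < 2)
    stop("train_mlp: training partition must contain both classes")
  scaler <- fit_scaler(X[tr, , drop = FALSE])
  Xs <- apply_scaler(scaler, X)
  sizes <- c(ncol(X), config$hidden, 2L)
  par <- mlp_init(sizes, config$seed)
  set.seed(config$seed + 1L)
  nt <- sum(tr)
  bs <- if (is.finite(config$batch_size)) min(config$batch_size, nt) else nt
  Xtr <- Xs[tr, , drop = FALSE]; Ttr <- T[tr, , drop = FALSE]
  best <- list(loss = Inf, par = par, epoch = 0L)
  fails <- 0L
  trace <- data.frame(epoch = integer(), train_loss = double(),
                      val_loss = double(), test_loss = double(),
                      grad_norm = double(), val_failures = integer())
  for (ep in seq_len(config$max_epochs)) {
    ord <- if (bs < nt) sample.int(nt) else seq_len(nt)
    gnorm <- 0
    for (start in seq(1, nt, by = bs)) {
      idx <- ord[start:min(start + bs - 1, nt)]
      fw <- mlp_forward(par, Xtr[idx, , drop = FALSE])
      g <- mlp_backward(par, fw, Ttr[idx, , drop = FALSE], config$objective)
      gnorm <- grad_norm(g)
      if (!is.finite(gnorm))
        stop(sprintf("train_mlp: divergence at epoch %d (learning rate %g)",
                     ep, config$learning_rate))
      for (l in seq_along(par$W)) {
        par$W[[l]] <- par$W[[l]] - config$learning_rate * g$W[[l]]
        par$b[[l]] <- par$b[[l]] - config$learning_rate * g$b[[l]]
      }
    }
    ltr <- mlp_loss(mlp_forward(par, Xtr)$P, Ttr, config$objective)
    lva <- mlp_loss(mlp_forward(par, Xs[va, , drop = FALSE])$P,
                    T[va, , drop = FALSE], config$objective)
    lte <- if (any(te))
      mlp_loss(mlp_forward(par, Xs[te, , drop = FALSE])$P,
               T[te, , drop = FALSE], config$objective) else NA_real_
    if (!is.finite(ltr))
      stop(sprintf("train_mlp: divergence at epoch %d (learning rate %g)",
                   ep, config$learning_rate))
    if (lva < best$loss) {
      best <- list(loss = lva, par = par, epoch = ep)
      fails <- 0L
    } else {
      fails <- fails + 1L
    }
    trace <- rbind(trace, data.frame(epoch = ep, train_loss = ltr,
                                     val_loss = lva, test_loss = lte,
                                     grad_norm = gnorm, val_failures = fails))
    if (fails >= config$max_validation_failures) break
  }
  structure(list(par = best$par, scaler = scaler, sizes = sizes,
                 objective = config$objective, trace = trace,
                 best_epoch = best$epoch, levels = c("normal", "leukemia")),
            class = "mlp_model")
}

#' @export
predict.mlp_model <- function(object, features, ...) {
  X <- as.matrix(features)
  if (ncol(X) != object$sizes[1])
    stop("predict: feature width does not match the model input width")
  P <- mlp_forward(object$par, apply_scaler(object$scaler, X))$P
  data.frame(class = object$levels[max.col(P, ties.method = "first")],
             score = P[, 2], stringsAsFactors = FALSE)
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("mlp_model: %s, objective %s, best epoch %d (val loss %.5f)\n",
              paste(x$sizes, collapse = "-"), x$objective, x$best_epoch,
              min(x$trace$val_loss)))
  invisible(x)
}

#' Train the max-margin (SVM) classifier
#'
#' Soft-margin hyperplane on standardized features (linear kernel, default
#' `C = 1`), the classifier that separates the two classes by the hyperplane
#' of maximal margin. Stores the weight vector, bias and support-vector
#' indices.
#'
#' @param features numeric matrix, one row per sample.
#' @param labels `"leukemia"` / `"normal"` per row.
#' @param C regularization constant (default 1).
#' @return list of class `max_margin_model`.
#' @export
train_max_margin <- function(features, labels, C = 1) {
  X <- as.matrix(features)
  f <- factor(labels, levels = c("normal", "leukemia"))
  if (any(is.na(f))) stop("labels must be 'normal' or 'leukemia'")
  if (nlevels(droplevels(f)) < 2)
    stop("train_max_margin: both classes must be present")
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(scaler, X)
  y <- ifelse(f == "leukemia", 1, -1)
  fit <- e1071::svm(Xs, factor(y, levels = c(-1, 1)), kernel = "linear",
                    cost = C, scale = FALSE)
  w <- as.vector(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # e1071 orients decision values toward the first factor level (-1); flip
  # so positive signed distance means leukemia
  dv <- as.vector(Xs %*% w) + b
  if (stats::cor(dv, y) < 0) { w <- -w; b <- -b }
  structure(list(w = w, b = b, support = fit$index, C = C, scaler = scaler,
                 levels = c("normal", "leukemia")),
            class = "max_margin_model")
}

#' @export
predict.max_margin_model <- function(object, features, ...) {
  X <- as.matrix(features)
  if (ncol(X) != length(object$w))
    stop("predict: feature width does not match the model input width")
  d <- as.vector(apply_scaler(object$scaler, X) %*% object$w) + object$b
  data.frame(class = ifelse(d >= 0, "leukemia", "normal"), score = d,
             stringsAsFactors = FALSE)
}

#' @export
print.max_margin_model <- function(x, ...) {
  cat(sprintf("max_margin_model: linear, C = %g, %d support vectors, |w| = %.4f\n",
              x$C, length(x$support), sqrt(sum(x$w^2))))
  invisible(x)
}
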