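# Feature maps are numeric h x w x c arrays. Convolution is implemented as
# cross-correlation (the modern CNN convention); the classic flipped-kernel
# form differs only by a kernel reversal.

as_feature_map <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (length(dim(x)) != 3L) stop("feature map must be h x w x c")
  x
}

#' Convolution kernel
#'
#' @param weights `k x k x c_in x c_out` array (a `k x k` matrix is promoted
#'   to `k x k x 1 x 1`).
#' @param stride positive step size.
#' @param padding nonnegative zero-padding width; with `padding = (k-1)/2`,
#'   stride 1 and odd `k`, the spatial size is preserved.
#' @param bias per-output-channel bias (default zeros).
#' @return list of class `conv_kernel`.
#' @export
conv_kernel <- function(weights, stride = 1L, padding = 0L, bias = NULL) {
  if (is.matrix(weights)) weights <- array(weights, dim = c(dim(weights), 1L, 1L))
  d <- dim(weights)
  if (length(d) != 4L || d[1] != d[2]) stop("weights must be k x k x c_in x c_out")
  if (stride < 1L) stop("stride must be >= 1")
  if (padding < 0L) stop("padding must be >= 0")
  if (is.null(bias)) bias <- numeric(d[4])
  structure(list(weights = weights, stride = as.integer(stride),
                 padding = as.integer(padding), bias = bias),
            class = "conv_kernel")
}

pad_map <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), ] <- x
  out
}

# im2col: rows = output positions (row-major over (row, col)), cols = k*k*c_in
im2col <- function(x, k, stride) {
  d <- dim(x)
  ho <- (d[1] - k) %/% stride + 1L
  wo <- (d[2] - k) %/% stride + 1L
  r0 <- (seq_len(ho) - 1L) * stride
  c0 <- (seq_len(wo) - 1L) * stride
  cols <- matrix(0, ho * wo, k * k * d[3])
  col <- 0L
  for (ch in seq_len(d[3])) for (dc in seq_len(k)) for (dr in seq_len(k)) {
    col <- col + 1L
    cols[, col] <- as.vector(x[r0 + dr, c0 + dc, ch])
  }
  list(cols = cols, ho = ho, wo = wo)
}

#' 2-d convolution (cross-correlation) of a feature map
#'
#' Output spatial size is `floor((h + 2 pad - k) / stride) + 1`.
#'
#' @param input feature map (`h x w x c_in` array or matrix).
#' @param kernel a [conv_kernel()] with matching `c_in`.
#' @return `h' x w' x c_out` feature map.
#' @export
conv2d <- function(input, kernel) {
  x <- as_feature_map(input)
  d <- dim(kernel$weights)
  if (dim(x)[3] != d[3]) stop("conv2d: input channels do not match kernel c_in")
  xp <- pad_map(x, kernel$padding)
  if (d[1] > dim(xp)[1] || d[1] > dim(xp)[2])
    stop("conv2d: kernel larger than the padded input")
  ic <- im2col(xp, d[1], kernel$stride)
  W <- matrix(kernel$weights, d[1] * d[2] * d[3], d[4])
  out <- ic$cols %*% W
  out <- sweep(out, 2, kernel$bias, "+")
  array(out, dim = c(ic$ho, ic$wo, d[4]))
}

#' Rectified linear unit
#'
#' Elementwise `max(0, x)`: passes positive inputs, suppresses negatives.
#'
#' @param input feature map or numeric array.
#' @return same shape.
#' @export
relu <- function(input) pmax(input, 0)

pool_generic <- function(input, k, stride, f) {
  x <- as_feature_map(input)
  d <- dim(x)
  ho <- (d[1] - k) %/% stride + 1L
  wo <- (d[2] - k) %/% stride + 1L
  if (ho < 1 || wo < 1) stop("pooling window does not fit the input")
  out <- array(0, dim = c(ho, wo, d[3]))
  for (ch in seq_len(d[3])) for (i in seq_len(ho)) for (j in seq_len(wo)) {
    win <- x[(i - 1) * stride + seq_len(k), (j - 1) * stride + seq_len(k), ch]
    out[i, j, ch] <- f(win)
  }
  out
}

#' Max pooling
#'
#' Per-window maximum over `k x k` windows with step `stride`.
#'
#' @param input feature map.
#' @param k window edge.
#' @param stride step (default `k`).
#' @return pooled feature map.
#' @export
max_pool <- function(input, k = 2L, stride = k) pool_generic(input, k, stride, max)

#' Average pooling
#'
#' Per-window mean (`1/k^2` normalization) over `k x k` windows.
#'
#' @inheritParams max_pool
#' @return pooled feature map.
#' @export
avg_pool <- function(input, k = 2L, stride = k) pool_generic(input, k, stride, mean)

#' Dropout
#'
#' Training mode zeroes each unit independently with probability `rate` and
#' scales survivors by `1/(1-rate)` (inverted dropout), so evaluation mode is
#' the identity. Deterministic under a fixed seed.
#'
#' @param input feature map or numeric array.
#' @param rate drop probability in \[0, 1).
#' @param mode `"train"` or `"eval"`.
#' @param seed optional integer seed for the Bernoulli mask.
#' @return same shape as input.
#' @export
dropout <- function(input, rate = 0.5, mode = c("eval", "train"), seed = NULL) {
  mode <- match.arg(mode)
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (mode == "eval" || rate == 0) return(input)
  if (!is.null(seed)) set.seed(seed)
  keep <- runif(length(input)) >= rate
  out <- input
  out[!keep] <- 0
  out / (1 - rate)
}

#' Numerically stable softmax
#'
#' `exp(x_i - max(x)) / sum_j exp(x_j - max(x))`; the output is a probability
#' vector and is invariant to adding a constant to all logits.
#'
#' @param logits finite numeric vector.
#' @return probability vector of the same length.
#' @export
softmax <- function(logits) {
  if (!all(is.finite(logits))) stop("softmax: logits must be finite")
  z <- exp(logits - max(logits))
  z / sum(z)
}

softmax_rows <- function(M) {
  z <- exp(M - apply(M, 1, max))
  z / rowSums(z)
}

#' Micro-CNN specification
#'
#' A small trainable convolutional network that exercises every layer
#' operator at desk scale: conv(8 filters 3x3) - relu - maxpool(2) -
#' conv(16 filters 3x3) - relu - maxpool(2) - dense(32) - relu - dense(2) -
#' softmax, with dropout before the final dense layer during training. The
#' deep-feature tap is the 32-unit hidden activation; [extract_deep_features()]
#' returns it for the hybrid CNN-to-max-margin mode.
#'
#' @param input_size spatial input edge (images are resized to
#'   `input_size x input_size` grayscale; default 32).
#' @param conv_filters filter counts of the two conv layers.
#' @param dense_units width of the penultimate dense layer (the feature tap).
#' @param dropout_rate drop probability before the final layer (default 0.5).
#' @return list of class `micro_cnn_spec`.
#' @export
micro_cnn_spec <- function(input_size = 32L, conv_filters = c(8L, 16L),
                           dense_units = 32L, dropout_rate = 0.5) {
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  s <- as.integer(input_size)
  if (s %% 4 != 0) stop("input_size must be divisible by 4")
  structure(list(input_size = s, conv_filters = as.integer(conv_filters),
                 dense_units = as.integer(dense_units),
                 dropout_rate = dropout_rate,
                 flat_size = (s %/% 4)^2 * conv_filters[2]),
            class = "micro_cnn_spec")
}

init_micro_cnn <- function(spec, seed = 0L) {
  set.seed(seed)
  he <- function(fanin, n) rnorm(n, 0, sqrt(2 / fanin))
  list(
    W1 = array(he(9, 9 * spec$conv_filters[1]), dim = c(3, 3, 1, spec$conv_filters[1])),
    b1 = numeric(spec$conv_filters[1]),
    W2 = array(he(9 * spec$conv_filters[1],
                  9 * spec$conv_filters[1] * spec$conv_filters[2]),
               dim = c(3, 3, spec$conv_filters[1], spec$conv_filters[2])),
    b2 = numeric(spec$conv_filters[2]),
    W3 = matrix(he(spec$flat_size, spec$flat_size * spec$dense_units),
                spec$flat_size, spec$dense_units),
    b3 = numeric(spec$dense_units),
    W4 = matrix(he(spec$dense_units, spec$dense_units * 2), spec$dense_units, 2),
    b4 = numeric(2)
  )
}

# forward pass; keeps intermediates for backprop when train = TRUE
micro_cnn_forward <- function(state, spec, x, train = FALSE, drop_mask = NULL) {
  k1 <- conv_kernel(state$W1, stride = 1L, padding = 1L, bias = state$b1)
  k2 <- conv_kernel(state$W2, stride = 1L, padding = 1L, bias = state$b2)
  a0 <- as_feature_map(x)
  z1 <- conv2d(a0, k1); a1 <- relu(z1)
  p1 <- max_pool_cache(a1, 2L)
  z2 <- conv2d(p1$out, k2); a2 <- relu(z2)
  p2 <- max_pool_cache(a2, 2L)
  flat <- as.vector(p2$out)
  z3 <- as.vector(flat %*% state$W3) + state$b3
  a3 <- pmax(z3, 0)
  a3d <- a3
  if (train && !is.null(drop_mask)) a3d <- a3 * drop_mask
  z4 <- as.vector(a3d %*% state$W4) + state$b4
  p <- softmax(z4)
  list(a0 = a0, z1 = z1, a1 = a1, p1 = p1, z2 = z2, a2 = a2, p2 = p2,
       flat = flat, z3 = z3, a3 = a3, a3d = a3d, z4 = z4, p = p)
}

max_pool_cache <- function(x, k) {
  d <- dim(x)
  ho <- d[1] %/% k; wo <- d[2] %/% k
  out <- array(0, dim = c(ho, wo, d[3]))
  arg <- array(0L, dim = c(ho, wo, d[3]))
  for (ch in seq_len(d[3])) for (i in seq_len(ho)) for (j in seq_len(wo)) {
    rs <- (i - 1) * k + seq_len(k); cs <- (j - 1) * k + seq_len(k)
    win <- x[rs, cs, ch]
    m <- which.max(win)
    out[i, j, ch] <- win[m]
    arg[i, j, ch] <- (rs[(m - 1) %% k + 1]) + (cs[(m - 1) %/% k + 1] - 1) * d[1] +
      (ch - 1) * d[1] * d[2]
  }
  list(out = out, arg = arg, in_dim = d, k = k)
}

max_pool_backward <- function(cache, dout) {
  dx <- array(0, dim = cache$in_dim)
  dx[as.vector(cache$arg)] <- dx[as.vector(cache$arg)] + as.vector(dout)
  dx
}

conv2d_backward <- function(x, kernel, dout) {
  # returns gradients w.r.t. weights, bias and input
  d <- dim(kernel$weights); k <- d[1]
  xp <- pad_map(as_feature_map(x), kernel$padding)
  ic <- im2col(xp, k, kernel$stride)
  dmat <- matrix(dout, ic$ho * ic$wo, d[4])
  dW <- array(t(ic$cols) %*% dmat, dim = d)
  db <- colSums(dmat)
  W <- matrix(kernel$weights, k * k * d[3], d[4])
  dcols <- dmat %*% t(W)
  # scatter dcols back (col2im)
  dxp <- array(0, dim = dim(xp))
  r0 <- (seq_len(ic$ho) - 1L) * kernel$stride
  c0 <- (seq_len(ic$wo) - 1L) * kernel$stride
  col <- 0L
  for (ch in seq_len(d[3])) for (dc in seq_len(k)) for (dr in seq_len(k)) {
    col <- col + 1L
    dxp[r0 + dr, c0 + dc, ch] <- dxp[r0 + dr, c0 + dc, ch] +
      matrix(dcols[, col], ic$ho, ic$wo)
  }
  p <- kernel$padding
  din <- if (p > 0)
    dxp[p + seq_len(dim(xp)[1] - 2 * p), p + seq_len(dim(xp)[2] - 2 * p), , drop = FALSE]
  else dxp
  list(dW = dW, db = db, din = din)
}

# cross-entropy loss and full backward pass for one sample; y in {1, 2}
micro_cnn_grad <- function(state, spec, x, y, dm) {
  fw <- micro_cnn_forward(state, spec, x, train = TRUE, drop_mask = dm)
  t2 <- c(0, 0); t2[y] <- 1
  loss <- -log(max(fw$p[y], 1e-12))
  dz4 <- fw$p - t2
  dW4 <- outer(fw$a3d, dz4); db4 <- dz4
  da3d <- as.vector(state$W4 %*% dz4)
  da3 <- da3d * dm
  dz3 <- da3 * (fw$z3 > 0)
  dW3 <- outer(fw$flat, dz3); db3 <- dz3
  dflat <- as.vector(state$W3 %*% dz3)
  dp2 <- array(dflat, dim = dim(fw$p2$out))
  da2 <- max_pool_backward(fw$p2, dp2)
  dz2 <- da2 * (fw$z2 > 0)
  k2 <- conv_kernel(state$W2, 1L, 1L, state$b2)
  g2 <- conv2d_backward(fw$p1$out, k2, dz2)
  da1 <- max_pool_backward(fw$p1, g2$din)
  dz1 <- da1 * (fw$z1 > 0)
  k1 <- conv_kernel(state$W1, 1L, 1L, state$b1)
  g1 <- conv2d_backward(fw$a0, k1, dz1)
  list(loss = loss,
       grads = list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db,
                    W3 = dW3, b3 = db3, W4 = dW4, b4 = db4))
}

#' Train the micro-CNN
#'
#' Mini-batch stochastic gradient descent on the softmax cross-entropy, with
#' inverted dropout before the final dense layer. All randomness
#' (initialization, batch order, dropout masks) flows from `seed`.
#'
#' @param images list of single-channel `raster_image`s or matrices (resized
#'   to the spec input size internally).
#' @param labels factor or character vector with levels
#'   `c("normal", "leukemia")`.
#' @param spec a [micro_cnn_spec()].
#' @param epochs training epochs (default 40).
#' @param batch_size mini-batch size (default 16).
#' @param lr learning rate (default 0.05).
#' @param momentum classical momentum coefficient (default 0.9).
#' @param weight_decay optional L2 penalty on the weights (not biases),
#'   default 0.
#' @param seed integer seed (default 0).
#' @return list of class `micro_cnn` with elements `spec`, `state`, `trace`
#'   (per-epoch mean training loss).
#' @export
train_micro_cnn <- function(images, labels, spec = micro_cnn_spec(),
                            epochs = 40L, batch_size = 16L, lr = 0.05,
                            momentum = 0.9, weight_decay = 0, seed = 0L) {
  labels <- factor(labels, levels = c("normal", "leukemia"))
  if (any(is.na(labels))) stop("labels must be 'normal' or 'leukemia'")
  xs <- lapply(images, function(im) micro_cnn_input(im, spec))
  y <- as.integer(labels)  # 1 = normal, 2 = leukemia
  n <- length(xs)
  state <- init_micro_cnn(spec, seed = seed)
  set.seed(seed + 1L)
  trace <- numeric(epochs)
  vel <- lapply(state, function(p) p * 0)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      grads <- NULL
      bl <- 0
      for (i in idx) {
        dm <- if (spec$dropout_rate > 0)
          (runif(spec$dense_units) >= spec$dropout_rate) / (1 - spec$dropout_rate)
        else rep(1, spec$dense_units)
        res <- micro_cnn_grad(state, spec, xs[[i]], y[i], dm)
        bl <- bl + res$loss
        grads <- if (is.null(grads)) res$grads else Map(`+`, grads, res$grads)
      }
      scale <- lr / length(idx)
      for (nm in names(grads)) {
        g <- grads[[nm]]
        if (substr(nm, 1, 1) == "W") g <- g + weight_decay * length(idx) * state[[nm]]
        vel[[nm]] <- momentum * vel[[nm]] - scale * g
        state[[nm]] <- state[[nm]] + vel[[nm]]
      }
      losses <- c(losses, bl / length(idx))
    }
    trace[ep] <- mean(losses)
  }
  structure(list(spec = spec, state = state, trace = trace,
                 levels = c("normal", "leukemia")),
            class = "micro_cnn")
}

micro_cnn_input <- function(im, spec) {
  if (inherits(im, "raster_image")) {
    im <- to_grayscale(im)
    if (img_height(im) != spec$input_size || img_width(im) != spec$input_size)
      im <- resize_image(im, spec$input_size, spec$input_size)
    m <- img_data(im)[, , 1]
  } else {
    m <- as.matrix(im)
    if (!all(dim(m) == spec$input_size))
      stop("matrix input must already be input_size x input_size")
  }
  # center on mid-gray so early layers see signed contrast
  array(m / 255 - 0.5, dim = c(spec$input_size, spec$input_size, 1L))
}

#' Deep features from the micro-CNN
#'
#' Runs the forward pass in evaluation mode (dropout is the identity) up to
#' the feature tap — the penultimate dense layer's rectified activation —
#' and returns it as a flat vector.
#'
#' @param model a trained `micro_cnn`.
#' @param image single-channel or color `raster_image` (resized internally).
#' @return numeric vector of length `dense_units`.
#' @export
extract_deep_features <- function(model, image) {
  x <- micro_cnn_input(image, model$spec)
  fw <- micro_cnn_forward(model$state, model$spec, x, train = FALSE)
  fw$a3
}

#' @export
predict.micro_cnn <- function(object, images, ...) {
  if (inherits(images, "raster_image") || is.matrix(images)) images <- list(images)
  res <- t(vapply(images, function(im) {
    x <- micro_cnn_input(im, object$spec)
    micro_cnn_forward(object$state, object$spec, x)$p
  }, numeric(2)))
  colnames(res) <- object$levels
  data.frame(class = object$levels[max.col(res, ties.method = "first")],
             score = res[, "leukemia"], stringsAsFactors = FALSE)
}

#' @export
print.micro_cnn <- function(x, ...) {
  cat(sprintf("micro_cnn: input %dx%d, conv %s, dense %d, final loss %.4f\n",
              x$spec$input_size, x$spec$input_size,
              paste(x$spec$conv_filters, collapse = "/"),
              x$spec$dense_units, utils::tail(x$trace, 1)))
  invisible(x)
}
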