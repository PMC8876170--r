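test_that("convolution reproduces identity, border and brute-force cases", {
  set.seed(61)
  x <- matrix(runif(25), 5, 5)
  ident <- conv_kernel(matrix(1, 1, 1))
  expect_equal(conv2d(x, ident)[, , 1], x)

  ones <- conv_kernel(matrix(1, 3, 3), stride = 1L, padding = 1L)
  out <- conv2d(matrix(1, 5, 5), ones)[, , 1]
  expect_equal(out[3, 3], 9)
  expect_equal(out[1, 1], 4)
  expect_equal(dim(out), c(5L, 5L))  # pad (k-1)/2 preserves size

  for (i in 1:4) {
    cin <- sample(1:2, 1); cout <- sample(1:3, 1)
    stride <- sample(1:2, 1); pad <- sample(0:1, 1)
    xx <- array(runif(6 * 6 * cin), dim = c(6, 6, cin))
    wts <- array(rnorm(3 * 3 * cin * cout), dim = c(3, 3, cin, cout))
    bias <- rnorm(cout)
    k <- conv_kernel(wts, stride = stride, padding = pad, bias = bias)
    expect_equal(conv2d(xx, k), brute_conv2d(xx, wts, stride, pad, bias),
                 tolerance = 1e-9)
  }
  expect_error(conv2d(matrix(1, 2, 2), conv_kernel(matrix(1, 5, 5))),
               "kernel larger")
})

test_that("relu passes positives, suppresses negatives, and is idempotent", {
  expect_equal(relu(-2), 0)
  expect_equal(relu(3), 3)
  set.seed(62)
  x <- array(rnorm(32), dim = c(4, 4, 2))
  expect_equal(relu(relu(x)), relu(x))
})

test_that("pooling layers match their per-window definitions", {
  m <- matrix(c(1, 3, 2, 4), 2, 2)  # [[1,2],[3,4]] row-wise
  expect_equal(as.vector(max_pool(m, 2L)), 4)
  expect_equal(as.vector(avg_pool(m, 2L)), 2.5)
  cmap <- array(7, dim = c(6, 6, 2))
  expect_true(all(max_pool(cmap, 2L) == 7))
  expect_true(all(avg_pool(cmap, 3L) == 7))
  set.seed(63)
  x <- array(runif(128), dim = c(8, 8, 2))
  expect_equal(max_pool(x, 2L, 2L), brute_pool(x, 2L, 2L, max), tolerance = 1e-9)
  expect_equal(avg_pool(x, 2L, 2L), brute_pool(x, 2L, 2L, mean), tolerance = 1e-9)
  expect_equal(max_pool(x, 3L, 1L), brute_pool(x, 3L, 1L, max), tolerance = 1e-9)
})

test_that("dropout is identity in eval mode and Bernoulli in train mode", {
  x <- array(1, dim = c(100, 100, 1))
  expect_equal(dropout(x, 0.5, "eval"), x)
  expect_equal(dropout(x, 0, "train"), x)
  d <- dropout(x, 0.5, "train", seed = 99)
  frac <- mean(d == 0)
  expect_lt(abs(frac - 0.5), 0.02)
  expect_true(all(d[d != 0] == 2))  # inverted scaling
  expect_equal(dropout(x, 0.5, "train", seed = 99), d)  # seeded determinism
})

test_that("softmax is a stable probability simplex map", {
  expect_equal(softmax(c(1, 1)), c(0.5, 0.5))
  expect_equal(softmax(c(0, log(3))), c(0.25, 0.75))
  set.seed(64)
  z <- rnorm(5)
  expect_equal(softmax(z), softmax(z + 42), tolerance = 1e-12)
  big <- c(1000, 1001)
  p <- softmax(big)
  expect_true(all(is.finite(p)) && abs(sum(p) - 1) < 1e-12)
  expect_error(softmax(c(1, Inf)), "finite")
})

test_that("convolution backward pass agrees with numerical gradients", {
  set.seed(65)
  x <- array(runif(5 * 5 * 2), dim = c(5, 5, 2))
  wts <- array(rnorm(3 * 3 * 2 * 2, 0, 0.5), dim = c(3, 3, 2, 2))
  k <- conv_kernel(wts, stride = 1L, padding = 1L, bias = rnorm(2))
  dout <- array(rnorm(5 * 5 * 2), dim = c(5, 5, 2))
  g <- leukodiag:::conv2d_backward(x, k, dout)
  loss <- function(w) sum(conv2d(x, conv_kernel(w, 1L, 1L, k$bias)) * dout)
  eps <- 1e-6
  for (idx in sample(length(wts), 6)) {
    wp <- wts; wp[idx] <- wp[idx] + eps
    wm <- wts; wm[idx] <- wm[idx] - eps
    expect_equal(g$dW[idx], (loss(wp) - loss(wm)) / (2 * eps), tolerance = 1e-4)
  }
  lossx <- function(xx) sum(conv2d(xx, k) * dout)
  for (idx in sample(length(x), 6)) {
    xp <- x; xp[idx] <- xp[idx] + eps
    xm <- x; xm[idx] <- xm[idx] - eps
    expect_equal(g$din[idx], (lossx(xp) - lossx(xm)) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("the micro network trains and yields deterministic deep features", {
  # tiny separable problem: bright-center versus bright-corner 8x8 patterns
  set.seed(66)
  mk <- function(type) {
    m <- matrix(runif(64, 0, 40), 8, 8)
    if (type == "leukemia") m[3:6, 3:6] <- m[3:6, 3:6] + 180
    else m[1:3, 1:3] <- m[1:3, 1:3] + 180
    raster_image(m)
  }
  imgs <- c(lapply(1:12, function(i) mk("leukemia")),
            lapply(1:12, function(i) mk("normal")))
  labs <- rep(c("leukemia", "normal"), each = 12)
  spec <- micro_cnn_spec(input_size = 8L, conv_filters = c(4L, 8L),
                         dense_units = 8L)
  model <- train_micro_cnn(imgs, labs, spec, epochs = 15L, batch_size = 8L,
                           seed = 1L)
  expect_lt(tail(model$trace, 1), model$trace[1])  # loss decreased
  pred <- predict(model, imgs)
  expect_gte(mean(pred$class == labs), 0.9)

  f1 <- extract_deep_features(model, imgs[[1]])
  f2 <- extract_deep_features(model, imgs[[1]])
  expect_identical(f1, f2)
  expect_length(f1, 8L)

  # two identical runs give identical weights
  model2 <- train_micro_cnn(imgs, labs, spec, epochs = 15L, batch_size = 8L,
                            seed = 1L)
  expect_identical(model$state, model2$state)
})
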