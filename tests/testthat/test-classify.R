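make_blobs <- function(n_per = 100, sep = 6, d = 5, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * d), n_per, d),
             matrix(rnorm(n_per * d, mean = sep), n_per, d))
  list(X = X, y = rep(c("normal", "leukemia"), each = n_per))
}

test_that("mean squared error follows its definition", {
  expect_equal(mse(c(1, 2), c(1, 2)), 0)
  expect_equal(mse(c(1, 2), c(3, 2)), 2.0)
  set.seed(71)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(mse(a, a + 2 * (b - a)), 4 * mse(a, b), tolerance = 1e-12)
  expect_error(mse(numeric(0), numeric(0)), "empty")
})

test_that("the perceptron fits separable data deterministically", {
  bl <- make_blobs()
  part <- rep(c("train", "validation"), length.out = 200)
  cfg <- train_config(max_epochs = 200L, seed = 3L)
  fit <- train_mlp(bl$X, bl$y, part, cfg)
  pred <- predict(fit, bl$X[part == "train", ])
  expect_equal(mean(pred$class == bl$y[part == "train"]), 1.0)
  # determinism: identical runs, identical weights
  fit2 <- train_mlp(bl$X, bl$y, part, cfg)
  expect_identical(fit$par, fit2$par)
  # softmax scores sum to 1 and are order independent
  p_all <- predict(fit, bl$X)
  expect_true(all(abs(p_all$score - (1 - (1 - p_all$score))) < 1e-12))
  ord <- sample(nrow(bl$X))
  expect_equal(predict(fit, bl$X[ord, ])$score, p_all$score[ord])
})

test_that("early stopping halts after six failed validation checks", {
  # adversarial validation set (flipped labels): validation loss worsens as
  # the fit improves, forcing the patience rule to trigger
  bl <- make_blobs(n_per = 40, seed = 5)
  Xv <- bl$X[c(1:10, 41:50), ] + 0
  yv <- rev(bl$y[c(1:10, 41:50)])
  X <- rbind(bl$X, Xv)
  y <- c(bl$y, yv)
  part <- c(rep("train", 80), rep("validation", 20))
  cfg <- train_config(max_epochs = 500L, seed = 2L)
  fit <- train_mlp(X, y, part, cfg)
  tr <- fit$trace
  expect_lt(nrow(tr), 500L)
  expect_equal(nrow(tr), fit$best_epoch + 6L)
  expect_equal(tail(tr$val_failures, 1), 6L)
  # returned checkpoint is the validation-loss minimum, not the final epoch
  expect_equal(tr$val_loss[fit$best_epoch], min(tr$val_loss))
  # train loss along the best-so-far sequence is non-increasing
  best_idx <- which(tr$val_loss == cummin(tr$val_loss))
  expect_true(all(diff(tr$train_loss[best_idx]) <= 1e-9))
})

test_that("perceptron rejects degenerate inputs", {
  bl <- make_blobs(n_per = 10)
  expect_error(train_mlp(bl$X[1:10, ], bl$y[1:10], config = train_config()),
               "both classes")
  Xbad <- bl$X; Xbad[1, 1] <- NA
  expect_error(train_mlp(Xbad, bl$y, config = train_config()), "finite")
})

test_that("the max-margin classifier finds the maximal-margin hyperplane", {
  # symmetric pair in 1-d: boundary at 0, both points support vectors
  X <- matrix(c(-1, 1), 2, 1)
  y <- c("normal", "leukemia")
  fit <- train_max_margin(X, y)
  expect_setequal(fit$support, c(1L, 2L))
  p <- predict(fit, matrix(c(-0.5, 0.5), 2, 1))
  expect_equal(p$class, c("normal", "leukemia"))
  expect_equal(sum(predict(fit, X)$score), 0, tolerance = 1e-6)

  # 5-point toy: margin matches the coarse-to-fine brute-force maximizer
  X5 <- rbind(c(0, 0), c(1, 0.5), c(0.4, -0.7),
              c(3, 2.5), c(2.6, 3.4))
  y5 <- c(-1, -1, -1, 1, 1)
  fit5 <- train_max_margin(X5, ifelse(y5 > 0, "leukemia", "normal"), C = 1e6)
  # the fitted functional margin in scaled space: min |w x + b| / |w|
  Xs <- leukodiag:::apply_scaler(fit5$scaler, X5)
  dv <- as.vector(Xs %*% fit5$w) + fit5$b
  fitted_margin <- min(abs(dv)) / sqrt(sum(fit5$w^2))
  oracle <- brute_max_margin_2d(Xs, y5)
  expect_equal(fitted_margin, oracle$margin, tolerance = 1e-6)

  # separable blobs: zero training errors; duplication leaves boundary put
  bl <- make_blobs(n_per = 30, seed = 7)
  f1 <- train_max_margin(bl$X, bl$y)
  expect_equal(mean(predict(f1, bl$X)$class == bl$y), 1.0)
  f2 <- train_max_margin(rbind(bl$X, bl$X), c(bl$y, bl$y))
  expect_equal(predict(f2, bl$X)$score, predict(f1, bl$X)$score,
               tolerance = 1e-4)

  # removing a non-support vector does not move the boundary
  non_sv <- setdiff(seq_len(nrow(X5)), fit5$support)[1]
  fit5b <- train_max_margin(X5[-non_sv, ],
                            ifelse(y5[-non_sv] > 0, "leukemia", "normal"),
                            C = 1e6)
  pr_before <- predict(fit5, X5)$class
  pr_after <- predict(fit5b, X5)$class
  expect_equal(pr_after, pr_before)

  expect_error(train_max_margin(X5, rep("normal", 5)), "both classes")
  expect_error(predict(fit5, matrix(0, 1, 3)), "width")
})
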