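test_that("confusion counts agree with a one-pass tally oracle", {
  truth <- rep(c("leukemia", "normal"), c(10, 12))
  cm <- confusion(truth, truth)
  expect_equal(unlist(cm[c("tp", "fn", "fp", "tn")]),
               c(tp = 10L, fn = 0L, fp = 0L, tn = 12L))
  all_neg <- confusion(rep(c("leukemia", "normal"), c(6, 4)),
                       rep("normal", 10))
  expect_equal(all_neg$tp, 0L)
  expect_equal(all_neg$fn, 6L)
  set.seed(81)
  yt <- sample(c("leukemia", "normal"), 50, replace = TRUE)
  yp <- sample(c("leukemia", "normal"), 50, replace = TRUE)
  cm2 <- confusion(yt, yp)
  tally <- c(tp = 0L, fn = 0L, fp = 0L, tn = 0L)
  for (i in 1:50) {
    k <- if (yt[i] == "leukemia") {
      if (yp[i] == "leukemia") "tp" else "fn"
    } else {
      if (yp[i] == "leukemia") "fp" else "tn"
    }
    tally[k] <- tally[k] + 1L
  }
  expect_equal(unlist(cm2[c("tp", "fn", "fp", "tn")]), tally)
  expect_error(confusion(yt, yp[1:10]), "length")
})

test_that("the four screening metrics follow their printed formulas", {
  perfect <- structure(list(tp = 10L, fn = 0L, fp = 0L, tn = 12L),
                       class = "confusion_2x2")
  expect_equal(unname(classification_metrics(perfect)), rep(100, 4))
  mixed <- structure(list(tp = 5L, fn = 1L, fp = 2L, tn = 12L),
                     class = "confusion_2x2")
  m <- classification_metrics(mixed)
  expect_equal(round(unname(m), 2), c(85.00, 71.43, 83.33, 85.71))
  nopos <- structure(list(tp = 0L, fn = 0L, fp = 3L, tn = 7L),
                     class = "confusion_2x2")
  expect_warning(m2 <- classification_metrics(nopos), "sensitivity undefined")
  expect_equal(unname(m2["precision"]), 0)
  expect_true(is.nan(m2[["sensitivity"]]))
  # accuracy decomposes into the class-rate mixture
  set.seed(82)
  for (i in 1:10) {
    cm <- structure(as.list(setNames(sample(1:20, 4), c("tp", "fn", "fp", "tn"))),
                    class = "confusion_2x2")
    mm <- classification_metrics(cm)
    tot <- cm$tp + cm$fn + cm$fp + cm$tn
    lhs <- mm[["accuracy"]]
    rhs <- (mm[["sensitivity"]] * (cm$tp + cm$fn) +
              mm[["specificity"]] * (cm$tn + cm$fp)) / tot
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("rank-based AUC handles separation, ties and concordance counting", {
  y <- rep(c("leukemia", "normal"), each = 5)
  expect_equal(roc_auc(c(6:10, 1:5), y)$auc, 100)
  expect_equal(roc_auc(rep(1, 10), y)$auc, 50)
  r <- roc_auc(c(0.9, 0.8, 0.3, 0.1), c("leukemia", "normal", "leukemia", "normal"))
  expect_equal(r$auc, 75)
  # invariance under strictly monotone transforms
  set.seed(83)
  sc <- rnorm(40)
  yy <- sample(c("leukemia", "normal"), 40, replace = TRUE,
               prob = c(0.5, 0.5))
  yy[1:2] <- c("leukemia", "normal")
  expect_equal(roc_auc(sc, yy)$auc, roc_auc(exp(sc), yy)$auc)
  expect_equal(roc_auc(sc, yy)$auc, roc_auc(atan(sc) * 3 + 2, yy)$auc)
  # curve geometry: (0,0) to (1,1), monotone in both coordinates
  cv <- roc_auc(sc, yy)$curve
  expect_equal(c(cv$fpr[1], cv$tpr[1]), c(0, 0))
  expect_equal(c(tail(cv$fpr, 1), tail(cv$tpr, 1)), c(1, 1))
  expect_true(all(diff(cv$fpr) >= 0) && all(diff(cv$tpr) >= 0))
  # independent reference implementation agrees
  skip_if_not_installed("pROC")
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = factor(yy, levels = c("normal", "leukemia")), predictor = sc,
    direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(sc, yy)$auc, 100 * as.numeric(ref), tolerance = 1e-9)
  expect_error(roc_auc(sc, rep("normal", 40)), "both classes")
})

test_that("error histogram conserves counts over equal-width bins", {
  eh0 <- error_histogram(rep(1, 5), rep(1, 5))
  expect_equal(sum(eh0$counts), 5L)
  zero_bins <- which(eh0$breaks[-1] >= 0 & head(eh0$breaks, -1) <= 0)
  expect_equal(sum(eh0$counts[zero_bins]), 5L)
  eh2 <- error_histogram(c(-1, 1), c(0, 0), bins = 2L)
  expect_equal(eh2$counts, c(1L, 1L))
  expect_equal(eh2$breaks, c(-1, 0, 1))
  set.seed(84)
  a <- rnorm(100); p <- rnorm(100)
  eh <- error_histogram(a, p)
  expect_length(eh$counts, 20L)
  expect_equal(sum(eh$counts), 100L)
})

test_that("regression R is the Pearson correlation", {
  x <- c(0.2, 0.4, 0.9, 0.1, 0.5)
  expect_equal(regression_r(x, x), 1.0)
  expect_equal(regression_r(x, -x), -1.0)
  set.seed(85)
  a <- rnorm(10); p <- rnorm(10)
  oracle <- sum((a - mean(a)) * (p - mean(p))) /
    sqrt(sum((a - mean(a))^2) * sum((p - mean(p))^2))
  expect_equal(regression_r(a, p), oracle, tolerance = 1e-12)
  expect_warning(rr <- regression_r(rep(1, 5), 1:5), "zero variance")
  expect_true(is.na(rr))
})

test_that("the bundled report carries consistent pieces", {
  set.seed(86)
  y <- sample(c("leukemia", "normal"), 30, replace = TRUE)
  y[1:2] <- c("leukemia", "normal")
  sc <- rnorm(30) + 2 * (y == "leukemia")
  rep_ <- evaluation_report(y, ifelse(sc > 1, "leukemia", "normal"), sc)
  expect_s3_class(rep_, "evaluation_report")
  expect_equal(rep_$n, 30L)
  expect_equal(sum(rep_$error_histogram$counts), 30L)
  expect_true(rep_$auc >= 0 && rep_$auc <= 100)
  cm <- rep_$confusion
  expect_equal(cm$tp + cm$fn + cm$fp + cm$tn, 30L)
})
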