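test_that("LBP histogram matches forced and hand-derived cases", {
  # constant ROI: every difference is 0, s(0) = 1, code = 2^24 - 1, last bin
  m <- matrix(100, 9, 9)
  roi <- matrix(TRUE, 9, 9)
  h <- lbp_histogram(m, roi)
  expect_length(h, 203L)
  expect_equal(h[203], 1)
  expect_equal(sum(h), 1)

  # additive shift invariance
  set.seed(51)
  m2 <- matrix(runif(81, 0, 200), 9, 9)
  expect_equal(lbp_histogram(m2, roi), lbp_histogram(m2 + 17, roi))

  # empty ROI: zero vector with a warning
  expect_warning(h0 <- lbp_histogram(m2, matrix(FALSE, 9, 9)), "empty ROI")
  expect_equal(h0, numeric(203))
})

test_that("LBP codes equal the brute-force double-loop evaluation", {
  set.seed(52)
  for (i in 1:5) {
    m <- matrix(sample(0:255, 81, replace = TRUE), 9, 9)
    roi <- matrix(runif(81) < 0.8, 9, 9)
    expect_equal(lbp_histogram(m, roi), brute_lbp_histogram(m, roi),
                 tolerance = 1e-9)
  }
  # a 7x7 toy: all interior codes individually
  m7 <- matrix(sample(0:20, 49, replace = TRUE), 7, 7)
  codes <- leukodiag:::lbp_codes_cpp(m7, matrix(1L, 7, 7))
  for (r in 3:5) for (c in 3:5) {
    expect_equal(codes[r, c], brute_lbp_code(m7, r, c))
  }
})

test_that("co-occurrence matrices are symmetric probability tables", {
  q <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)
  P <- leukodiag:::cooccurrence_matrix(q, matrix(TRUE, 2, 2), 0L, 1L, 2L)
  expect_equal(P, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  st <- haralick_stats(P)
  expect_equal(unname(st["contrast"]), 0)
  expect_equal(unname(st["asm"]), 0.5)
  set.seed(53)
  m <- matrix(runif(64, 0, 255), 8, 8)
  roi <- matrix(runif(64) < 0.9, 8, 8)
  qq <- leukodiag:::quantize_gray(m, 16L)
  for (off in list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))) {
    P2 <- leukodiag:::cooccurrence_matrix(qq, roi, off[1], off[2], 16L)
    expect_equal(P2, t(P2))
    expect_equal(sum(P2), 1)
  }
})

test_that("the 13 Haralick statistics match a scalar-loop oracle", {
  set.seed(54)
  for (i in 1:5) {
    n <- sample(2:6, 1)
    C <- matrix(runif(n * n), n, n)
    C <- C + t(C)
    P <- C / sum(C)
    expect_equal(unname(haralick_stats(P)), brute_haralick(P), tolerance = 1e-9)
  }
})

test_that("GLCM features have the printed arity and degenerate limits", {
  m <- matrix(128, 10, 10)
  roi <- matrix(TRUE, 10, 10)
  v <- glcm_features(m, roi)
  expect_length(v, 13L)
  expect_equal(unname(v["asm"]), 1)
  expect_equal(unname(v["contrast"]), 0)
  expect_equal(unname(v["entropy"]), 0)
  expect_warning(v0 <- glcm_features(m, matrix(FALSE, 10, 10)), "no co-occurring")
  expect_equal(unname(v0), numeric(13))
})

test_that("color histogram implements crisp and fuzzy membership", {
  # single color: one crisp bin
  img <- raster_image(array(rep(c(10, 10, 200), each = 16), dim = c(4, 4, 3)))
  roi <- matrix(TRUE, 4, 4)
  v <- fch_features(img, roi)
  expect_length(v, 16L)
  expect_equal(sum(v), 1)
  expect_equal(sum(v == 1), 1L)

  # half in one bin, half in another
  a <- array(0, dim = c(2, 2, 3))
  a[1, , ] <- rep(c(10, 10, 10), each = 2)     # dark bin
  a[2, , ] <- rep(c(240, 240, 240), each = 2)  # bright bin
  v2 <- fch_features(raster_image(a), matrix(TRUE, 2, 2))
  expect_equal(sort(v2[v2 > 0]), c(0.5, 0.5))

  # fuzzy memberships still sum to one, and both modes are permutation
  # invariant by construction (pixel sums)
  set.seed(55)
  img3 <- raster_image(array(runif(75, 0, 255), dim = c(5, 5, 3)))
  roi3 <- matrix(runif(25) < 0.7, 5, 5)
  for (mode in c("crisp", "fuzzy")) {
    v3 <- fch_features(img3, roi3, fch_params(membership = mode))
    expect_equal(sum(v3), 1, tolerance = 1e-12)
    expect_true(all(v3 >= 0))
  }
  expect_warning(fch_features(img3, matrix(FALSE, 5, 5)), "empty ROI")
})

test_that("fusion concatenates 203+13+16 into a named 232-vector and back", {
  lbp <- runif(203); glcm <- runif(13); fch <- runif(16)
  v <- fuse_features(lbp, glcm, fch)
  expect_length(v, 232L)
  expect_equal(unname(v[feature_layout[["lbp"]] + 1:203]), lbp)
  expect_equal(unname(v[feature_layout[["glcm"]] + 1:13]), glcm)
  expect_equal(unname(v[feature_layout[["fch"]] + 1:16]), fch)
  expect_equal(names(v)[1], "lbp_000")
  expect_equal(names(v)[204], "glcm_00")
  expect_equal(names(v)[217], "fch_00")
  expect_error(fuse_features(runif(10), glcm, fch), "lbp")
  expect_error(fuse_features(lbp, runif(3), fch), "glcm")
  z <- fuse_features(numeric(203), numeric(13), numeric(16))
  expect_true(all(z == 0) && length(z) == 232L)
})
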