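test_that("uniform images collapse to a single region", {
  lab <- region_grow(raster_image(matrix(80, 30, 30)))
  expect_equal(lab$region_count, 1L)
  expect_true(all(lab$labels == 1L))
})

test_that("two bright squares on a dark field give three exact regions", {
  m <- matrix(0, 40, 40)
  sq1 <- list(r = 5:14, c = 5:14)
  sq2 <- list(r = 25:34, c = 22:31)
  m[sq1$r, sq1$c] <- 200
  m[sq2$r, sq2$c] <- 200
  lab <- region_grow(raster_image(m), segmentation_params(similarity_k = 0.5))
  expect_equal(lab$region_count, 3L)
  # the two bright regions' pixel sets equal the squares exactly
  bright_labels <- unique(as.vector(lab$labels[m == 200]))
  expect_length(bright_labels, 2L)
  for (bl in bright_labels) {
    expect_true(all(m[lab$labels == bl] == 200))
  }
  expect_equal(sum(lab$labels %in% bright_labels), 200L)
})

test_that("grown label maps satisfy the four completeness conditions", {
  set.seed(31)
  for (i in 1:3) {
    s <- generate_smear(sample(c("normal", "leukemia"), 1),
                        small_smear_params(), seed = 100 + i)
    g <- to_grayscale(enhance(s$image))
    lab <- region_grow(g)
    cond <- check_segmentation_conditions(lab, g)
    expect_true(all(cond), info = paste("seed", 100 + i, ":",
                                        paste(names(cond)[!cond], collapse = ",")))
  }
})

test_that("ROI selection finds nucleus regions and rejects gray images", {
  s <- generate_smear("normal", small_smear_params(), seed = 5)
  img <- enhance(s$image)
  lab <- region_grow(to_grayscale(img))
  roi <- select_roi(lab, img)
  expect_gte(sum(roi & s$mask) / sum(s$mask), 0.9)
  expect_lte(sum(roi & !s$mask) / sum(!s$mask), 0.1)

  # saturation gate: grayscale-converted input has no nucleus-like color
  g <- unclass(to_grayscale(img))[, , 1]
  gray3 <- raster_image(array(rep(g, 3), dim = c(dim(g), 3)))
  expect_warning(roi0 <- select_roi(lab, gray3), "no nucleus-like region")
  expect_false(any(roi0))

  # two non-touching nuclei give two ROI components
  s2 <- generate_smear("normal",
                       small_smear_params(height = 256L, width = 256L,
                                          wbc_count = 2L), seed = 12)
  truth <- leukodiag:::label_components_cpp(matrix(as.integer(s2$mask),
                                                   nrow(s2$mask)), 8L)
  expect_equal(max(truth), 2L)
  img2 <- enhance(s2$image)
  lab2 <- region_grow(to_grayscale(img2))
  roi2 <- morphological_refine(select_roi(lab2, img2))
  comps <- leukodiag:::label_components_cpp(matrix(as.integer(roi2), nrow(roi2)), 8L)
  expect_equal(max(comps), 2L)
})

test_that("morphological refinement closes, fills and opens as specified", {
  solid <- matrix(FALSE, 30, 30); solid[6:25, 6:25] <- TRUE
  expect_equal(morphological_refine(solid), solid)

  holed <- solid; holed[12:13, 12:13] <- FALSE
  expect_equal(morphological_refine(holed), solid)
  expect_equal(fill_holes(holed), solid)   # oracle: fill of non-border background

  lone <- matrix(FALSE, 20, 20); lone[10, 10] <- TRUE
  expect_false(any(morphological_refine(lone)))

  # idempotence and opening/closing directionality on random masks
  set.seed(41)
  for (i in 1:5) {
    m <- matrix(runif(900) < 0.45, 30, 30)
    r1 <- morphological_refine(m)
    expect_equal(morphological_refine(r1), r1)
  }
})

test_that("segmented+refined nuclei overlap ground truth (Dice >= 0.8 over 20 seeds)", {
  dices <- vapply(1:20, function(i) {
    lbl <- if (i %% 2 == 0) "leukemia" else "normal"
    s <- generate_smear(lbl, seed = 1000 + i)
    img <- enhance(s$image)
    lab <- region_grow(to_grayscale(img))
    roi <- morphological_refine(suppressWarnings(select_roi(lab, img)))
    2 * sum(roi & s$mask) / (sum(roi) + sum(s$mask))
  }, 0)
  expect_gte(mean(dices), 0.8)
})

test_that("degenerate segmentation inputs are rejected", {
  expect_error(segmentation_params(similarity_k = -1), ">= 0")
  expect_error(region_grow(raster_image(array(0, dim = c(2, 2, 3)))),
               "single-channel")
  expect_error(structuring_element(matrix(TRUE, 4, 4)), "odd")
  expect_error(structuring_element(matrix(FALSE, 3, 3)), "TRUE")
})
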