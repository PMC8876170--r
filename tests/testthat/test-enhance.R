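test_that("average filter reproduces hand-computed window means", {
  # constants are fixed points for any window
  cimg <- raster_image(matrix(42, 8, 8))
  out <- average_filter(cimg)
  expect_equal(as.vector(unclass(out)), rep(42, 64))

  # 3x3 window, center excluded: center of a 3x3 ramp is (1+2+3+4+6+7+8+9)/8
  m <- matrix(1:9, 3, 3, byrow = TRUE)
  cfg <- enhancement_config(window_size = 3L)
  out3 <- unclass(average_filter(raster_image(m), cfg))[, , 1]
  expect_equal(out3[2, 2], 5.0)

  # default 6x6 window: each interior pixel is the mean of exactly 35 neighbors
  set.seed(11)
  big <- matrix(runif(400, 0, 255), 20, 20)
  out6 <- unclass(average_filter(raster_image(big)))[, , 1]
  r <- 10; c <- 11  # interior, window rows r-2..r+3
  win <- big[(r - 2):(r + 3), (c - 2):(c + 3)]
  expect_equal(out6[r, c], (sum(win) - big[r, c]) / 35, tolerance = 1e-12)
})

test_that("Laplacian response matches the stencil definitions", {
  cfg <- enhancement_config()
  expect_true(all(unclass(laplacian_filter(raster_image(matrix(7, 6, 6)), cfg)) == 0))
  # linear ramp: zero second derivative on interior pixels
  ramp <- raster_image(matrix(rep(0:7, each = 8), 8, 8, byrow = TRUE) * 10)
  lap <- unclass(laplacian_filter(ramp, cfg))[, , 1]
  expect_true(all(abs(lap[2:7, 2:7]) < 1e-12))
  # hand dot-product: center row of nines below zeros
  m <- rbind(c(0, 0, 0), c(0, 0, 0), c(9, 9, 9))
  lapm <- unclass(laplacian_filter(raster_image(m), cfg))[, , 1]
  expect_equal(lapm[2, 2], 9)
})

test_that("both filters match the brute-force sliding-window oracle", {
  set.seed(21)
  for (mode in c("reflect", "replicate", "zero")) {
    m <- matrix(runif(144, 0, 255), 12, 12)
    cfg <- enhancement_config(border_mode = mode)
    expect_equal(unclass(average_filter(raster_image(m), cfg))[, , 1],
                 brute_average_filter(m, 6L, TRUE, mode), tolerance = 1e-9)
    expect_equal(unclass(laplacian_filter(raster_image(m), cfg))[, , 1],
                 brute_laplacian(m, 4L, mode), tolerance = 1e-9)
    cfg8 <- enhancement_config(laplacian_connectivity = 8L, border_mode = mode)
    expect_equal(unclass(laplacian_filter(raster_image(m), cfg8))[, , 1],
                 brute_laplacian(m, 8L, mode), tolerance = 1e-9)
    cfg5 <- enhancement_config(window_size = 5L, exclude_center = FALSE,
                               border_mode = mode)
    expect_equal(unclass(average_filter(raster_image(m), cfg5))[, , 1],
                 brute_average_filter(m, 5L, FALSE, mode), tolerance = 1e-9)
  }
})

test_that("enhancement is the clipped difference of the two filters", {
  cimg <- raster_image(matrix(42, 8, 8))
  expect_equal(as.vector(unclass(enhance(cimg))), rep(42, 64))
  set.seed(22)
  img <- raster_image(array(runif(12 * 12 * 3, 0, 255), dim = c(12, 12, 3)))
  cfg <- enhancement_config()
  direct <- unclass(average_filter(img, cfg)) - unclass(laplacian_filter(img, cfg))
  out <- unclass(enhance(img, cfg))
  expect_equal(out, pmin(pmax(direct, 0), 255), tolerance = 1e-12)
  expect_true(all(out >= 0 & out <= 255))
  # never exceeds input range for the smoothing filter alone
  avg <- unclass(average_filter(img, cfg))
  expect_true(min(avg) >= min(unclass(img)) - 1e-9)
  expect_true(max(avg) <= max(unclass(img)) + 1e-9)
})

test_that("enhancement raises edge energy at nucleus boundaries of a smear", {
  s <- generate_smear("leukemia", small_smear_params(), seed = 7)
  tenengrad <- function(img, sel) {
    m <- unclass(to_grayscale(img))[, , 1]
    gx <- m[, c(2:ncol(m), ncol(m))] - m[, c(1, 1:(ncol(m) - 1))]
    gy <- m[c(2:nrow(m), nrow(m)), ] - m[c(1, 1:(nrow(m) - 1)), ]
    mean((gx^2 + gy^2)[sel])
  }
  # evaluate on the nucleus plus a small shell around its boundary
  shell <- fill_holes(s$mask)
  enhanced <- enhance(s$image)
  expect_gt(tenengrad(enhanced, shell), tenengrad(s$image, shell))
})

test_that("degenerate enhancement parameters are rejected", {
  expect_error(enhancement_config(window_size = 2L), ">= 3")
  expect_error(enhancement_config(laplacian_connectivity = 6), "4 or 8")
  tiny <- raster_image(matrix(0, 3, 3))
  expect_error(average_filter(tiny, enhancement_config(window_size = 9L)),
               "window larger")
})
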