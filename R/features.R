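#' Feature layout constants
#'
#' Offsets of the three segments inside the fused 232-entry feature vector:
#' LBP histogram at 0, co-occurrence statistics at 203, color histogram at
#' 216 (0-based).
#'
#' @format named integer vector.
#' @export
feature_layout <- c(lbp = 0L, glcm = 203L, fch = 216L, total = 232L)

#' LBP parameters
#'
#' The texture code uses the square 5 x 5 neighborhood (radius 2): the 24
#' pixels around the center, enumerated clockwise from the top-left corner
#' (outer 16-pixel ring first, then the inner 8-pixel ring). Codes span
#' `[0, 2^24 - 1]` and are binned into `n_bins` equal-width bins
#' (`bin = floor(code * n_bins / 2^24)`), giving the 203-entry histogram at
#' defaults.
#'
#' @param radius neighborhood radius (fixed at 2 for the 5 x 5 window).
#' @param neighbors number of neighbors (fixed at 24 for radius 2).
#' @param n_bins histogram length (default 203).
#' @param normalize divide by the code count so the histogram sums to 1
#'   (default `TRUE`).
#' @return list of class `lbp_params`.
#' @export
lbp_params <- function(radius = 2L, neighbors = 24L, n_bins = 203L,
                       normalize = TRUE) {
  if (radius != 2L || neighbors != 24L)
    stop("only the 5 x 5 neighborhood (radius 2, 24 neighbors) is implemented")
  if (n_bins < 1) stop("n_bins must be >= 1")
  structure(list(radius = 2L, neighbors = 24L, n_bins = as.integer(n_bins),
                 normalize = normalize),
            class = "lbp_params")
}

#' Local binary pattern histogram over an ROI
#'
#' For each ROI pixel whose full 5 x 5 neighborhood lies inside the image,
#' computes the 24-bit code `sum_p s(g_p - g_c) 2^p` with `s(x) = 1` iff
#' `x >= 0`, bins the codes into `n_bins` equal-width bins over
#' `[0, 2^24 - 1]`, and returns the (normalized) histogram. Invariant to
#' global additive intensity shifts. An empty ROI yields a zero vector with
#' a warning.
#'
#' @param gray single-channel `raster_image` or matrix.
#' @param roi logical matrix of the same shape.
#' @param params an [lbp_params()].
#' @return numeric vector of length `n_bins`.
#' @export
lbp_histogram <- function(gray, roi, params = lbp_params()) {
  m <- if (inherits(gray, "raster_image")) img_data(gray)[, , 1] else as.matrix(gray)
  if (!all(dim(m) == dim(roi))) stop("lbp_histogram: roi shape mismatch")
  codes <- lbp_codes_cpp(m, matrix(as.integer(roi != 0), nrow(roi)))
  v <- codes[codes >= 0]
  nb <- params$n_bins
  if (length(v) == 0) {
    warning("lbp_histogram: empty ROI; returning zero vector")
    return(numeric(nb))
  }
  bins <- pmin(floor(v * nb / 2^24), nb - 1)
  h <- tabulate(bins + 1L, nbins = nb)
  if (params$normalize) h <- h / sum(h)
  as.numeric(h)
}

#' GLCM parameters
#'
#' Gray levels are quantized into `gray_levels` equal-width bins over
#' \[0, 255\]. The default offsets realize the four directions 0, 45, 90 and
#' 135 degrees as pixel displacements (0,1), (-1,1), (-1,0), (-1,-1)
#' (distance 1 on the axes and sqrt(2) on the diagonals).
#'
#' @param gray_levels number of quantization levels (default 16).
#' @param offsets integer matrix with columns `dr, dc`, one row per offset.
#' @param symmetric accumulate each pair in both directions (default `TRUE`).
#' @return list of class `glcm_params`.
#' @export
glcm_params <- function(gray_levels = 16L,
                        offsets = rbind(c(0L, 1L), c(-1L, 1L),
                                        c(-1L, 0L), c(-1L, -1L)),
                        symmetric = TRUE) {
  if (nrow(offsets) < 1) stop("at least one offset is required")
  structure(list(gray_levels = as.integer(gray_levels),
                 offsets = offsets, symmetric = symmetric),
            class = "glcm_params")
}

quantize_gray <- function(m, levels) {
  pmin(floor(m * levels / 256), levels - 1L)
}

cooccurrence_matrix <- function(q, roi, dr, dc, levels, symmetric = TRUE) {
  h <- nrow(q); w <- ncol(q)
  r1 <- max(1, 1 - dr):min(h, h - dr)
  c1 <- max(1, 1 - dc):min(w, w - dc)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  ok <- roi[r1, c1, drop = FALSE] & roi[r1 + dr, c1 + dc, drop = FALSE]
  if (!any(ok)) return(matrix(0, levels, levels))
  ij <- a[ok] * levels + b[ok]
  cnt <- tabulate(ij + 1L, nbins = levels * levels)
  P <- matrix(cnt, levels, levels, byrow = TRUE)
  if (symmetric) P <- P + t(P)
  P / sum(P)
}

#' The 13 Haralick statistics of a normalized co-occurrence matrix
#'
#' Angular second moment, contrast, correlation, sum of squares (variance),
#' inverse difference moment, sum average, sum variance, sum entropy,
#' entropy, difference variance, difference entropy, and the two information
#' measures of correlation. Natural logarithms; `0 log 0 = 0`; indices are
#' 1-based. Sum variance is taken about the sum average (the conventional
#' reading of the classic formula, whose printed reference to sum entropy is
#' widely treated as a typo).
#'
#' @param P square nonnegative matrix summing to 1.
#' @return named numeric vector of length 13.
#' @export
haralick_stats <- function(P) {
  N <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(N) * px); muy <- sum(seq_len(N) * py)
  sdx <- sqrt(sum((seq_len(N) - mux)^2 * px))
  sdy <- sqrt(sum((seq_len(N) - muy)^2 * py))
  xlogx <- function(x) ifelse(x > 0, x * log(x), 0)
  # p_{x+y}(k), k = 2..2N ; p_{x-y}(k), k = 0..N-1
  psum <- vapply(2:(2 * N), function(k) sum(P[i + j == k]), 0)
  pdiff <- vapply(0:(N - 1), function(k) sum(P[abs(i - j) == k]), 0)
  asm <- sum(P^2)
  contrast <- sum((0:(N - 1))^2 * pdiff)
  correlation <- if (sdx > 0 && sdy > 0)
    (sum(i * j * P) - mux * muy) / (sdx * sdy) else 0
  variance <- sum((i - mux)^2 * P)
  idm <- sum(P / (1 + (i - j)^2))
  sum_average <- sum((2:(2 * N)) * psum)
  sum_variance <- sum(((2:(2 * N)) - sum_average)^2 * psum)
  sum_entropy <- -sum(xlogx(psum))
  entropy <- -sum(xlogx(P))
  kd <- 0:(N - 1)
  diff_mean <- sum(kd * pdiff)
  diff_variance <- sum((kd - diff_mean)^2 * pdiff)
  diff_entropy <- -sum(xlogx(pdiff))
  hx <- -sum(xlogx(px)); hy <- -sum(xlogx(py))
  pxy <- outer(px, py)
  hxy1 <- -sum(ifelse(pxy > 0, P * log(pxy), 0))
  hxy2 <- -sum(xlogx(pxy))
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  arg <- 1 - exp(-2 * (hxy2 - entropy))
  imc2 <- sqrt(max(arg, 0))
  c(asm = asm, contrast = contrast, correlation = correlation,
    variance = variance, idm = idm, sum_average = sum_average,
    sum_variance = sum_variance, sum_entropy = sum_entropy,
    entropy = entropy, diff_variance = diff_variance,
    diff_entropy = diff_entropy, imc1 = imc1, imc2 = imc2)
}

#' GLCM texture statistics over an ROI
#'
#' Quantizes the image to `gray_levels`, accumulates one symmetric
#' co-occurrence matrix per offset over pixel pairs lying entirely inside the
#' ROI, normalizes each to sum 1, computes the 13 Haralick statistics per
#' offset, and averages across offsets. An ROI with no co-occurring pair for
#' any offset yields a zero vector with a warning.
#'
#' @inheritParams lbp_histogram
#' @param params a [glcm_params()].
#' @return named numeric vector of length 13.
#' @export
glcm_features <- function(gray, roi, params = glcm_params()) {
  m <- if (inherits(gray, "raster_image")) img_data(gray)[, , 1] else as.matrix(gray)
  if (!all(dim(m) == dim(roi))) stop("glcm_features: roi shape mismatch")
  roi <- roi != 0
  q <- quantize_gray(m, params$gray_levels)
  mats <- list()
  for (k in seq_len(nrow(params$offsets))) {
    P <- cooccurrence_matrix(q, roi, params$offsets[k, 1], params$offsets[k, 2],
                             params$gray_levels, params$symmetric)
    if (sum(P) > 0) mats[[length(mats) + 1]] <- P
  }
  if (length(mats) == 0) {
    warning("glcm_features: no co-occurring ROI pairs; returning zero vector")
    return(stats::setNames(numeric(13), names(haralick_stats(diag(2) / 2))))
  }
  rowMeans(vapply(mats, haralick_stats, numeric(13)))
}

#' FCH parameters
#'
#' The color histogram quantizes RGB into `n_bins` coarse bins; the default
#' 16 bins factor as 4 x 2 x 2 equal-width ranges over R x G x B. Crisp mode
#' assigns each pixel wholly to its bin; fuzzy mode splits a triangular
#' membership between the pixel's bin and the nearest neighboring bin per
#' channel, memberships summing to 1 per pixel.
#'
#' @param n_bins histogram length (default 16; must factor as
#'   `r_bins * g_bins * b_bins` given in `bin_shape`).
#' @param membership `"crisp"` or `"fuzzy"`.
#' @param fuzzy_width fraction of mass (at maximal channel offset) handed to
#'   the neighboring bin in fuzzy mode, in (0, 1\] (default 0.5).
#' @param bin_shape integer vector of per-channel bin counts
#'   (default `c(4, 2, 2)`).
#' @return list of class `fch_params`.
#' @export
fch_params <- function(n_bins = 16L, membership = c("crisp", "fuzzy"),
                       fuzzy_width = 0.5, bin_shape = c(4L, 2L, 2L)) {
  membership <- match.arg(membership)
  if (prod(bin_shape) != n_bins)
    stop("bin_shape must multiply to n_bins")
  if (fuzzy_width <= 0 || fuzzy_width > 1) stop("fuzzy_width must be in (0, 1]")
  structure(list(n_bins = as.integer(n_bins), membership = membership,
                 fuzzy_width = fuzzy_width, bin_shape = as.integer(bin_shape)),
            class = "fch_params")
}

# per-channel (bin index, neighbor index, neighbor weight) for fuzzy mode
channel_membership <- function(v, nb, width) {
  b <- pmin(floor(v * nb / 256), nb - 1L)
  center <- (b + 0.5) * (256 / nb)
  d <- (v - center) / (256 / nb)           # in [-0.5, 0.5]
  nbr <- b + sign(d)
  wn <- width * abs(d)
  edge <- nbr < 0 | nbr > nb - 1
  nbr[edge] <- b[edge]; wn[edge] <- 0
  list(bin = b, nbr = nbr, wn = wn)
}

#' Fuzzy color histogram over an ROI
#'
#' Coarse RGB histogram of the ROI pixels. Crisp mode is the indicator
#' assignment (each pixel contributes 1 to exactly one bin); fuzzy mode
#' distributes each pixel's unit mass over its own and the nearest
#' neighboring bin per channel with triangular memberships. The result is
#' the per-bin mean membership, which sums to 1 for a nonempty ROI. An empty
#' ROI yields a zero vector with a warning.
#'
#' @param image 3-channel `raster_image`.
#' @param roi logical matrix of the same height/width.
#' @param params an [fch_params()].
#' @return numeric vector of length `n_bins`.
#' @export
fch_features <- function(image, roi, params = fch_params()) {
  a <- img_data(image)
  if (dim(a)[3] != 3L) stop("fch_features: image must have 3 channels")
  if (!all(dim(a)[1:2] == dim(roi))) stop("fch_features: roi shape mismatch")
  sel <- roi != 0
  n <- sum(sel)
  if (n == 0) {
    warning("fch_features: empty ROI; returning zero vector")
    return(numeric(params$n_bins))
  }
  r <- a[, , 1][sel]; g <- a[, , 2][sel]; b <- a[, , 3][sel]
  sh <- params$bin_shape
  if (params$membership == "crisp") {
    rb <- pmin(floor(r * sh[1] / 256), sh[1] - 1L)
    gb <- pmin(floor(g * sh[2] / 256), sh[2] - 1L)
    bb <- pmin(floor(b * sh[3] / 256), sh[3] - 1L)
    idx <- rb * sh[2] * sh[3] + gb * sh[3] + bb
    h <- tabulate(idx + 1L, nbins = params$n_bins)
    return(h / n)
  }
  mR <- channel_membership(r, sh[1], params$fuzzy_width)
  mG <- channel_membership(g, sh[2], params$fuzzy_width)
  mB <- channel_membership(b, sh[3], params$fuzzy_width)
  h <- numeric(params$n_bins)
  for (cr in 0:1) for (cg in 0:1) for (cb in 0:1) {
    br <- if (cr) mR$nbr else mR$bin
    bg <- if (cg) mG$nbr else mG$bin
    bb <- if (cb) mB$nbr else mB$bin
    wt <- (if (cr) mR$wn else 1 - mR$wn) *
          (if (cg) mG$wn else 1 - mG$wn) *
          (if (cb) mB$wn else 1 - mB$wn)
    idx <- br * sh[2] * sh[3] + bg * sh[3] + bb
    h <- h + as.numeric(tapply(wt, factor(idx, levels = 0:(params$n_bins - 1)),
                               sum, default = 0))
  }
  h / n
}

#' Fuse the three descriptor segments
#'
#' Concatenates the LBP histogram (203), the co-occurrence statistics (13)
#' and the color histogram (16) into the 232-entry fused feature vector with
#' stable per-entry names (`lbp_000..lbp_202`, `glcm_00..glcm_12`,
#' `fch_00..fch_15`).
#'
#' @param lbp,glcm,fch numeric vectors of lengths 203, 13 and 16.
#' @return named numeric vector of class `feature_vector`, length 232.
#' @export
fuse_features <- function(lbp, glcm, fch) {
  if (length(lbp) != 203L) stop("fuse_features: lbp segment must have length 203")
  if (length(glcm) != 13L) stop("fuse_features: glcm segment must have length 13")
  if (length(fch) != 16L) stop("fuse_features: fch segment must have length 16")
  v <- c(as.numeric(lbp), as.numeric(glcm), as.numeric(fch))
  names(v) <- c(sprintf("lbp_%03d", 0:202), sprintf("glcm_%02d", 0:12),
                sprintf("fch_%02d", 0:15))
  structure(v, class = "feature_vector")
}

#' Extract the fused 232-entry descriptor of one image
#'
#' Convenience wrapper running the three extractors on the ROI and fusing
#' them: LBP and GLCM on the luminance, FCH on the color image.
#'
#' @param image 3-channel `raster_image`.
#' @param roi logical matrix (the refined ROI).
#' @param lbp,glcm,fch parameter objects for the three extractors.
#' @return a `feature_vector` of length 232.
#' @export
extract_features <- function(image, roi, lbp = lbp_params(),
                             glcm = glcm_params(), fch = fch_params()) {
  gray <- to_grayscale(image)
  fuse_features(lbp_histogram(gray, roi, lbp),
                glcm_features(gray, roi, glcm),
                fch_features(image, roi, fch))
}
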