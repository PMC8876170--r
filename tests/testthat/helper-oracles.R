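# Independent brute-force oracles: naive double/quadruple loops, written
# directly from the operation definitions. They share only the documented
# conventions (padding mode, neighbor enumeration order) with the package.

# index into a matrix with symmetric-reflect / replicate / zero border rules
border_lookup <- function(m, r, c, mode) {
  h <- nrow(m); w <- ncol(m)
  fix <- function(i, n) {
    if (mode == "replicate") return(min(max(i, 1), n))
    if (mode == "reflect") {
      while (i < 1 || i > n) {
        if (i < 1) i <- 1 - i
        if (i > n) i <- 2 * n + 1 - i
      }
      return(i)
    }
    i
  }
  if (mode == "zero" && (r < 1 || r > h || c < 1 || c > w)) return(0)
  m[fix(r, h), fix(c, w)]
}

brute_average_filter <- function(m, win = 6L, exclude_center = TRUE,
                                 mode = "reflect") {
  h <- nrow(m); w <- ncol(m)
  before <- ceiling(win / 2) - 1L
  out <- matrix(0, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    acc <- 0; n <- 0
    for (dr in -before:(win - 1 - before)) for (dc in -before:(win - 1 - before)) {
      if (exclude_center && dr == 0 && dc == 0) next
      acc <- acc + border_lookup(m, r + dr, c + dc, mode)
      n <- n + 1
    }
    out[r, c] <- acc / n
  }
  out
}

brute_laplacian <- function(m, connectivity = 4L, mode = "reflect") {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  if (connectivity == 4L) {
    offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
    cw <- -4
  } else {
    offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
                 c(1, -1), c(1, 0), c(1, 1))
    cw <- -8
  }
  for (r in seq_len(h)) for (c in seq_len(w)) {
    acc <- cw * m[r, c]
    for (o in offs) acc <- acc + border_lookup(m, r + o[1], c + o[2], mode)
    out[r, c] <- acc
  }
  out
}

# the documented 24-neighbor enumeration: outer 5x5 ring clockwise from the
# top-left corner, then the inner 3x3 ring clockwise from its top-left corner
lbp_neighbor_offsets <- function() {
  outer_ring <- list(c(-2, -2), c(-2, -1), c(-2, 0), c(-2, 1), c(-2, 2),
                     c(-1, 2), c(0, 2), c(1, 2), c(2, 2), c(2, 1), c(2, 0),
                     c(2, -1), c(2, -2), c(1, -2), c(0, -2), c(-1, -2))
  inner_ring <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                     c(1, 0), c(1, -1), c(0, -1))
  c(outer_ring, inner_ring)
}

brute_lbp_code <- function(m, r, c) {
  offs <- lbp_neighbor_offsets()
  code <- 0
  for (p in seq_along(offs)) {
    gp <- m[r + offs[[p]][1], c + offs[[p]][2]]
    if (gp - m[r, c] >= 0) code <- code + 2^(p - 1)
  }
  code
}

brute_lbp_histogram <- function(m, roi, n_bins = 203L) {
  h <- nrow(m); w <- ncol(m)
  codes <- c()
  for (r in 3:(h - 2)) for (c in 3:(w - 2)) {
    if (!roi[r, c]) next
    codes <- c(codes, brute_lbp_code(m, r, c))
  }
  if (length(codes) == 0) return(numeric(n_bins))
  hst <- numeric(n_bins)
  for (code in codes) {
    b <- min(floor(code * n_bins / 2^24), n_bins - 1)
    hst[b + 1] <- hst[b + 1] + 1
  }
  hst / sum(hst)
}

# Haralick statistics straight from the textbook definitions, scalar loops
brute_haralick <- function(P) {
  N <- nrow(P)
  asm <- 0; contrast_acc <- 0; idm <- 0; ent <- 0; varsum <- 0
  px <- rowSums(P); py <- colSums(P)
  mux <- sum((1:N) * px); muy <- sum((1:N) * py)
  sx <- sqrt(sum((1:N - mux)^2 * px)); sy <- sqrt(sum((1:N - muy)^2 * py))
  corr_num <- 0
  psum <- numeric(2 * N - 1)   # k = 2..2N
  pdif <- numeric(N)           # k = 0..N-1
  for (i in 1:N) for (j in 1:N) {
    p <- P[i, j]
    asm <- asm + p^2
    idm <- idm + p / (1 + (i - j)^2)
    if (p > 0) ent <- ent - p * log(p)
    varsum <- varsum + (i - mux)^2 * p
    corr_num <- corr_num + i * j * p
    psum[i + j - 1] <- psum[i + j - 1] + p
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + p
  }
  contrast <- sum((0:(N - 1))^2 * pdif)
  corr <- if (sx > 0 && sy > 0) (corr_num - mux * muy) / (sx * sy) else 0
  ks <- 2:(2 * N)
  sum_avg <- sum(ks * psum)
  sum_var <- sum((ks - sum_avg)^2 * psum)
  sum_ent <- -sum(ifelse(psum > 0, psum * log(psum), 0))
  kd <- 0:(N - 1)
  dmean <- sum(kd * pdif)
  dvar <- sum((kd - dmean)^2 * pdif)
  dent <- -sum(ifelse(pdif > 0, pdif * log(pdif), 0))
  hx <- -sum(ifelse(px > 0, px * log(px), 0))
  hy <- -sum(ifelse(py > 0, py * log(py), 0))
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:N) for (j in 1:N) {
    q <- px[i] * py[j]
    if (q > 0) {
      hxy1 <- hxy1 - P[i, j] * log(q)
      hxy2 <- hxy2 - q * log(q)
    }
  }
  imc1 <- if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(1 - exp(-2 * (hxy2 - ent)), 0))
  c(asm, contrast, corr, varsum, idm, sum_avg, sum_var, sum_ent, ent,
    dvar, dent, imc1, imc2)
}

brute_conv2d <- function(x, wts, stride = 1L, pad = 0L, bias = NULL) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  d <- dim(wts); k <- d[1]
  if (is.null(bias)) bias <- numeric(d[4])
  xp <- array(0, dim = c(dim(x)[1] + 2 * pad, dim(x)[2] + 2 * pad, dim(x)[3]))
  xp[pad + seq_len(dim(x)[1]), pad + seq_len(dim(x)[2]), ] <- x
  ho <- (dim(xp)[1] - k) %/% stride + 1
  wo <- (dim(xp)[2] - k) %/% stride + 1
  out <- array(0, dim = c(ho, wo, d[4]))
  for (f in seq_len(d[4])) for (i in seq_len(ho)) for (j in seq_len(wo)) {
    acc <- bias[f]
    for (ch in seq_len(d[3])) for (a in seq_len(k)) for (b in seq_len(k))
      acc <- acc + xp[(i - 1) * stride + a, (j - 1) * stride + b, ch] *
        wts[a, b, ch, f]
    out[i, j, f] <- acc
  }
  out
}

brute_pool <- function(x, k, stride, f) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  d <- dim(x)
  ho <- (d[1] - k) %/% stride + 1
  wo <- (d[2] - k) %/% stride + 1
  out <- array(0, dim = c(ho, wo, d[3]))
  for (ch in seq_len(d[3])) for (i in seq_len(ho)) for (j in seq_len(wo))
    out[i, j, ch] <- f(x[(i - 1) * stride + seq_len(k),
                         (j - 1) * stride + seq_len(k), ch])
  out
}

# hard-margin maximizer for 2-d toys: coarse-to-fine scan over boundary
# direction; margin at a direction is half the gap between class projections
brute_max_margin_2d <- function(X, y) {
  margin_at <- function(theta) {
    w <- c(cos(theta), sin(theta))
    proj <- X %*% w
    gap <- min(proj[y > 0]) - max(proj[y < 0])
    gap / 2
  }
  lo <- 0; hi <- 2 * pi; best <- -Inf; best_th <- 0
  for (pass in 1:6) {
    ths <- seq(lo, hi, length.out = 721)
    vals <- vapply(ths, margin_at, 0)
    i <- which.max(vals)
    if (vals[i] > best) { best <- vals[i]; best_th <- ths[i] }
    step <- ths[2] - ths[1]
    lo <- ths[i] - step; hi <- ths[i] + step
  }
  list(margin = best, theta = best_th)
}
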