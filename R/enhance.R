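#' Enhancement configuration
#'
#' Parameters of the two-filter enhancement stage. The default average filter
#' uses a 6 x 6 window with the center pixel excluded, so each pixel is
#' replaced by the mean of its 35 adjacent pixels. An even window has no
#' central cell: the window covering pixel `(r, c)` spans rows `r-2 .. r+3`
#' and columns `c-2 .. c+3` (0-based), a fixed documented convention.
#'
#' @param window_size average-filter window edge length, >= 3 (default 6).
#' @param exclude_center drop the center pixel from the window mean
#'   (default `TRUE`; with a 6 x 6 window this gives the 35-neighbor mean).
#' @param laplacian_connectivity 4 or 8; selects the discrete Laplacian kernel
#'   `[[0,1,0],[1,-4,1],[0,1,0]]` or `[[1,1,1],[1,-8,1],[1,1,1]]`.
#' @param border_mode `"reflect"`, `"replicate"` or `"zero"` padding.
#' @return list of class `enhancement_config`.
#' @export
enhancement_config <- function(window_size = 6L, exclude_center = TRUE,
                               laplacian_connectivity = 4L,
                               border_mode = c("reflect", "replicate", "zero")) {
  border_mode <- match.arg(border_mode)
  window_size <- as.integer(window_size)
  if (window_size < 3L) stop("window_size must be >= 3")
  if (!laplacian_connectivity %in% c(4L, 8L))
    stop("laplacian_connectivity must be 4 or 8")
  structure(list(window_size = window_size, exclude_center = exclude_center,
                 laplacian_connectivity = as.integer(laplacian_connectivity),
                 border_mode = border_mode),
            class = "enhancement_config")
}

# pad a matrix by `k` pixels on the top/left and `k2` on the bottom/right
pad_matrix <- function(m, top, bottom, left, right, mode) {
  h <- nrow(m); w <- ncol(m)
  idx_pad <- function(n, before, after, mode) {
    core <- seq_len(n)
    pre <- switch(mode,
                  reflect = rev(seq_len(min(before, n))),
                  replicate = rep(1L, before),
                  zero = rep(NA_integer_, before))
    if (mode == "reflect" && before > n) pre <- rep(pre, length.out = before)
    post <- switch(mode,
                   reflect = n + 1L - seq_len(min(after, n)),
                   replicate = rep(n, after),
                   zero = rep(NA_integer_, after))
    if (mode == "reflect" && after > n) post <- rep(post, length.out = after)
    c(pre, core, post)
  }
  ri <- idx_pad(h, top, bottom, mode)
  ci <- idx_pad(w, left, right, mode)
  out <- matrix(0, length(ri), length(ci))
  ok_r <- !is.na(ri); ok_c <- !is.na(ci)
  out[ok_r, ok_c] <- m[ri[ok_r], ci[ok_c]]
  out
}

box_sum <- function(padded, win) {
  # sliding win x win sums via an integral image
  S <- rbind(0, apply(padded, 2, cumsum))
  S <- cbind(0, t(apply(S, 1, cumsum)))
  h <- nrow(padded) - win + 1L
  w <- ncol(padded) - win + 1L
  S[(win + 1):(win + h), (win + 1):(win + w)] -
    S[1:h, (win + 1):(win + w)] -
    S[(win + 1):(win + h), 1:w] +
    S[1:h, 1:w]
}

avg_filter_matrix <- function(m, cfg) {
  win <- cfg$window_size
  if (win > nrow(m) && win > ncol(m))
    stop("average_filter: window larger than both image dimensions")
  # window anchored at r-(ceil(win/2)-1) .. r+floor(win/2) in each axis
  before <- ceiling(win / 2) - 1L
  after <- win - 1L - before
  p <- pad_matrix(m, before, after, before, after, cfg$border_mode)
  s <- box_sum(p, win)
  if (cfg$exclude_center) (s - m) / (win^2 - 1) else s / win^2
}

shift_matrix <- function(p, dr, dc, h, w, before) {
  p[(1 + before + dr):(h + before + dr), (1 + before + dc):(w + before + dc)]
}

laplacian_matrix <- function(m, cfg) {
  h <- nrow(m); w <- ncol(m)
  p <- pad_matrix(m, 1L, 1L, 1L, 1L, cfg$border_mode)
  n4 <- shift_matrix(p, -1, 0, h, w, 1L) + shift_matrix(p, 1, 0, h, w, 1L) +
        shift_matrix(p, 0, -1, h, w, 1L) + shift_matrix(p, 0, 1, h, w, 1L)
  if (cfg$laplacian_connectivity == 4L) {
    n4 - 4 * m
  } else {
    diag4 <- shift_matrix(p, -1, -1, h, w, 1L) + shift_matrix(p, -1, 1, h, w, 1L) +
             shift_matrix(p, 1, -1, h, w, 1L) + shift_matrix(p, 1, 1, h, w, 1L)
    n4 + diag4 - 8 * m
  }
}

per_channel <- function(image, f) {
  a <- img_data(image)
  out <- a
  for (ch in seq_len(dim(a)[3])) out[, , ch] <- f(a[, , ch])
  raster_image(out)
}

#' Average (smoothing) filter
#'
#' Replaces each pixel by the mean of its `window_size x window_size`
#' neighborhood, excluding the center pixel by default (35 neighbors for the
#' default 6 x 6 window). Applied per channel; borders handled per the
#' configured padding mode. Output values are not clipped.
#'
#' @param image a `raster_image`.
#' @param config an [enhancement_config()].
#' @return filtered `raster_image` of the same shape.
#' @export
average_filter <- function(image, config = enhancement_config()) {
  per_channel(image, function(m) avg_filter_matrix(m, config))
}

#' Laplacian (edge) filter
#'
#' Discrete Laplacian response per channel; values may be negative and are
#' not clipped. Kernel selected by `laplacian_connectivity` in the config.
#'
#' @inheritParams average_filter
#' @return response `raster_image` of the same shape.
#' @export
laplacian_filter <- function(image, config = enhancement_config()) {
  per_channel(image, function(m) laplacian_matrix(m, config))
}

#' Enhance an image
#'
#' The enhancement stage: smooths with the average filter, computes the
#' Laplacian edge response, subtracts the Laplacian from the smoothed image
#' (sharpening edges such as nucleus boundaries), and clips the result to
#' \[0, 255\]. Clipping happens only after the subtraction.
#'
#' @inheritParams average_filter
#' @return enhanced `raster_image` with values in \[0, 255\].
#' @export
enhance <- function(image, config = enhancement_config()) {
  avg <- average_filter(image, config)
  lap <- laplacian_filter(image, config)
  raster_image(clip01(img_data(avg) - img_data(lap)))
}
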