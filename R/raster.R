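#' @useDynLib leukodiag, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats sd runif rnorm rbinom quantile predict
#' @importFrom utils read.csv write.csv head
#' @importFrom grDevices rgb2hsv
NULL

clip01 <- function(x, lo = 0, hi = 255) pmin(pmax(x, lo), hi)

#' Construct a raster image
#'
#' The package-wide image container: a numeric `height x width x channels`
#' array of intensities on the \[0, 255\] scale. Pixel coordinates are 0-based
#' in documentation prose but stored as ordinary 1-based R indices, row-major,
#' origin at the top-left. Intensities stay real-valued throughout processing;
#' quantization to integers happens only on export ([write_image()]).
#'
#' @param data numeric matrix (grayscale) or `h x w x c` array with
#'   `c` in `{1, 3}`.
#' @return object of class `raster_image` (a 3-d array, channels last).
#' @export
raster_image <- function(data) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (length(dim(data)) != 3L || !(dim(data)[3] %in% c(1L, 3L)))
    stop("raster_image: data must be h x w x c with c in {1, 3}")
  if (dim(data)[1] < 1L || dim(data)[2] < 1L)
    stop("raster_image: height and width must be >= 1")
  if (!all(is.finite(data)))
    stop("raster_image: intensities must be finite")
  structure(data, class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("raster_image: %d x %d, %d channel(s), range [%.2f, %.2f]\n",
              d[1], d[2], d[3], min(x), max(x)))
  invisible(x)
}

img_height <- function(x) dim(x)[1]
img_width <- function(x) dim(x)[2]
img_channels <- function(x) dim(x)[3]

# strip class so arithmetic keeps plain-array semantics internally
img_data <- function(x) {
  a <- unclass(x)
  if (is.matrix(a)) a <- array(a, dim = c(dim(a), 1L))
  a
}

ebimage_to_raster <- function(img) {
  # EBImage stores x (width) first and values on [0, 1]
  d <- dim(img)
  a <- as.array(img)
  if (length(d) == 2L) {
    out <- array(t(a), dim = c(d[2], d[1], 1L))
  } else {
    out <- array(0, dim = c(d[2], d[1], d[3]))
    for (ch in seq_len(d[3])) out[, , ch] <- t(a[, , ch])
  }
  raster_image(out * 255)
}

raster_to_ebimage <- function(x) {
  a <- img_data(x) / 255
  h <- dim(a)[1]; w <- dim(a)[2]; ch <- dim(a)[3]
  if (ch == 1L) {
    EBImage::Image(t(a[, , 1]))
  } else {
    b <- array(0, dim = c(w, h, ch))
    for (k in seq_len(ch)) b[, , k] <- t(a[, , k])
    EBImage::Image(b, colormode = "Color")
  }
}

image_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
         png = "png", jpg = "jpeg", jpeg = "jpeg",
         tif = "tiff", tiff = "tiff", bmp = "bmp",
         stop("unsupported image format: ", path))
}

#' Read an image file
#'
#' Reads PNG, JPEG, TIFF or BMP into a [raster_image()]. Color files give
#' 3-channel images, grayscale files 1-channel; intensities are on \[0, 255\].
#'
#' @param path file path.
#' @return a `raster_image`.
#' @export
read_image <- function(path) {
  fmt <- image_format(path)
  if (!file.exists(path)) stop("read_image: file not found: ", path)
  if (fmt == "bmp") return(read_bmp(path))
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("read_image: cannot read ", path,
                                           " (", conditionMessage(e), ")"))
  d <- dim(img)
  if (length(d) == 3L && d[3] == 4L) img <- img[, , 1:3]  # drop alpha
  if (length(d) == 3L && d[3] == 2L) img <- img[, , 1]    # gray + alpha
  ebimage_to_raster(img)
}

#' Write an image file
#'
#' Quantizes intensities to integers in \[0, 255\] and writes PNG, JPEG
#' (quality 95), TIFF or BMP.
#'
#' @param image a `raster_image`.
#' @param path destination path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  fmt <- image_format(path)
  q <- raster_image(round(clip01(img_data(image))))
  if (fmt == "bmp") return(write_bmp(q, path))
  eb <- raster_to_ebimage(q)
  if (fmt == "jpeg") EBImage::writeImage(eb, path, type = "jpeg", quality = 95)
  else EBImage::writeImage(eb, path, type = fmt)
  invisible(path)
}

#' Convert to grayscale
#'
#' Rec. 601 luminance: `0.299 R + 0.587 G + 0.114 B`. Single-channel input is
#' returned unchanged.
#'
#' @param image a `raster_image`.
#' @return 1-channel `raster_image`.
#' @export
to_grayscale <- function(image) {
  a <- img_data(image)
  if (dim(a)[3] == 1L) return(raster_image(a))
  g <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
  raster_image(array(g, dim = c(dim(a)[1], dim(a)[2], 1L)))
}

#' Gray-world color normalization
#'
#' Fixes the color cast of a 3-channel image by scaling each channel so all
#' channel means agree: channel `c` is multiplied by
#' `mean(channel means) / mean(c)`, then clipped to \[0, 255\]. A channel with
#' mean 0 is left unscaled.
#'
#' @param image 3-channel `raster_image`.
#' @param method `"grayworld"` (the only implemented scaling) or `"none"`.
#' @return `raster_image` of the same shape.
#' @export
normalize_channels <- function(image, method = c("grayworld", "none")) {
  method <- match.arg(method)
  a <- img_data(image)
  if (dim(a)[3] != 3L) stop("normalize_channels: image must have 3 channels")
  if (method == "none") return(raster_image(a))
  mu <- c(mean(a[, , 1]), mean(a[, , 2]), mean(a[, , 3]))
  target <- mean(mu)
  for (ch in 1:3) {
    if (mu[ch] > 0) a[, , ch] <- a[, , ch] * (target / mu[ch])
  }
  raster_image(clip01(a))
}

#' Resize an image
#'
#' Bilinear resize (used to bring images to the micro-CNN input size and by
#' the crop-and-resize augmentation).
#'
#' @param image a `raster_image`.
#' @param height,width target size in pixels.
#' @return resized `raster_image`.
#' @export
resize_image <- function(image, height, width) {
  eb <- raster_to_ebimage(image)
  out <- EBImage::resize(eb, w = width, h = height)  # EBImage's first dim is our column axis
  r <- ebimage_to_raster(out)
  raster_image(clip01(img_data(r)))
}

# ---- minimal 24-bit uncompressed BMP I/O (no installed package reads BMP) ----

read_bmp <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  if (!identical(rawToChar(magic), "BM")) stop("read_bmp: not a BMP file: ", path)
  readBin(con, "integer", 2, size = 4, endian = "little")      # file size + reserved
  offset <- readBin(con, "integer", 1, size = 4, endian = "little")
  hsz <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (hsz < 40) stop("read_bmp: unsupported BMP header in ", path)
  w <- readBin(con, "integer", 1, size = 4, endian = "little")
  h <- readBin(con, "integer", 1, size = 4, endian = "little")
  readBin(con, "integer", 1, size = 2, endian = "little")      # planes
  bpp <- readBin(con, "integer", 1, size = 2, endian = "little")
  comp <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (bpp != 24L || comp != 0L)
    stop("read_bmp: only 24-bit uncompressed BMP is supported: ", path)
  seek(con, offset)
  stride <- (3 * w + 3) %/% 4 * 4
  raw <- readBin(con, "raw", stride * abs(h))
  if (length(raw) < stride * abs(h)) stop("read_bmp: truncated file: ", path)
  flip <- h > 0; h <- abs(h)
  a <- array(0, dim = c(h, w, 3L))
  for (row in seq_len(h)) {
    off <- (row - 1) * stride
    px <- as.integer(raw[off + seq_len(3 * w)])
    r_out <- if (flip) h - row + 1 else row
    a[r_out, , 1] <- px[seq(3, 3 * w, by = 3)]  # BGR order on disk
    a[r_out, , 2] <- px[seq(2, 3 * w, by = 3)]
    a[r_out, , 3] <- px[seq(1, 3 * w, by = 3)]
  }
  raster_image(a)
}

write_bmp <- function(image, path) {
  a <- img_data(image)
  if (dim(a)[3] == 1L) a <- array(rep(a, 3), dim = c(dim(a)[1:2], 3L))
  h <- dim(a)[1]; w <- dim(a)[2]
  stride <- (3 * w + 3) %/% 4 * 4
  data_size <- stride * h
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  writeBin(as.integer(54 + data_size), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")
  writeBin(54L, con, size = 4, endian = "little")
  writeBin(40L, con, size = 4, endian = "little")
  writeBin(as.integer(w), con, size = 4, endian = "little")
  writeBin(as.integer(h), con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(24L, con, size = 2, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  writeBin(c(2835L, 2835L, 0L, 0L), con, size = 4, endian = "little")
  pad <- raw(stride - 3 * w)
  v <- round(clip01(a))
  for (row in h:1) {
    px <- as.raw(as.vector(rbind(v[row, , 3], v[row, , 2], v[row, , 1])))
    writeBin(px, con)
    if (length(pad)) writeBin(pad, con)
  }
  invisible(path)
}

#' Read a dataset manifest
#'
#' A manifest is a CSV with columns `source_id,path,label` (label one of
#' `leukemia`, `normal`, `unlabeled`).
#'
#' @param path CSV path.
#' @return data.frame with validated columns.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("source_id", "path", "label")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(m$source_id))
    stop("manifest source_id values must be unique")
  bad <- setdiff(unique(m$label), c("leukemia", "normal", "unlabeled"))
  if (length(bad)) stop("unknown labels in manifest: ", paste(bad, collapse = ", "))
  m
}
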