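#' Split specification
#'
#' Per class: `round(test_fraction * class size)` records go to the test
#' partition (round half up), the remaining pool is split with
#' `round(validation_fraction_of_pool * pool size)` validation records, the
#' rest train. With the 49/59 class sizes of a typical single-smear archive
#' this reproduces 31/8/10 and 38/9/12.
#'
#' @param test_fraction fraction held out for testing (default 0.2).
#' @param validation_fraction_of_pool validation share of the non-test pool
#'   (default 0.2).
#' @param stratified split per class (default `TRUE`).
#' @param seed integer seed.
#' @return list of class `split_spec`.
#' @export
split_spec <- function(test_fraction = 0.2, validation_fraction_of_pool = 0.2,
                       stratified = TRUE, seed = 0L) {
  if (test_fraction <= 0 || test_fraction >= 1) stop("test_fraction in (0,1)")
  if (validation_fraction_of_pool <= 0 || validation_fraction_of_pool >= 1)
    stop("validation_fraction_of_pool in (0,1)")
  structure(list(test_fraction = test_fraction,
                 validation_fraction_of_pool = validation_fraction_of_pool,
                 stratified = stratified, seed = as.integer(seed)),
            class = "split_spec")
}

round_half_up <- function(x) floor(x + 0.5)

#' Assign train/validation/test partitions
#'
#' Deterministic under the spec seed; partitions are disjoint, exhaustive
#' and stratified by class.
#'
#' @param records data.frame with at least `source_id` and `label` columns
#'   (e.g. a manifest).
#' @param spec a [split_spec()].
#' @return the records with a `partition` column added.
#' @export
split_records <- function(records, spec = split_spec()) {
  n <- nrow(records)
  part <- character(n)
  groups <- if (spec$stratified) split(seq_len(n), records$label)
            else list(all = seq_len(n))
  set.seed(spec$seed)
  for (g in names(sort(vapply(groups, min, 0)))) {
    idx <- groups[[g]]
    m <- length(idx)
    n_test <- round_half_up(spec$test_fraction * m)
    pool <- m - n_test
    n_val <- round_half_up(spec$validation_fraction_of_pool * pool)
    n_train <- pool - n_val
    if (spec$stratified && (n_test < 1 || n_val < 1 || n_train < 1))
      stop("split_records: class '", g, "' too small to populate all partitions")
    ord <- idx[sample.int(m)]
    part[ord] <- rep(c("train", "validation", "test"),
                     c(n_train, n_val, n_test))
  }
  records$partition <- part
  records
}

#' Augmentation specification
#'
#' Label-preserving image transforms used to expand the training partition:
#' rotation at several angles (90, 180, 270, +-15, +-30 degrees), horizontal
#' and vertical flips, random crop-and-resize keeping at least 80% of each
#' dimension, and shifts up to 10% of the extent. Each original yields
#' exactly `factor` images, the original itself included when
#' `include_original`.
#'
#' @param factor per-class multiplication factor; either a single integer or
#'   a named vector like `c(leukemia = 20, normal = 17)`.
#' @param operations subset of
#'   `c("rotation", "hflip", "vflip", "crop", "shift")`.
#' @param include_original count the untouched original toward the factor
#'   (default `TRUE`, which makes 39 originals at factor 20 come out to 780).
#' @param seed integer seed.
#' @return list of class `augmentation_spec`.
#' @export
augmentation_spec <- function(factor = 1L,
                              operations = c("rotation", "hflip", "vflip",
                                             "crop", "shift"),
                              include_original = TRUE, seed = 0L) {
  if (any(factor < 1)) stop("augmentation factor must be >= 1")
  operations <- match.arg(operations, several.ok = TRUE)
  structure(list(factor = factor, operations = operations,
                 include_original = include_original, seed = as.integer(seed)),
            class = "augmentation_spec")
}

rotation_angles <- c(90, 180, 270, 15, -15, 30, -30)

augment_one <- function(image, op, rng_draws) {
  eb <- raster_to_ebimage(image)
  out <- switch(op,
    rotation = {
      ang <- rotation_angles[1 + (rng_draws[1] %% length(rotation_angles))]
      EBImage::rotate(eb, ang, output.dim = dim(eb)[1:2], bg.col = 0)
    },
    hflip = EBImage::flop(eb),
    vflip = EBImage::flip(eb),
    crop = {
      h <- img_height(image); w <- img_width(image)
      kh <- max(2L, round(h * (0.8 + 0.2 * rng_draws[2] / 1e6)))
      kw <- max(2L, round(w * (0.8 + 0.2 * rng_draws[3] / 1e6)))
      r0 <- 1 + (rng_draws[4] %% max(h - kh + 1, 1))
      c0 <- 1 + (rng_draws[5] %% max(w - kw + 1, 1))
      sub <- img_data(image)[r0:(r0 + kh - 1), c0:(c0 + kw - 1), , drop = FALSE]
      return(resize_image(raster_image(sub), h, w))
    },
    shift = {
      h <- img_height(image); w <- img_width(image)
      dr <- (rng_draws[6] %% (2 * max(1, round(0.1 * h)) + 1)) - round(0.1 * h)
      dc <- (rng_draws[7] %% (2 * max(1, round(0.1 * w)) + 1)) - round(0.1 * w)
      EBImage::translate(eb, c(dc, dr), bg.col = 0)
    },
    stop("unknown augmentation operation: ", op))
  if (inherits(out, "Image")) {
    r <- ebimage_to_raster(out)
    raster_image(clip01(img_data(r)))
  } else out
}

#' Augment a list of training records
#'
#' Expands each record into exactly `factor` images by sampled operations
#' (deterministic under the spec seed). Labels and a suffixed `source_id`
#' are inherited. Only training records should be passed: augmentation never
#' mixes partitions.
#'
#' @param records list of records, each a list with `image` (a
#'   `raster_image`), `label` and `source_id`.
#' @param spec an [augmentation_spec()].
#' @return list of augmented records of length
#'   `sum(per-class factor * originals)`.
#' @export
augment_records <- function(records, spec = augmentation_spec()) {
  set.seed(spec$seed)
  out <- vector("list", 0)
  for (rec in records) {
    f <- if (length(spec$factor) > 1) {
      if (!rec$label %in% names(spec$factor))
        stop("no augmentation factor for class ", rec$label)
      spec$factor[[rec$label]]
    } else spec$factor
    n_new <- if (spec$include_original) f - 1L else f
    if (spec$include_original)
      out[[length(out) + 1]] <- rec
    if (n_new > 0) {
      for (i in seq_len(n_new)) {
        op <- spec$operations[1 + ((length(out) + i) %% length(spec$operations))]
        draws <- sample.int(1e6, 7)
        img <- augment_one(rec$image, op, draws)
        out[[length(out) + 1]] <- list(image = img, label = rec$label,
                                       source_id = sprintf("%s_aug%03d",
                                                           rec$source_id, i))
      }
    }
  }
  out
}
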