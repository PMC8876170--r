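#' Segmentation parameters
#'
#' Controls the adaptive region-growing stage. During growth a region admits
#' an adjacent pixel `q` when `|I(q) - running mean| <= similarity_k *
#' max(running sd, 1)`. Region-level homogeneity (the predicate behind the
#' completeness conditions, see [check_segmentation_conditions()]) is
#' `max(region) - min(region) <= range_cap`: after growth, over-dispersed
#' regions are repaired by splitting off extreme pixels, and adjacent
#' regions whose union stays homogeneous are merged until no such pair
#' remains. A range cap (rather than a dispersion cap) keeps the predicate
#' sensitive to small inclusions inside large regions, which is exactly the
#' nucleus-in-background configuration segmentation must preserve.
#'
#' @param similarity_k adaptive threshold multiplier, >= 0 (default 2.5).
#' @param seed_spacing regular seed-grid spacing in pixels (default 16).
#' @param min_region_area minimum area in pixels for ROI candidates
#'   (default 64).
#' @param connectivity 4 or 8 (default 8).
#' @param range_cap region-level homogeneity cap on the intensity range
#'   (default 160 intensity units).
#' @return list of class `segmentation_params`.
#' @export
segmentation_params <- function(similarity_k = 2.5, seed_spacing = 16L,
                                min_region_area = 64L, connectivity = 8L,
                                range_cap = 160) {
  if (similarity_k < 0) stop("similarity_k must be >= 0")
  if (seed_spacing < 1) stop("seed_spacing must be >= 1")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  structure(list(similarity_k = similarity_k,
                 seed_spacing = as.integer(seed_spacing),
                 min_region_area = as.integer(min_region_area),
                 connectivity = as.integer(connectivity),
                 range_cap = range_cap),
            class = "segmentation_params")
}

#' Structuring element
#'
#' Boolean footprint for the morphological refinement, default 5 x 5
#' all-true.
#'
#' @param footprint logical matrix with odd edge lengths and at least one
#'   `TRUE` cell.
#' @return logical matrix of class `structuring_element`.
#' @export
structuring_element <- function(footprint = matrix(TRUE, 5, 5)) {
  footprint <- footprint != 0
  if (any(dim(footprint) %% 2 == 0)) stop("structuring element edges must be odd")
  if (!any(footprint)) stop("structuring element needs at least one TRUE cell")
  structure(footprint, class = "structuring_element")
}

#' Adaptive region growing
#'
#' Partitions a single-channel image into homogeneous, connected regions.
#' Seeds are placed on a regular grid; each seed grows breadth-first,
#' admitting adjacent pixels within `similarity_k` running standard
#' deviations of the running region mean (sd floored at 1). Unassigned
#' pixels become new seeds until every pixel is labeled. A repair pass
#' splits off pixels that ended up incompatible with their region, and a
#' merge pass joins adjacent regions whose union is still homogeneous, so
#' that the output satisfies the four completeness conditions (exhaustive
#' partition, connected regions, within-region homogeneity, no mergeable
#' neighbors).
#'
#' @param image single-channel `raster_image` (or matrix).
#' @param params a [segmentation_params()].
#' @return list of class `region_label_map` with elements `labels`
#'   (integer matrix, 0 never occurs: regions are exhaustive) and
#'   `region_count`.
#' @export
region_grow <- function(image, params = segmentation_params()) {
  m <- if (inherits(image, "raster_image")) {
    if (img_channels(image) != 1L)
      stop("region_grow: pass a single-channel image (e.g. to_grayscale())")
    img_data(image)[, , 1]
  } else as.matrix(image)
  if (length(m) == 0) stop("region_grow: empty image")
  lab <- region_grow_cpp(m, params$similarity_k, params$seed_spacing,
                         params$connectivity)
  lab <- region_repair_cpp(lab, m, params$similarity_k, params$range_cap,
                           params$connectivity, 100L)
  lab <- region_merge_cpp(lab, m, params$range_cap, params$connectivity)
  structure(list(labels = lab, region_count = max(lab)),
            class = "region_label_map")
}

#' @export
print.region_label_map <- function(x, ...) {
  cat(sprintf("region_label_map: %d x %d, %d region(s)\n",
              nrow(x$labels), ncol(x$labels), x$region_count))
  invisible(x)
}

#' Check the region-growing completeness conditions
#'
#' Asserts, on a label map produced by [region_grow()], the four conditions a
#' successful segmentation must satisfy: (1) the partition is exhaustive
#' (every pixel labeled, regions disjoint by construction); (2) every region
#' is connected; (3) the homogeneity predicate holds within every region
#' (intensity range within `range_cap`); (4) no two adjacent regions could
#' be merged without breaking the predicate.
#'
#' @param labels a `region_label_map`.
#' @param image the single-channel image the map was grown on.
#' @param params the [segmentation_params()] used.
#' @return named logical vector `c(exhaustive, connected, homogeneous,
#'   maximal)`.
#' @export
check_segmentation_conditions <- function(labels, image,
                                          params = segmentation_params()) {
  m <- if (inherits(image, "raster_image")) img_data(image)[, , 1] else as.matrix(image)
  lab <- labels$labels
  exhaustive <- all(lab >= 1L) && max(lab) == labels$region_count &&
    all(seq_len(labels$region_count) %in% lab)
  # connectivity: relabeling components must not increase the region count
  conn <- TRUE
  for (g in seq_len(labels$region_count)) {
    comp <- label_components_cpp(matrix(as.integer(lab == g), nrow(lab)),
                                 params$connectivity)
    if (max(comp) != 1L) { conn <- FALSE; break }
  }
  st <- region_stats_cpp(lab, m)
  homog <- all(st[, 5] - st[, 4] <= params$range_cap + 1e-9)
  # maximality: every adjacent pair's union must break the predicate
  merged <- region_merge_cpp(lab, m, params$range_cap, params$connectivity)
  maximal <- max(merged) == labels$region_count
  c(exhaustive = exhaustive, connected = conn, homogeneous = homog,
    maximal = maximal)
}

#' Select the lymphocyte-nucleus ROI
#'
#' Picks, from a region label map, the regions that look like stained
#' lymphocyte nuclei: mean color with saturation at least `s_min` and hue in
#' the blue-purple window, and area at least `min_region_area`. Returns the
#' union of the qualifying regions as a binary mask.
#'
#' @param labels a `region_label_map`.
#' @param image the 3-channel `raster_image` the map refers to.
#' @param params a [segmentation_params()] (for `min_region_area`).
#' @param s_min minimum mean saturation (default 0.2).
#' @param hue_range nucleus hue window in degrees (default `c(200, 320)`).
#' @return logical matrix (the ROI mask). Empty with a warning when no
#'   region qualifies.
#' @export
select_roi <- function(labels, image, params = segmentation_params(),
                       s_min = 0.2, hue_range = c(200, 320)) {
  a <- img_data(image)
  if (dim(a)[3] != 3L) stop("select_roi: image must have 3 channels")
  lab <- labels$labels
  if (!all(dim(lab) == dim(a)[1:2])) stop("select_roi: shape mismatch")
  n <- labels$region_count
  mask <- matrix(FALSE, nrow(lab), ncol(lab))
  if (n == 0) { warning("select_roi: no regions"); return(mask) }
  idx <- as.vector(lab)
  mr <- tapply(as.vector(a[, , 1]), idx, mean)
  mg <- tapply(as.vector(a[, , 2]), idx, mean)
  mb <- tapply(as.vector(a[, , 3]), idx, mean)
  area <- tabulate(idx, nbins = n)
  hsv <- rgb2hsv(r = mr, g = mg, b = mb, maxColorValue = 255)
  hue <- hsv[1, ] * 360
  sat <- hsv[2, ]
  keep <- which(sat >= s_min & hue >= hue_range[1] & hue <= hue_range[2] &
                  area >= params$min_region_area)
  if (length(keep) == 0) {
    warning("select_roi: no nucleus-like region found; returning empty mask")
    return(mask)
  }
  mask[lab %in% keep] <- TRUE
  mask
}

#' Morphological refinement of a binary mask
#'
#' Applies, in order: closing with the structuring element, filling of
#' interior holes (background components with no pixel on the image border),
#' and opening with the same element. Closing bridges small gaps, hole
#' filling removes enclosed background left inside the ROI, and opening
#' removes debris smaller than the element. The operation is idempotent.
#'
#' @param mask logical matrix.
#' @param se a [structuring_element()] (default 5 x 5 all-true).
#' @return refined logical matrix of the same shape.
#' @export
morphological_refine <- function(mask, se = structuring_element()) {
  mode(mask) <- "logical"
  brush <- matrix(as.numeric(unclass(se)), nrow(unclass(se)))
  img <- EBImage::Image(t(mask * 1))
  out <- EBImage::closing(img, brush)
  out <- EBImage::fillHull(out)
  out <- EBImage::opening(out, brush)
  t(as.array(out)) > 0.5
}

#' Fill interior holes of a binary mask
#'
#' A hole is a background connected component with no pixel on the image
#' border. Exposed because it is the oracle-friendly core of
#' [morphological_refine()].
#'
#' @param mask logical matrix.
#' @return logical matrix with holes filled.
#' @export
fill_holes <- function(mask) {
  mode(mask) <- "logical"
  bg <- label_components_cpp(matrix(as.integer(!mask), nrow(mask)), 4L)
  border_labels <- setdiff(unique(c(bg[1, ], bg[nrow(bg), ],
                                    bg[, 1], bg[, ncol(bg)])), 0L)
  hole <- matrix(!(bg %in% c(0L, border_labels)), nrow(mask))
  mask | hole
}
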