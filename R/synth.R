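#' Synthetic smear parameters
#'
#' Deterministic generator of stained blood-smear look-alikes: a pale plasma
#' background, soft-edged red-cell discs, and one or more darkly stained
#' lymphocyte nuclei composited last, plus additive Gaussian pixel noise.
#' The two classes differ in nucleus morphology, mirroring how blast cells
#' present under the microscope: normal lymphocytes get a single round,
#' homogeneous nucleus; leukemic (blast) cells get a larger nucleus with an
#' irregular (perturbed-polygon) boundary, optional extra lobes, and
#' coarser, lumpier chromatin texture. Nucleus color is drawn from the same
#' blue-purple band for both classes, so class signal is carried by size and
#' texture rather than color.
#'
#' @param height,width canvas size in pixels (default 512 x 512; the native
#'   2592 x 1944 of high-resolution smear micrographs is available but slow).
#' @param rbc_count_mean mean red-cell count (Poisson; default 35).
#' @param wbc_count nuclei per image (default 1).
#' @param background_rgb plasma background color.
#' @param noise_sigma additive Gaussian noise sd in intensity units
#'   (default 4).
#' @param rbc_radius_mean,rbc_radius_sd red-cell disc radius distribution.
#' @param nucleus_rgb center of the nucleus color band (blue-purple).
#' @param normal_radius_mean,normal_radius_sd nucleus radius for the normal
#'   class.
#' @param blast_radius_mean,blast_radius_sd nucleus radius for the leukemia
#'   class (stochastically larger).
#' @param blast_irregularity boundary perturbation amplitude as a fraction
#'   of the radius (default 0.25; normal nuclei use 0.03).
#' @param blast_lobe_prob probability of a second nucleus lobe (default 0.4).
#' @param chromatin_sd_normal,chromatin_sd_blast amplitude of the intra-
#'   nucleus chromatin mottling for the two classes (default 4 and 14).
#' @return list of class `smear_synth_params`.
#' @export
smear_synth_params <- function(height = 512L, width = 512L,
                               rbc_count_mean = 35, wbc_count = 1L,
                               background_rgb = c(235, 225, 232),
                               noise_sigma = 4,
                               rbc_radius_mean = 26, rbc_radius_sd = 3,
                               nucleus_rgb = c(95, 60, 160),
                               normal_radius_mean = 30, normal_radius_sd = 3,
                               blast_radius_mean = 46, blast_radius_sd = 5,
                               blast_irregularity = 0.25,
                               blast_lobe_prob = 0.4,
                               chromatin_sd_normal = 4,
                               chromatin_sd_blast = 14) {
  if (blast_radius_mean <= normal_radius_mean)
    stop("blast radius mean must exceed the normal radius mean")
  structure(as.list(environment()), class = "smear_synth_params")
}

# soft-edged filled disc/blob membership on the pixel grid.
# boundary radius is modulated by a low-order harmonic perturbation.
blob_mask <- function(h, w, cy, cx, radius, irregularity = 0, phases = NULL,
                      soft = 1.5) {
  ys <- pmax(1, floor(cy - 1.6 * radius)):pmin(h, ceiling(cy + 1.6 * radius))
  xs <- pmax(1, floor(cx - 1.6 * radius)):pmin(w, ceiling(cx + 1.6 * radius))
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  r <- sqrt(dy^2 + dx^2)
  if (irregularity > 0 && !is.null(phases)) {
    th <- atan2(dy, dx)
    mod <- 1 + irregularity * (0.6 * sin(2 * th + phases[1]) +
                               0.3 * sin(3 * th + phases[2]) +
                               0.1 * sin(5 * th + phases[3]))
  } else mod <- 1
  alpha <- pmin(pmax((radius * mod - r) / soft + 0.5, 0), 1)
  list(ys = ys, xs = xs, alpha = alpha)
}

composite <- function(canvas, blob, rgb) {
  for (ch in 1:3) {
    sub <- canvas[blob$ys, blob$xs, ch]
    canvas[blob$ys, blob$xs, ch] <- sub * (1 - blob$alpha) + rgb[ch] * blob$alpha
  }
  canvas
}

# coarse-scale mottling field (chromatin texture): smoothed white noise,
# rescaled to unit sd
mottle_field <- function(h, w, scale = 6L) {
  base <- matrix(rnorm(ceiling(h / scale) * ceiling(w / scale)),
                 ceiling(h / scale))
  up <- base[rep(seq_len(nrow(base)), each = scale)[seq_len(h)],
             rep(seq_len(ncol(base)), each = scale)[seq_len(w)]]
  k <- enhancement_config(window_size = 5L, exclude_center = FALSE,
                          border_mode = "replicate")
  sm <- avg_filter_matrix(up, k)
  sm / max(sd(sm), 1e-9)
}

#' Generate one synthetic smear
#'
#' Deterministic under `(params, seed)`: identical inputs give bit-identical
#' images. The ground-truth mask records exactly the nucleus pixels (alpha
#' over one half).
#'
#' @param label `"leukemia"` or `"normal"`.
#' @param params a [smear_synth_params()].
#' @param seed integer seed.
#' @return list of class `smear_sample` with `image` (`raster_image`),
#'   `mask` (logical matrix), `label` and `provenance`.
#' @export
generate_smear <- function(label = c("normal", "leukemia"),
                           params = smear_synth_params(), seed = 0L) {
  label <- match.arg(label)
  h <- params$height; w <- params$width
  if (min(h, w) <= 4 * params$blast_radius_mean + 2)
    stop("generate_smear: canvas smaller than 4x the blast nucleus radius; ",
         "enlarge the canvas or shrink the radius distributions")
  set.seed(seed)
  canvas <- array(rep(params$background_rgb, each = h * w), dim = c(h, w, 3))
  n_rbc <- rpois(1, params$rbc_count_mean)
  for (i in seq_len(n_rbc)) {
    cy <- runif(1, 1, h); cx <- runif(1, 1, w)
    rad <- max(4, rnorm(1, params$rbc_radius_mean, params$rbc_radius_sd))
    tint <- runif(1, -12, 12)
    col <- clip01(c(228 + tint, 160 + tint, 168 + tint))
    b <- blob_mask(h, w, cy, cx, rad, soft = 2.5)
    # pale center: red cells are biconcave, brighter in the middle
    center <- blob_mask(h, w, cy, cx, rad * 0.45, soft = 2.5)
    canvas <- composite(canvas, b, col)
    canvas <- composite(canvas,
                        list(ys = center$ys, xs = center$xs,
                             alpha = center$alpha * 0.5),
                        clip01(col + 18))
  }
  mask <- matrix(FALSE, h, w)
  margin <- params$blast_radius_mean * 2
  for (i in seq_len(params$wbc_count)) {
    cy <- runif(1, margin, h - margin)
    cx <- runif(1, margin, w - margin)
    if (label == "leukemia") {
      rad <- max(8, rnorm(1, params$blast_radius_mean, params$blast_radius_sd))
      irr <- params$blast_irregularity
      chrom <- params$chromatin_sd_blast
    } else {
      rad <- max(8, rnorm(1, params$normal_radius_mean, params$normal_radius_sd))
      irr <- 0.03
      chrom <- params$chromatin_sd_normal
    }
    col <- clip01(params$nucleus_rgb + runif(3, -15, 15))
    phases <- runif(3, 0, 2 * pi)
    b <- blob_mask(h, w, cy, cx, rad, irregularity = irr, phases = phases)
    blob_alpha <- b$alpha
    canvas <- composite(canvas, b, col)
    sub_mask <- blob_alpha > 0.5
    if (label == "leukemia" && runif(1) < params$blast_lobe_prob) {
      ang <- runif(1, 0, 2 * pi)
      l_cy <- cy + 0.9 * rad * sin(ang); l_cx <- cx + 0.9 * rad * cos(ang)
      l_rad <- rad * runif(1, 0.4, 0.6)
      lb <- blob_mask(h, w, l_cy, l_cx, l_rad, irregularity = irr,
                      phases = phases)
      canvas <- composite(canvas, lb, col)
      mask[cbind(rep(lb$ys, length(lb$xs)),
                 rep(lb$xs, each = length(lb$ys)))] <-
        mask[cbind(rep(lb$ys, length(lb$xs)),
                   rep(lb$xs, each = length(lb$ys)))] | (lb$alpha > 0.5)
    }
    mask[cbind(rep(b$ys, length(b$xs)), rep(b$xs, each = length(b$ys)))] <-
      mask[cbind(rep(b$ys, length(b$xs)), rep(b$xs, each = length(b$ys)))] |
      sub_mask
    # chromatin mottling inside the nucleus
    field <- mottle_field(length(b$ys), length(b$xs))
    for (ch in 1:3) {
      sub <- canvas[b$ys, b$xs, ch]
      canvas[b$ys, b$xs, ch] <- sub + field * chrom * (blob_alpha > 0.5)
    }
  }
  canvas <- canvas + array(rnorm(h * w * 3, 0, params$noise_sigma),
                           dim = c(h, w, 3))
  structure(list(image = raster_image(clip01(canvas)), mask = mask,
                 label = label,
                 provenance = list(seed = seed,
                                   digest = paste0("hw", h, "x", w,
                                                   "_wbc", params$wbc_count))),
            class = "smear_sample")
}

#' Generate a balanced synthetic dataset
#'
#' `n_per_class` smears per class, either in memory or written to
#' `out_dir/images`, `out_dir/masks` with a `manifest.csv`. Reproducible
#' under the seed; sample `i` of class `cls` uses seed
#' `seed + i + 10000 * (cls == "leukemia")`.
#'
#' @param n_per_class samples per class.
#' @param params a [smear_synth_params()].
#' @param seed integer base seed.
#' @param out_dir optional output directory; when `NULL` (default) samples
#'   stay in memory.
#' @return list with `samples` (list of `smear_sample`, `NULL` when written
#'   to disk), `manifest` (data.frame `source_id, path, label`).
#' @export
generate_dataset <- function(n_per_class, params = smear_synth_params(),
                             seed = 0L, out_dir = NULL) {
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  manifest <- data.frame(source_id = character(), path = character(),
                         label = character(), stringsAsFactors = FALSE)
  samples <- list()
  write_out <- !is.null(out_dir)
  if (write_out) {
    dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  }
  for (cls in c("leukemia", "normal")) {
    for (i in seq_len(n_per_class)) {
      s <- generate_smear(cls, params,
                          seed = seed + i + 10000L * (cls == "leukemia"))
      sid <- sprintf("%s_%04d", cls, i)
      path <- if (write_out) file.path(out_dir, "images", paste0(sid, ".png")) else ""
      if (write_out) {
        write_image(s$image, path)
        write_image(raster_image(matrix(s$mask * 255, nrow(s$mask))),
                    file.path(out_dir, "masks", paste0(sid, ".png")))
      } else {
        samples[[sid]] <- s
      }
      manifest <- rbind(manifest,
                        data.frame(source_id = sid, path = path, label = cls,
                                   stringsAsFactors = FALSE))
    }
  }
  if (write_out)
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  list(samples = if (write_out) NULL else samples, manifest = manifest)
}
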