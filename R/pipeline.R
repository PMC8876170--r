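# stage-name hash: one global seed fans out to per-stage seeds so stages can
# be re-run in isolation; kept below 2^31.
stage_seed <- function(seed, stage) {
  s <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + s) %% .Machine$integer.max)
}

#' Run configuration for the diagnosis pipeline
#'
#' @param mode `"handcrafted"` (enhance, segment, fused 232-entry features,
#'   classifier), `"cnn"` (micro-CNN end to end) or `"hybrid_cnn_svm"`
#'   (micro-CNN deep features into the max-margin classifier).
#' @param classifier for handcrafted mode: `"ffnn"` (cross-entropy
#'   perceptron), `"ann"` (mean-squared-error perceptron) or `"svm"`.
#' @param seed global seed; per-stage seeds are derived from it by a
#'   stage-name hash.
#' @param enhancement an [enhancement_config()].
#' @param segmentation a [segmentation_params()].
#' @param split a [split_spec()] (its seed is overridden by the derived
#'   stage seed).
#' @param augmentation `NULL` (default, no augmentation) or an
#'   [augmentation_spec()] applied to the training partition only.
#' @param cnn a [micro_cnn_spec()] for the cnn/hybrid modes.
#' @param cnn_epochs micro-CNN training epochs (default 30).
#' @param mlp a [train_config()]; its objective is set by the preset.
#' @param svm_cost max-margin regularization constant (default 1).
#' @return list of class `run_config`.
#' @export
run_config <- function(mode = c("handcrafted", "cnn", "hybrid_cnn_svm"),
                       classifier = c("ffnn", "ann", "svm"),
                       seed = 0L,
                       enhancement = enhancement_config(),
                       segmentation = segmentation_params(),
                       split = split_spec(),
                       augmentation = NULL,
                       cnn = micro_cnn_spec(),
                       cnn_epochs = 30L,
                       mlp = train_config(max_epochs = 300L),
                       svm_cost = 1) {
  mode <- match.arg(mode)
  classifier <- match.arg(classifier)
  stopifnot(inherits(enhancement, "enhancement_config"),
            inherits(segmentation, "segmentation_params"),
            inherits(split, "split_spec"),
            is.null(augmentation) || inherits(augmentation, "augmentation_spec"),
            inherits(cnn, "micro_cnn_spec"), inherits(mlp, "train_config"))
  structure(list(mode = mode, classifier = classifier, seed = as.integer(seed),
                 enhancement = enhancement, segmentation = segmentation,
                 split = split, augmentation = augmentation, cnn = cnn,
                 cnn_epochs = as.integer(cnn_epochs), mlp = mlp,
                 svm_cost = svm_cost),
            class = "run_config")
}

load_samples <- function(manifest, samples = NULL) {
  if (!is.null(samples)) return(samples)
  out <- list()
  for (i in seq_len(nrow(manifest))) {
    if (!file.exists(manifest$path[i]))
      stop("pipeline: missing image for ", manifest$source_id[i], ": ",
           manifest$path[i])
    out[[manifest$source_id[i]]] <- list(image = read_image(manifest$path[i]),
                                         label = manifest$label[i])
  }
  out
}

pipeline_features <- function(samples, config, progress = FALSE) {
  feats <- matrix(NA_real_, length(samples), feature_layout[["total"]])
  for (i in seq_along(samples)) {
    img <- enhance(samples[[i]]$image, config$enhancement)
    lab <- region_grow(to_grayscale(img), config$segmentation)
    roi <- suppressWarnings(select_roi(lab, img, config$segmentation))
    roi <- morphological_refine(roi)
    feats[i, ] <- suppressWarnings(extract_features(img, roi))
    if (progress && i %% 25 == 0)
      message(sprintf("  features: %d/%d images", i, length(samples)))
  }
  colnames(feats) <- names(fuse_features(numeric(203), numeric(13), numeric(16)))
  feats
}

#' Fit a leukemia screening pipeline
#'
#' The central fitting function. Takes labeled smear images, runs the
#' configured variant — enhancement, nucleus segmentation and fused
#' texture/color features into a perceptron or max-margin classifier
#' (`handcrafted`); the micro convolutional network end to end (`cnn`); or
#' micro-CNN deep features into the max-margin classifier
#' (`hybrid_cnn_svm`) — on a stratified train/validation/test split, and
#' returns the fitted model with its held-out evaluation report.
#'
#' @param manifest data.frame with `source_id` and `label` columns (and
#'   `path` when images are on disk).
#' @param samples optional named list of in-memory records (`image`,
#'   `label`), e.g. from [generate_dataset()]; read from `manifest$path`
#'   when absent.
#' @param config a [run_config()].
#' @param progress emit progress messages (default `FALSE`).
#' @return object of class `leukodiag`.
#' @export
leukodiag <- function(manifest, samples = NULL, config = run_config(),
                      progress = FALSE) {
  samples <- load_samples(manifest, samples)
  stopifnot(length(samples) == nrow(manifest))
  labels <- vapply(samples, function(s) s$label, "")
  split_cfg <- config$split
  split_cfg$seed <- stage_seed(config$seed, "split")
  man <- split_records(data.frame(source_id = names(samples), label = labels,
                                  stringsAsFactors = FALSE), split_cfg)
  part <- man$partition
  if (!is.null(config$augmentation) && config$mode != "handcrafted") {
    aug_spec <- config$augmentation
    aug_spec$seed <- stage_seed(config$seed, "augment")
    tr_idx <- which(part == "train")
    recs <- lapply(tr_idx, function(i)
      list(image = samples[[i]]$image, label = labels[i],
           source_id = man$source_id[i]))
    aug <- augment_records(recs, aug_spec)
    keep <- which(part != "train")
    samples <- c(lapply(aug, function(r) list(image = r$image, label = r$label)),
                 samples[keep])
    labels <- vapply(samples, function(s) s$label, "")
    part <- c(rep("train", length(aug)), part[keep])
  }
  trained <- NULL; feats <- NULL; cnn_model <- NULL
  feature_source <- NULL
  if (config$mode == "handcrafted") {
    if (progress) message("extracting handcrafted features...")
    feats <- pipeline_features(samples, config, progress)
    feature_source <- "handcrafted:lbp+glcm+fch"
    if (config$classifier == "svm") {
      trained <- train_max_margin(feats[part == "train", , drop = FALSE],
                                  labels[part == "train"], C = config$svm_cost)
    } else {
      cfg <- config$mlp
      cfg$objective <- if (config$classifier == "ann") "mse" else "cross_entropy"
      cfg$seed <- stage_seed(config$seed, "mlp")
      trained <- train_mlp(feats, labels, part, cfg)
    }
  } else {
    if (progress) message("preparing micro-CNN inputs...")
    imgs <- lapply(samples, function(s) enhance(s$image, config$enhancement))
    tr <- part == "train"
    cnn_model <- train_micro_cnn(imgs[tr], labels[tr], config$cnn,
                                 epochs = config$cnn_epochs,
                                 seed = stage_seed(config$seed, "cnn"))
    if (config$mode == "cnn") {
      trained <- cnn_model
      feature_source <- "cnn:end_to_end"
    } else {
      feats <- t(vapply(imgs, function(im) extract_deep_features(cnn_model, im),
                        numeric(config$cnn$dense_units)))
      feature_source <- "cnn:tap"
      trained <- train_max_margin(feats[tr, , drop = FALSE], labels[tr],
                                  C = config$svm_cost)
    }
  }
  te <- part == "test"
  pred <- if (config$mode == "cnn") {
    imgs <- lapply(samples[te], function(s) enhance(s$image, config$enhancement))
    predict(trained, imgs)
  } else {
    predict(trained, feats[te, , drop = FALSE])
  }
  report <- evaluation_report(labels[te], pred$class, pred$score)
  structure(list(config = config, model = trained, cnn = cnn_model,
                 features = feats, partition = part, labels = labels,
                 feature_source = feature_source,
                 classifier_name = if (config$mode == "handcrafted")
                   config$classifier else if (config$mode == "cnn")
                     "micro_cnn" else "max_margin",
                 report = report),
            class = "leukodiag")
}

#' @export
print.leukodiag <- function(x, ...) {
  cat(sprintf("leukodiag pipeline (%s mode, %s classifier)\n",
              x$config$mode, x$classifier_name))
  cat(sprintf("features: %s; n = %d (train %d / val %d / test %d)\n",
              x$feature_source, length(x$partition),
              sum(x$partition == "train"), sum(x$partition == "validation"),
              sum(x$partition == "test")))
  cat(sprintf("held-out accuracy %.2f%%, AUC %.2f%%\n",
              x$report$metrics["accuracy"], x$report$auc))
  invisible(x)
}

#' @export
summary.leukodiag <- function(object, ...) {
  print(object)
  print(object$report)
  invisible(object)
}

#' @export
predict.leukodiag <- function(object, images, ...) {
  if (inherits(images, "raster_image")) images <- list(images)
  cfg <- object$config
  if (cfg$mode == "handcrafted") {
    feats <- pipeline_features(lapply(images, function(im) list(image = im)),
                               cfg)
    predict(object$model, feats)
  } else if (cfg$mode == "cnn") {
    predict(object$model, lapply(images, function(im) enhance(im, cfg$enhancement)))
  } else {
    feats <- t(vapply(images, function(im)
      extract_deep_features(object$cnn, enhance(im, cfg$enhancement)),
      numeric(cfg$cnn$dense_units)))
    predict(object$model, feats)
  }
}

#' @export
plot.leukodiag <- function(x, which = c("roc", "error_histogram", "trace"), ...) {
  which <- match.arg(which)
  if (which == "roc") {
    graphics::plot(x$report$roc_curve$fpr, x$report$roc_curve$tpr, type = "s",
                   xlab = "false positive rate", ylab = "true positive rate",
                   main = sprintf("ROC (AUC %.2f%%)", x$report$auc))
    graphics::abline(0, 1, lty = 3)
  } else if (which == "error_histogram") {
    eh <- x$report$error_histogram
    mids <- (utils::head(eh$breaks, -1) + eh$breaks[-1]) / 2
    graphics::barplot(eh$counts, names.arg = sprintf("%.2f", mids),
                      las = 2, main = "error histogram",
                      ylab = "count", xlab = "target - score")
  } else {
    if (inherits(x$model, "mlp_model")) {
      tr <- x$model$trace
      graphics::matplot(tr$epoch, cbind(tr$train_loss, tr$val_loss), type = "l",
                        lty = 1, xlab = "epoch", ylab = "loss",
                        main = "training trace")
      graphics::legend("topright", c("train", "validation"), lty = 1,
                       col = 1:2)
    } else if (!is.null(x$cnn)) {
      graphics::plot(x$cnn$trace, type = "l", xlab = "epoch",
                     ylab = "training loss", main = "micro-CNN trace")
    }
  }
  invisible(x)
}

report_to_list <- function(x) {
  r <- x$report
  list(mode = x$config$mode,
       classifier = x$classifier_name,
       feature_source = x$feature_source,
       seed = x$config$seed,
       n = r$n,
       confusion = list(tp = r$confusion$tp, fn = r$confusion$fn,
                        fp = r$confusion$fp, tn = r$confusion$tn),
       accuracy = round(unname(r$metrics["accuracy"]), 2),
       precision = round(unname(r$metrics["precision"]), 2),
       sensitivity = round(unname(r$metrics["sensitivity"]), 2),
       specificity = round(unname(r$metrics["specificity"]), 2),
       auc = round(r$auc, 2),
       regression_r = round(r$regression_r, 6))
}

#' Run the full pipeline and write its artifacts
#'
#' Thin orchestration over [leukodiag()]: fits the configured variant and
#' writes the feature table, the evaluation report and a reproducibility
#' record (config digest + seed) into `out_dir`. Identical config and seed
#' produce byte-identical reports.
#'
#' @param config a [run_config()].
#' @param manifest manifest data.frame (see [leukodiag()]).
#' @param out_dir output directory (created if needed).
#' @param samples optional in-memory samples.
#' @return the fitted `leukodiag` object, invisibly.
#' @export
run_pipeline <- function(config, manifest, out_dir, samples = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fit <- leukodiag(manifest, samples = samples, config = config)
  if (!is.null(fit$features)) {
    df <- data.frame(source_id = names(fit$labels), label = fit$labels,
                     partition = fit$partition, fit$features,
                     check.names = FALSE, row.names = NULL)
    write.csv(df, file.path(out_dir, "features.csv"), row.names = FALSE)
  }
  jsonlite::write_json(report_to_list(fit), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  repro <- list(seed = config$seed, mode = config$mode,
                classifier = config$classifier,
                n_records = nrow(manifest),
                stage_seeds = list(split = stage_seed(config$seed, "split"),
                                   augment = stage_seed(config$seed, "augment"),
                                   mlp = stage_seed(config$seed, "mlp"),
                                   cnn = stage_seed(config$seed, "cnn")))
  jsonlite::write_json(repro, file.path(out_dir, "repro.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(fit)
}
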