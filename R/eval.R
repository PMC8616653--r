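# Confusion-matrix metrics (pixel accuracy, per-class IoU, MIoU),
# dataset-level evaluation, overlay rendering and the ablation harness.

#' Pixel confusion matrix of a predicted mask against the truth
#'
#' `counts[i, j]` is the number of pixels with true class `i - 1` and
#' predicted class `j - 1` (rows = truth, columns = prediction). Matrices
#' from several images accumulate by elementwise addition.
#'
#' @param pred_mask,true_mask integer matrices of identical shape with
#'   labels in `0..C-1`.
#' @param C number of classes.
#' @return a `C x C` numeric matrix of counts.
#' @export
confusion <- function(pred_mask, true_mask, C = 2L) {
  if (!identical(dim(pred_mask), dim(true_mask))) {
    stop("prediction and truth must have identical shape")
  }
  p <- as.integer(pred_mask)
  y <- as.integer(true_mask)
  if (any(p < 0L) || any(p >= C) || any(y < 0L) || any(y >= C)) {
    stop("labels must lie in [0, ", C, ")")
  }
  matrix(tabulate(y * C + p + 1L, nbins = C * C), C, C, byrow = TRUE)
}

#' Pixel accuracy from a confusion matrix
#'
#' Fraction of pixels whose predicted class equals the true class:
#' trace / total.
#'
#' @param cm confusion matrix from [confusion()].
#' @return real in `[0, 1]`.
#' @export
pixel_accuracy <- function(cm) {
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix is empty")
  sum(diag(cm)) / total
}

#' Per-class intersection-over-union from a confusion matrix
#'
#' `IoU_c = cm[c, c] / (row_c + col_c - cm[c, c])`. A class whose union is
#' zero (absent from both prediction and truth) gets `NA`.
#'
#' @param cm confusion matrix.
#' @return numeric vector of length `C`, possibly with `NA`s.
#' @export
class_iou <- function(cm) {
  if (sum(cm) <= 0) stop("confusion matrix is empty")
  inter <- diag(cm)
  union <- rowSums(cm) + colSums(cm) - inter
  ifelse(union > 0, inter / union, NA_real_)
}

#' Mean intersection-over-union from a confusion matrix
#'
#' Mean of the defined per-class IoUs; classes with zero union are excluded
#' from the mean. Errors if every class has zero union.
#'
#' @param cm confusion matrix.
#' @return real in `[0, 1]`.
#' @export
miou <- function(cm) {
  iou <- class_iou(cm)
  if (all(is.na(iou))) stop("no class has a nonzero union")
  mean(iou, na.rm = TRUE)
}

metrics_report <- function(cm, mean_loss, n_images) {
  structure(list(pixel_accuracy = pixel_accuracy(cm),
                 per_class_iou = class_iou(cm),
                 miou = miou(cm),
                 mean_loss = mean_loss,
                 n_images = as.integer(n_images),
                 confusion = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d image(s)\n", x$n_images))
  cat(sprintf("  PA    %.4f\n", x$pixel_accuracy))
  cat(sprintf("  MIoU  %.4f  (per class: %s)\n", x$miou,
              paste(sprintf("%.4f", x$per_class_iou), collapse = ", ")))
  if (!is.na(x$mean_loss)) cat(sprintf("  loss  %.4f\n", x$mean_loss))
  invisible(x)
}

#' Evaluate a model (or a predictor function) on labeled samples
#'
#' Metrics are computed on one confusion matrix accumulated over all
#' images — the standard dataset-level definition — not by averaging
#' per-image scores; the loss is averaged per image. Samples are resized to
#' the model's input size and predictions compared at that size.
#'
#' `model` may also be a plain function `sample -> mask` (e.g. a trivial
#' all-background baseline); in that case masks are compared at native
#' resolution and no loss is reported.
#'
#' @param model a `fissure_model` or a predictor `function(sample)`.
#' @param samples nonempty list of labeled samples.
#' @param class_weights optional class weights for the reported loss.
#' @return a `metrics_report`.
#' @export
evaluate <- function(model, samples, class_weights = NULL) {
  if (!length(samples)) stop("no samples to evaluate")
  for (s in samples) {
    if (is.null(s$mask)) stop("evaluation samples must be labeled")
  }
  if (is.function(model)) {
    C <- max(2L, max(vapply(samples, function(s) max(s$mask), 0)) + 1L)
    cm <- NULL
    for (s in samples) {
      pred <- model(s)
      cmi <- confusion(pred, s$mask, C)
      cm <- if (is.null(cm)) cmi else cm + cmi
    }
    return(metrics_report(cm, NA_real_, length(samples)))
  }
  stopifnot(inherits(model, "fissure_model"))
  size <- model$config$input_size
  pr <- prepare_arrays(samples, size, model$config$in_channels)
  if (is.null(pr$Y)) stop("evaluation samples must be labeled")
  ev <- eval_arrays(model, pr$X, pr$Y, model$config$num_classes,
                    class_weights)
  metrics_report(ev$cm, ev$mean_loss, length(samples))
}

#' Blend a mask onto an image for visual inspection
#'
#' Mask-positive pixels become `(1 - alpha) * image + alpha * color`;
#' all other pixels are unchanged.
#'
#' @param image `(H, W, 3)` array in 0..255.
#' @param mask integer matrix in `{0, 1}` of the same spatial size.
#' @param color RGB triple in 0..255.
#' @param alpha blend factor in `[0, 1]`.
#' @return the blended `(H, W, 3)` array.
#' @export
overlay <- function(image, mask, color = c(255, 0, 0), alpha = 0.5) {
  stopifnot(alpha >= 0, alpha <= 1)
  d <- dim(image)
  stopifnot(identical(d[1:2], dim(mask)))
  out <- image
  sel <- mask > 0
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[sel] <- (1 - alpha) * plane[sel] + alpha * color[ch]
    out[, , ch] <- plane
  }
  out
}

#' Ablation harness: train and score a grid of model configurations
#'
#' Trains every configuration on identical data and seeds and reports
#' mean and standard deviation of PA, loss and MIoU on the held-out split,
#' one row per configuration — the layout of a backbone/module comparison
#' table. PA and MIoU are reported in percent and the cross-entropy loss
#' multiplied by 100, matching the conventional table scales.
#'
#' @param configs list of [model_config()]s.
#' @param dataset_spec list with `params` (a [synthetic_params()]), `n`
#'   (dataset size) and optional `train_fraction` (default 0.7).
#' @param train_cfg a [train_config()] applied to every configuration.
#' @param n_seeds number of independent replicate seeds.
#' @param verbose print per-fit progress.
#' @return a data.frame with one row per configuration: `model`, `pa`,
#'   `pa_sd`, `loss_pct`, `loss_sd`, `miou`, `miou_sd`.
#' @export
compare_configs <- function(configs, dataset_spec, train_cfg, n_seeds = 1L,
                            verbose = FALSE) {
  stopifnot(length(configs) >= 1, n_seeds >= 1)
  frac <- dataset_spec$train_fraction %||% 0.7
  res <- array(NA_real_, c(length(configs), n_seeds, 3),
               dimnames = list(NULL, NULL, c("pa", "loss", "miou")))
  for (s in seq_len(n_seeds)) {
    data_seed <- derive_seed(s, "compare-data")
    samples <- generate_dataset(dataset_spec$params, dataset_spec$n,
                                seed = data_seed)
    split <- split_dataset(seq_along(samples), frac, seed = data_seed)
    train_set <- samples[split$train_ids]
    test_set <- samples[split$held_out_ids]
    for (ci in seq_along(configs)) {
      mdl <- build_improved_unet(configs[[ci]],
                                 seed = derive_seed(s, "compare-init"))
      cfg <- train_cfg
      cfg$seed <- derive_seed(s, "compare-train")
      fit <- train_model(mdl, train_set, NULL, cfg)
      rep <- evaluate(fit$model, test_set, train_cfg$class_weights)
      res[ci, s, ] <- c(rep$pixel_accuracy, rep$mean_loss, rep$miou)
      if (verbose) {
        message(sprintf("seed %d  %-24s PA %.3f  MIoU %.3f",
                        s, config_label(configs[[ci]]),
                        rep$pixel_accuracy, rep$miou))
      }
    }
  }
  sd0 <- function(v) if (length(v) > 1) stats::sd(v) else 0
  data.frame(
    model = vapply(configs, config_label, character(1)),
    pa = 100 * apply(res[, , "pa", drop = FALSE], 1, mean),
    pa_sd = 100 * apply(res[, , "pa", drop = FALSE], 1, sd0),
    loss_pct = 100 * apply(res[, , "loss", drop = FALSE], 1, mean),
    loss_sd = 100 * apply(res[, , "loss", drop = FALSE], 1, sd0),
    miou = 100 * apply(res[, , "miou", drop = FALSE], 1, mean),
    miou_sd = 100 * apply(res[, , "miou", drop = FALSE], 1, sd0),
    stringsAsFactors = FALSE
  )
}
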