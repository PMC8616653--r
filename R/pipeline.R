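# End-to-end experiment pipeline: configuration, seeding, artifact writing
# and external-image validation. The workflow is
# generate/ingest -> augment -> split -> train -> evaluate -> overlay,
# driven by one YAML configuration file whose single global seed fans out
# deterministically to every stage.

experiment_schema <- list(
  seed = NULL,
  output_dir = NULL,
  n_overlays = NULL,
  data = c("synthetic", "manifest"),
  augment = c("orbit", "crop", "crop_size", "crops_per_sample"),
  split = c("train_fraction", "val_fraction"),
  model = c("encoder", "use_gcn", "gcn_kernel_size", "gcn_variant",
            "use_br", "num_classes", "base_channels", "in_channels",
            "input_size", "upsample", "fusion"),
  train = c("learning_rate", "batch_size", "beta1", "input_size", "epochs",
            "lr_decay", "class_weights")
)

synthetic_keys <- c("n_images", "image_size", "crack_count_range",
                    "branch_probability", "step_length", "crack_width_range",
                    "crack_intensity_delta", "background_base_color",
                    "texture_noise_scale", "foreground_ellipse_axes_fraction")

validate_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stop("unknown configuration key(s) in ", where, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
}

#' Read and validate an experiment configuration
#'
#' The configuration is a YAML file with sections `data` (either
#' `synthetic:` generator parameters plus `n_images`, or `manifest:` a
#' dataset manifest path), `augment`, `split`, `model`, `train`, and
#' top-level
#' `seed`, `output_dir`, `n_overlays`. Unknown keys raise an error naming
#' the key before any computation happens.
#'
#' @param path YAML file path, or a pre-parsed list.
#' @return a validated `experiment_config` list with all defaults filled.
#' @export
read_experiment_config <- function(path) {
  raw <- if (is.character(path)) yaml::read_yaml(path) else path
  validate_keys(raw, names(experiment_schema), "top level")
  for (sec in c("data", "augment", "split", "model", "train")) {
    if (!is.null(raw[[sec]])) {
      validate_keys(raw[[sec]], experiment_schema[[sec]], sec)
    }
  }
  if (is.null(raw$data)) stop("configuration needs a 'data' section")
  if (!is.null(raw$data$synthetic)) {
    validate_keys(raw$data$synthetic, synthetic_keys, "data.synthetic")
  } else if (is.null(raw$data$manifest)) {
    stop("data section needs either 'synthetic' or 'manifest'")
  }
  model_args <- raw$model %||% list()
  if (!is.null(model_args$input_size)) {
    model_args$input_size <- as.integer(unlist(model_args$input_size))
  }
  model_cfg <- do.call(model_config, model_args)
  train_args <- raw$train %||% list()
  if (!is.null(train_args$input_size)) {
    train_args$input_size <- as.integer(unlist(train_args$input_size))
  }
  if (!is.null(train_args$class_weights)) {
    train_args$class_weights <- as.numeric(unlist(train_args$class_weights))
  }
  train_cfg <- do.call(train_config, train_args)
  train_cfg$input_size <- model_cfg$input_size
  structure(list(
    seed = as.integer(raw$seed %||% 1L),
    output_dir = raw$output_dir,
    n_overlays = as.integer(raw$n_overlays %||% 3L),
    data = raw$data,
    augment = raw$augment %||% list(orbit = TRUE),
    split = list(train_fraction = raw$split$train_fraction %||% 0.7,
                 val_fraction = raw$split$val_fraction %||% 0.7),
    model = model_cfg,
    train = train_cfg
  ), class = "experiment_config")
}

load_experiment_samples <- function(cfg) {
  if (!is.null(cfg$data$synthetic)) {
    sy <- cfg$data$synthetic
    n <- sy$n_images %||% 32L
    pa <- sy[setdiff(names(sy), "n_images")]
    pa <- lapply(pa, function(v) if (is.list(v)) unlist(v) else v)
    params <- do.call(synthetic_params, pa)
    generate_dataset(params, n, seed = derive_seed(cfg$seed, "data"))
  } else {
    load_dataset(cfg$data$manifest)
  }
}

#' Run a full experiment from a configuration file
#'
#' Executes generate/ingest, outer split into a training-validation pool
#' and a held-out test set, augmentation of the pool (dihedral orbit and
#' optional crops, before the inner split), inner train/validation split,
#' training, test-set evaluation, and overlay rendering for the first
#' `n_overlays` test images. Writes `checkpoint.rds`, `history.csv`,
#' `metrics.json`, `overlay_*.png` and a `manifest.json` recording every
#' derived seed and the md5 of every artifact. Identical configurations
#' produce byte-identical `metrics.json`.
#'
#' @param config path to a YAML configuration, or the list from
#'   [read_experiment_config()].
#' @param output_dir overrides the configured output directory.
#' @param verbose print per-epoch progress.
#' @return invisibly, a list with `metrics` (the test `metrics_report`),
#'   `history`, `model` and `paths`.
#' @export
run_experiment <- function(config, output_dir = NULL, verbose = FALSE) {
  cfg <- if (inherits(config, "experiment_config")) {
    config
  } else {
    read_experiment_config(config)
  }
  out_dir <- output_dir %||% cfg$output_dir
  if (is.null(out_dir)) stop("an output directory is required")

  samples <- load_experiment_samples(cfg)
  outer <- split_dataset(seq_along(samples), cfg$split$train_fraction,
                         seed = derive_seed(cfg$seed, "outer-split"))
  pool <- samples[outer$train_ids]
  test_set <- samples[outer$held_out_ids]

  ops <- c(if (isTRUE(cfg$augment$orbit %||% TRUE)) "orbit",
           if (isTRUE(cfg$augment$crop)) "crop")
  if (length(ops)) {
    pool <- augment_dataset(pool, ops,
                            seed = derive_seed(cfg$seed, "augment"),
                            crop_size = cfg$augment$crop_size,
                            crops_per_sample =
                              cfg$augment$crops_per_sample %||% 1L)
  }
  inner <- split_dataset(seq_along(pool), cfg$split$val_fraction,
                         seed = derive_seed(cfg$seed, "inner-split"))
  train_set <- pool[inner$train_ids]
  val_set <- pool[inner$held_out_ids]

  model <- build_improved_unet(cfg$model,
                               seed = derive_seed(cfg$seed, "model-init"))
  tcfg <- cfg$train
  tcfg$seed <- derive_seed(cfg$seed, "train")
  fit <- train_model(model, train_set, val_set, tcfg, verbose = verbose)
  report <- evaluate(fit$model, test_set, tcfg$class_weights)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(checkpoint = file.path(out_dir, "checkpoint.rds"),
                history = file.path(out_dir, "history.csv"),
                metrics = file.path(out_dir, "metrics.json"),
                manifest = file.path(out_dir, "manifest.json"))
  save_checkpoint(fit$model, paths$checkpoint)
  write.csv(fit$history, paths$history, row.names = FALSE)
  jsonlite::write_json(
    list(pixel_accuracy = report$pixel_accuracy,
         per_class_iou = as.numeric(report$per_class_iou),
         miou = report$miou,
         mean_loss = report$mean_loss,
         n_images = report$n_images),
    paths$metrics, auto_unbox = TRUE, digits = NA, na = "null")
  k <- min(cfg$n_overlays, length(test_set))
  overlay_paths <- character(0)
  for (i in seq_len(k)) {
    s <- test_set[[i]]
    pred <- predict(fit$model, s)
    sized <- resize_sample(s, cfg$model$input_size)
    op <- file.path(out_dir, sprintf("overlay_%02d.png", i))
    write_image(overlay(sized$image, pred), op)
    overlay_paths <- c(overlay_paths, op)
  }
  paths$overlays <- overlay_paths
  artifact_files <- c(unlist(paths[c("checkpoint", "history", "metrics")]),
                      overlay_paths)
  manifest <- list(
    seed = cfg$seed,
    derived_seeds = list(data = derive_seed(cfg$seed, "data"),
                         outer_split = derive_seed(cfg$seed, "outer-split"),
                         augment = derive_seed(cfg$seed, "augment"),
                         inner_split = derive_seed(cfg$seed, "inner-split"),
                         model_init = derive_seed(cfg$seed, "model-init"),
                         train = derive_seed(cfg$seed, "train")),
    n_samples = length(samples),
    n_train = length(train_set), n_val = length(val_set),
    n_test = length(test_set),
    artifacts = lapply(artifact_files, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(metrics = report, history = fit$history,
                 model = fit$model, paths = paths))
}

#' Segment an external image with a trained checkpoint
#'
#' Loads the checkpoint, reads the image (grayscale inputs are promoted to
#' 3 channels), resizes to the model's input size, predicts, and writes the
#' mask and an overlay next to each other. No ground-truth mask is needed.
#'
#' @param checkpoint path to a checkpoint from [save_checkpoint()].
#' @param image_path PNG or JPEG image.
#' @param out_dir output directory (default: the image's directory).
#' @return list with `mask`, `mask_path`, `overlay_path`.
#' @export
validate_external_image <- function(checkpoint, image_path, out_dir = NULL) {
  model <- load_checkpoint(checkpoint)
  img <- read_image(image_path)
  out_dir <- out_dir %||% dirname(image_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pred <- predict(model, img)
  base <- tools::file_path_sans_ext(basename(image_path))
  mask_path <- file.path(out_dir, paste0(base, "_mask.png"))
  overlay_path <- file.path(out_dir, paste0(base, "_overlay.png"))
  write_mask(pred, mask_path)
  sized <- resize_sample(list(image = img), model$config$input_size)
  write_image(overlay(sized$image, pred), overlay_path)
  list(mask = pred, mask_path = mask_path, overlay_path = overlay_path)
}
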