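# Model configuration, encoder backbones and the improved U-Net assembly.

#' Model configuration
#'
#' Everything needed to build a segmentation network deterministically.
#'
#' Encoders: `"googlenet"` (Inception groups), `"vgg"` (stacked 3x3
#' conv-ReLU pairs), `"seresnet"` (residual blocks with squeeze-excite),
#' each with a stride-4 stem and four stages at strides 4/8/16/32; and
#' `"plain_unet"`, the classic double-3x3-conv encoder with stages at
#' strides 2/4/8/16. With `encoder = "plain_unet"`, `use_gcn = FALSE` and
#' `use_br = FALSE` the assembly reduces to a classic U-Net with
#' concatenation skips.
#'
#' @param encoder one of `"googlenet"`, `"vgg"`, `"seresnet"`,
#'   `"plain_unet"`.
#' @param use_gcn put a large-kernel GCN module on every skip pathway
#'   (otherwise a plain 1x1 projection to `num_classes`).
#' @param gcn_kernel_size odd GCN kernel size (default 7).
#' @param gcn_variant `"dense"` or `"separable"` GCN convolutions.
#' @param use_br apply a Boundary Refinement block after every skip
#'   projection and every decoder fusion/upsampling step.
#' @param num_classes number of output classes (>= 2; class 0 is
#'   background).
#' @param base_channels width multiplier of the encoder (googlenet/vgg/
#'   seresnet widths are 2/4/8/16/16 x this; must be a multiple of 8 for
#'   the Inception branch arithmetic).
#' @param in_channels input image channels (3 for RGB).
#' @param input_size `(H, W)` the network is trained/evaluated at; spatial
#'   dims must be divisible by 32.
#' @param upsample decoder upsampling: `"deconv"` (learnable 2x2 stride-2
#'   transposed convolution) or `"bilinear"`.
#' @param fusion how a decoder level merges the upsampled map with the skip
#'   output: `"add"` (elementwise, the default) or `"concat"`
#'   (concatenation followed by a 1x1 projection back to `num_classes`).
#' @return a `model_config` list.
#' @export
model_config <- function(encoder = "googlenet",
                         use_gcn = TRUE, gcn_kernel_size = 7L,
                         gcn_variant = c("dense", "separable"),
                         use_br = TRUE, num_classes = 2L,
                         base_channels = 8L, in_channels = 3L,
                         input_size = c(256L, 256L),
                         upsample = c("deconv", "bilinear"),
                         fusion = c("add", "concat")) {
  if (length(encoder) != 1 ||
      !encoder %in% c("googlenet", "vgg", "seresnet", "plain_unet")) {
    stop("unknown encoder \"", paste(encoder, collapse = "/"),
         "\"; expected one of googlenet, vgg, seresnet, plain_unet")
  }
  gcn_variant <- match.arg(gcn_variant)
  upsample <- match.arg(upsample)
  fusion <- match.arg(fusion)
  gcn_kernel_size <- as.integer(gcn_kernel_size)
  if (use_gcn && (gcn_kernel_size < 1L || gcn_kernel_size %% 2L == 0L)) {
    stop("gcn_kernel_size must be a positive odd integer, got ",
         gcn_kernel_size)
  }
  if (num_classes < 2L) stop("num_classes must be >= 2")
  if (base_channels < 1L) stop("base_channels must be >= 1")
  if (encoder %in% c("googlenet") && base_channels %% 2L != 0L) {
    stop("base_channels must be even for the googlenet encoder")
  }
  if (length(input_size) != 2L || any(input_size %% 32L != 0L)) {
    stop("input_size must be two dimensions, each divisible by 32")
  }
  structure(
    list(encoder = encoder, use_gcn = isTRUE(use_gcn),
         gcn_kernel_size = gcn_kernel_size, gcn_variant = gcn_variant,
         use_br = isTRUE(use_br), num_classes = as.integer(num_classes),
         base_channels = as.integer(base_channels),
         in_channels = as.integer(in_channels),
         input_size = as.integer(input_size),
         upsample = upsample, fusion = fusion, check_input = TRUE),
    class = "model_config"
  )
}

config_label <- function(config) {
  enc <- switch(config$encoder, googlenet = "GoogLeNet", vgg = "VGGNet",
                seresnet = "SEResNet", plain_unet = "Unet")
  mid <- if (config$use_gcn) {
    if (config$gcn_variant == "separable") "_GCND" else "_GCN"
  } else ""
  paste0(enc, mid, if (config$encoder == "plain_unet") "" else "_Unet")
}

# ---- encoders --------------------------------------------------------------

# Shared stride-4 stem: two conv-BN-ReLU + max-pool groups, 3 -> 2b channels.
add_stem4 <- function(gb, base, in_ch) {
  c1 <- nx_cbr(gb, "stem1", ".input", 3, in_ch, base)
  p1 <- nx_pool2(gb, "stem1_pool", c1)
  c2 <- nx_cbr(gb, "stem2", p1, 3, base, 2 * base)
  nx_pool2(gb, "stem2_pool", c2)
}

# Builds the four encoder stages; returns stage output node names, their
# channel widths and strides (plus the stride-1 stem for plain_unet, used
# by the classic decoder).
add_encoder <- function(gb, name, base, in_ch) {
  b <- base
  if (name == "googlenet") {
    stem <- add_stem4(gb, b, in_ch)
    ch <- c(4, 8, 16, 16) * b
    s1 <- add_inception(gb, "enc1", stem, 2 * b, inception_channels(ch[1]))
    s2 <- add_inception(gb, "enc2", nx_pool2(gb, "enc2_pool", s1),
                        ch[1], inception_channels(ch[2]))
    s3 <- add_inception(gb, "enc3", nx_pool2(gb, "enc3_pool", s2),
                        ch[2], inception_channels(ch[3]))
    s4 <- add_inception(gb, "enc4", nx_pool2(gb, "enc4_pool", s3),
                        ch[3], inception_channels(ch[4]))
    list(stages = c(s1, s2, s3, s4), channels = ch,
         strides = c(4L, 8L, 16L, 32L))
  } else if (name == "vgg") {
    stem <- add_stem4(gb, b, in_ch)
    ch <- c(4, 8, 16, 16) * b
    pair <- function(prefix, input, cin, cout) {
      a <- nx_cbr(gb, paste0(prefix, "a"), input, 3, cin, cout)
      nx_cbr(gb, paste0(prefix, "b"), a, 3, cout, cout)
    }
    s1 <- pair("enc1", stem, 2 * b, ch[1])
    s2 <- pair("enc2", nx_pool2(gb, "enc2_pool", s1), ch[1], ch[2])
    s3 <- pair("enc3", nx_pool2(gb, "enc3_pool", s2), ch[2], ch[3])
    s4 <- pair("enc4", nx_pool2(gb, "enc4_pool", s3), ch[3], ch[4])
    list(stages = c(s1, s2, s3, s4), channels = ch,
         strides = c(4L, 8L, 16L, 32L))
  } else if (name == "seresnet") {
    stem <- add_stem4(gb, b, in_ch)
    ch <- c(4, 8, 16, 16) * b
    s1 <- add_residual(gb, "enc1", stem, 2 * b, ch[1], use_se = TRUE)
    s2 <- add_residual(gb, "enc2", nx_pool2(gb, "enc2_pool", s1),
                       ch[1], ch[2], use_se = TRUE)
    s3 <- add_residual(gb, "enc3", nx_pool2(gb, "enc3_pool", s2),
                       ch[2], ch[3], use_se = TRUE)
    s4 <- add_residual(gb, "enc4", nx_pool2(gb, "enc4_pool", s3),
                       ch[3], ch[4], use_se = TRUE)
    list(stages = c(s1, s2, s3, s4), channels = ch,
         strides = c(4L, 8L, 16L, 32L))
  } else if (name == "plain_unet") {
    dbl <- function(prefix, input, cin, cout) {
      a <- nx_cbr(gb, paste0(prefix, "a"), input, 3, cin, cout)
      nx_cbr(gb, paste0(prefix, "b"), a, 3, cout, cout)
    }
    stem <- dbl("stem", ".input", in_ch, b)
    ch <- c(2, 4, 8, 16) * b
    s1 <- dbl("enc1", nx_pool2(gb, "enc1_pool", stem), b, ch[1])
    s2 <- dbl("enc2", nx_pool2(gb, "enc2_pool", s1), ch[1], ch[2])
    s3 <- dbl("enc3", nx_pool2(gb, "enc3_pool", s2), ch[2], ch[3])
    s4 <- dbl("enc4", nx_pool2(gb, "enc4_pool", s3), ch[3], ch[4])
    list(stages = c(s1, s2, s3, s4), channels = ch,
         strides = c(2L, 4L, 8L, 16L), stem = stem, stem_channels = b)
  } else {
    stop("unknown encoder: ", name)
  }
}

#' Build one of the encoder backbones on its own
#'
#' Four feature stages; googlenet/vgg/seresnet run at strides 4/8/16/32
#' (after a stride-4 stem), plain_unet at strides 2/4/8/16. Mostly useful
#' for inspection; [build_improved_unet()] embeds the same code.
#'
#' @param name encoder name, see [model_config()].
#' @param base_channels width multiplier.
#' @param in_channels input channels.
#' @param seed integer seed for weight initialization.
#' @return a list with `model` (a `fissure_model` whose output is the
#'   deepest stage), `stages` (node names of the four stage outputs),
#'   `channels` and `strides`.
#' @export
build_encoder <- function(name, base_channels = 8L, in_channels = 3L,
                          seed = 0L) {
  withr::with_seed(derive_seed(seed, "encoder"), {
    gb <- graph_builder()
    enc <- add_encoder(gb, name, base_channels, in_channels)
    model <- finish_model(block_config("encoder", encoder = name,
                                       in_channels = in_channels),
                          gb, enc$stages[4])
    c(list(model = model), enc)
  })
}

# ---- assembly --------------------------------------------------------------

add_up2 <- function(gb, name, input, channels, kind) {
  if (kind == "deconv") {
    w <- he_init(c(2, 2, channels, channels), 4 * channels)
    gb$add(name, "upconv", input,
           params = list(w = w, b = numeric(channels)))
  } else {
    gb$add(name, "upsample2", input)
  }
}

#' Build the improved U-Net (or a plain U-Net) from a configuration
#'
#' In the improved assembly every encoder stage output passes through a GCN
#' module mapping it to `num_classes` score channels (a 1x1 projection when
#' `use_gcn` is off), followed by a BR block when `use_br` is on. Decoding
#' starts from the deepest stage: upsample x2, fuse with the next-shallower
#' skip output (elementwise addition by default), apply BR, and repeat;
#' after the shallowest stage the score map is upsampled step by step (BR
#' after each x2 step) back to input resolution. The output is a
#' `num_classes x H x W` score map.
#'
#' With `encoder = "plain_unet"` and both modules off, the function instead
#' builds the classic U-Net: concatenation skips and double-conv decoder
#' blocks, with a final 1x1 classifier.
#'
#' @param config a [model_config()].
#' @param seed integer seed; two builds with the same seed have identical
#'   initial weights.
#' @return a `fissure_model`.
#' @export
build_improved_unet <- function(config, seed = 0L) {
  stopifnot(inherits(config, "model_config"))
  withr::with_seed(derive_seed(seed, "model-init"), {
    if (config$encoder == "plain_unet" && !config$use_gcn && !config$use_br) {
      build_classic_unet(config)
    } else {
      build_gcn_unet(config)
    }
  })
}

build_gcn_unet <- function(config) {
  gb <- graph_builder()
  enc <- add_encoder(gb, config$encoder, config$base_channels,
                     config$in_channels)
  ncls <- config$num_classes
  skips <- character(4)
  for (i in 1:4) {
    s <- if (config$use_gcn) {
      add_gcn(gb, paste0("skip", i), enc$stages[i], enc$channels[i], ncls,
              config$gcn_kernel_size, config$gcn_variant)
    } else {
      nx_conv(gb, paste0("skip", i, "_proj"), enc$stages[i], 1, 1,
              enc$channels[i], ncls)
    }
    if (config$use_br) s <- add_br(gb, paste0("skip", i, "_br"), s, ncls)
    skips[i] <- s
  }
  d <- skips[4]
  for (i in 3:1) {
    u <- add_up2(gb, paste0("up", i), d, ncls, config$upsample)
    f <- if (config$fusion == "add") {
      gb$add(paste0("fuse", i), "add", c(u, skips[i]))
    } else {
      cc <- gb$add(paste0("fuse", i, "_cat"), "concat", c(u, skips[i]))
      nx_conv(gb, paste0("fuse", i, "_proj"), cc, 1, 1, 2 * ncls, ncls)
    }
    if (config$use_br) f <- add_br(gb, paste0("fuse", i, "_br"), f, ncls)
    d <- f
  }
  s <- enc$strides[1]
  j <- 0
  while (s > 1) {
    j <- j + 1
    d <- add_up2(gb, paste0("final_up", j), d, ncls, config$upsample)
    if (config$use_br) d <- add_br(gb, paste0("final_br", j), d, ncls)
    s <- s / 2
  }
  finish_model(config, gb, d)
}

build_classic_unet <- function(config) {
  gb <- graph_builder()
  enc <- add_encoder(gb, "plain_unet", config$base_channels,
                     config$in_channels)
  b <- config$base_channels
  dbl <- function(prefix, input, cin, cout) {
    a <- nx_cbr(gb, paste0(prefix, "a"), input, 3, cin, cout)
    nx_cbr(gb, paste0(prefix, "b"), a, 3, cout, cout)
  }
  skip_nodes <- c(enc$stem, enc$stages[1:3])
  skip_ch <- c(enc$stem_channels, enc$channels[1:3])
  d <- enc$stages[4]
  dch <- enc$channels[4]
  for (i in 4:1) {
    up_ch <- skip_ch[i]
    w <- he_init(c(2, 2, dch, up_ch), 4 * dch)
    u <- gb$add(paste0("dec", i, "_up"), "upconv", d,
                params = list(w = w, b = numeric(up_ch)))
    cc <- gb$add(paste0("dec", i, "_cat"), "concat", c(u, skip_nodes[i]))
    d <- dbl(paste0("dec", i), cc, 2 * up_ch, up_ch)
    dch <- up_ch
  }
  out <- nx_conv(gb, "classifier", d, 1, 1, dch, config$num_classes)
  finish_model(config, gb, out)
}

# ---- prediction ------------------------------------------------------------

# Fixed photometric normalization applied to every network input:
# 8-bit intensities scaled to [0,1], then standardized.
normalize_image <- function(img) (img / 255 - 0.5) / 0.25

#' Per-pixel argmax over class score maps
#'
#' Ties are broken toward the lower class index, so exactly tied scores
#' yield background.
#'
#' @param scores `(H, W, C)` score array.
#' @return an `H x W` integer matrix of class labels in `0..C-1`.
#' @export
argmax_scores <- function(scores) {
  d <- dim(scores)
  stopifnot(length(d) == 3)
  best <- scores[, , 1]
  pred <- matrix(0L, d[1], d[2])
  if (d[3] > 1) {
    for (ci in 2:d[3]) {
      sc <- scores[, , ci]
      m <- sc > best
      pred[m] <- ci - 1L
      best[m] <- sc[m]
    }
  }
  pred
}

#' Predict a label mask for one image
#'
#' The image is resized (bilinear) to the model's `input_size`, normalized,
#' run through the network in inference mode, and converted to per-pixel
#' class labels by [argmax_scores()]. The mask is returned at `input_size`.
#'
#' @param object a `fissure_model` built by [build_improved_unet()].
#' @param image an `(H, W, C)` array of 8-bit intensities (0-255), or a
#'   sample list with an `image` field. Grayscale matrices are promoted to
#'   the model's channel count.
#' @param ... unused.
#' @return an integer label mask at the model's input size.
#' @export
predict.fissure_model <- function(object, image, ...) {
  if (is.list(image) && !is.null(image$image)) image <- image$image
  if (is.matrix(image)) {
    image <- array(rep(image, object$config$in_channels),
                   c(dim(image), object$config$in_channels))
  }
  size <- object$config$input_size
  x <- resize_bilinear_cpp(as4d(image), size[1], size[2])
  scores <- model_forward(object, normalize_image(x), training = FALSE)
  argmax_scores(array(scores, dim(scores)[1:3]))
}

# ---- checkpoints -----------------------------------------------------------

#' Save a self-describing model checkpoint
#'
#' Stores the configuration record together with all weights and running
#' statistics, so [load_checkpoint()] can rebuild the model without any
#' other context.
#'
#' @param model a `fissure_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(format = "fissureseg-checkpoint-1",
               config = unclass(model$config),
               weights = model_weights(model)),
          path, version = 2)
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint()]
#'
#' @param path checkpoint file.
#' @return a `fissure_model` with the stored weights.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "fissureseg-checkpoint-1")) {
    stop("not a fissureseg checkpoint: ", path)
  }
  cfg <- do.call(model_config, ck$config[setdiff(names(ck$config),
                                                 "check_input")])
  model <- build_improved_unet(cfg, seed = 0L)
  set_model_weights(model, ck$weights)
  model
}
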