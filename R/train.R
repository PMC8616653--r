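# Loss, learning-rate schedule and the training loop.

#' Training configuration
#'
#' Shipped defaults follow the full-scale regime: adaptive-moment (Adam)
#' optimization with first-moment coefficient 0.9, minibatches of 4 images,
#' initial learning rate 1e-5, inputs at 256 x 256, and a learning rate
#' that decays exponentially per epoch. Tests and the synthetic benchmark
#' use the desk-scale profile ([desk_profile()]): 64 x 64 inputs and
#' lr 1e-3, appropriate when the encoder is trained from scratch.
#'
#' @param learning_rate initial learning rate (> 0).
#' @param batch_size minibatch size (>= 1).
#' @param beta1 first-moment decay of the adaptive-moment optimizer
#'   ("momentum"); the second-moment decay is fixed at 0.999.
#' @param input_size `(H, W)` images are resized to before training.
#' @param epochs number of epochs.
#' @param lr_decay per-epoch multiplicative decay factor in (0, 1].
#' @param seed integer seed covering data order and any other randomness of
#'   the loop.
#' @param class_weights optional per-class positive weights for the loss;
#'   `NULL` for unweighted.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-5, batch_size = 4L, beta1 = 0.9,
                         input_size = c(256L, 256L), epochs = 10L,
                         lr_decay = 0.98, seed = 1L, class_weights = NULL) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (lr_decay <= 0 || lr_decay > 1) stop("lr_decay must be in (0, 1]")
  if (epochs < 1) stop("epochs must be >= 1")
  if (!is.null(class_weights) && any(class_weights <= 0)) {
    stop("class_weights must be positive")
  }
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), beta1 = beta1,
                 input_size = as.integer(input_size),
                 epochs = as.integer(epochs), lr_decay = lr_decay,
                 seed = as.integer(seed), class_weights = class_weights),
            class = "train_config")
}

#' Desk-scale model and training profile for the synthetic benchmark
#'
#' A small improved U-Net (googlenet encoder at base width 8, dense GCN
#' with k = 7, BR on) and a from-scratch training regime at 64 x 64:
#' lr 1e-3, batch 4, 20 epochs, and capped inverse-frequency class weights
#' (1, 10) for the heavily imbalanced thin-structure foreground.
#'
#' @param epochs number of epochs (default 20).
#' @return list with `model` ([model_config()]) and `train`
#'   ([train_config()]).
#' @export
desk_profile <- function(epochs = 20L) {
  list(
    model = model_config(encoder = "googlenet", use_gcn = TRUE,
                         gcn_kernel_size = 7L, gcn_variant = "dense",
                         use_br = TRUE, num_classes = 2L, base_channels = 8L,
                         input_size = c(64L, 64L)),
    train = train_config(learning_rate = 1e-3, batch_size = 4L, beta1 = 0.9,
                         input_size = c(64L, 64L), epochs = epochs,
                         lr_decay = 0.98, seed = 1L,
                         class_weights = c(1, 10))
  )
}

#' Learning rate at a given epoch
#'
#' Exponential schedule: `learning_rate * lr_decay^epoch`, non-increasing
#' in the epoch.
#'
#' @param config a [train_config()].
#' @param epoch epoch index (0-based; epoch 0 is the initial rate).
#' @return the learning rate.
#' @export
lr_at_epoch <- function(config, epoch) {
  stopifnot(epoch >= 0)
  config$learning_rate * config$lr_decay^epoch
}

# Softmax cross-entropy over a score map, with optional class weights.
# Returns the (weighted mean) loss and, when requested, the gradient with
# respect to the scores.
softmax_ce <- function(scores, masks, class_weights = NULL,
                       want_grad = FALSE) {
  s4 <- as4d(scores)
  d <- dim(s4)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  y <- as.integer(masks)
  if (length(y) != H * W * N) {
    stop("mask size does not match the score map")
  }
  if (any(y < 0L) || any(y >= C)) {
    stop("mask labels must lie in [0, ", C, ")")
  }
  sm <- aperm(s4, c(1, 2, 4, 3))
  dim(sm) <- c(H * W * N, C)
  mx <- sm[, 1]
  for (ci in seq_len(C - 1)) mx <- pmax(mx, sm[, ci + 1])
  e <- exp(sm - mx)
  P <- e / rowSums(e)
  iy <- cbind(seq_len(H * W * N), y + 1L)
  wv <- if (is.null(class_weights)) rep(1, H * W * N) else class_weights[y + 1L]
  loss <- sum(-log(pmax(P[iy], 1e-300)) * wv) / sum(wv)
  if (!want_grad) return(list(loss = loss))
  G <- P
  G[iy] <- G[iy] - 1
  G <- G * (wv / sum(wv))
  dim(G) <- c(H, W, N, C)
  list(loss = loss, grad = aperm(G, c(1, 2, 4, 3)))
}

#' Mean per-pixel cross-entropy of a score map against a label mask
#'
#' The mean over pixels of the negative log softmax probability of the true
#' class, optionally class-weighted (weighted mean). Uniform two-class
#' scores give `log(2)`.
#'
#' @param scores `(C, classes last)` — an `(H, W, C)` or `(H, W, C, N)`
#'   score array.
#' @param mask integer labels in `0..C-1`, matching the spatial (and batch)
#'   dimensions.
#' @param class_weights optional per-class positive weights.
#' @return nonnegative scalar loss.
#' @export
pixel_loss <- function(scores, mask, class_weights = NULL) {
  softmax_ce(scores, mask, class_weights)$loss
}

# Stack samples into network-ready arrays at a fixed size.
prepare_arrays <- function(samples, size, in_channels) {
  n <- length(samples)
  X <- array(0, c(size[1], size[2], in_channels, n))
  Y <- array(0L, c(size[1], size[2], n))
  has_mask <- TRUE
  for (i in seq_len(n)) {
    s <- resize_sample(samples[[i]], size)
    X[, , , i] <- normalize_image(s$image)
    if (is.null(s$mask)) has_mask <- FALSE else Y[, , i] <- s$mask
  }
  list(X = X, Y = if (has_mask) Y, n = n)
}

# Inference-mode metrics over prepared arrays: one accumulated confusion
# matrix, per-image mean loss.
eval_arrays <- function(model, X, Y, C, class_weights = NULL,
                        batch = 8L) {
  n <- dim(X)[4]
  cm <- matrix(0, C, C)
  losses <- numeric(n)
  for (start in seq(1, n, by = batch)) {
    idx <- start:min(n, start + batch - 1)
    out <- nn_forward(model, X[, , , idx, drop = FALSE], training = FALSE)$out
    for (k in seq_along(idx)) {
      i <- idx[k]
      sc <- out[, , , k, drop = FALSE]
      losses[i] <- softmax_ce(sc, Y[, , i], class_weights)$loss
      pred <- argmax_scores(array(sc, dim(sc)[1:3]))
      cm <- cm + confusion(pred, Y[, , i], C)
    }
  }
  list(cm = cm, mean_loss = mean(losses))
}

#' Train a model
#'
#' Minibatch training with the adaptive-moment optimizer (first-moment
#' coefficient `config$beta1`, second 0.999) and the exponential
#' [lr_at_epoch()] schedule. Samples are resized to `config$input_size`
#' (bilinear for images, nearest for masks), scaled to `[0, 1]` and
#' standardized by fixed constants. Fully seeded: data order and weight
#' updates are reproducible. When a validation set is given, the weights
#' with the best validation MIoU are retained.
#'
#' @param model a `fissure_model` (modified in place and returned).
#' @param train_samples nonempty list of labeled samples.
#' @param val_samples optional validation samples.
#' @param config a [train_config()].
#' @param verbose print a line per epoch.
#' @return list with `model` and `history` (a data.frame with one row per
#'   epoch: train loss, validation loss/PA/MIoU, learning rate).
#' @export
train_model <- function(model, train_samples, val_samples = NULL, config,
                        verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  if (!length(train_samples)) stop("train set must be nonempty")
  for (s in train_samples) {
    if (is.null(s$mask)) stop("training samples must be labeled")
  }
  C <- model$config$num_classes
  tr <- prepare_arrays(train_samples, config$input_size,
                       model$config$in_channels)
  va <- if (length(val_samples)) {
    prepare_arrays(val_samples, config$input_size, model$config$in_channels)
  }
  cw <- config$class_weights
  hist_rows <- vector("list", config$epochs)
  best_miou <- -Inf
  best_weights <- NULL
  t <- 0L
  withr::with_seed(derive_seed(config$seed, "train-loop"), {
    for (epoch in seq_len(config$epochs)) {
      lr <- lr_at_epoch(config, epoch - 1)
      ord <- sample.int(tr$n)
      ep_loss <- 0
      for (start in seq(1, tr$n, by = config$batch_size)) {
        idx <- ord[start:min(tr$n, start + config$batch_size - 1)]
        fw <- nn_forward(model, tr$X[, , , idx, drop = FALSE],
                         training = TRUE)
        l <- softmax_ce(fw$out, tr$Y[, , idx, drop = FALSE], cw,
                        want_grad = TRUE)
        nn_backward(model, l$grad)
        t <- t + 1L
        adam_step(model, lr, beta1 = config$beta1, t = t)
        ep_loss <- ep_loss + l$loss * length(idx)
      }
      row <- data.frame(epoch = epoch, lr = lr,
                        train_loss = ep_loss / tr$n,
                        val_loss = NA_real_, val_pa = NA_real_,
                        val_miou = NA_real_)
      if (!is.null(va)) {
        ev <- eval_arrays(model, va$X, va$Y, C, cw)
        row$val_loss <- ev$mean_loss
        row$val_pa <- pixel_accuracy(ev$cm)
        row$val_miou <- miou(ev$cm)
        if (row$val_miou > best_miou) {
          best_miou <- row$val_miou
          best_weights <- model_weights(model)
        }
      }
      hist_rows[[epoch]] <- row
      if (verbose) {
        message(sprintf(
          "epoch %3d  lr %.2e  train %.4f  val %.4f  PA %.4f  MIoU %.4f",
          epoch, lr, row$train_loss, row$val_loss, row$val_pa, row$val_miou))
      }
    }
  })
  if (!is.null(best_weights)) set_model_weights(model, best_weights)
  list(model = model, history = do.call(rbind, hist_rows))
}
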