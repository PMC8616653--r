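# Network blocks and the improved U-Net assembly.

zero_all_conv_weights <- function(model) {
  for (nm in model$order) {
    node <- model$nodes[[nm]]
    if (node$op %in% c("conv", "dwconv", "upconv")) {
      node$params$w <- node$params$w * 0
      if (!is.null(node$params$b)) node$params$b <- node$params$b * 0
    }
  }
  model
}

test_that("inception block has the contracted shape and parameter count", {
  blk <- new_inception_block(32, branch_channels = c(8, 16, 4, 4), seed = 1)
  x <- array(rnorm(16 * 16 * 32), c(16, 16, 32))
  y <- model_forward(blk, x)
  expect_equal(dim(y), c(16, 16, 32))

  # parameter count from the closed-form conv/bn formulas
  cbr <- function(k, cin, cout) conv_params(k, k, cin, cout, bias = FALSE) +
    2 * cout
  want <- cbr(1, 32, 8) +                      # 1x1 branch
    cbr(1, 32, 8) + cbr(3, 8, 16) +            # 1x1 -> 3x3
    cbr(1, 32, 4) + cbr(5, 4, 4) +             # 1x1 -> 5x5 (reduce max(4, 2))
    cbr(1, 32, 4)                              # pool -> 1x1
  expect_equal(count_params(blk), want)
  expect_equal(sum(layer_specs(blk)$n_params), count_params(blk))

  # deterministic rebuild
  blk2 <- new_inception_block(32, branch_channels = c(8, 16, 4, 4), seed = 1)
  expect_identical(model_weights(blk2), model_weights(blk))

  # all conv weights zero and BN offsets zero => output all zeros
  zero_all_conv_weights(blk)
  expect_equal(max(abs(model_forward(blk, x))), 0)
})

test_that("residual and squeeze-excite blocks have their identity modes", {
  blk <- new_residual_block(8, 8, seed = 2)
  x <- array(abs(rnorm(6 * 6 * 8)) + 0.1, c(6, 6, 8))
  # zero the residual branch: output = relu(shortcut) = x for positive x
  zero_all_conv_weights(blk)
  expect_equal(model_forward(blk, x), x, tolerance = 1e-12)

  # SE gate forced to 1 (large positive fc2 bias) => identity
  se <- new_se_block(4, seed = 3)
  se$nodes[["se_fc2"]]$params$w <- se$nodes[["se_fc2"]]$params$w * 0
  se$nodes[["se_fc2"]]$params$b <- rep(1e6, 4)
  xs <- array(rnorm(5 * 5 * 4), c(5, 5, 4))
  expect_equal(model_forward(se, xs), xs, tolerance = 1e-9)
  # gate forced to 0 => all-zero output
  se$nodes[["se_fc2"]]$params$b <- rep(-1e6, 4)
  expect_equal(max(abs(model_forward(se, xs))), 0, tolerance = 1e-12)
})

test_that("GCN impulse responses stay inside k x k and match a dense oracle", {
  for (variant in c("dense", "separable")) {
    for (k in c(3L, 7L, 11L)) {
      blk <- new_gcn_block(3, k = k, out_channels = 2, variant = variant,
                           seed = k)
      H <- 2 * k + 5
      x <- array(0, c(H, H, 3))
      x[(H + 1) / 2, (H + 1) / 2, 2] <- 1
      y <- model_forward(blk, x)
      support <- which(apply(abs(y) > 1e-12, c(1, 2), any), arr.ind = TRUE)
      ctr <- (H + 1) / 2
      expect_true(all(abs(support[, 1] - ctr) <= (k - 1) / 2),
                  info = paste(variant, k))
      expect_true(all(abs(support[, 2] - ctr) <= (k - 1) / 2))

      # dense-convolution oracle: compose the branch convolutions naively
      nd <- blk$nodes
      pad <- as.integer((k - 1) / 2)
      want <- if (variant == "dense") {
        a <- naive_conv(x, nd[["gcn_a1"]]$params$w, padh = pad, padw = 0)
        a <- naive_conv(a, nd[["gcn_a2"]]$params$w, padh = 0, padw = pad)
        b <- naive_conv(x, nd[["gcn_b1"]]$params$w, padh = 0, padw = pad)
        b <- naive_conv(b, nd[["gcn_b2"]]$params$w, padh = pad, padw = 0)
        a + b
      } else {
        pw <- function(z, node) naive_conv(z, node$params$w)
        a <- pw(naive_dwconv(x, nd[["gcn_a1_dw"]]$params$w, pad, 0),
                nd[["gcn_a1_pw"]])
        a <- pw(naive_dwconv(a, nd[["gcn_a2_dw"]]$params$w, 0, pad),
                nd[["gcn_a2_pw"]])
        b <- pw(naive_dwconv(x, nd[["gcn_b1_dw"]]$params$w, 0, pad),
                nd[["gcn_b1_pw"]])
        b <- pw(naive_dwconv(b, nd[["gcn_b2_dw"]]$params$w, pad, 0),
                nd[["gcn_b2_pw"]])
        a + b
      }
      expect_equal(y, want, tolerance = 1e-10)
    }
  }
  expect_error(new_gcn_block(3, k = 4), "odd")
})

test_that("k = 1 GCN degenerates to a sum of 1x1 convolution paths", {
  blk <- new_gcn_block(5, k = 1L, out_channels = 3, variant = "dense",
                       seed = 4)
  x <- array(rnorm(4 * 4 * 5), c(4, 4, 5))
  nd <- blk$nodes
  w_a <- nd[["gcn_a1"]]$params$w
  w_a2 <- nd[["gcn_a2"]]$params$w
  w_b <- nd[["gcn_b1"]]$params$w
  w_b2 <- nd[["gcn_b2"]]$params$w
  want <- naive_conv(naive_conv(x, w_a), w_a2) +
    naive_conv(naive_conv(x, w_b), w_b2)
  expect_equal(model_forward(blk, x), want, tolerance = 1e-12)

  # with branch 2 zeroed it is a single composed 1x1 path
  blk$nodes[["gcn_b1"]]$params$w <- w_b * 0
  expect_equal(model_forward(blk, x),
               naive_conv(naive_conv(x, w_a), w_a2), tolerance = 1e-12)
})

test_that("GCN parameter economy: linear in k, beating the dense kernel", {
  # closed-form counts and instantiated counts agree
  expect_equal(gcn_params(7, 64, 2, "dense"), 1848L)
  expect_equal(conv_params(7, 7, 64, 2, bias = FALSE), 6272L)
  blk <- new_gcn_block(64, k = 7, out_channels = 2, variant = "dense")
  expect_equal(count_params(blk), 1848L)
  blk_sep <- new_gcn_block(64, k = 7, out_channels = 2,
                           variant = "separable")
  expect_equal(count_params(blk_sep), gcn_params(7, 64, 2, "separable"))

  # dense GCN grows linearly in k; the full k x k conv quadratically;
  # GCN is strictly cheaper whenever k > 4
  ks <- c(3, 5, 7, 9, 11)
  gcn_counts <- vapply(ks, gcn_params, numeric(1), c_in = 64, c_out = 2)
  diffs <- diff(gcn_counts)
  expect_true(all(diffs == diffs[1]))        # linear growth
  full_counts <- vapply(ks, function(k) conv_params(k, k, 64, 2, FALSE),
                        numeric(1))
  expect_true(all(diff(diff(full_counts)) > 0))  # strictly convex
  for (k in c(5, 7, 9, 11)) {
    expect_lt(gcn_params(k, 64, 2), conv_params(k, k, 64, 2, FALSE))
  }
})

test_that("BR block is the exact identity at init and locally supported", {
  blk <- new_br_block(2, seed = 5)
  x <- array(rnorm(12 * 9 * 2), c(12, 9, 2))
  expect_identical(model_forward(blk, x), x)  # bit-exact: second conv is 0

  # with a random second conv, (out - x) support is the 5x5 dilation of an
  # impulse (two stacked 3x3 convolutions)
  withr::with_seed(6, {
    blk$nodes[["br_c2"]]$params$w <- array(rnorm(3 * 3 * 2 * 2), c(3, 3, 2, 2))
  })
  H <- 11
  imp <- array(0, c(H, H, 2))
  imp[6, 6, 1] <- 1
  delta <- model_forward(blk, imp) - imp
  support <- which(apply(abs(delta) > 1e-12, c(1, 2), any), arr.ind = TRUE)
  expect_true(all(abs(support - 6) <= 2))
})

test_that("encoders expose four stages at the contracted strides", {
  for (enc in c("googlenet", "vgg", "seresnet")) {
    built <- build_encoder(enc, base_channels = 8, seed = 1)
    expect_equal(built$strides, c(4L, 8L, 16L, 32L))
    x <- array(rnorm(64 * 64 * 3), c(64, 64, 3, 1))
    fw <- fissureseg:::nn_forward(built$model, x)
    for (i in 1:4) {
      stage_out <- get(built$stages[i], envir = fw$acts)
      expect_equal(dim(stage_out)[1:3],
                   c(64 / built$strides[i], 64 / built$strides[i],
                     built$channels[i]),
                   info = paste(enc, i))
    }
  }
  built <- build_encoder("plain_unet", base_channels = 4, seed = 1)
  expect_equal(built$strides, c(2L, 4L, 8L, 16L))
  expect_error(build_encoder("alexnet"), "unknown encoder")

  # determinism of initialization
  b1 <- build_encoder("googlenet", base_channels = 8, seed = 7)
  b2 <- build_encoder("googlenet", base_channels = 8, seed = 7)
  expect_identical(model_weights(b1$model), model_weights(b2$model))
})

test_that("improved U-Net maps images to full-resolution score maps", {
  cfg <- model_config(encoder = "googlenet", gcn_kernel_size = 7,
                      use_br = TRUE, base_channels = 8,
                      input_size = c(64L, 64L))
  m <- build_improved_unet(cfg, seed = 1)
  x <- array(rnorm(64 * 64 * 3), c(64, 64, 3))
  y <- model_forward(m, x)
  expect_equal(dim(y), c(64, 64, 2))

  # inference determinism
  expect_identical(model_forward(m, x), y)

  # input-contract errors
  expect_error(model_forward(m, array(0, c(48, 48, 3))), "divisible by 32")
  expect_error(model_forward(m, array(0, c(64, 64, 4))), "channels")

  # every ablation variant builds and preserves shape
  for (enc in c("vgg", "seresnet", "plain_unet")) {
    for (gcn in c(TRUE, FALSE)) {
      cc <- model_config(encoder = enc, use_gcn = gcn, use_br = gcn,
                         base_channels = 8, input_size = c(64L, 64L))
      mm <- build_improved_unet(cc, seed = 2)
      expect_equal(dim(model_forward(mm, x)), c(64, 64, 2),
                   info = paste(enc, gcn))
    }
  }

  # separable variant and concat fusion build too
  cc <- model_config(encoder = "googlenet", gcn_variant = "separable",
                     fusion = "concat", base_channels = 8,
                     input_size = c(64L, 64L))
  expect_equal(dim(model_forward(build_improved_unet(cc, 3), x)),
               c(64, 64, 2))
})

test_that("plain U-Net with modules off matches the classic parameter count", {
  b <- 4L
  cfg <- model_config(encoder = "plain_unet", use_gcn = FALSE,
                      use_br = FALSE, base_channels = b, in_channels = 1L,
                      input_size = c(64L, 64L))
  m <- build_improved_unet(cfg, seed = 1)
  x1 <- array(rnorm(64 * 64), c(64, 64, 1))
  expect_equal(dim(model_forward(m, x1)), c(64, 64, 2))

  # independent count of the classic U-Net at this width:
  # conv-BN-ReLU pairs in stem/stages/decoders, 2x2 transposed convs with
  # bias, and a biased 1x1 classifier
  cbr <- function(k, cin, cout) k * k * cin * cout + 2 * cout
  dbl <- function(cin, cout) cbr(3, cin, cout) + cbr(3, cout, cout)
  up <- function(cin, cout) 2 * 2 * cin * cout + cout
  want <- dbl(1, b) +
    dbl(b, 2 * b) + dbl(2 * b, 4 * b) + dbl(4 * b, 8 * b) +
    dbl(8 * b, 16 * b) +
    up(16 * b, 8 * b) + dbl(16 * b, 8 * b) +
    up(8 * b, 4 * b) + dbl(8 * b, 4 * b) +
    up(4 * b, 2 * b) + dbl(4 * b, 2 * b) +
    up(2 * b, b) + dbl(2 * b, b) +
    (b * 2 + 2)
  expect_equal(count_params(m), want)
})

test_that("prediction is an argmax with background-favoring ties", {
  scores <- array(0, c(3, 3, 2))
  scores[, , 2] <- 1
  expect_equal(argmax_scores(scores), matrix(1L, 3, 3))
  # exact ties go to class 0
  expect_equal(argmax_scores(array(0.5, c(3, 3, 2))), matrix(0L, 3, 3))

  withr::with_seed(41, {
    for (case in 1:20) {
      sc <- array(rnorm(8 * 8 * 2), c(2, 8, 8))
      sc <- aperm(sc, c(2, 3, 1))
      want <- matrix(0L, 8, 8)
      for (h in 1:8) for (w in 1:8) {
        want[h, w] <- which.max(sc[h, w, ]) - 1L  # first max = lowest class
      }
      expect_equal(argmax_scores(sc), want)
    }
  })
})

test_that("a point-symmetric fixed-weight model commutes with 180-degree rotation", {
  # rot180 equivariance of a convolution requires the kernel itself to be
  # point-symmetric (w(d) = w(-d)); with symmetric padding, symmetric
  # kernels and non-learnable bilinear upsampling the whole assembly
  # commutes with 180-degree rotation.
  cfg <- model_config(encoder = "googlenet", base_channels = 8,
                      upsample = "bilinear", input_size = c(64L, 64L))
  m <- build_improved_unet(cfg, seed = 9)
  for (nm in m$order) {
    node <- m$nodes[[nm]]
    if (node$op %in% c("conv", "dwconv")) {
      w <- node$params$w
      d <- dim(w)
      flipped <- if (length(d) == 4) {
        w[d[1]:1, d[2]:1, , , drop = FALSE]
      } else {
        w[d[1]:1, d[2]:1, , drop = FALSE]
      }
      node$params$w <- (w + array(flipped, d)) / 2
    }
  }
  withr::with_seed(10, {
    x <- array(rnorm(64 * 64 * 3), c(64, 64, 3))
  })
  rot <- function(a) {
    out <- a
    for (c in seq_len(dim(a)[3])) out[, , c] <- a[64:1, 64:1, c]
    out
  }
  y <- model_forward(m, x)
  y_rot <- model_forward(m, rot(x))
  expect_equal(y_rot, rot(y), tolerance = 1e-8)
})

test_that("checkpoints round trip config and weights", {
  cfg <- model_config(encoder = "googlenet", base_channels = 8,
                      input_size = c(64L, 64L))
  m <- build_improved_unet(cfg, seed = 4)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(model_weights(m2), model_weights(m))
  x <- array(rnorm(64 * 64 * 3), c(64, 64, 3))
  expect_identical(model_forward(m2, x), model_forward(m, x))
})
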