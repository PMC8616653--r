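test_that("confusion matrices count, accumulate and validate", {
  m <- matrix(c(0L, 1L, 0L, 1L), 2, 2)
  expect_equal(confusion(m, m, 2), diag(c(2, 2)))

  # 4x4 fixture: truth has 4 fissure pixels, prediction all background
  truth <- matrix(0L, 4, 4)
  truth[1:2, 1:2] <- 1L
  pred <- matrix(0L, 4, 4)
  cm <- confusion(pred, truth, 2)
  expect_equal(cm, matrix(c(12, 4, 0, 0), 2, 2))

  # additivity: accumulation equals the confusion of concatenated images
  withr::with_seed(61, {
    a_p <- matrix(rbinom(16, 1, 0.5), 4, 4)
    a_t <- matrix(rbinom(16, 1, 0.5), 4, 4)
    b_p <- matrix(rbinom(16, 1, 0.5), 4, 4)
    b_t <- matrix(rbinom(16, 1, 0.5), 4, 4)
  })
  expect_equal(confusion(a_p, a_t) + confusion(b_p, b_t),
               confusion(rbind(a_p, b_p), rbind(a_t, b_t)))

  expect_error(confusion(matrix(0L, 2, 2), matrix(0L, 3, 3)), "shape")
  expect_error(confusion(matrix(2L, 2, 2), matrix(0L, 2, 2), 2), "labels")
})

test_that("PA and MIoU match hand arithmetic and the set-overlap oracle", {
  # perfect prediction
  expect_equal(pixel_accuracy(diag(c(5, 5, 5))), 1)
  expect_equal(miou(diag(c(5, 5, 5))), 1)

  # the all-background fixture: PA 0.75, IoU (0.75, 0), MIoU 0.375
  cm <- matrix(c(12, 4, 0, 0), 2, 2)
  expect_equal(pixel_accuracy(cm), 0.75)
  expect_equal(class_iou(cm), c(0.75, 0))
  expect_equal(miou(cm), 0.375)

  expect_error(pixel_accuracy(matrix(0, 2, 2)), "empty")
  # zero-union classes are excluded from the mean
  cm3 <- matrix(0, 3, 3)
  cm3[1, 1] <- 8; cm3[2, 2] <- 2; cm3[1, 2] <- 2
  expect_equal(miou(cm3), mean(c(8 / 10, 2 / 4)))

  # brute-force oracle on 100 random 16x16 mask pairs
  withr::with_seed(62, {
    for (case in 1:100) {
      pred <- matrix(rbinom(256, 1, runif(1)), 16, 16)
      true <- matrix(rbinom(256, 1, runif(1)), 16, 16)
      cm <- confusion(pred, true, 2)
      want <- metrics_oracle(pred, true, 2)
      expect_identical(pixel_accuracy(cm), want$pa)
      expect_identical(miou(cm), want$miou)
    }
  })
})

test_that("metrics are invariant and equivariant where they should be", {
  withr::with_seed(63, {
    pred <- matrix(rbinom(64, 1, 0.4), 8, 8)
    true <- matrix(rbinom(64, 1, 0.4), 8, 8)
  })
  base_cm <- confusion(pred, true, 2)
  # simultaneous dihedral transforms leave PA and MIoU unchanged
  for (k in dihedral_kinds) {
    f <- fissureseg:::plane_transform(k)
    cm <- confusion(f(pred), f(true), 2)
    expect_equal(pixel_accuracy(cm), pixel_accuracy(base_cm))
    expect_equal(miou(cm), miou(base_cm))
  }
  # class-permutation equivariance
  cm_swapped <- confusion(1L - pred, 1L - true, 2)
  expect_equal(class_iou(cm_swapped), rev(class_iou(base_cm)))
  expect_equal(miou(cm_swapped), miou(base_cm))
  # both metrics always in [0, 1]
  expect_true(pixel_accuracy(base_cm) >= 0 && pixel_accuracy(base_cm) <= 1)
  expect_true(miou(base_cm) >= 0 && miou(base_cm) <= 1)
})

test_that("evaluate accumulates one confusion matrix over the dataset", {
  params <- desk_synth_params()
  samples <- generate_dataset(params, 4, seed = 31)

  # an identity oracle (predicts the true mask) scores perfectly
  oracle <- function(s) s$mask
  rep0 <- evaluate(oracle, samples)
  expect_equal(rep0$pixel_accuracy, 1)
  expect_equal(rep0$miou, 1)

  # duplicating every sample leaves the report's ratios unchanged
  rep_dup <- evaluate(oracle, c(samples, samples))
  expect_equal(rep_dup$pixel_accuracy, rep0$pixel_accuracy)
  expect_equal(rep_dup$miou, rep0$miou)

  # model evaluation equals a manual accumulation over predict()
  cfg <- model_config(encoder = "plain_unet", use_gcn = FALSE,
                      use_br = FALSE, base_channels = 4,
                      input_size = c(64L, 64L))
  m <- build_improved_unet(cfg, seed = 2)
  rep1 <- evaluate(m, samples)
  cm <- matrix(0, 2, 2)
  for (s in samples) {
    sized <- resize_sample(s, c(64L, 64L))
    cm <- cm + confusion(predict(m, s), sized$mask, 2)
  }
  expect_equal(rep1$pixel_accuracy, pixel_accuracy(cm))
  expect_equal(rep1$miou, miou(cm))
  expect_equal(rep1$n_images, 4L)

  unlabeled <- list(list(image = samples[[1]]$image, id = "u"))
  expect_error(evaluate(m, unlabeled), "labeled")
  expect_error(evaluate(m, list()), "no samples")
})

test_that("overlay blends only mask pixels", {
  img <- array(100, c(4, 4, 3))
  mask <- matrix(0L, 4, 4)
  mask[2, 2] <- 1L
  expect_equal(overlay(img, mask, alpha = 0), img)
  full <- overlay(img, mask, color = c(255, 0, 0), alpha = 1)
  expect_equal(full[2, 2, ], c(255, 0, 0))
  expect_equal(full[1, 1, ], c(100, 100, 100))
  expect_equal(overlay(img, matrix(0L, 4, 4), alpha = 0.7), img)
  half <- overlay(img, mask, color = c(200, 0, 0), alpha = 0.5)
  expect_equal(half[2, 2, 1], 150)
})

test_that("the ablation harness produces a deterministic comparison table", {
  params <- synthetic_params(image_size = c(32L, 32L))
  grid <- list(
    model_config(encoder = "plain_unet", use_gcn = FALSE, use_br = FALSE,
                 base_channels = 4, input_size = c(32L, 32L)),
    model_config(encoder = "plain_unet", use_gcn = TRUE, use_br = TRUE,
                 gcn_kernel_size = 7, base_channels = 4,
                 input_size = c(32L, 32L)),
    model_config(encoder = "plain_unet", use_gcn = TRUE, use_br = TRUE,
                 gcn_kernel_size = 7, base_channels = 4,
                 input_size = c(32L, 32L))
  )
  tcfg <- train_config(learning_rate = 1e-3, batch_size = 4, epochs = 2,
                       input_size = c(32L, 32L), class_weights = c(1, 10))
  tab <- compare_configs(grid, list(params = params, n = 10), tcfg,
                         n_seeds = 1)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$model,
               c("Unet", "Unet_GCN", "Unet_GCN"))
  expect_true(all(tab$miou > 0 & tab$miou <= 100))
  expect_true(all(tab$pa > 0 & tab$pa <= 100))
  # identical configs give identical rows under the same seeds
  expect_equal(tab[2, -1], tab[3, -1], ignore_attr = TRUE)
})
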