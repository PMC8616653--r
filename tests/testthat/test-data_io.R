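test_that("labelme annotations are parsed, filtered and validated", {
  tri1 <- list(label = "fissure", points = cbind(c(1, 5, 1), c(1, 1, 5)))
  tri2 <- list(label = "fissure", points = cbind(c(6, 9, 6), c(6, 6, 9)))
  path <- withr::local_tempfile(fileext = ".json")
  write_labelme(path, list(tri1, tri2), H = 10, W = 12)
  ann <- read_annotation(path)
  expect_s3_class(ann, "polygon_annotation")
  expect_length(ann$shapes, 2)
  expect_equal(ann$image_height, 10L)
  expect_equal(ann$image_width, 12L)
  expect_equal(ann$shapes[[1]]$points, tri1$points)

  # label filtering
  other <- list(label = "coating", points = tri2$points)
  path2 <- withr::local_tempfile(fileext = ".json")
  write_labelme(path2, list(tri1, other), H = 10, W = 12)
  expect_length(read_annotation(path2)$shapes, 2)
  expect_length(read_annotation(path2, label_filter = "fissure")$shapes, 1)

  # empty shapes list
  path3 <- withr::local_tempfile(fileext = ".json")
  write_labelme(path3, list(), H = 4, W = 4)
  expect_length(read_annotation(path3)$shapes, 0)

  # contract violations name the offending key
  expect_error(read_annotation(file.path(tempdir(), "no-such-file.json")),
               "not found")
  path4 <- withr::local_tempfile(fileext = ".json")
  writeLines('{"shapes": [{"label": "fissure"}], "imageHeight": 4, "imageWidth": 4}',
             path4)
  expect_error(read_annotation(path4), "points")
  path5 <- withr::local_tempfile(fileext = ".json")
  writeLines('{"imageHeight": 4, "imageWidth": 4}', path5)
  expect_error(read_annotation(path5), "shapes")
  path6 <- withr::local_tempfile(fileext = ".json")
  writeLines("not json at all {", path6)
  expect_error(read_annotation(path6), "malformed")
})

test_that("rasterize covers trivial cases exactly", {
  empty <- structure(list(shapes = list(), image_height = 8L,
                          image_width = 8L),
                     class = "polygon_annotation")
  expect_equal(rasterize(empty), matrix(0L, 8, 8))

  full <- structure(list(
    shapes = list(list(label = "f",
                       points = cbind(c(0, 8, 8, 0), c(0, 0, 8, 8)))),
    image_height = 8L, image_width = 8L), class = "polygon_annotation")
  expect_equal(rasterize(full), matrix(1L, 8, 8))

  degenerate <- structure(list(
    shapes = list(list(label = "f", points = cbind(c(0, 4), c(0, 4)))),
    image_height = 4L, image_width = 4L), class = "polygon_annotation")
  expect_error(rasterize(degenerate), "at least 3 points")
})

test_that("rasterize agrees with the per-pixel point-in-polygon oracle", {
  tri <- cbind(c(0, 4, 0), c(0, 0, 4))
  ann <- structure(list(shapes = list(list(label = "f", points = tri)),
                        image_height = 4L, image_width = 4L),
                   class = "polygon_annotation")
  expect_equal(rasterize(ann), raster_oracle(list(tri), 4, 4))

  withr::with_seed(7, {
    for (case in 1:12) {
      H <- sample(8:32, 1)
      W <- sample(8:32, 1)
      shapes <- lapply(seq_len(sample(1:3, 1)), function(i) {
        list(label = "f", points = random_convex_polygon(H, W))
      })
      ann <- structure(list(shapes = shapes, image_height = H,
                            image_width = W),
                       class = "polygon_annotation")
      expect_equal(rasterize(ann),
                   raster_oracle(lapply(shapes, `[[`, "points"), H, W))
    }
  })
})

test_that("mask PNG round trip is the identity and contracts hold", {
  withr::with_seed(3, {
    mask <- matrix(rbinom(16 * 16, 1, 0.3), 16, 16)
  })
  path <- withr::local_tempfile(fileext = ".png")
  write_mask(mask, path)
  expect_identical(read_mask(path), matrix(as.integer(mask), 16, 16))

  # files store 0/255
  raw <- png::readPNG(path)
  expect_setequal(unique(as.vector(raw)) * 255, unique(c(0, 255 * mask)))

  # an RGB png is rejected
  rgb_path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(runif(4 * 4 * 3), c(4, 4, 3)), rgb_path)
  expect_error(read_mask(rgb_path), "single-channel")
  expect_error(read_mask(withr::local_tempfile(fileext = ".tif")), "PNG")
})

test_that("image io handles PNG, JPEG and grayscale promotion", {
  img <- quantize8_test <- array(round(runif(6 * 5 * 3) * 255), c(6, 5, 3))
  p <- withr::local_tempfile(fileext = ".png")
  write_image(img, p)
  expect_equal(read_image(p), img)

  jp <- withr::local_tempfile(fileext = ".jpg")
  jpeg::writeJPEG(img / 255, jp)
  got <- read_image(jp)
  expect_equal(dim(got), c(6, 5, 3))

  gp <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(runif(12), 4, 3), gp)
  gray <- read_image(gp)
  expect_equal(dim(gray), c(4, 3, 3))
  expect_equal(gray[, , 1], gray[, , 2])
})

test_that("split_dataset partitions deterministically", {
  s <- split_dataset(letters[1:10], 0.7, seed = 1)
  expect_length(s$train_ids, 7)
  expect_length(s$held_out_ids, 3)
  expect_identical(s, split_dataset(letters[1:10], 0.7, seed = 1))

  empty <- split_dataset(character(0), 0.7, seed = 1)
  expect_length(empty$train_ids, 0)
  expect_length(empty$held_out_ids, 0)

  expect_error(split_dataset(letters, 0), "between 0 and 1")
  expect_error(split_dataset(letters, 1.2), "between 0 and 1")

  # partition property over many random cases
  withr::with_seed(11, {
    for (case in 1:200) {
      n <- sample(1:60, 1)
      ids <- sample(100000, n)
      frac <- runif(1, 0.05, 0.95)
      sp <- split_dataset(ids, frac, seed = case)
      expect_setequal(c(sp$train_ids, sp$held_out_ids), ids)
      expect_length(intersect(sp$train_ids, sp$held_out_ids), 0)
      expect_length(sp$train_ids, round(n * frac))
    }
  })

  # different seeds generally differ
  splits <- vapply(1:20, function(s) {
    paste(split_dataset(1:30, 0.7, seed = s)$train_ids, collapse = ",")
  }, character(1))
  expect_gt(length(unique(splits)), 1)
})
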