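# Independent brute-force oracles used across the suite. These deliberately
# re-derive results with naive loops so they share no code with the package
# implementations they check.

# Dense 2d convolution by direct summation. x: (H, W, Cin); w: (kh, kw,
# Cin, Cout); returns (Ho, Wo, Cout).
naive_conv <- function(x, w, b = NULL, padh = 0, padw = 0) {
  d <- dim(x); wd <- dim(w)
  Ho <- d[1] + 2 * padh - wd[1] + 1
  Wo <- d[2] + 2 * padw - wd[2] + 1
  xp <- array(0, c(d[1] + 2 * padh, d[2] + 2 * padw, d[3]))
  xp[padh + seq_len(d[1]), padw + seq_len(d[2]), ] <- x
  y <- array(0, c(Ho, Wo, wd[4]))
  for (co in seq_len(wd[4])) {
    for (ho in seq_len(Ho)) {
      for (wo in seq_len(Wo)) {
        acc <- if (is.null(b)) 0 else b[co]
        for (ci in seq_len(d[3])) {
          acc <- acc + sum(xp[ho:(ho + wd[1] - 1), wo:(wo + wd[2] - 1), ci] *
                             w[, , ci, co])
        }
        y[ho, wo, co] <- acc
      }
    }
  }
  y
}

# Depthwise convolution oracle. w: (kh, kw, C).
naive_dwconv <- function(x, w, padh = 0, padw = 0) {
  d <- dim(x); wd <- dim(w)
  y <- array(0, c(d[1], d[2], 0))
  planes <- lapply(seq_len(d[3]), function(c) {
    naive_conv(array(x[, , c], c(d[1], d[2], 1)),
               array(w[, , c], c(wd[1], wd[2], 1, 1)),
               padh = padh, padw = padw)[, , 1]
  })
  out <- array(0, c(dim(planes[[1]]), d[3]))
  for (c in seq_len(d[3])) out[, , c] <- planes[[c]]
  out
}

# Point-in-polygon by the even-odd crossing rule, one point at a time.
pip_oracle <- function(x, y, pts) {
  n <- nrow(pts)
  inside <- FALSE
  for (e in seq_len(n)) {
    x1 <- pts[e, 1]; y1 <- pts[e, 2]
    j <- if (e == n) 1 else e + 1
    x2 <- pts[j, 1]; y2 <- pts[j, 2]
    if ((y1 > y) != (y2 > y)) {
      xint <- x1 + (y - y1) * (x2 - x1) / (y2 - y1)
      if (x < xint) inside <- !inside
    }
  }
  inside
}

# Rasterization oracle: test every pixel center independently.
raster_oracle <- function(shapes, H, W) {
  m <- matrix(0L, H, W)
  for (h in seq_len(H)) {
    for (w in seq_len(W)) {
      for (s in shapes) {
        if (pip_oracle(w - 0.5, h - 0.5, s)) {
          m[h, w] <- 1L
          break
        }
      }
    }
  }
  m
}

# Random convex polygon inside a margin of an H x W canvas.
random_convex_polygon <- function(H, W, n = 6) {
  x <- runif(n, 1, W - 1)
  y <- runif(n, 1, H - 1)
  hull <- chull(x, y)
  cbind(x[hull], y[hull])
}

# Segmentation metric oracle from raw masks via per-class set overlap.
metrics_oracle <- function(pred, true, C = 2) {
  pa <- mean(pred == true)
  ious <- numeric(0)
  for (c in seq_len(C) - 1) {
    inter <- sum(pred == c & true == c)
    union <- sum(pred == c | true == c)
    if (union > 0) ious <- c(ious, inter / union)
  }
  list(pa = pa, miou = mean(ious))
}

# Write a minimal labelme-dialect annotation file; shapes is a list of
# lists(label, points-matrix).
write_labelme <- function(path, shapes, H, W) {
  obj <- list(
    version = "3.16.7",
    shapes = lapply(shapes, function(s) {
      list(label = s$label,
           points = lapply(seq_len(nrow(s$points)),
                           function(i) as.list(s$points[i, ])))
    }),
    imageHeight = H,
    imageWidth = W
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  path
}

# Small deterministic labeled sample for augmentation/training tests.
tiny_sample <- function(H = 8, W = 8, seed = 1) {
  withr::with_seed(seed, {
    img <- array(sample(0:255, H * W * 3, replace = TRUE), c(H, W, 3))
    mask <- matrix(0L, H, W)
    mask[2:min(3, H), 2:min(4, W)] <- 1L
    structure(list(image = img, mask = mask, id = "tiny"),
              class = "fissure_sample")
  })
}

# Stable fingerprint of a sample for set comparisons.
sample_key <- function(s) paste(c(dim(s$image), s$image, s$mask),
                                collapse = ",")

desk_synth_params <- function() synthetic_params(image_size = c(64L, 64L))
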