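# Synthetic fissured-tongue image generator.
#
# Emulates the essential structure of clinical fissured-tongue photographs:
# a textured convex (elliptical) foreground region on a dark background,
# containing thin, branching, darker crack structures that occupy a small
# fraction of pixels, with pixel-exact binary ground-truth masks. Crack
# skeletons are bounded-turning random walks; the rendered crack is the
# skeleton dilated to a per-crack width and darkened.

#' Parameters of the synthetic fissured-tongue generator
#'
#' @param image_size `(H, W)`, each >= 32.
#' @param crack_count_range inclusive integer interval for the number of
#'   primary cracks.
#' @param branch_probability per-step probability that a walk spawns a side
#'   branch (branches may branch once more).
#' @param step_length random-walk step length in pixels.
#' @param crack_width_range interval the per-crack stroke width (pixels) is
#'   drawn from.
#' @param crack_intensity_delta negative intensity offset applied to crack
#'   pixels (8-bit scale, all channels, with small per-pixel jitter).
#' @param background_base_color RGB triple (0..255) of the tongue surface.
#' @param texture_noise_scale standard deviation (8-bit scale) of the
#'   low-frequency surface texture; fine grain uses a third of it.
#' @param foreground_ellipse_axes_fraction `(fx, fy)` in (0, 1]: ellipse
#'   semi-axes as fractions of W/2 and H/2.
#' @param seed default seed used when an operation is not given one.
#' @return a `synthetic_params` list.
#' @export
synthetic_params <- function(image_size = c(128L, 128L),
                             crack_count_range = c(2L, 6L),
                             branch_probability = 0.15,
                             step_length = 3,
                             crack_width_range = c(1, 3),
                             crack_intensity_delta = -60,
                             background_base_color = c(205, 125, 130),
                             texture_noise_scale = 12,
                             foreground_ellipse_axes_fraction = c(0.85, 0.8),
                             seed = 1L) {
  stopifnot(length(image_size) == 2, all(image_size >= 32))
  stopifnot(length(crack_count_range) == 2,
            crack_count_range[1] >= 0,
            crack_count_range[1] <= crack_count_range[2])
  stopifnot(branch_probability >= 0, branch_probability <= 1)
  stopifnot(step_length > 0)
  stopifnot(length(crack_width_range) == 2, crack_width_range[1] > 0,
            crack_width_range[1] <= crack_width_range[2])
  if (crack_intensity_delta > 0) {
    stop("crack_intensity_delta must be a negative (darkening) offset")
  }
  stopifnot(length(foreground_ellipse_axes_fraction) == 2,
            all(foreground_ellipse_axes_fraction > 0),
            all(foreground_ellipse_axes_fraction <= 1))
  structure(
    list(image_size = as.integer(image_size),
         crack_count_range = as.integer(crack_count_range),
         branch_probability = branch_probability,
         step_length = step_length,
         crack_width_range = as.numeric(crack_width_range),
         crack_intensity_delta = crack_intensity_delta,
         background_base_color = as.numeric(background_base_color),
         texture_noise_scale = texture_noise_scale,
         foreground_ellipse_axes_fraction =
           as.numeric(foreground_ellipse_axes_fraction),
         seed = as.integer(seed)),
    class = "synthetic_params"
  )
}

ellipse_geometry <- function(params) {
  H <- params$image_size[1]
  W <- params$image_size[2]
  list(cx = W / 2, cy = H / 2,
       ax = params$foreground_ellipse_axes_fraction[1] * W / 2,
       ay = params$foreground_ellipse_axes_fraction[2] * H / 2)
}

in_ellipse <- function(x, y, g) {
  ((x - g$cx) / g$ax)^2 + ((y - g$cy) / g$ay)^2 <= 1
}

# Logical (H, W) matrix: pixel centers inside the foreground ellipse.
ellipse_mask <- function(params) {
  H <- params$image_size[1]
  W <- params$image_size[2]
  g <- ellipse_geometry(params)
  px <- rep(seq_len(W) - 0.5, each = H)
  py <- rep(seq_len(H) - 0.5, times = W)
  matrix(in_ellipse(px, py, g), H, W)
}

#' Generate crack skeletons (random-walk polylines)
#'
#' Each primary crack is a random walk started well inside the foreground
#' ellipse (within 60% of its radius, so no crack degenerates to a point),
#' with turning angle bounded per step; walks terminate at the ellipse
#' boundary or after a maximum step count. At each step a side branch
#' spawns with `branch_probability` (branch depth is capped at 2).
#'
#' @param params a [synthetic_params()].
#' @param seed integer seed; identical `(params, seed)` give identical
#'   polylines.
#' @return a list of polylines, each an n x 2 matrix of (x, y) coordinates.
#' @export
generate_skeleton <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "synthetic_params"))
  g <- ellipse_geometry(params)
  step <- params$step_length
  max_steps0 <- max(8L, ceiling(0.6 * max(params$image_size) / step))
  polylines <- list()

  walk <- function(x, y, dir, max_steps, depth) {
    pts <- matrix(c(x, y), 1, 2)
    for (s in seq_len(max_steps)) {
      dir <- dir + runif(1, -0.35, 0.35)
      x2 <- x + step * cos(dir)
      y2 <- y + step * sin(dir)
      if (!in_ellipse(x2, y2, g)) break
      pts <- rbind(pts, c(x2, y2))
      x <- x2; y <- y2
      if (depth < 2 && runif(1) < params$branch_probability) {
        bdir <- dir + sample(c(-1, 1), 1) * runif(1, 0.5, 1.1)
        walk(x, y, bdir, max(2L, (max_steps - s) %/% 2L), depth + 1)
      }
    }
    if (nrow(pts) >= 2) polylines[[length(polylines) + 1]] <<- pts
    invisible(NULL)
  }

  withr::with_seed(derive_seed(seed, "skeleton"), {
    lo <- params$crack_count_range[1]
    hi <- params$crack_count_range[2]
    count <- if (lo == hi) lo else lo + sample.int(hi - lo + 1L, 1) - 1L
    for (i in seq_len(count)) {
      r <- 0.6 * sqrt(runif(1))
      th <- runif(1, 0, 2 * pi)
      x0 <- g$cx + r * g$ax * cos(th)
      y0 <- g$cy + r * g$ay * sin(th)
      walk(x0, y0, runif(1, 0, 2 * pi), max_steps0, 0)
    }
  })
  polylines
}

# Stamp a polyline, dilated to the given width, into a logical mask.
stamp_polyline <- function(mask, pts, width) {
  H <- nrow(mask); W <- ncol(mask)
  radius <- width / 2
  # densify: points every ~0.5 px along each segment
  dense <- lapply(seq_len(nrow(pts) - 1), function(i) {
    p <- pts[i, ]; q <- pts[i + 1, ]
    len <- sqrt(sum((q - p)^2))
    t <- seq(0, 1, length.out = max(2, ceiling(len / 0.5) + 1))
    cbind(p[1] + t * (q[1] - p[1]), p[2] + t * (q[2] - p[2]))
  })
  dense <- do.call(rbind, c(dense, list(pts[nrow(pts), , drop = FALSE])))
  r <- ceiling(radius + 0.5)
  for (i in seq_len(nrow(dense))) {
    x <- dense[i, 1]; y <- dense[i, 2]
    h0 <- max(1L, floor(y - r) + 1L); h1 <- min(H, ceiling(y + r) + 1L)
    w0 <- max(1L, floor(x - r) + 1L); w1 <- min(W, ceiling(x + r) + 1L)
    if (h0 > h1 || w0 > w1) next
    hh <- h0:h1; ww <- w0:w1
    dy2 <- (hh - 0.5 - y)^2
    dx2 <- (ww - 0.5 - x)^2
    hit <- outer(dy2, dx2, `+`) <= radius^2
    mask[hh, ww] <- mask[hh, ww] | hit
  }
  mask
}

# Smooth low-frequency noise field: coarse Gaussian grid upsampled
# bilinearly to full resolution.
smooth_noise <- function(H, W, sd) {
  hc <- max(2L, ceiling(H / 16)); wc <- max(2L, ceiling(W / 16))
  coarse <- array(rnorm(hc * wc, 0, sd), c(hc, wc, 1L, 1L))
  matrix(resize_bilinear_cpp(coarse, H, W), H, W)
}

#' Render one synthetic sample (image + pixel-exact mask)
#'
#' The image is a textured ellipse ("tongue") on a dark background; each
#' skeleton from [generate_skeleton()] is dilated to a width drawn from
#' `crack_width_range` and darkened by `crack_intensity_delta`. The mask is
#' exactly the dilated skeleton pixels, clipped to the foreground ellipse.
#'
#' @param params a [synthetic_params()].
#' @param seed integer seed.
#' @param id identifier string stored in the sample.
#' @return a `fissure_sample`: list with `image` `(H, W, 3)` in 0..255,
#'   `mask` (integer matrix in `{0, 1}`) and `id`.
#' @export
render_sample <- function(params, seed = params$seed, id = NULL) {
  stopifnot(inherits(params, "synthetic_params"))
  H <- params$image_size[1]
  W <- params$image_size[2]
  skeletons <- generate_skeleton(params, seed)
  emask <- ellipse_mask(params)
  withr::with_seed(derive_seed(seed, "render"), {
    dark <- c(45, 38, 40)
    image <- array(0, c(H, W, 3))
    low <- smooth_noise(H, W, params$texture_noise_scale)
    fine <- matrix(rnorm(H * W, 0, params$texture_noise_scale / 3), H, W)
    for (ch in 1:3) {
      plane <- matrix(dark[ch], H, W) +
        matrix(rnorm(H * W, 0, 3), H, W)
      fg <- params$background_base_color[ch] + low + fine
      plane[emask] <- fg[emask]
      image[, , ch] <- plane
    }
    mask <- matrix(FALSE, H, W)
    for (pts in skeletons) {
      width <- runif(1, params$crack_width_range[1],
                     params$crack_width_range[2])
      mask <- stamp_polyline(mask, pts, width)
    }
    mask <- mask & emask
    npix <- sum(mask)
    if (npix > 0) {
      jitter <- rnorm(npix, 0, 6)
      for (ch in 1:3) {
        plane <- image[, , ch]
        plane[mask] <- plane[mask] + params$crack_intensity_delta + jitter
        image[, , ch] <- plane
      }
    }
    image <- quantize8(image)
    structure(list(image = image,
                   mask = matrix(as.integer(mask), H, W),
                   id = id %||% sprintf("synthetic_%d", seed)),
              class = "fissure_sample")
  })
}

#' Generate a reproducible synthetic dataset
#'
#' Per-sample seeds are derived deterministically from `(seed, index)`, so
#' the i-th sample is the same regardless of `n`.
#'
#' @param params a [synthetic_params()].
#' @param n number of samples (>= 0).
#' @param seed integer dataset seed.
#' @return a list of `fissure_sample`s.
#' @export
generate_dataset <- function(params, n, seed = params$seed) {
  stopifnot(n >= 0)
  lapply(seq_len(n), function(i) {
    render_sample(params, seed = derive_seed(seed, paste0("sample-", i)),
                  id = sprintf("sample_%04d", i))
  })
}

#' @export
print.fissure_sample <- function(x, ...) {
  d <- dim(x$image)
  cat("<fissure_sample> ", x$id, ": ", d[1], "x", d[2],
      if (!is.null(x$mask)) {
        sprintf(", %d fissure pixels (%.2f%%)", sum(x$mask),
                100 * mean(x$mask))
      } else ", unlabeled", "\n", sep = "")
  invisible(x)
}

#' Write a dataset as paired image/mask PNGs plus a manifest
#'
#' @param samples list of `fissure_sample`s.
#' @param dir output directory (created if needed).
#' @param params optional parameter record stored in the manifest.
#' @return path of the manifest JSON file, invisibly.
#' @export
write_dataset <- function(samples, dir, params = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(samples, function(s) {
    img <- file.path(dir, paste0(s$id, ".png"))
    write_image(s$image, img)
    entry <- list(id = s$id, image = basename(img))
    if (!is.null(s$mask)) {
      msk <- file.path(dir, paste0(s$id, "_mask.png"))
      write_mask(s$mask, msk)
      entry$mask <- basename(msk)
    }
    entry
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(samples = entries,
                            params = if (!is.null(params)) unclass(params)),
                       manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Load a dataset from a manifest written by [write_dataset()]
#'
#' @param manifest path to `manifest.json`.
#' @return a list of `fissure_sample`s.
#' @export
load_dataset <- function(manifest) {
  m <- jsonlite::fromJSON(manifest, simplifyVector = FALSE)
  dir <- dirname(manifest)
  lapply(m$samples, function(e) {
    structure(list(image = read_image(file.path(dir, e$image)),
                   mask = if (!is.null(e$mask)) {
                     read_mask(file.path(dir, e$mask))
                   },
                   id = e$id),
              class = "fissure_sample")
  })
}
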