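# Reading and writing images, polygon annotations and label masks, and
# reproducible dataset splits.
#
# Conventions: pixel coordinates are 0-based with the origin at the top-left
# corner, x rightward and y downward; the center of pixel (row h, col w)
# (1-based array indices) is at (x, y) = (w - 0.5, h - 0.5). In-memory masks
# are integer matrices with 0 = background, 1 = fissure; mask PNG files
# store 0/255 so they are viewable. Images are (H, W, 3) arrays of 8-bit
# intensities stored as doubles in 0..255.

#' Read a polygon annotation file (labelme JSON dialect)
#'
#' Parses the labelme layout: a top-level `"shapes"` list whose entries
#' carry `"label"` and `"points"`, plus `"imageHeight"` and `"imageWidth"`.
#'
#' @param path JSON file path.
#' @param label_filter optional character vector; keep only shapes whose
#'   label is in this set (default: keep all shapes).
#' @return a `polygon_annotation`: list with `shapes` (each a list with
#'   `label` and an n x 2 `points` matrix) and `image_height`,
#'   `image_width`.
#' @export
read_annotation <- function(path, label_filter = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  j <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      stop("malformed JSON in '", path, "': ", conditionMessage(e))
    }
  )
  for (key in c("shapes", "imageHeight", "imageWidth")) {
    if (is.null(j[[key]])) {
      stop("annotation '", path, "' is missing required key \"", key, "\"")
    }
  }
  shapes <- lapply(j$shapes, function(s) {
    if (is.null(s$label)) stop("shape is missing required key \"label\"")
    if (is.null(s$points)) stop("shape is missing required key \"points\"")
    pts <- do.call(rbind, lapply(s$points, function(p) as.numeric(unlist(p))))
    if (is.null(pts) || ncol(pts) != 2) {
      stop("shape \"points\" must be a list of (x, y) pairs")
    }
    if (!all(is.finite(pts))) stop("shape contains non-finite coordinates")
    list(label = as.character(s$label), points = pts)
  })
  if (!is.null(label_filter)) {
    shapes <- Filter(function(s) s$label %in% label_filter, shapes)
  }
  structure(list(shapes = shapes,
                 image_height = as.integer(j$imageHeight),
                 image_width = as.integer(j$imageWidth)),
            class = "polygon_annotation")
}

# Even-odd crossing test for a set of points against one polygon.
# px, py: point coordinates; pts: n x 2 polygon vertex matrix.
point_in_polygon <- function(px, py, pts) {
  n <- nrow(pts)
  parity <- rep(FALSE, length(px))
  for (e in seq_len(n)) {
    x1 <- pts[e, 1]; y1 <- pts[e, 2]
    j <- if (e == n) 1L else e + 1L
    x2 <- pts[j, 1]; y2 <- pts[j, 2]
    cross <- (y1 > py) != (y2 > py)
    idx <- which(cross)
    if (length(idx)) {
      xint <- x1 + (py[idx] - y1) * (x2 - x1) / (y2 - y1)
      hit <- px[idx] < xint
      parity[idx] <- xor(parity[idx], hit)
    }
  }
  parity
}

#' Rasterize a polygon annotation to a binary label mask
#'
#' A pixel is labeled 1 iff its center (`x + 0.5`, `y + 0.5` in 0-based
#' pixel coordinates) lies inside any polygon under the even-odd rule;
#' overlapping polygons union.
#'
#' @param ann a `polygon_annotation` from [read_annotation()].
#' @return an `image_height x image_width` integer matrix in `{0, 1}`.
#' @export
rasterize <- function(ann) {
  stopifnot(inherits(ann, "polygon_annotation"))
  H <- ann$image_height
  W <- ann$image_width
  if (!length(ann$shapes)) return(matrix(0L, H, W))
  px <- rep(seq_len(W) - 0.5, each = H)
  py <- rep(seq_len(H) - 0.5, times = W)
  inside <- rep(FALSE, H * W)
  for (s in ann$shapes) {
    if (nrow(s$points) < 3) {
      stop("polygon must have at least 3 points, got ", nrow(s$points))
    }
    inside <- inside | point_in_polygon(px, py, s$points)
  }
  matrix(as.integer(inside), H, W)
}

#' Read / write a binary label mask as single-channel PNG
#'
#' Mask files store 0 (background) and 255 (fissure) for visibility; any
#' nonzero file value maps to in-memory label 1. `write_mask` is the
#' inverse, so a write-read round trip is the identity on `{0, 1}` masks.
#'
#' @param path PNG file path.
#' @return `read_mask`: an integer matrix in `{0, 1}`.
#' @export
read_mask <- function(path) {
  if (!grepl("\\.png$", path, ignore.case = TRUE)) {
    stop("mask files must be PNG, got '", path, "'")
  }
  if (!file.exists(path)) stop("mask file not found: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) != 2) {
    stop("mask PNG must be single-channel, '", path, "' has ",
         dim(img)[3], " channels")
  }
  matrix(as.integer(img > 0), nrow(img), ncol(img))
}

#' @rdname read_mask
#' @param mask an integer matrix in `{0, 1}`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask), all(mask %in% c(0L, 1L)))
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read / write an RGB image (PNG or JPEG)
#'
#' Returns an `(H, W, 3)` array of 8-bit intensities in 0..255. Grayscale
#' images are promoted to 3 channels; an alpha channel is dropped. Writing
#' always produces PNG (lossless), regardless of extension.
#'
#' @param path image file path.
#' @return `read_image`: an `(H, W, 3)` numeric array in 0..255.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- if (grepl("\\.(jpg|jpeg)$", path, ignore.case = TRUE)) {
    jpeg::readJPEG(path)
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    stop("unsupported image format: '", path, "' (use PNG or JPEG)")
  }
  if (is.matrix(img)) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 1) img <- array(rep(img, 3), c(dim(img)[1:2], 3))
  round(img * 255)
}

#' @rdname read_image
#' @param image an `(H, W, 3)` array in 0..255.
#' @export
write_image <- function(image, path) {
  stopifnot(length(dim(image)) == 3)
  png::writePNG(clamp01(image / 255), path)
  invisible(path)
}

#' Split identifiers into training and held-out sets
#'
#' Deterministic given the seed: the identifiers are shuffled once and the
#' first `round(n * train_fraction)` become the training set.
#'
#' @param ids vector of identifiers.
#' @param train_fraction real in (0, 1).
#' @param seed integer seed.
#' @return a `dataset_split`: list with `train_ids`, `held_out_ids`,
#'   `train_fraction`, `seed`.
#' @export
split_dataset <- function(ids, train_fraction = 0.7, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be strictly between 0 and 1")
  }
  n <- length(ids)
  if (n == 0) {
    return(structure(list(train_ids = ids, held_out_ids = ids,
                          train_fraction = train_fraction,
                          seed = as.integer(seed)),
                     class = "dataset_split"))
  }
  k <- round(n * train_fraction)
  ord <- withr::with_seed(derive_seed(seed, "split"), sample.int(n))
  structure(list(train_ids = ids[ord[seq_len(k)]],
                 held_out_ids = ids[ord[setdiff(seq_len(n), seq_len(k))]],
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "dataset_split")
}
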