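# Geometric data augmentation applied jointly to image and mask: the
# 8-element dihedral orbit (flip x rotation) and random cropping.

#' Kinds of augmentation in the dihedral orbit
#'
#' The fixed order of the 8 flip/rotation compositions: rotations are
#' applied first (clockwise multiples of 90 degrees), then the horizontal
#' flip. These 8 operations form the symmetry group of the square.
#'
#' @export
dihedral_kinds <- c("identity", "rot90", "rot180", "rot270",
                    "hflip", "hflip_rot90", "hflip_rot180", "hflip_rot270")

rot90m <- function(m) t(m[nrow(m):1, , drop = FALSE])   # 90 deg clockwise
rot180m <- function(m) m[nrow(m):1, ncol(m):1, drop = FALSE]
rot270m <- function(m) t(m)[nrow(m):1, , drop = FALSE]
hflipm <- function(m) m[, ncol(m):1, drop = FALSE]

plane_transform <- function(kind) {
  switch(kind,
    identity = function(m) m,
    rot90 = rot90m,
    rot180 = rot180m,
    rot270 = rot270m,
    hflip = hflipm,
    hflip_rot90 = function(m) hflipm(rot90m(m)),
    hflip_rot180 = function(m) hflipm(rot180m(m)),
    hflip_rot270 = function(m) hflipm(rot270m(m)),
    stop("unknown dihedral kind: ", kind)
  )
}

apply_planes <- function(a, f) {
  if (is.matrix(a)) return(f(a))
  planes <- lapply(seq_len(dim(a)[3]), function(ch) f(a[, , ch]))
  out <- array(0, c(dim(planes[[1]]), length(planes)))
  for (ch in seq_along(planes)) out[, , ch] <- planes[[ch]]
  out
}

#' Apply one dihedral operation to a sample
#'
#' Image and mask undergo the identical transform.
#'
#' @param sample a `fissure_sample` (or any list with `image`, optional
#'   `mask`, `id`).
#' @param kind one of [dihedral_kinds].
#' @return the transformed sample.
#' @export
dihedral_transform <- function(sample, kind) {
  f <- plane_transform(kind)
  out <- sample
  out$image <- apply_planes(sample$image, f)
  if (!is.null(sample$mask)) out$mask <- f(sample$mask)
  if (!is.null(sample$id) && kind != "identity") {
    out$id <- paste0(sample$id, "_", kind)
  }
  out
}

#' The 8-element flip/rotation orbit of a sample
#'
#' Returns the 8 samples obtained by composing the horizontal flip with
#' rotations of 0/90/180/270 degrees, in the fixed order of
#' [dihedral_kinds]. The mask undergoes the identical transform as the
#' image. For an asymmetric input all 8 outputs are pairwise distinct; for
#' a fully symmetric input they coincide.
#'
#' @param sample a `fissure_sample`.
#' @return a list of 8 samples.
#' @export
dihedral_orbit <- function(sample) {
  lapply(dihedral_kinds, function(k) dihedral_transform(sample, k))
}

#' Random crop applied jointly to image and mask
#'
#' The crop offset is uniform over all valid positions and identical for
#' image and mask; deterministic given the seed.
#'
#' @param sample a `fissure_sample`.
#' @param size `(h, w)` crop size, each at most the sample dimension.
#' @param seed integer seed.
#' @return the cropped sample.
#' @export
random_crop <- function(sample, size, seed = 1L) {
  d <- dim(sample$image)
  h <- size[1]; w <- size[2]
  if (h > d[1] || w > d[2]) {
    stop("crop size ", h, "x", w, " exceeds sample size ",
         d[1], "x", d[2])
  }
  off <- withr::with_seed(derive_seed(seed, "crop"), {
    c(sample.int(d[1] - h + 1L, 1) - 1L, sample.int(d[2] - w + 1L, 1) - 1L)
  })
  out <- sample
  out$image <- sample$image[off[1] + seq_len(h), off[2] + seq_len(w), ,
                            drop = FALSE]
  if (!is.null(sample$mask)) {
    out$mask <- sample$mask[off[1] + seq_len(h), off[2] + seq_len(w),
                            drop = FALSE]
  }
  if (!is.null(sample$id)) out$id <- paste0(sample$id, "_crop", seed)
  out
}

#' Resize a sample to a target size
#'
#' Bilinear interpolation for the image (re-quantized to the 8-bit grid),
#' nearest-neighbor for the mask so labels stay binary.
#'
#' @param sample a `fissure_sample`.
#' @param size target `(H, W)`.
#' @return the resized sample.
#' @export
resize_sample <- function(sample, size) {
  d <- dim(sample$image)
  if (d[1] == size[1] && d[2] == size[2]) return(sample)
  out <- sample
  img4 <- as4d(sample$image)
  res <- resize_bilinear_cpp(img4, as.integer(size[1]), as.integer(size[2]))
  out$image <- quantize8(array(res, c(size[1], size[2], d[3])))
  if (!is.null(sample$mask)) {
    ih <- pmin(d[1], floor((seq_len(size[1]) - 0.5) * d[1] / size[1]) + 1L)
    iw <- pmin(d[2], floor((seq_len(size[2]) - 0.5) * d[2] / size[2]) + 1L)
    out$mask <- sample$mask[ih, iw, drop = FALSE]
  }
  out
}

#' Amplify a dataset by the dihedral orbit and optional random crops
#'
#' Every sample is replaced by its 8-element flip/rotation orbit; when
#' `"crop"` is among `ops`, `crops_per_sample` random crops of `crop_size`
#' are additionally taken from each original sample and resized back to its
#' resolution. Output count is `8 * n` plus the crops. Deterministic given
#' the seed.
#'
#' @param samples list of `fissure_sample`s.
#' @param ops nonempty character vector from `c("orbit", "crop")`.
#' @param seed integer seed (used by the crops).
#' @param crop_size `(h, w)` for `"crop"`.
#' @param crops_per_sample crops per input sample.
#' @return the augmented list of samples.
#' @export
augment_dataset <- function(samples, ops = "orbit", seed = 1L,
                            crop_size = NULL, crops_per_sample = 1L) {
  if (!length(ops)) stop("ops must be nonempty")
  bad <- setdiff(ops, c("orbit", "crop"))
  if (length(bad)) stop("unknown augmentation op(s): ",
                        paste(bad, collapse = ", "))
  out <- list()
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    if ("orbit" %in% ops) {
      out <- c(out, dihedral_orbit(s))
    } else {
      out <- c(out, list(s))
    }
    if ("crop" %in% ops) {
      if (is.null(crop_size)) stop("crop_size is required for the crop op")
      for (j in seq_len(crops_per_sample)) {
        cs <- random_crop(s, crop_size,
                          seed = derive_seed(seed, paste0(i, "-", j)))
        out <- c(out, list(resize_sample(cs, dim(s$image)[1:2])))
      }
    }
  }
  out
}
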