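#' Derive a stage-specific random seed from a global seed
#'
#' Stable arithmetic fan-out of one global seed into independent per-stage
#' seeds, so that pipeline stages (data generation, augmentation, weight
#' initialization, batch shuffling, ...) can be rerun in isolation while the
#' whole experiment stays reproducible. The result is always a positive
#' integer below 2^31.
#'
#' @param seed integer global seed.
#' @param label character tag naming the consumer of the derived seed.
#' @return an integer seed.
#' @export
#' @examples
#' derive_seed(1, "train")
derive_seed <- function(seed, label) {
  h <- 0
  for (code in utf8ToInt(as.character(label))) {
    h <- (h * 31 + code) %% 2147483629
  }
  s <- as.numeric(seed) %% 2147483629
  as.integer((h + s * 7919 + 1) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coerce an (H,W,C) activation to (H,W,C,1); pass 4d arrays through.
as4d <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array with a dim attribute")
  if (length(d) == 2) {
    dim(x) <- c(d, 1L, 1L)
  } else if (length(d) == 3) {
    dim(x) <- c(d, 1L)
  } else if (length(d) != 4) {
    stop("expected a 2d, 3d or 4d array")
  }
  x
}

# Per-channel sum of an (H,W,C,N) array -> length-C vector.
chan_sum <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3], d[4])
  cs <- colSums(x)            # (C, N)
  if (is.matrix(cs)) rowSums(cs) else cs
}

# Per-channel mean.
chan_mean <- function(x) {
  d <- dim(x)
  chan_sum(x) / (d[1] * d[2] * d[4])
}

# Expand a (1,1,C,N) gate to (H,W,C,N).
expand_cn <- function(g, H, W) {
  d <- dim(g)
  array(rep(as.vector(g), each = H * W), dim = c(H, W, d[3], d[4]))
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Round an intensity array to the 8-bit grid while keeping doubles.
quantize8 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  round(x)
}
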