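# Network building blocks: conv/BN/ReLU units, Inception groups, residual
# and squeeze-excite blocks, large-kernel GCN modules and BR refinement
# blocks. The nx_* helpers append nodes to a graph_builder and return the
# name of the block's output node. Weight initialization draws from the
# caller's RNG state (He-style for convolutions, zeros for biases), so a
# single set.seed() before building makes the whole model reproducible.

nx_conv <- function(gb, name, input, kh, kw, cin, cout, bias = TRUE,
                    zero = FALSE, pad = "same") {
  w <- if (zero) {
    array(0, c(kh, kw, cin, cout))
  } else {
    he_init(c(kh, kw, cin, cout), kh * kw * cin)
  }
  b <- if (bias) numeric(cout) else NULL
  padh <- if (identical(pad, "same")) as.integer((kh - 1) / 2) else 0L
  padw <- if (identical(pad, "same")) as.integer((kw - 1) / 2) else 0L
  gb$add(name, "conv", input, params = list(w = w, b = b),
         args = list(padh = padh, padw = padw))
}

nx_dwconv <- function(gb, name, input, kh, kw, channels, bias = FALSE) {
  w <- he_init(c(kh, kw, channels), kh * kw)
  b <- if (bias) numeric(channels) else NULL
  gb$add(name, "dwconv", input, params = list(w = w, b = b),
         args = list(padh = as.integer((kh - 1) / 2),
                     padw = as.integer((kw - 1) / 2)))
}

nx_bn <- function(gb, name, input, channels, momentum = 0.9, eps = 1e-5) {
  gb$add(name, "bn", input,
         params = list(gamma = rep(1, channels), beta = rep(0, channels)),
         args = list(momentum = momentum, eps = eps),
         stats = list(mean = rep(0, channels), var = rep(1, channels)))
}

nx_relu <- function(gb, name, input) gb$add(name, "relu", input)

nx_pool2 <- function(gb, name, input) {
  gb$add(name, "pool", input, args = list(k = 2L, stride = 2L, pad = 0L))
}

# conv (no bias) + batch norm + ReLU, the standard encoder unit.
nx_cbr <- function(gb, prefix, input, k, cin, cout) {
  c1 <- nx_conv(gb, paste0(prefix, "_conv"), input, k, k, cin, cout,
                bias = FALSE)
  b1 <- nx_bn(gb, paste0(prefix, "_bn"), c1, cout)
  nx_relu(gb, paste0(prefix, "_relu"), b1)
}

# ---- Inception -------------------------------------------------------------

# Branch widths for an Inception group of total output width cout:
# 1x1, 1x1->3x3, 1x1->5x5 and 3x3-maxpool->1x1 branches in the classic
# 1/4 : 1/2 : 1/8 : 1/8 proportion, with dimensionality-reducing 1x1 convs
# in front of the 3x3 and 5x5 branches.
inception_channels <- function(cout) {
  if (cout %% 8 != 0) {
    stop("inception output channels must be a multiple of 8, got ", cout)
  }
  list(o1 = cout / 4, r3 = cout / 4, o3 = cout / 2,
       r5 = max(4, cout / 16), o5 = cout / 8, op = cout / 8)
}

add_inception <- function(gb, prefix, input, cin, ch) {
  b1 <- nx_cbr(gb, paste0(prefix, "_b1"), input, 1, cin, ch$o1)
  r3 <- nx_cbr(gb, paste0(prefix, "_b2r"), input, 1, cin, ch$r3)
  b2 <- nx_cbr(gb, paste0(prefix, "_b2"), r3, 3, ch$r3, ch$o3)
  r5 <- nx_cbr(gb, paste0(prefix, "_b3r"), input, 1, cin, ch$r5)
  b3 <- nx_cbr(gb, paste0(prefix, "_b3"), r5, 5, ch$r5, ch$o5)
  p <- gb$add(paste0(prefix, "_b4pool"), "pool", input,
              args = list(k = 3L, stride = 1L, pad = 1L))
  b4 <- nx_cbr(gb, paste0(prefix, "_b4"), p, 1, cin, ch$op)
  gb$add(paste0(prefix, "_cat"), "concat", c(b1, b2, b3, b4))
}

# ---- residual / squeeze-excite ---------------------------------------------

add_se_gate <- function(gb, prefix, input, channels, reduction = 4) {
  mid <- max(4, channels %/% reduction)
  gp <- gb$add(paste0(prefix, "_gap"), "gap", input)
  f1 <- nx_conv(gb, paste0(prefix, "_fc1"), gp, 1, 1, channels, mid)
  r1 <- nx_relu(gb, paste0(prefix, "_fc1_relu"), f1)
  f2 <- nx_conv(gb, paste0(prefix, "_fc2"), r1, 1, 1, mid, channels)
  sg <- gb$add(paste0(prefix, "_sigmoid"), "sigmoid", f2)
  gb$add(paste0(prefix, "_scale"), "scale", c(input, sg))
}

add_residual <- function(gb, prefix, input, cin, cout, use_se = FALSE) {
  c1 <- nx_cbr(gb, paste0(prefix, "_c1"), input, 3, cin, cout)
  c2 <- nx_conv(gb, paste0(prefix, "_c2_conv"), c1, 3, 3, cout, cout,
                bias = FALSE)
  branch <- nx_bn(gb, paste0(prefix, "_c2_bn"), c2, cout)
  if (use_se) branch <- add_se_gate(gb, paste0(prefix, "_se"), branch, cout)
  shortcut <- input
  if (cin != cout) {
    sc <- nx_conv(gb, paste0(prefix, "_proj"), input, 1, 1, cin, cout,
                  bias = FALSE)
    shortcut <- nx_bn(gb, paste0(prefix, "_proj_bn"), sc, cout)
  }
  s <- gb$add(paste0(prefix, "_add"), "add", c(branch, shortcut))
  nx_relu(gb, paste0(prefix, "_relu"), s)
}

# ---- GCN / BR --------------------------------------------------------------

# Large-kernel GCN module: the sum of two separable branches,
# (k x 1 then 1 x k) and (1 x k then k x 1), each densely connecting a
# k x k receptive field to the output channels at O(k) parameter cost.
# Purely linear: no normalization or nonlinearity inside, no biases.
# The "separable" variant additionally factors every constituent
# convolution into a depthwise spatial kernel followed by a pointwise
# (1 x 1) channel mix.
add_gcn <- function(gb, prefix, input, cin, cout, k, variant = "dense") {
  if (k %% 2 == 0) stop("GCN kernel size must be odd, got ", k)
  mk <- function(name, inp, kh, kw, ci, co) {
    if (variant == "dense") {
      nx_conv(gb, name, inp, kh, kw, ci, co, bias = FALSE)
    } else {
      d <- nx_dwconv(gb, paste0(name, "_dw"), inp, kh, kw, ci)
      nx_conv(gb, paste0(name, "_pw"), d, 1, 1, ci, co, bias = FALSE)
    }
  }
  a1 <- mk(paste0(prefix, "_a1"), input, k, 1, cin, cout)
  a2 <- mk(paste0(prefix, "_a2"), a1, 1, k, cout, cout)
  b1 <- mk(paste0(prefix, "_b1"), input, 1, k, cin, cout)
  b2 <- mk(paste0(prefix, "_b2"), b1, k, 1, cout, cout)
  gb$add(paste0(prefix, "_sum"), "add", c(a2, b2))
}

# Boundary Refinement: x + conv(relu(conv(x))), 3x3 kernels, channels
# preserved. The second convolution is zero-initialized so the block is an
# exact identity at initialization and learns an additive boundary
# correction.
add_br <- function(gb, prefix, input, channels) {
  c1 <- nx_conv(gb, paste0(prefix, "_c1"), input, 3, 3, channels, channels)
  r1 <- nx_relu(gb, paste0(prefix, "_relu"), c1)
  c2 <- nx_conv(gb, paste0(prefix, "_c2"), r1, 3, 3, channels, channels,
                zero = TRUE)
  gb$add(paste0(prefix, "_out"), "add", c(input, c2))
}

# ---- standalone block constructors (for inspection and testing) ------------

block_config <- function(kind, ...) {
  c(list(kind = kind, check_input = FALSE), list(...))
}

#' Standalone Inception block
#'
#' Four parallel branches — 1x1; 1x1 then 3x3; 1x1 then 5x5; 3x3 max-pool
#' then 1x1 — concatenated along channels. Spatial size is preserved; output
#' width is the sum of the four branch widths.
#'
#' @param c_in input channels.
#' @param branch_channels integer vector `(o1, o3, o5, op)` of per-branch
#'   output widths; the reduction widths in front of the 3x3/5x5 branches
#'   default to half the branch width (minimum 4).
#' @param seed integer seed for weight initialization.
#' @return a `fissure_model` wrapping the single block.
#' @export
new_inception_block <- function(c_in, branch_channels = c(8, 16, 4, 4),
                                seed = 0L) {
  stopifnot(length(branch_channels) == 4, all(branch_channels >= 1))
  ch <- list(o1 = branch_channels[1],
             r3 = max(4, branch_channels[2] %/% 2),
             o3 = branch_channels[2],
             r5 = max(4, branch_channels[3] %/% 2),
             o5 = branch_channels[3],
             op = branch_channels[4])
  withr::with_seed(derive_seed(seed, "inception"), {
    gb <- graph_builder()
    out <- add_inception(gb, "inc", ".input", c_in, ch)
    finish_model(block_config("inception", c_in = c_in, channels = ch), gb, out)
  })
}

#' Standalone residual block (optionally with squeeze-excite recalibration)
#'
#' `f(x) + shortcut(x)` with `f` = conv-BN-ReLU-conv-BN (3x3 kernels); the
#' shortcut is the identity when `c_in == c_out`, else a 1x1 projection.
#' With `use_se = TRUE` the residual branch is rescaled per channel by a
#' squeeze (global average) and excite (two-layer sigmoid gate) factor.
#'
#' @param c_in,c_out input/output channels.
#' @param use_se logical, add the squeeze-excite gate.
#' @param seed integer seed for weight initialization.
#' @return a `fissure_model`.
#' @export
new_residual_block <- function(c_in, c_out = c_in, use_se = FALSE, seed = 0L) {
  withr::with_seed(derive_seed(seed, "residual"), {
    gb <- graph_builder()
    out <- add_residual(gb, "res", ".input", c_in, c_out, use_se = use_se)
    finish_model(block_config("residual", c_in = c_in, c_out = c_out), gb, out)
  })
}

#' Standalone squeeze-excite gate
#'
#' Channel-wise recalibration: global average pool, a two-layer bottleneck
#' with sigmoid output in `[0, 1]`, multiplied back onto the input.
#'
#' @param channels number of channels.
#' @param reduction bottleneck reduction factor.
#' @param seed integer seed.
#' @return a `fissure_model`.
#' @export
new_se_block <- function(channels, reduction = 4, seed = 0L) {
  withr::with_seed(derive_seed(seed, "se"), {
    gb <- graph_builder()
    out <- add_se_gate(gb, "se", ".input", channels, reduction)
    finish_model(block_config("se", channels = channels), gb, out)
  })
}

#' Standalone Global Convolutional Network (GCN) module
#'
#' Approximates a dense k x k convolution by the sum of two separable
#' branches, `(k x 1 -> 1 x k)` and `(1 x k -> k x 1)`, mapping `c_in`
#' channels to `out_channels` with no bias and no nonlinearity. The
#' `"separable"` variant factors each constituent convolution into a
#' depthwise spatial kernel followed by a pointwise 1x1 channel mix.
#'
#' @param c_in input channels.
#' @param k odd kernel size.
#' @param out_channels output channels (typically the number of classes).
#' @param variant `"dense"` or `"separable"`.
#' @param seed integer seed.
#' @return a `fissure_model`.
#' @export
new_gcn_block <- function(c_in, k = 7L, out_channels = 2L,
                          variant = c("dense", "separable"), seed = 0L) {
  variant <- match.arg(variant)
  withr::with_seed(derive_seed(seed, "gcn"), {
    gb <- graph_builder()
    out <- add_gcn(gb, "gcn", ".input", c_in, out_channels, k, variant)
    finish_model(block_config("gcn", c_in = c_in, k = k,
                              out_channels = out_channels, variant = variant),
                 gb, out)
  })
}

#' Standalone Boundary Refinement (BR) block
#'
#' Residual refinement `x + conv(relu(conv(x)))` with 3x3 kernels and
#' channels preserved. The second convolution starts at zero, so a freshly
#' built block is an exact identity.
#'
#' @param channels number of channels.
#' @param seed integer seed.
#' @return a `fissure_model`.
#' @export
new_br_block <- function(channels, seed = 0L) {
  withr::with_seed(derive_seed(seed, "br"), {
    gb <- graph_builder()
    out <- add_br(gb, "br", ".input", channels)
    finish_model(block_config("br", channels = channels), gb, out)
  })
}

# ---- closed-form parameter counts -----------------------------------------

#' Parameter count of a single convolution
#'
#' `kh * kw * c_in * c_out` weights plus `c_out` biases when `bias` is set.
#'
#' @param kh,kw kernel height/width.
#' @param c_in,c_out channel counts.
#' @param bias logical.
#' @return integer count.
#' @export
conv_params <- function(kh, kw, c_in, c_out, bias = TRUE) {
  as.integer(kh * kw * c_in * c_out + if (bias) c_out else 0L)
}

#' Parameter count of a GCN module
#'
#' Closed-form count matching [new_gcn_block()] exactly. The dense variant
#' has `2 * (k * c_in * c_out + k * c_out^2)` weights — linear in `k`, versus
#' the quadratic `k^2 * c_in * c_out` of a full dense k x k convolution
#' (see [conv_params()]).
#'
#' @param k odd kernel size.
#' @param c_in,c_out channel counts.
#' @param variant `"dense"` or `"separable"`.
#' @return integer count.
#' @export
gcn_params <- function(k, c_in, c_out, variant = c("dense", "separable")) {
  variant <- match.arg(variant)
  if (variant == "dense") {
    # two branches, each: (k x 1, c_in -> c_out) then (1 x k, c_out -> c_out)
    as.integer(2 * (k * c_in * c_out + k * c_out * c_out))
  } else {
    # each constituent conv becomes depthwise (k spatial weights per input
    # channel) + pointwise (c_in * c_out)
    inner <- function(ci, co) k * ci + ci * co
    as.integer(2 * (inner(c_in, c_out) + inner(c_out, c_out)))
  }
}
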